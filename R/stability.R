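#' Normalize time-course counts to baseline abundance
#'
#' Converts a count tensor (oligo x timepoint x replicate) into per-replicate
#' normalized abundances \eqn{C_i(t) / \bar C_i(t_0)}, where the denominator
#' is the mean across replicates at the first (baseline) timepoint, which is
#' re-indexed to t = 0. Oligos with zero baseline mean, or with all-zero
#' counts at every post-baseline timepoint, are dropped and reported in the
#' `"dropped"` attribute rather than raising an error. Remaining zero counts
#' are replaced by `pseudocount` before taking logs.
#'
#' If a row named `spike_id` is present, every log-abundance is measured
#' relative to the spike-in (the spike's log-normalized value at the same
#' timepoint/replicate is subtracted) and the spike row is removed. This
#' anchors absolute decay rates in fixed-depth (compositional) sequencing;
#' pass `spike_id = NULL` to disable.
#'
#' Per-timepoint regression weights are the inverse standard deviation
#' across replicates, computed on the log scale by default
#' (`weight_scale = "raw"` uses the normalized values instead). Timepoints
#' with zero spread receive the largest finite weight seen for that oligo.
#'
#' @param counts 3-d array as produced by [simulate_counts()] or
#'   [read_counts_tsv()].
#' @param spike_id row name of a stable spike-in species, or NULL.
#' @param pseudocount value replacing zero counts before the log transform.
#' @param weight_scale `"log"` or `"raw"`; scale on which replicate SDs are
#'   taken.
#' @return A long data.frame of class `"normalized_series"` with columns
#'   `oligo_id`, `timepoint` (minutes since baseline), `replicate`, `norm`,
#'   `log_norm`, `weight`; attributes `"dropped"` (data.frame of oligo_id,
#'   reason) and `"timepoints"`.
#' @export
normalize_counts <- function(counts, spike_id = "spike_in", pseudocount = 0.5,
                             weight_scale = c("log", "raw")) {
  weight_scale <- match.arg(weight_scale)
  stopifnot(length(dim(counts)) == 3)
  tps <- attr(counts, "timepoints")
  if (is.null(tps)) tps <- as.numeric(dimnames(counts)[[2]])
  if (anyNA(tps)) stop("timepoints must be numeric (dimnames or attribute)")
  t_rel <- tps - tps[1]
  ids <- dimnames(counts)[[1]]
  nrep <- dim(counts)[3]

  base_mean <- rowMeans(counts[, 1, , drop = FALSE], dims = 1)
  post <- counts[, -1, , drop = FALSE]
  all_zero_post <- if (dim(post)[2] == 0) {
    rep(FALSE, dim(counts)[1])
  } else {
    apply(post == 0, 1, all)
  }
  drop_zero_base <- base_mean == 0
  dropped <- data.frame(
    oligo_id = c(ids[drop_zero_base], ids[!drop_zero_base & all_zero_post]),
    reason = c(rep("zero_baseline", sum(drop_zero_base)),
               rep("all_zero_post", sum(!drop_zero_base & all_zero_post))),
    stringsAsFactors = FALSE)
  keep <- !drop_zero_base & !all_zero_post

  x <- counts[keep, , , drop = FALSE]
  x[x == 0] <- pseudocount
  norm <- x / base_mean[keep]
  lognorm <- log(norm)

  has_spike <- !is.null(spike_id) && spike_id %in% rownames(norm)
  if (has_spike) {
    sl <- lognorm[spike_id, , ]                       # timepoint x replicate
    lognorm <- sweep(lognorm, c(2, 3), sl, "-")
    norm <- exp(lognorm)
    sel <- rownames(norm) != spike_id
    norm <- norm[sel, , , drop = FALSE]
    lognorm <- lognorm[sel, , , drop = FALSE]
  }

  wmat <- lognorm
  sd_src <- if (weight_scale == "log") lognorm else norm
  sds <- apply(sd_src, c(1, 2), sd)                   # oligo x timepoint
  w <- 1 / sds
  w[!is.finite(w)] <- NA
  maxw <- apply(w, 1, function(z) if (all(is.na(z))) 1 else max(z, na.rm = TRUE))
  for (j in seq_len(ncol(w))) w[is.na(w[, j]), j] <- maxw[is.na(w[, j])]

  n <- nrow(norm)
  raw <- x[rownames(norm), , , drop = FALSE]
  out <- data.frame(
    oligo_id = rep(rownames(norm), times = length(t_rel) * nrep),
    timepoint = rep(rep(t_rel, each = n), times = nrep),
    replicate = rep(seq_len(nrep), each = n * length(t_rel)),
    count = as.vector(raw),
    norm = as.vector(norm),
    log_norm = as.vector(lognorm),
    weight = as.vector(w[, rep(seq_along(t_rel), times = nrep)]),
    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  attr(out, "timepoints") <- t_rel
  class(out) <- c("normalized_series", "data.frame")
  out
}

## Internal: weighted least-squares decay fit on one series.
## Returns lambda (negated slope on t), r2 (uncentered for the no-intercept
## form, centered otherwise), weighted MSE and point count.
wls_decay <- function(t, y, w, intercept = FALSE) {
  t <- as.numeric(t); y <- as.numeric(y); w <- as.numeric(w)
  ok <- is.finite(y) & is.finite(t) & is.finite(w) & w > 0
  t <- t[ok]; y <- y[ok]; w <- w[ok]
  if (length(unique(t)) < 2) {
    return(list(lambda = NA_real_, r2 = NA_real_, mse = NA_real_,
                n = length(y), valid = FALSE))
  }
  X <- if (intercept) cbind(`(Intercept)` = 1, t = t) else cbind(t = t)
  fit <- lm.wfit(X, y, w)
  slope <- fit$coefficients["t"]
  e <- fit$residuals
  rss <- sum(w * e^2)
  tss <- if (intercept) sum(w * (y - sum(w * y) / sum(w))^2) else sum(w * y^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(lambda = unname(-slope), r2 = r2, mse = rss / sum(w),
       n = length(y), valid = TRUE)
}

#' Fit per-oligo exponential decay
#'
#' Fits the log-linear decay model
#' \eqn{\ln(C_i(t)/C_i(0)) = -\lambda t_i + \epsilon_i} to each oligo's
#' normalized series by weighted least squares through the origin (the
#' baseline is t = 0 and its normalized mean is 1 by construction;
#' `intercept = TRUE` adds an intercept for sensitivity analysis). Half-life
#' is \eqn{\ln 2 / \hat\lambda}. Fits pass QC when \eqn{R^2 > 0.5} and the
#' weighted mean squared error is below 1; for the no-intercept form
#' \eqn{R^2} is uncentered.
#'
#' @param series a [normalize_counts()] result.
#' @param intercept include an intercept term.
#' @param qc_r2,qc_mse QC thresholds.
#' @return A data.frame of class `"decay_fits"` with columns `oligo_id`,
#'   `lambda`, `half_life_min`, `r2`, `mse`, `n_points`, `qc_pass`.
#' @export
#' @examples
#' cfg <- sim_config(n_pairs = 3, seed = 2)
#' lib <- generate_library(cfg)
#' fits <- fit_decay(normalize_counts(simulate_counts(lib$truth, cfg)))
fit_decay <- function(series, intercept = FALSE, qc_r2 = 0.5, qc_mse = 1) {
  stopifnot(inherits(series, "normalized_series"))
  idx <- split(seq_len(nrow(series)), series$oligo_id)
  ids <- names(idx)
  if (length(ids) == 0) {
    out <- data.frame(oligo_id = character(), lambda = numeric(),
                      half_life_min = numeric(), r2 = numeric(),
                      mse = numeric(), n_points = integer(),
                      qc_pass = logical())
    class(out) <- c("decay_fits", "data.frame")
    return(out)
  }
  out <- data.frame(oligo_id = ids, lambda = NA_real_, half_life_min = NA_real_,
                    r2 = NA_real_, mse = NA_real_, n_points = NA_integer_,
                    qc_pass = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    f <- wls_decay(series$timepoint[i], series$log_norm[i], series$weight[i],
                   intercept = intercept)
    out$lambda[k] <- f$lambda
    out$half_life_min[k] <- if (isTRUE(f$lambda > 0)) log(2) / f$lambda else NA_real_
    out$r2[k] <- f$r2
    out$mse[k] <- f$mse
    out$n_points[k] <- f$n
    out$qc_pass[k] <- f$valid && isTRUE(f$r2 > qc_r2) && isTRUE(f$mse < qc_mse)
  }
  rownames(out) <- NULL
  class(out) <- c("decay_fits", "data.frame")
  out
}

#' @export
print.decay_fits <- function(x, ...) {
  cat("Decay fits for", nrow(x), "oligos;", sum(x$qc_pass), "pass QC\n")
  hl <- intersect(c("half_life_min", "half_life_hr"), names(x))[1]
  cat("  median half-life:",
      round(median(x[[hl]][x$qc_pass], na.rm = TRUE), 2),
      if (endsWith(hl, "min")) "min\n" else "hr\n")
  invisible(x)
}

#' @export
summary.decay_fits <- function(object, ...) {
  cat("Decay fits:", nrow(object), "oligos,", sum(object$qc_pass), "QC-pass\n")
  print(summary(object[, c("lambda", "half_life_min", "r2", "mse")]))
  invisible(object)
}

## Internal: the genotype-by-time interaction fit for one ref/mt pair.
## Weights: per-timepoint replicate SDs of log-abundance, pooled across the
## two alleles (root mean square), inverse-variance weighted. Per-allele
## intercepts absorb the shared baseline-normalization error; the printed
## through-origin form is available with intercept = FALSE.
pair_engine <- function(t, y, g, w, intercept = TRUE) {
  X <- if (intercept) cbind(`(Intercept)` = 1, G = g, t = t, `t:G` = t * g)
       else cbind(t = t, `t:G` = t * g)
  fit <- lm.wfit(X, y, w)
  k <- ncol(X)
  df <- length(y) - k
  e <- fit$residuals
  s2 <- sum(w * e^2) / df
  R <- fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE]
  XtWXi <- chol2inv(R)
  se <- sqrt(diag(XtWXi) * s2)
  names(se) <- colnames(X)
  theta <- unname(fit$coefficients["t:G"])
  se_th <- unname(se["t:G"])
  p <- if (se_th < 1e-10 && abs(theta) < 1e-10) {
    # numerically exact fit: no evidence against theta = 0
    1
  } else if (se_th == 0) {
    0
  } else {
    2 * pt(-abs(theta / se_th), df)
  }
  list(beta = unname(fit$coefficients["t"]), theta = theta, se = se_th, p = p,
       df = df)
}

#' Test ref-vs-mt stability differences
#'
#' Pools the normalized series of the two alleles of each pair and fits the
#' weighted interaction model
#' \eqn{\ln(C_i(t)/C_i(0)) = \beta t_i + \theta\, t_i G_i + \epsilon_i}
#' (G = 0 for ref, 1 for mt). The genotype-by-time coefficient \eqn{\theta}
#' measures the variant's effect on the decay rate; its two-sided p-value is
#' corrected across pairs with [adjust_fdr()]. By default each allele also
#' receives its own intercept (absorbing the shared baseline-normalization
#' error) and observations are weighted by their read counts — the Poisson
#' inverse variance of a log count — because weights estimated from the
#' spread of a few replicates are so noisy that they break the t-test's
#' calibration (see the methods vignette). `weights = "pooled_sd"` restores
#' inverse-SD weighting (replicate SDs pooled across the two alleles),
#' `weights = "none"` disables weighting, and `intercept = FALSE` restores
#' the plain through-origin form.
#'
#' Pairs with a missing allele, or (when `fits` is supplied) with an allele
#' failing QC, are excluded and counted in the `"excluded"` attribute.
#'
#' @param series a [normalize_counts()] result covering both alleles.
#' @param oligos data.frame with `oligo_id`, `pair_id`, `allele` (the
#'   `oligos` element of [generate_library()], or [read_library()]).
#' @param fits optional [fit_decay()] result used for QC gating.
#' @param intercept per-allele intercepts (default TRUE).
#' @param weights `"counts"`, `"pooled_sd"` or `"none"`.
#' @param alpha q-value threshold for classification.
#' @param fdr_method passed to [adjust_fdr()].
#' @return A data.frame of class `"pair_tests"`: `pair_id`, `beta`, `theta`,
#'   `se`, `p`, `q`, `class` (destabilizing / stabilizing /
#'   not_significant).
#' @export
test_pairs <- function(series, oligos, fits = NULL, intercept = TRUE,
                       weights = c("counts", "pooled_sd", "none"),
                       alpha = 0.05, fdr_method = "BH") {
  weights <- match.arg(weights)
  stopifnot(inherits(series, "normalized_series"),
            all(c("oligo_id", "pair_id", "allele") %in% names(oligos)))
  qc_ok <- if (is.null(fits)) NULL else fits$oligo_id[fits$qc_pass]
  present <- unique(series$oligo_id)
  omap <- oligos[oligos$oligo_id %in% present, c("oligo_id", "pair_id", "allele")]
  if (!is.null(qc_ok)) omap <- omap[omap$oligo_id %in% qc_ok, , drop = FALSE]
  cnt <- table(omap$pair_id)
  complete <- names(cnt)[cnt == 2]
  excluded <- setdiff(unique(oligos$pair_id), complete)

  sidx <- split(seq_len(nrow(series)), series$oligo_id)
  res <- vector("list", length(complete))
  for (k in seq_along(complete)) {
    pid <- complete[k]
    sub <- omap[omap$pair_id == pid, ]
    id_ref <- sub$oligo_id[sub$allele == "ref"]
    id_mt <- sub$oligo_id[sub$allele == "mt"]
    if (length(id_ref) != 1 || length(id_mt) != 1) {
      excluded <- c(excluded, pid)
      next
    }
    i_ref <- sidx[[id_ref]]; i_mt <- sidx[[id_mt]]
    t <- c(series$timepoint[i_ref], series$timepoint[i_mt])
    y <- c(series$log_norm[i_ref], series$log_norm[i_mt])
    g <- rep(c(0, 1), c(length(i_ref), length(i_mt)))
    w <- pair_weights(series, i_ref, i_mt, weights)
    pe <- pair_engine(t, y, g, w, intercept = intercept)
    res[[k]] <- data.frame(pair_id = pid, beta = pe$beta, theta = pe$theta,
                           se = pe$se, p = pe$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(pair_id = character(), beta = numeric(),
                                      theta = numeric(), se = numeric(),
                                      p = numeric())
  out$q <- adjust_fdr(out$p, method = fdr_method)
  out$class <- ifelse(out$q < alpha,
                      ifelse(out$theta < 0, "destabilizing", "stabilizing"),
                      "not_significant")
  rownames(out) <- NULL
  attr(out, "excluded") <- unique(excluded)
  class(out) <- c("pair_tests", "data.frame")
  out
}

## Internal: regression weights for one pair, aligned with
## c(rows_ref, rows_mt).
## "counts": the observation's read count, i.e. the Poisson inverse
## variance of its log -- fully determined by the data, so the t-test's
## null distribution stays clean. "pooled_sd": inverse of the per-timepoint
## replicate SD pooled across the two alleles (root mean square); the
## classical description, but SDs estimated from a few replicates are noisy
## and correlated with the residuals they scale, which fattens the test's
## tail. "none": unweighted.
pair_weights <- function(series, i_ref, i_mt, scheme) {
  if (scheme == "none") return(rep(1, length(i_ref) + length(i_mt)))
  if (scheme == "counts") {
    if (is.null(series$count)) {
      stop("count-based weights need a 'count' column in the series")
    }
    return(c(series$count[i_ref], series$count[i_mt]))
  }
  pooled_pair_weights(series, i_ref, i_mt)
}

## Internal: the "pooled_sd" scheme of pair_weights().
pooled_pair_weights <- function(series, i_ref, i_mt) {
  sd_by_t <- function(i) {
    tapply(series$log_norm[i], series$timepoint[i], sd)
  }
  s_ref <- sd_by_t(i_ref); s_mt <- sd_by_t(i_mt)
  tp <- names(s_ref)
  pooled <- sqrt((s_ref[tp]^2 + s_mt[tp]^2) / 2)
  w <- as.numeric(1 / pooled)
  names(w) <- tp
  if (any(!is.finite(w))) {
    mx <- if (any(is.finite(w))) max(w[is.finite(w)]) else 1
    w[!is.finite(w)] <- mx
  }
  unname(c(w[as.character(series$timepoint[i_ref])],
           w[as.character(series$timepoint[i_mt])]))
}

#' Test a single ref/mt pair
#'
#' Convenience wrapper around the interaction engine of [test_pairs()] for
#' two already-normalized series.
#'
#' @param ref,mt single-oligo subsets of a [normalize_counts()] result.
#' @inheritParams test_pairs
#' @return A one-row data.frame with `beta`, `theta`, `se`, `p`.
#' @export
test_pair <- function(ref, mt, intercept = TRUE,
                      weights = c("counts", "pooled_sd", "none")) {
  weights <- match.arg(weights)
  t <- c(ref$timepoint, mt$timepoint)
  y <- c(ref$log_norm, mt$log_norm)
  g <- rep(c(0, 1), c(nrow(ref), nrow(mt)))
  series <- data.frame(timepoint = t, log_norm = y)
  series$count <- c(ref$count, mt$count)
  w <- pair_weights(series, seq_len(nrow(ref)),
                    nrow(ref) + seq_len(nrow(mt)), weights)
  pe <- pair_engine(t, y, g, w, intercept = intercept)
  data.frame(beta = pe$beta, theta = pe$theta, se = pe$se, p = pe$p)
}

#' Benjamini-Hochberg (or Storey) q-values
#'
#' @param p p-values in \[0, 1\].
#' @param method `"BH"` (step-up false discovery rate, default) or
#'   `"storey"` (BH scaled by the fixed-lambda 0.5 estimate of the null
#'   proportion pi0).
#' @return q-values in the input order; empty input gives an empty vector.
#' @export
adjust_fdr <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5, na.rm = TRUE) / 0.5)
    q <- pmin(1, q * pi0)
  }
  q
}

#' Classify pairs by half-life fold change
#'
#' Direction-symmetric rule: a pair is called significant when the larger of
#' the two half-life ratios reaches `threshold` (default 1.5-fold). Pairs
#' with non-positive or non-finite half-lives are excluded (NA).
#'
#' @param ref_halflife,mt_halflife half-lives in the same units.
#' @param threshold fold-change cutoff (>= 1).
#' @return Character vector: `"significant"`, `"non_significant"`, or NA for
#'   excluded pairs.
#' @export
classify_pairs_by_foldchange <- function(ref_halflife, mt_halflife,
                                         threshold = 1.5) {
  stopifnot(threshold >= 1)
  ratio <- mt_halflife / ref_halflife
  fold <- pmax(ratio, 1 / ratio)
  out <- ifelse(fold >= threshold, "significant", "non_significant")
  bad <- !is.finite(ref_halflife) | !is.finite(mt_halflife) |
    ref_halflife <= 0 | mt_halflife <= 0
  out[bad] <- NA_character_
  out
}

#' @export
print.pair_tests <- function(x, ...) {
  cat("Variant stability tests:", nrow(x), "pairs;",
      sum(x$class != "not_significant"), "significant (",
      sum(x$class == "destabilizing"), "destabilizing /",
      sum(x$class == "stabilizing"), "stabilizing )\n")
  ex <- attr(x, "excluded")
  if (length(ex)) cat("  excluded pairs:", length(ex), "\n")
  invisible(x)
}

#' One-call half-life estimation from a count tensor
#'
#' [normalize_counts()] followed by [fit_decay()].
#'
#' @inheritParams normalize_counts
#' @inheritParams fit_decay
#' @return A `"decay_fits"` data.frame.
#' @export
estimate_halflives <- function(counts, spike_id = "spike_in",
                               pseudocount = 0.5, intercept = FALSE) {
  fit_decay(normalize_counts(counts, spike_id = spike_id,
                             pseudocount = pseudocount),
            intercept = intercept)
}
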