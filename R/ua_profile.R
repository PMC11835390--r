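#' UA-dinucleotide ratio
#'
#' Overlapping UA dinucleotide count divided by (length - 1). Sequences
#' shorter than `min_len` (default 10 nt) are excluded: they get NA and are
#' listed in the `"excluded"` attribute.
#'
#' @param seq character vector of sequences.
#' @param min_len minimum sequence length.
#' @param dimer focal dimer, `"UA"` (default) or `"AU"`.
#' @return Numeric vector of ratios (NA for excluded sequences) with
#'   attribute `"excluded"` (indices).
#' @export
#' @examples
#' ua_ratio("UAUAUAUAUA")  # 5/9
ua_ratio <- function(seq, min_len = 10, dimer = c("UA", "AU")) {
  dimer <- match.arg(dimer)
  seq <- norm_rna(seq)
  len <- nchar(seq)
  out <- rep(NA_real_, length(seq))
  ok <- len >= min_len
  if (any(ok)) {
    set <- Biostrings::RNAStringSet(seq[ok])
    out[ok] <- Biostrings::vcountPattern(dimer, set) / (len[ok] - 1)
  }
  attr(out, "excluded") <- which(!ok)
  out
}

#' Sliding-window UA-ratio profile
#'
#' Computes the UA ratio of every 10-nt window (slid by 1 nt) and
#' normalizes for length by averaging the window ratios into 100
#' position-fraction bins. When a sequence has fewer than 100 windows,
#' empty bins inherit the value of the nearest non-empty bin.
#'
#' @param seq a single sequence (>= `window` nt).
#' @param window window width in nt.
#' @param n_bins number of length-normalized bins.
#' @param dimer focal dimer.
#' @return Numeric vector of `n_bins` bin means; attributes
#'   `"window_ratios"` (raw per-window ratios) and `"bin_counts"` (windows
#'   per bin).
#' @export
sliding_profile <- function(seq, window = 10, n_bins = 100,
                            dimer = c("UA", "AU")) {
  dimer <- match.arg(dimer)
  seq <- norm_rna(seq)
  L <- nchar(seq)
  if (L < window) stop("sequence shorter than the window")
  ch <- strsplit(seq, "")[[1]]
  hit <- ch[-L] == substr(dimer, 1, 1) & ch[-1] == substr(dimer, 2, 2)
  # rolling sum of dimer indicators over the window's (window - 1) slots
  cs <- cumsum(c(0, hit))
  W <- L - window + 1L
  ratios <- (cs[(window - 1L) + seq_len(W)] - cs[seq_len(W)]) / (window - 1L)
  if (W == 1) {
    bin <- 1L
  } else {
    frac <- (seq_len(W) - 0.5) / W
    bin <- pmin(n_bins, pmax(1L, ceiling(frac * n_bins)))
  }
  sums <- tapply(ratios, bin, mean)
  counts <- tabulate(bin, nbins = n_bins)
  prof <- rep(NA_real_, n_bins)
  prof[as.integer(names(sums))] <- sums
  if (anyNA(prof)) {
    filled <- which(!is.na(prof))
    for (b in which(is.na(prof))) {
      prof[b] <- prof[filled[which.min(abs(filled - b))]]
    }
  }
  attr(prof, "window_ratios") <- ratios
  attr(prof, "bin_counts") <- counts
  prof
}

#' Sliding profiles for a set of sequences
#'
#' @param seqs character vector (each >= `window` nt; shorter ones are
#'   dropped with a warning).
#' @inheritParams sliding_profile
#' @return Matrix (sequences x bins).
#' @export
sliding_profiles <- function(seqs, window = 10, n_bins = 100,
                             dimer = "UA") {
  ok <- nchar(seqs) >= window
  if (any(!ok)) warning(sum(!ok), " sequences shorter than the window dropped")
  t(vapply(seqs[ok], function(s) as.numeric(sliding_profile(s, window, n_bins,
                                                            dimer)),
           numeric(n_bins)))
}

#' Per-bin correlation between UA profile and stability
#'
#' Spearman correlation between each profile bin and the half-lives.
#' Constant bins are reported as NA.
#'
#' @param profiles matrix from [sliding_profiles()].
#' @param half_lives numeric vector, one per profile row.
#' @return Numeric vector of per-bin correlations.
#' @export
window_correlation <- function(profiles, half_lives) {
  stopifnot(nrow(profiles) == length(half_lives), nrow(profiles) >= 3)
  apply(profiles, 2, function(b) {
    if (sd(b) == 0) return(NA_real_)
    cor(b, half_lives, method = "spearman")
  })
}

#' Permutation test of group UA-ratio enrichment
#'
#' For every group with more than `min_size` members present in the
#' background, compares the group mean UA ratio with the overall mean by a
#' label-permutation (Fisher-Pitman style) test: `n_perm` random draws of
#' the group size from the background, two-sided on the mean difference.
#' Groups small enough for complete enumeration (`choose(N, k)` up to
#' `exact_limit`) are tested exactly. P-values are Bonferroni-corrected
#' across tested groups; enrichment/depletion is significant below `alpha`.
#'
#' @param values named numeric vector of per-transcript UA ratios (the
#'   background: all transcripts).
#' @param groups data.frame with `group_id`, `transcript_id`.
#' @param n_perm permutation draws.
#' @param seed integer seed.
#' @param min_size groups need more than this many qualified members.
#' @param alpha adjusted-p significance threshold.
#' @param exact_limit enumeration cutoff on `choose(N, k)`.
#' @return data.frame of class `"group_enrichment"`: `group_id`, `n`,
#'   `group_mean`, `background_mean`, `p`, `p_adjusted`, `direction`,
#'   `significant`; attribute `"skipped"` lists undersized groups.
#' @export
group_enrichment <- function(values, groups, n_perm = 10000, seed = 1,
                             min_size = 20, alpha = 0.01,
                             exact_limit = 1e5) {
  stopifnot(!is.null(names(values)),
            all(c("group_id", "transcript_id") %in% names(groups)))
  set.seed(sub_seed(seed, 0L))
  bg <- values[is.finite(values)]
  bg_mean <- mean(bg)
  N <- length(bg)
  # permutation pool sorted by value: p-values do not depend on how the
  # background happened to be ordered
  pool <- sort(unname(bg))
  gl <- split(groups$transcript_id, groups$group_id)
  gl <- lapply(gl, function(ids) intersect(unique(ids), names(bg)))
  sizes <- lengths(gl)
  skipped <- names(gl)[sizes <= min_size]
  tested <- names(gl)[sizes > min_size]
  rows <- vector("list", length(tested))
  for (k in seq_along(tested)) {
    ids <- gl[[tested[k]]]
    gv <- bg[ids]
    obs <- mean(gv) - bg_mean
    ksz <- length(ids)
    if (choose(N, ksz) <= exact_limit) {
      combs <- combn(N, ksz)
      perm <- colMeans(matrix(pool[combs], nrow = ksz)) - bg_mean
      p <- mean(abs(perm) >= abs(obs) - 1e-15)
    } else {
      hits <- 0L
      for (r in seq_len(n_perm)) {
        perm <- mean(pool[sample.int(N, ksz)]) - bg_mean
        if (abs(perm) >= abs(obs) - 1e-15) hits <- hits + 1L
      }
      p <- (1 + hits) / (n_perm + 1)
    }
    rows[[k]] <- data.frame(group_id = tested[k], n = ksz,
                            group_mean = mean(gv), background_mean = bg_mean,
                            p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group_id = character(), n = integer(),
                      group_mean = numeric(), background_mean = numeric(),
                      p = numeric())
  }
  out$p_adjusted <- pmin(1, out$p * nrow(out))
  out$direction <- ifelse(out$group_mean >= out$background_mean, "above", "below")
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("group_enrichment", "data.frame")
  out
}

#' UA x GC interaction model of half-life
#'
#' Ordinary least squares of half-life on the UA-dinucleotide ratio, GC
#' fraction, and their interaction:
#' `half_life ~ ua + gc + ua:gc`.
#'
#' @param half_life numeric response.
#' @param ua,gc numeric predictors.
#' @return Object of class `"ua_interaction"` wrapping the `lm` fit, with a
#'   coefficient table (`coefficients`), `confint`, and the fit itself.
#' @export
interaction_fit <- function(half_life, ua, gc) {
  stopifnot(length(half_life) >= 10)
  if (sd(ua) == 0) stop("degenerate input: ua is constant")
  if (sd(gc) == 0) stop("degenerate input: gc is constant")
  dat <- data.frame(half_life = half_life, ua = ua, gc = gc)
  fit <- lm(half_life ~ ua * gc, data = dat)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("collinear design; offending term(s): ", paste(bad, collapse = ", "))
  }
  out <- list(coefficients = summary(fit)$coefficients,
              confint = confint(fit), fit = fit)
  class(out) <- "ua_interaction"
  out
}

#' @export
print.ua_interaction <- function(x, ...) {
  cat("Half-life ~ UA + GC + UA:GC\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.ua_interaction <- function(object, ...) object$coefficients[, "Estimate"]

#' Stratified univariate stability effects
#'
#' Splits the data into strata of one compositional variable (median or
#' quartile split) and regresses half-life on the other within each
#' stratum.
#'
#' @param data data.frame with columns `half_life`, `ua`, `gc`.
#' @param stratify_by `"gc"` (default: report the UA slope within GC
#'   strata) or `"ua"`.
#' @param split `"median"` or `"quartile"`.
#' @return data.frame with `stratum`, `n`, `slope`, `p`; strata with fewer
#'   than 3 points are skipped.
#' @export
stratified_effect <- function(data, stratify_by = c("gc", "ua"),
                              split = c("median", "quartile")) {
  stratify_by <- match.arg(stratify_by)
  split <- match.arg(split)
  stopifnot(all(c("half_life", "ua", "gc") %in% names(data)))
  svar <- data[[stratify_by]]
  focal <- if (stratify_by == "gc") "ua" else "gc"
  strata <- if (split == "median") {
    # <= median goes low so a 2k-point split is k and k
    factor(ifelse(svar <= median(svar), "low", "high"),
           levels = c("low", "high"))
  } else {
    cut(svar, breaks = quantile(svar, probs = seq(0, 1, 0.25)),
        labels = paste0("Q", 1:4), include.lowest = TRUE)
  }
  rows <- lapply(levels(strata), function(s) {
    i <- which(strata == s)
    if (length(i) < 3) return(NULL)
    fit <- summary(lm(data$half_life[i] ~ data[[focal]][i]))
    data.frame(stratum = s, n = length(i),
               slope = fit$coefficients[2, "Estimate"],
               p = fit$coefficients[2, "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
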