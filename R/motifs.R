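#' Build a filtered 7-mer count table
#'
#' Overlapping 7-mer counts per oligo, keeping only 7-mers that occur at
#' least `min_total` times across the whole library (default 20).
#'
#' @param seqs character vector of sequences (>= 7 nt; primers already
#'   stripped).
#' @param ids optional oligo ids for the rows.
#' @param min_total library-wide occurrence filter.
#' @return Sparse `dgCMatrix` (oligos x 7-mers) with attribute `"totals"`
#'   giving the pre-filter library occurrence totals of the retained
#'   columns.
#' @export
count_7mers <- function(seqs, ids = NULL, min_total = 20) {
  seqs <- norm_rna(seqs, allow_n = FALSE)
  if (any(nchar(seqs) < 7)) stop("all sequences must be at least 7 nt")
  n <- length(seqs)
  tabs <- lapply(seqs, function(s) {
    L <- nchar(s)
    table(substring(s, 1:(L - 6L), 7:L))
  })
  totals <- table(unlist(lapply(tabs, function(tb) rep(names(tb), tb))))
  keep <- sort(names(totals)[totals >= min_total])
  if (length(keep) == 0) stop("no 7-mer reaches the occurrence filter")
  ii <- jj <- xx <- vector("list", n)
  for (i in seq_len(n)) {
    tb <- tabs[[i]]
    tb <- tb[names(tb) %in% keep]
    if (length(tb)) {
      ii[[i]] <- rep(i, length(tb))
      jj[[i]] <- match(names(tb), keep)
      xx[[i]] <- as.numeric(tb)
    }
  }
  out <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(n, length(keep)),
                              dimnames = list(ids %||% as.character(seq_len(n)),
                                              keep))
  attr(out, "totals") <- as.numeric(totals[keep])
  out
}

#' Trim extreme response values
#'
#' Returns the index of observations inside the given quantile range of the
#' response (default 1st to 99th percentile), the rule applied to log2
#' half-lives before motif regression.
#'
#' @param y numeric response.
#' @param quantiles lower/upper trimming quantiles.
#' @return Integer indices of retained observations.
#' @export
trim_extremes <- function(y, quantiles = c(0.01, 0.99)) {
  qs <- quantile(y, quantiles, na.rm = TRUE)
  which(y >= qs[1] & y <= qs[2] & is.finite(y))
}

#' Bootstrap-LASSO 7-mer selection
#'
#' Resamples oligos with replacement `B` times; on each resample fits an
#' L1-penalized regression of the response on the 7-mer counts with a
#' cross-validation-chosen penalty, and records which 7-mers receive a
#' non-zero coefficient. A 7-mer's selection count out of `B` measures the
#' stability of its association; its coefficient draws feed the
#' permutation test.
#'
#' The penalty path is kept short (`nlambda`, `lambda_min_ratio`) and the
#' fold count small (`nfolds = 5`) because the fit is repeated B times;
#' `nfolds = 10` restores the conventional choice.
#'
#' @param table 7-mer count matrix from [count_7mers()] (dense or sparse).
#' @param response numeric response (log2 half-life), one value per row.
#' @param B bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param nfolds cross-validation folds per resample.
#' @param lambda_choice `"min"` (CV-minimum, default) or `"1se"`.
#' @param nlambda,lambda_min_ratio,thresh glmnet path controls.
#' @return List of class `"bootstrap_lasso"`: `selection_count` (named),
#'   `coef_draws` (B x 7-mers matrix, zeros where unselected), `B`,
#'   `skipped` (degenerate resamples).
#' @export
bootstrap_lasso <- function(table, response, B = 2000, seed = 1, nfolds = 5,
                            lambda_choice = c("min", "1se"), nlambda = 20,
                            lambda_min_ratio = 0.1, thresh = 1e-5) {
  lambda_choice <- match.arg(lambda_choice)
  stopifnot(B >= 1, nrow(table) == length(response))
  set.seed(sub_seed(seed, 0L))
  x <- methods::as(table, "CsparseMatrix")
  n <- nrow(x); p <- ncol(x)
  s <- if (lambda_choice == "min") "lambda.min" else "lambda.1se"
  draws <- matrix(0, B, p, dimnames = list(NULL, colnames(x)))
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- response[idx]
    if (var(yb) == 0) {
      skipped <- skipped + 1L
      next
    }
    cv <- glmnet::cv.glmnet(x[idx, , drop = FALSE], yb, nfolds = nfolds,
                            nlambda = nlambda,
                            lambda.min.ratio = lambda_min_ratio,
                            thresh = thresh)
    beta <- as.matrix(coef(cv, s = s))[-1, 1]
    draws[b, ] <- beta
  }
  out <- list(selection_count = colSums(draws != 0),
              coef_draws = draws, B = B, skipped = skipped)
  class(out) <- "bootstrap_lasso"
  out
}

#' @export
print.bootstrap_lasso <- function(x, ...) {
  cat("Bootstrap LASSO:", ncol(x$coef_draws), "7-mers,", x$B, "resamples",
      if (x$skipped) paste0("(", x$skipped, " skipped)"), "\n")
  top <- sort(x$selection_count, decreasing = TRUE)
  print(head(top, 5))
  invisible(x)
}

#' Sign-flip permutation test of bootstrap coefficients
#'
#' Tests whether the mean of a 7-mer's bootstrap coefficient draws differs
#' from zero by randomly flipping the signs of the draws (`n_perm` flips,
#' seeded) and comparing |mean|. P-values are Bonferroni-adjusted by the
#' number of tested 7-mers and capped at 1. 7-mers whose draws are all zero
#' get p = 1.
#'
#' @param draws numeric matrix of coefficient draws (resamples x 7-mers),
#'   or a `"bootstrap_lasso"` object.
#' @param n_perm number of sign-flip permutations.
#' @param seed integer seed.
#' @return data.frame with `kmer`, `mean_coef`, `p`, `p_adjusted`.
#' @export
permutation_nonzero_test <- function(draws, n_perm = 10000, seed = 1) {
  if (inherits(draws, "bootstrap_lasso")) draws <- draws$coef_draws
  stopifnot(is.matrix(draws), nrow(draws) >= 2)
  set.seed(sub_seed(seed, 1L))
  p_raw <- vapply(seq_len(ncol(draws)), function(j) {
    d <- draws[, j]
    if (all(d == 0)) return(1)
    obs <- abs(mean(d))
    hits <- 0L
    # chunked sign flips keep memory flat for large n_perm
    left <- n_perm
    while (left > 0) {
      m <- min(left, 2000L)
      signs <- matrix(sample(c(-1, 1), m * length(d), replace = TRUE),
                      nrow = m)
      hits <- hits + sum(abs(signs %*% d) / length(d) >= obs - 1e-15)
      left <- left - m
    }
    (1 + hits) / (n_perm + 1)
  }, numeric(1))
  data.frame(kmer = colnames(draws),
             mean_coef = colMeans(draws),
             p = p_raw,
             p_adjusted = pmin(1, p_raw * ncol(draws)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster significant 7-mers into position weight matrices
#'
#' Splits 7-mers by coefficient sign (stabilizing vs destabilizing),
#' clusters each group by Levenshtein edit distance with complete-linkage
#' hierarchical clustering, cuts at height 2, and combines the members of
#' each cluster into a PWM whose column weights are the
#' |mean coefficient|-weighted base frequencies, normalized per column.
#'
#' @param kmers character vector of 7-mers.
#' @param mean_coefs their mean bootstrap coefficients.
#' @return List of motifs; each has `pwm` (4 x 7, rows A/C/G/U, columns
#'   summing to 1), `members`, `weights`, `direction`
#'   (`"stabilizing"`/`"destabilizing"`).
#' @export
cluster_kmers_to_pwms <- function(kmers, mean_coefs) {
  stopifnot(length(kmers) == length(mean_coefs), all(nchar(kmers) == 7))
  out <- list()
  for (dir in c("stabilizing", "destabilizing")) {
    sel <- if (dir == "stabilizing") mean_coefs > 0 else mean_coefs < 0
    km <- kmers[sel]; cf <- abs(mean_coefs[sel])
    if (length(km) == 0) next
    cl <- if (length(km) == 1) {
      setNames(1L, km)
    } else {
      d <- adist(km)
      dimnames(d) <- list(km, km)
      cutree(hclust(as.dist(d), method = "complete"), h = 2)
    }
    for (g in unique(cl)) {
      members <- km[cl == g]; weights <- cf[cl == g]
      pwm <- matrix(0, 4, 7, dimnames = list(c("A", "C", "G", "U"), NULL))
      for (i in seq_along(members)) {
        b <- strsplit(members[i], "")[[1]]
        for (j in 1:7) pwm[b[j], j] <- pwm[b[j], j] + weights[i]
      }
      pwm <- sweep(pwm, 2, colSums(pwm), "/")
      out[[length(out) + 1]] <- list(pwm = pwm, members = members,
                                     weights = weights, direction = dir)
    }
  }
  out
}

#' End-to-end 7-mer motif discovery
#'
#' [trim_extremes()] on the log2 half-lives, [count_7mers()],
#' [bootstrap_lasso()], [permutation_nonzero_test()], thresholding
#' (selection count > `selection_threshold` and adjusted p < `alpha`), and
#' [cluster_kmers_to_pwms()].
#'
#' @param seqs library sequences.
#' @param log2_halflife response, one value per sequence.
#' @param B,seed,nfolds,lambda_choice passed to [bootstrap_lasso()].
#' @param min_total occurrence filter of [count_7mers()].
#' @param selection_threshold minimum selection count (default 0.8 * B,
#'   i.e. 1600 of 2000).
#' @param alpha adjusted-p threshold.
#' @param trim_quantiles passed to [trim_extremes()].
#' @return List of class `"motif_discovery"`: `results` (per-7-mer table
#'   with selection counts, coefficients, adjusted p, direction),
#'   `motifs` (PWM list), `bootstrap`, `n_used`.
#' @export
discover_motifs <- function(seqs, log2_halflife, B = 2000, seed = 1,
                            nfolds = 5, lambda_choice = "min",
                            min_total = 20, selection_threshold = 0.8 * B,
                            alpha = 0.05, trim_quantiles = c(0.01, 0.99)) {
  keep <- trim_extremes(log2_halflife, trim_quantiles)
  tab <- count_7mers(seqs[keep], min_total = min_total)
  bl <- bootstrap_lasso(tab, log2_halflife[keep], B = B, seed = seed,
                        nfolds = nfolds, lambda_choice = lambda_choice)
  selected <- names(bl$selection_count)[bl$selection_count > selection_threshold]
  results <- data.frame(kmer = colnames(bl$coef_draws),
                        selection_count = unname(bl$selection_count),
                        mean_coef = unname(colMeans(bl$coef_draws)),
                        stringsAsFactors = FALSE)
  results$p_adjusted <- NA_real_
  motifs <- list()
  if (length(selected) > 0) {
    pt <- permutation_nonzero_test(bl$coef_draws[, selected, drop = FALSE],
                                   seed = seed)
    results$p_adjusted[match(pt$kmer, results$kmer)] <- pt$p_adjusted
    sig <- pt[pt$p_adjusted < alpha, ]
    if (nrow(sig) > 0) {
      motifs <- cluster_kmers_to_pwms(sig$kmer, sig$mean_coef)
    }
  }
  results$direction <- ifelse(results$mean_coef > 0, "stabilizing",
                              ifelse(results$mean_coef < 0, "destabilizing", NA))
  results$reported <- results$selection_count > selection_threshold &
    !is.na(results$p_adjusted) & results$p_adjusted < alpha
  out <- list(results = results[order(-results$selection_count), ],
              motifs = motifs, bootstrap = bl, n_used = length(keep))
  class(out) <- "motif_discovery"
  out
}

#' @export
print.motif_discovery <- function(x, ...) {
  rep <- x$results[x$results$reported, ]
  cat("Motif discovery on", x$n_used, "oligos:", nrow(rep),
      "reported 7-mers,", length(x$motifs), "motif PWMs\n")
  if (nrow(rep)) print(head(rep, 10), row.names = FALSE)
  invisible(x)
}
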