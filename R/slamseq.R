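#' Filter per-position conversion records
#'
#' Removes positions with coverage below 10 (insufficient evidence) or a
#' T-to-C conversion rate above 0.8 (likely SNPs rather than labelling).
#' Boundaries are inclusive on the kept side: coverage 10 and rate 0.8 both
#' stay.
#'
#' @param records data.frame with columns `coverage` and `rate` (plus any
#'   id columns, preserved).
#' @param min_coverage,max_rate filter thresholds.
#' @return Filtered data.frame; attribute `"removed"` counts removals by
#'   reason (`low_coverage`, `snp`).
#' @export
filter_positions <- function(records, min_coverage = 10, max_rate = 0.8) {
  stopifnot(all(c("coverage", "rate") %in% names(records)))
  low <- records$coverage < min_coverage
  snp <- !low & records$rate > max_rate
  out <- records[!low & !snp, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(low_coverage = sum(low), snp = sum(snp))
  out
}

#' Pooled per-transcript conversion rates
#'
#' Sums converted and unconverted T counts per transcript, timepoint and
#' batch and reports the pooled rate `ttoc / (ttoc + t_total)`. Transcripts
#' lacking at least 2 batches at any timepoint are dropped (recorded in the
#' `"dropped"` attribute); transcript-timepoint-batch rows with a zero
#' denominator are excluded.
#'
#' @param conversions data.frame with `transcript_id`, `timepoint_hr`,
#'   `batch`, `ttoc`, `t_total`.
#' @param min_batches batches required at every timepoint.
#' @return data.frame `transcript_id`, `timepoint_hr`, `batch`, `rate`.
#' @export
transcript_rates <- function(conversions, min_batches = 2) {
  need <- c("transcript_id", "timepoint_hr", "batch", "ttoc", "t_total")
  stopifnot(all(need %in% names(conversions)), nrow(conversions) > 0)
  agg <- aggregate(cbind(ttoc, t_total) ~ transcript_id + timepoint_hr + batch,
                   data = conversions, FUN = sum)
  denom <- agg$ttoc + agg$t_total
  agg <- agg[denom > 0, , drop = FALSE]
  agg$rate <- agg$ttoc / (agg$ttoc + agg$t_total)

  ntp <- length(unique(agg$timepoint_hr))
  per <- aggregate(batch ~ transcript_id + timepoint_hr, data = agg,
                   FUN = function(b) length(unique(b)))
  good <- tapply(per$batch >= min_batches, per$transcript_id, all) &
    tapply(per$timepoint_hr, per$transcript_id,
           function(t) length(unique(t))) == ntp
  keep_ids <- names(good)[good]
  out <- agg[agg$transcript_id %in% keep_ids,
             c("transcript_id", "timepoint_hr", "batch", "rate")]
  out <- out[order(out$transcript_id, out$timepoint_hr, out$batch), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- setdiff(unique(conversions$transcript_id), keep_ids)
  out
}

#' Fit half-lives from conversion-rate time courses
#'
#' Normalizes each transcript's rates to its mean baseline (first
#' timepoint) rate and applies the same weighted no-intercept log-linear
#' decay fit as the reporter stage,
#' \eqn{\ln(N_i(t)/N_i(0)) = -\lambda t_i + \epsilon_i}, with per-timepoint
#' inverse-SD weights across batches. Half-life is `ln(2) / lambda` in
#' hours. Transcripts with a zero baseline mean rate are excluded.
#'
#' @param rates data.frame from [transcript_rates()].
#' @param intercept passed to the shared fit engine.
#' @return data.frame of class `"decay_fits"` with `oligo_id` (transcript),
#'   `lambda`, `half_life_hr`, `r2`, `mse`, `n_points`, `qc_pass`.
#' @export
fit_conversion_decay <- function(rates, intercept = FALSE) {
  stopifnot(all(c("transcript_id", "timepoint_hr", "batch", "rate") %in%
                  names(rates)))
  t0 <- min(rates$timepoint_hr)
  sp <- split(rates, rates$transcript_id)
  rows <- vector("list", length(sp))
  excluded <- character(0)
  for (k in seq_along(sp)) {
    d <- sp[[k]]
    base <- mean(d$rate[d$timepoint_hr == t0])
    if (!is.finite(base) || base <= 0) {
      excluded <- c(excluded, d$transcript_id[1])
      next
    }
    y <- log(d$rate / base)
    tt <- d$timepoint_hr - t0
    sds <- tapply(y, tt, sd)
    w <- 1 / sds[as.character(tt)]
    if (any(!is.finite(w))) {
      mx <- if (any(is.finite(w))) max(w[is.finite(w)]) else 1
      w[!is.finite(w)] <- mx
    }
    ok <- is.finite(y)
    f <- wls_decay(tt[ok], y[ok], w[ok], intercept = intercept)
    rows[[k]] <- data.frame(
      oligo_id = d$transcript_id[1], lambda = f$lambda,
      half_life_hr = if (isTRUE(f$lambda > 0)) log(2) / f$lambda else NA_real_,
      r2 = f$r2, mse = f$mse, n_points = f$n,
      qc_pass = f$valid && isTRUE(f$r2 > 0.5) && isTRUE(f$mse < 1),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("decay_fits", "data.frame")
  out
}
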