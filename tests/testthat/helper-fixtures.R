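# Shared fixture builders; everything is generated in code.

# Count tensor from an explicit oligo x timepoint x replicate array of
# expected values (no sampling).
make_counts <- function(values, timepoints, ids = NULL) {
  d <- dim(values)
  ids <- ids %||% paste0("o", seq_len(d[1]))
  arr <- array(values, dim = d,
               dimnames = list(oligo_id = ids,
                               timepoint = format(timepoints, trim = TRUE),
                               replicate = seq_len(d[3])))
  attr(arr, "timepoints") <- timepoints
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free exponential-decay counts for given lambdas (per-replicate
# identical), scaled so that the baseline is `base`.
exp_counts <- function(lambdas, timepoints, nrep = 3, base = 1000) {
  n <- length(lambdas)
  vals <- array(0, c(n, length(timepoints), nrep))
  for (ti in seq_along(timepoints)) {
    vals[, ti, ] <- base * exp(-lambdas * (timepoints[ti] - timepoints[1]))
  }
  make_counts(vals, timepoints)
}

# Random RNA sequence.
rand_rna <- function(len, probs = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = probs),
        collapse = "")
}

# Brute-force overlapping IUPAC matcher used as the oracle for scan_iupac.
iupac_table <- list(A = "A", C = "C", G = "G", U = "U",
                    R = c("A", "G"), Y = c("C", "U"), W = c("A", "U"),
                    S = c("C", "G"), K = c("G", "U"), M = c("A", "C"),
                    B = c("C", "G", "U"), D = c("A", "G", "U"),
                    H = c("A", "C", "U"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "U"))

brute_iupac_count <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  L <- length(p); n <- length(s)
  if (n < L) return(0L)
  hits <- 0L
  for (start in seq_len(n - L + 1)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(s[start + j - 1] %in% iupac_table[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

# Brute-force per-window PWM scorer (oracle for scan_pwm).
brute_pwm_count <- function(seq, pwm, frac) {
  s <- strsplit(seq, "")[[1]]
  L <- ncol(pwm); n <- length(s)
  if (n < L) return(0L)
  smax <- sum(apply(pwm, 2, max))
  hits <- 0L
  for (start in seq_len(n - L + 1)) {
    sc <- 0
    for (j in seq_len(L)) sc <- sc + pwm[s[start + j - 1], j]
    if (sc >= frac * smax - 1e-9) hits <- hits + 1L
  }
  hits
}

# Closed-form weighted no-intercept slope (oracle for the decay fit).
closed_form_slope <- function(t, y, w) sum(w * t * y) / sum(w * t^2)

# Exhaustive overlapping-dimer counter (oracle for ua_ratio).
brute_dimer_ratio <- function(seq, dimer = "UA") {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  hits <- sum(s[-n] == substr(dimer, 1, 1) & s[-1] == substr(dimer, 2, 2))
  hits / (n - 1)
}
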