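test_that("baseline normalization divides by the replicate mean at t0", {
  vals <- array(0, c(1, 2, 3))
  vals[1, 1, ] <- c(10, 20, 30)
  vals[1, 2, ] <- c(20, 20, 20)
  counts <- make_counts(vals, c(30, 75))
  ser <- normalize_counts(counts, spike_id = NULL)
  base <- ser[ser$timepoint == 0, ]
  expect_equal(sort(base$norm), c(0.5, 1.0, 1.5))
})

test_that("constant counts normalize to one and log zero", {
  counts <- exp_counts(c(0, 0), c(30, 75, 120))
  ser <- normalize_counts(counts, spike_id = NULL)
  expect_equal(ser$norm, rep(1, nrow(ser)))
  expect_equal(ser$log_norm, rep(0, nrow(ser)))
})

test_that("oligos with zero baseline mean are dropped and reported", {
  vals <- array(100, c(2, 2, 3))
  vals[2, 1, ] <- 0
  counts <- make_counts(vals, c(0, 60))
  ser <- normalize_counts(counts, spike_id = NULL)
  expect_false("o2" %in% ser$oligo_id)
  dropped <- attr(ser, "dropped")
  expect_equal(dropped$reason[dropped$oligo_id == "o2"], "zero_baseline")
})

test_that("all-zero post-baseline oligos are dropped, not errored", {
  vals <- array(100, c(2, 3, 3))
  vals[2, 2:3, ] <- 0
  counts <- make_counts(vals, c(0, 30, 60))
  ser <- normalize_counts(counts, spike_id = NULL)
  expect_false("o2" %in% ser$oligo_id)
  expect_equal(attr(ser, "dropped")$reason, "all_zero_post")
})

test_that("a noise-free exponential is fit exactly", {
  counts <- exp_counts(log(2), c(0, 1, 2))
  fits <- fit_decay(normalize_counts(counts, spike_id = NULL))
  expect_equal(fits$lambda, log(2), tolerance = 1e-6)
  expect_equal(fits$half_life_min, 1.0, tolerance = 1e-6)
  expect_equal(fits$r2, 1)
  expect_true(fits$qc_pass)
})

test_that("the fitted slope equals the closed-form weighted LS solution", {
  set.seed(42)
  for (i in 1:100) {
    tps <- sort(sample(0:200, sample(3:6, 1)))
    nrep <- sample(2:4, 1)
    n <- length(tps)
    y <- matrix(rnorm(n * nrep, -0.01 * tps, 0.3), n, nrep)
    vals <- array(exp(y) * 500, c(1, n, nrep))
    counts <- make_counts(vals, tps)
    ser <- normalize_counts(counts, spike_id = NULL, pseudocount = 0)
    fit <- fit_decay(ser)
    oracle <- -closed_form_slope(ser$timepoint, ser$log_norm, ser$weight)
    expect_equal(fit$lambda, oracle, tolerance = 1e-10)
  }
})

test_that("QC applies the R2 > 0.5 and MSE < 1 thresholds", {
  # direct threshold check on synthetic r2/mse combinations via fit output
  good <- exp_counts(0.02, c(0, 30, 60))
  f <- fit_decay(normalize_counts(good, spike_id = NULL))
  expect_true(f$qc_pass)      # r2 = 1, mse = 0
  # noisy flat series: r2 near 0
  set.seed(1)
  vals <- array(exp(rnorm(9, 0, 0.8)) * 100, c(1, 3, 3))
  vals[1, 1, ] <- 100
  bad <- make_counts(vals, c(0, 30, 60))
  fb <- fit_decay(normalize_counts(bad, spike_id = NULL))
  expect_false(fb$qc_pass)
  expect_true(is.na(fb$half_life_min) || fb$r2 <= 0.5 || fb$mse >= 1)
})

test_that("fewer than two usable timepoints invalidates the fit", {
  vals <- array(c(100, 100, 100), c(1, 1, 3))
  counts <- make_counts(vals, 0)
  ser <- normalize_counts(counts, spike_id = NULL)
  f <- fit_decay(ser)
  expect_true(is.na(f$lambda))
  expect_false(f$qc_pass)
})

test_that("identical ref and mt series give theta 0 and p near 1", {
  counts <- exp_counts(c(0.02, 0.02), c(0, 45, 90))
  ser <- normalize_counts(counts, spike_id = NULL)
  ref <- ser[ser$oligo_id == "o1", ]
  mt <- ser[ser$oligo_id == "o2", ]
  res <- test_pair(ref, mt)
  expect_equal(res$theta, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("noiseless rates 0.5 and 0.8 give beta -0.5 and theta -0.3 exactly", {
  counts <- exp_counts(c(0.5, 0.8), c(0, 1, 2))
  ser <- normalize_counts(counts, spike_id = NULL)
  ref <- ser[ser$oligo_id == "o1", ]
  mt <- ser[ser$oligo_id == "o2", ]
  for (use_int in c(TRUE, FALSE)) {
    res <- test_pair(ref, mt, intercept = use_int)
    expect_equal(res$beta, -0.5, tolerance = 1e-10)
    expect_equal(res$theta, -0.3, tolerance = 1e-10)
  }
})

test_that("the pair engine agrees with R's weighted lm", {
  set.seed(7)
  for (i in 1:20) {
    tps <- c(0, 45, 90)
    counts <- make_counts(array(rpois(2 * 3 * 3, 500), c(2, 3, 3)), tps)
    ser <- normalize_counts(counts, spike_id = NULL)
    oligos <- data.frame(oligo_id = c("o1", "o2"), pair_id = "p1",
                         allele = c("ref", "mt"))
    scheme <- sample(c("counts", "pooled_sd", "none"), 1)
    pt <- test_pairs(ser, oligos, weights = scheme)
    i1 <- which(ser$oligo_id == "o1"); i2 <- which(ser$oligo_id == "o2")
    dat <- data.frame(y = ser$log_norm[c(i1, i2)],
                      t = ser$timepoint[c(i1, i2)],
                      G = rep(c(0, 1), each = length(i1)))
    w <- utrstab:::pair_weights(ser, i1, i2, scheme)
    ref_fit <- summary(lm(y ~ factor(G) + t + t:G, data = dat, weights = w))
    expect_equal(pt$theta, ref_fit$coefficients["t:G", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(pt$se, ref_fit$coefficients["t:G", "Std. Error"],
                 tolerance = 1e-10)
    expect_equal(pt$p, ref_fit$coefficients["t:G", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
})

test_that("pairs failing QC are excluded and counted", {
  counts <- exp_counts(c(0.02, 0.02, 0.03, 0.03), c(0, 45, 90))
  ser <- normalize_counts(counts, spike_id = NULL)
  oligos <- data.frame(oligo_id = paste0("o", 1:4),
                       pair_id = rep(c("p1", "p2"), each = 2),
                       allele = rep(c("ref", "mt"), 2))
  fits <- fit_decay(ser)
  fits$qc_pass[fits$oligo_id == "o3"] <- FALSE
  pt <- test_pairs(ser, oligos, fits = fits)
  expect_equal(pt$pair_id, "p1")
  expect_true("p2" %in% attr(pt, "excluded"))
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(numeric(0)), numeric(0))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in input ranks
  set.seed(3)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # storey variant never exceeds BH
  expect_true(all(adjust_fdr(p, "storey") <= q + 1e-12))
})

test_that("fold-change classification is direction-symmetric", {
  expect_equal(classify_pairs_by_foldchange(10, 15), "significant")
  expect_equal(classify_pairs_by_foldchange(15, 10), "significant")
  expect_equal(classify_pairs_by_foldchange(10, 10), "non_significant")
  expect_equal(classify_pairs_by_foldchange(10, 14.9), "non_significant")
  expect_true(is.na(classify_pairs_by_foldchange(-1, 10)))
  expect_true(is.na(classify_pairs_by_foldchange(10, Inf)))
})
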