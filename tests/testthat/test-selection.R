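test_that("sparse filtering applies the >= 90% zero rule at the boundary", {
  n <- 100
  m <- cbind(z91 = c(rep(0, 91), rep(1, 9)),
             z89 = c(rep(0, 89), rep(1, 11)),
             dense = rnorm(n))
  out <- sparse_filter(m)
  expect_false("z91" %in% colnames(out))
  expect_true(all(c("z89", "dense") %in% colnames(out)))
  expect_equal(attr(out, "removed"), "z91")
  expect_error(sparse_filter(cbind(a = rep(0, 10))), "every column")
})

test_that("correlated and anticorrelated features merge at height zero", {
  set.seed(10)
  x1 <- rnorm(50)
  m <- cbind(x1 = x1, x2 = 2 * x1, x3 = -x1, other = rnorm(50))
  hc <- cluster_features(m)
  cl0 <- cutree(hc, h = 1e-9)
  expect_equal(cl0[["x1"]], cl0[["x2"]])
  expect_equal(cl0[["x1"]], cl0[["x3"]])
  expect_false(cl0[["other"]] == cl0[["x1"]])
})

test_that("single-linkage tree matches a hand-built linkage on 3 features", {
  set.seed(11)
  x <- rnorm(40)
  m <- cbind(a = x + rnorm(40, 0, 0.3),
             b = x + rnorm(40, 0, 0.3),
             c = rnorm(40))
  hc <- cluster_features(m)
  rho <- cor(m, method = "spearman")
  d <- 1 - abs(rho)
  # brute-force single linkage on 3 points: first merge = smallest distance;
  # second merge height = min cross distance to the remaining point
  off <- c(d["a", "b"], d["a", "c"], d["b", "c"])
  expect_equal(min(hc$height), min(off))
  pairs <- list(c("a", "b"), c("a", "c"), c("b", "c"))
  first <- pairs[[which.min(off)]]
  rest <- setdiff(c("a", "b", "c"), first)
  expect_equal(max(hc$height), min(d[first, rest]))
})

test_that("zero-variance columns are dropped with a warning before clustering", {
  m <- cbind(a = rnorm(20), b = rnorm(20), flat = rep(1, 20))
  expect_warning(hc <- cluster_features(m), "flat")
  expect_equal(sort(hc$labels), c("a", "b"))
})

test_that("representatives maximize absolute univariate influence", {
  set.seed(12)
  n <- 200
  y <- rnorm(n)
  strong <- y + rnorm(n, 0, 0.5)
  weak <- strong + rnorm(n, 0, 0.9)      # same cluster, weaker influence
  lone <- rnorm(n)
  m <- cbind(ua_like = strong, au_like = weak, lone = lone)
  hc <- cluster_features(m)
  h <- 1 - abs(cor(m, method = "spearman"))["ua_like", "au_like"] + 0.01
  reps <- pick_representatives(hc, h, m, y)
  expect_true("ua_like" %in% reps)
  expect_false("au_like" %in% reps)
  # height 0: every feature represents itself
  reps0 <- pick_representatives(hc, 0, m, y)
  expect_equal(sort(reps0), sort(colnames(m)))
})

test_that("ties go to the lexicographically smallest feature name", {
  set.seed(13)
  x <- rnorm(30)
  m <- cbind(bbb = x, aaa = x)     # identical columns: exact influence tie
  y <- x + rnorm(30, 0, 0.1)
  hc <- cluster_features(m)
  reps <- pick_representatives(hc, 0.5, m, y)
  expect_equal(as.character(reps), "aaa")
})

test_that("VIF matches 1/(1 - R^2) from an independent OLS oracle", {
  set.seed(14)
  n <- 120
  a <- rnorm(n); b <- rnorm(n)
  m <- cbind(a = a, b = b, c = 0.8 * a + 0.4 * b + rnorm(n, 0, 0.5))
  v <- compute_vif(m)
  for (j in 1:3) {
    r2 <- summary(lm(m[, j] ~ m[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("orthogonal features have VIF 1 and duplicates are infinite", {
  x <- cbind(a = rep(c(1, -1), 25), b = rep(c(1, 1, -1, -1), length.out = 50))
  v <- compute_vif(x)
  expect_equal(unname(v), c(1, 1))
  dup <- cbind(a = rnorm(30), b = 0)
  dup[, "b"] <- dup[, "a"]
  expect_true(is.infinite(compute_vif(dup)["b"]))
})

test_that("height search stops at the first grid point satisfying the bound", {
  set.seed(15)
  n <- 300
  base <- rnorm(n)
  m <- cbind(f1 = base, f2 = base + rnorm(n, 0, 0.05),  # collinear pair
             f3 = rnorm(n), f4 = rnorm(n))
  y <- base + rnorm(n, 0, 0.5)
  expect_gt(max(compute_vif(m)), 5)
  hc <- cluster_features(m)
  sel <- select_height(hc, m, y)
  expect_lt(max(sel$vif), 5)
  expect_true(xor("f1" %in% sel$representatives, "f2" %in% sel$representatives))
  # pair merges at its |rho|-implied height
  rho <- abs(cor(m[, "f1"], m[, "f2"], method = "spearman"))
  expect_gte(sel$height + 0.01, 1 - rho)
  # already-fine matrices return height 0
  ok <- cbind(a = rnorm(n), b = rnorm(n))
  sel0 <- select_height(cluster_features(ok), ok, y)
  expect_equal(sel0$height, 0)
})

test_that("an overwhelming penalty shrinks every coefficient to zero", {
  set.seed(16)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- x[, 1] + rnorm(50, 0, 0.2)
  fit <- lasso_fit(x, y, lambda = 1e6, n_boot = 0)
  expect_equal(unname(fit$coefficients[-1]), rep(0, 4))
  expect_equal(unname(fit$coefficients["(Intercept)"]), mean(y))
})

test_that("the LASSO at penalty ~0 equals ordinary least squares", {
  set.seed(17)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- 2 + x %*% c(1, -0.5, 0.25) + rnorm(100, 0, 0.1)
  fit <- lasso_fit(x, y[, 1], lambda = 1e-8, n_boot = 0)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-4)
})

test_that("the CV solution satisfies the KKT conditions of the objective", {
  set.seed(18)
  n <- 150
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 1.5 - 2 * x[, 1] + x[, 2] + rnorm(n, 0, 0.3)
  fit <- lasso_fit(x, y, seed = 5, n_boot = 0)
  beta <- fit$coefficients
  # glmnet objective: 1/(2n) RSS + lambda * sum|beta| on standardized X;
  # check KKT on the original scale with matching scaling factors
  xs <- scale(x, scale = apply(x, 2, function(c) sqrt(mean((c - mean(c))^2))))
  ys <- y - mean(y)
  bs <- beta[-1] * attr(xs, "scaled:scale")
  r <- ys - xs %*% bs
  grad <- crossprod(xs, r) / n
  for (j in seq_len(ncol(x))) {
    if (bs[j] != 0) {
      expect_equal(unname(grad[j]), unname(sign(bs[j]) * fit$lambda),
                   tolerance = 1e-4)
    } else {
      expect_lte(abs(grad[j]), fit$lambda + 1e-4)
    }
  }
})

test_that("a planted negative UA effect is recovered with the right sign", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 150
    ua <- runif(n)
    x <- cbind(ua_ratio = ua, f2 = rnorm(n), f3 = rnorm(n))
    y <- -2 * ua + rnorm(n, 0, 0.3)
    fit <- lasso_fit(x, y, seed = seed, n_boot = 0)
    if (fit$coefficients["ua_ratio"] < 0) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("constant responses give an all-zero model", {
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  fit <- lasso_fit(x, rep(2, 20))
  expect_equal(unname(fit$coefficients), c(2, 0, 0, 0))
})

test_that("split evaluation reproduces hand-computed metrics", {
  # deterministic 5-point test partition via a fixed linear model object
  obs <- c(1, 2, 3, 4, 5)
  pred <- c(1.1, 1.9, 3.2, 3.8, 5.0)
  err <- obs - pred
  fake_model <- structure(list(pred = pred), class = "fake_pred")
  assign("predict.fake_pred", function(object, newx, ...) object$pred,
         envir = globalenv())
  on.exit(rm("predict.fake_pred", envir = globalenv()))
  x <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(15); y[1:5] <- obs
  res <- evaluate_split(x, y, fit_fun = function(x, y) fake_model,
                        train_fraction = 2 / 3, seed = 99)
  te_n <- res$n_test
  expect_equal(te_n, 5)
  # recompute on the same split
  set.seed(utrstab:::sub_seed(99, 1L))
  tr <- sample.int(15, 10)
  te <- setdiff(1:15, tr)
  obs2 <- y[te]; err2 <- obs2 - pred
  expect_equal(res$mae, mean(abs(err2)))
  expect_equal(res$rmse, sqrt(mean(err2^2)))
  expect_equal(res$mape, mean(abs(err2 / obs2)) * 100)
  expect_equal(res$r2, 1 - sum(err2^2) / sum((obs2 - mean(obs2))^2))
})

test_that("noiseless linear data scores perfectly; shuffled responses do not", {
  set.seed(19)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- drop(1 + x %*% c(2, -1, 0.5))
  # unpenalized fit: the pipeline metrics themselves are under test
  res <- evaluate_split(x, y, fit_fun = function(x, y)
    lasso_fit(x, y, lambda = 1e-8, n_boot = 0), seed = 3)
  expect_gt(res$r2, 0.999)
  expect_lt(res$mae, 1e-3)
  res_null <- evaluate_split(x, sample(y), seed = 3)
  expect_lt(abs(res_null$r2), 0.5)
})
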