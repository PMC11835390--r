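#' Remove near-constant sparse features
#'
#' Drops feature columns whose fraction of exact zeros reaches
#' `zero_fraction` (default: >= 90% zeros). Removed names are recorded in
#' the `"removed"` attribute.
#'
#' @param matrix numeric feature matrix (oligos x features).
#' @param zero_fraction removal threshold on the zero fraction.
#' @return The filtered matrix.
#' @export
sparse_filter <- function(matrix, zero_fraction = 0.9) {
  stopifnot(is.matrix(matrix), nrow(matrix) > 0)
  zf <- colMeans(matrix == 0)
  drop <- zf >= zero_fraction
  if (all(drop)) {
    stop("sparse_filter would remove every column; lower zero_fraction")
  }
  out <- matrix[, !drop, drop = FALSE]
  attr(out, "removed") <- colnames(matrix)[drop]
  cat_attr <- attr(matrix, "category")
  if (!is.null(cat_attr)) attr(out, "category") <- cat_attr[colnames(out)]
  out
}

#' Cluster features by absolute Spearman correlation
#'
#' Single-linkage hierarchical clustering of feature columns under the
#' distance `1 - |Spearman rho|`, so perfectly (anti-)correlated features
#' merge at height 0. Zero-variance columns cannot be ranked and are dropped
#' with a warning before clustering.
#'
#' @param matrix numeric feature matrix.
#' @return An `hclust` tree over the retained columns.
#' @export
cluster_features <- function(matrix) {
  v <- apply(matrix, 2, var)
  if (any(v == 0)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(matrix)[v == 0], collapse = ", "))
    matrix <- matrix[, v > 0, drop = FALSE]
  }
  if (ncol(matrix) < 2) stop("need at least 2 non-constant columns to cluster")
  rho <- cor(matrix, method = "spearman")
  d <- as.dist(1 - abs(rho))
  hclust(d, method = "single")
}

#' Pick one representative feature per cluster
#'
#' Cuts the tree at `height` and, within each cluster, picks the feature
#' with the greatest influence on the response: the largest absolute
#' univariate regression coefficient on the standardized feature (equal to
#' `|cor(x, y)| * sd(y)`, so the ordering is by absolute correlation). Ties
#' go to the lexicographically smallest feature name.
#'
#' @param dendrogram an `hclust` tree from [cluster_features()].
#' @param height cut height in distance units (`1 - |rho|`).
#' @param matrix the feature matrix the tree was built on.
#' @param response numeric response (log half-life).
#' @return Character vector of representative names; attribute
#'   `"clusters"` maps every feature to its cluster id.
#' @export
pick_representatives <- function(dendrogram, height, matrix, response) {
  stopifnot(height >= 0)
  cl <- cutree(dendrogram, h = height)
  feats <- names(cl)
  infl <- abs(cor(matrix[, feats, drop = FALSE], response))[, 1] * sd(response)
  reps <- vapply(split(feats, cl), function(members) {
    best <- infl[members]
    cand <- members[best == max(best)]
    sort(cand)[1]
  }, character(1))
  reps <- unname(reps)
  attr(reps, "clusters") <- cl
  reps
}

#' Variance inflation factors
#'
#' Regresses each feature on all the others (with intercept) and reports
#' `VIF_j = 1 / (1 - R_j^2)`. Perfectly collinear features are reported as
#' `Inf`.
#'
#' @param matrix numeric matrix restricted to the representative features
#'   (needs >= 2 columns and more rows than columns).
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(matrix) {
  p <- ncol(matrix)
  stopifnot(p >= 2, nrow(matrix) > p)
  out <- setNames(numeric(p), colnames(matrix))
  for (j in seq_len(p)) {
    yj <- matrix[, j]
    X <- cbind(1, matrix[, -j, drop = FALSE])
    fit <- lm.fit(X, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    out[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' VIF-bounded tree-cut selection of representatives
#'
#' Walks a fixed grid of cut heights from 0 upward and returns the smallest
#' height whose cluster representatives all have VIF below `vif_bound`
#' (default 5). If even a single cluster cannot satisfy the bound the
#' single-representative solution is returned with a warning.
#'
#' @inheritParams pick_representatives
#' @param vif_bound upper bound on any representative's VIF (> 1).
#' @param grid_step height increment of the search grid.
#' @param grid `"fixed"` (default: 0 to 1 by `grid_step`) or `"merge"`
#'   (the tree's own merge heights).
#' @return List of class `"selection_diagnostics"`: `height`,
#'   `representatives`, `vif`, `clusters`.
#' @export
select_height <- function(dendrogram, matrix, response, vif_bound = 5,
                          grid_step = 0.01, grid = c("fixed", "merge")) {
  grid <- match.arg(grid)
  stopifnot(vif_bound > 1)
  heights <- if (grid == "fixed") {
    seq(0, 1, by = grid_step)
  } else {
    sort(unique(c(0, dendrogram$height)))
  }
  res <- NULL
  for (h in heights) {
    reps <- pick_representatives(dendrogram, h, matrix, response)
    if (length(reps) == 1) {
      res <- list(height = h, representatives = reps,
                  vif = setNames(1, reps), clusters = attr(reps, "clusters"))
      break
    }
    v <- compute_vif(matrix[, reps, drop = FALSE])
    if (max(v) < vif_bound) {
      res <- list(height = h, representatives = as.character(reps), vif = v,
                  clusters = attr(reps, "clusters"))
      break
    }
  }
  if (is.null(res)) {
    warning("VIF bound unreachable; returning the single-representative solution")
    reps <- pick_representatives(dendrogram, max(dendrogram$height) + 1,
                                 matrix, response)
    res <- list(height = max(dendrogram$height), representatives = reps,
                vif = setNames(1, reps), clusters = attr(reps, "clusters"))
  }
  res$representatives <- as.character(res$representatives)
  class(res) <- "selection_diagnostics"
  res
}

#' @export
print.selection_diagnostics <- function(x, ...) {
  cat("VIF-bounded selection: cut height", x$height, "->",
      length(x$representatives), "representatives, max VIF",
      round(max(x$vif), 3), "\n")
  invisible(x)
}

## Internal: seeded fold assignment stratified by response quantile.
stratified_folds <- function(y, nfolds) {
  strata <- cut(rank(y, ties.method = "first"),
                breaks = nfolds, labels = FALSE)
  foldid <- integer(length(y))
  for (s in unique(strata)) {
    i <- which(strata == s)
    foldid[i] <- sample(rep_len(seq_len(nfolds), length(i)))
  }
  foldid
}

#' L1-penalized regression of log half-life on representatives
#'
#' Fits the LASSO objective
#' \deqn{\hat\beta = \arg\min_\beta \sum_i (y_i - \beta_0 - \sum_j \beta_j
#'   X_{ij})^2 + \lambda \sum_j |\beta_j|}
#' over a decreasing penalty path, choosing \eqn{\lambda} at the minimum
#' mean cross-validated error (seeded, quantile-stratified folds).
#' Coefficients are reported on the original feature scale; 95% bootstrap
#' percentile intervals are attached for the non-zero coefficients.
#'
#' @param x numeric matrix of representative features.
#' @param y numeric response (log half-life).
#' @param nfolds cross-validation folds.
#' @param seed integer seed for fold assignment and the bootstrap.
#' @param n_boot bootstrap replicates for the intervals (0 disables).
#' @param lambda optional fixed penalty; skips cross-validation.
#' @return Object of class `"stab_lasso"` with elements `coefficients`
#'   (including intercept), `lambda`, `cv` (lambda/cvm/cvsd path), `ci`,
#'   and the fitted `glmnet` object.
#' @export
lasso_fit <- function(x, y, nfolds = 10, seed = 1, n_boot = 200,
                      lambda = NULL) {
  stopifnot(nrow(x) >= nfolds)
  if (var(y) == 0) {
    beta <- setNames(numeric(ncol(x) + 1), c("(Intercept)", colnames(x)))
    beta["(Intercept)"] <- y[1]
    out <- list(coefficients = beta, lambda = Inf, cv = NULL, ci = NULL,
                glmnet_fit = NULL)
    class(out) <- "stab_lasso"
    return(out)
  }
  set.seed(sub_seed(seed, 0L))
  # glmnet needs >= 2 columns; pad single-feature inputs with a zero dummy
  pad <- ncol(x) == 1
  if (pad) x <- cbind(x, `..pad` = 0)
  if (is.null(lambda)) {
    foldid <- stratified_folds(y, nfolds)
    cv <- glmnet::cv.glmnet(x, y, foldid = foldid)
    beta <- as.matrix(coef(cv, s = "lambda.min"))[, 1]
    lambda_min <- cv$lambda.min
    cv_path <- data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd)
    gfit <- cv$glmnet.fit
  } else {
    gfit <- glmnet::glmnet(x, y, lambda = lambda)
    beta <- as.matrix(coef(gfit))[, 1]
    lambda_min <- lambda
    cv_path <- NULL
  }
  ci <- NULL
  if (n_boot > 0) {
    nz <- names(beta)[beta != 0 & names(beta) != "(Intercept)"]
    if (length(nz) > 0) {
      draws <- matrix(NA_real_, n_boot, length(nz), dimnames = list(NULL, nz))
      n <- nrow(x)
      for (b in seq_len(n_boot)) {
        i <- sample.int(n, n, replace = TRUE)
        if (var(y[i]) == 0) next
        fb <- glmnet::glmnet(x[i, , drop = FALSE], y[i], lambda = lambda_min)
        draws[b, ] <- as.matrix(coef(fb))[nz, 1]
      }
      ci <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
      colnames(ci) <- c("lower95", "upper95")
    }
  }
  if (pad) beta <- beta[names(beta) != "..pad"]
  out <- list(coefficients = beta, lambda = lambda_min,
              cv = cv_path, ci = ci, glmnet_fit = gfit)
  class(out) <- "stab_lasso"
  out
}

#' @export
coef.stab_lasso <- function(object, ...) object$coefficients

#' @export
predict.stab_lasso <- function(object, newx, ...) {
  beta <- object$coefficients
  drop(cbind(1, newx[, names(beta)[-1], drop = FALSE]) %*% beta)
}

#' @export
print.stab_lasso <- function(x, ...) {
  nz <- x$coefficients[x$coefficients != 0]
  cat("LASSO stability model: penalty", signif(x$lambda, 4), ";",
      sum(names(nz) != "(Intercept)"), "features selected\n")
  print(round(nz, 4))
  invisible(x)
}

#' Train/test split evaluation of a selection pipeline
#'
#' Splits the rows 2:1 into training and test partitions (seeded), fits the
#' supplied pipeline on the training part and reports test-set metrics:
#' Pearson correlation, MAE, RMSE, MAPE and R-squared. Points with a zero
#' response are excluded from MAPE and counted.
#'
#' @param x feature matrix.
#' @param y response.
#' @param fit_fun function `(x, y) -> model` whose result supports
#'   `predict(model, newx)`; defaults to [lasso_fit()].
#' @param train_fraction fraction of rows used for training.
#' @param seed integer seed for the split.
#' @return Named list of metrics plus `n_train`, `n_test`,
#'   `mape_excluded`.
#' @export
evaluate_split <- function(x, y, fit_fun = function(x, y) lasso_fit(x, y, seed = seed),
                           train_fraction = 2 / 3, seed = 1) {
  n <- nrow(x)
  stopifnot(n >= 3)
  set.seed(sub_seed(seed, 1L))
  n_train <- round(n * train_fraction)
  tr <- sample.int(n, n_train)
  te <- setdiff(seq_len(n), tr)
  model <- fit_fun(x[tr, , drop = FALSE], y[tr])
  pred <- predict(model, x[te, , drop = FALSE])
  obs <- y[te]
  err <- obs - pred
  nonzero <- obs != 0
  list(correlation = if (sd(pred) > 0) cor(obs, pred) else NA_real_,
       mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)),
       mape = mean(abs(err[nonzero] / obs[nonzero])) * 100,
       r2 = 1 - sum(err^2) / sum((obs - mean(obs))^2),
       n_train = n_train, n_test = length(te),
       mape_excluded = sum(!nonzero))
}

#' Full collinearity-aware selection pipeline
#'
#' [sparse_filter()], [cluster_features()], [select_height()] and
#' [lasso_fit()] chained with shared defaults.
#'
#' @param matrix feature matrix.
#' @param response log half-life response.
#' @param zero_fraction,vif_bound,nfolds,seed,n_boot passed through.
#' @return List with `diagnostics` (from [select_height()]) and `model`
#'   (a `"stab_lasso"`).
#' @export
select_features <- function(matrix, response, zero_fraction = 0.9,
                            vif_bound = 5, nfolds = 10, seed = 1,
                            n_boot = 200) {
  fm <- sparse_filter(matrix, zero_fraction)
  hc <- cluster_features(fm)
  kept <- hc$labels
  diag <- select_height(hc, fm[, kept, drop = FALSE], response,
                        vif_bound = vif_bound)
  model <- lasso_fit(fm[, diag$representatives, drop = FALSE], response,
                     nfolds = nfolds, seed = seed, n_boot = n_boot)
  list(diagnostics = diag, model = model)
}
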