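# Elastic-net affinity regression.
#
# The model is f(X) = beta0 + sum_j X_j beta_j fitted by minimizing
#
#   RSS + lambda * sum_j [ (1 - alpha)/2 * beta_j^2 + alpha * |beta_j| ]
#
# alpha = 0 is ridge, alpha = 1 is the LASSO.  Features are z-scored on the
# training set before penalization (the penalty acts on the standardized
# scale), the intercept is unpenalized, and predictions are returned on the
# original intensity scale.  Fitting is cyclic coordinate descent on the
# Gram matrix with warm starts along a decreasing lambda path (see
# src/en_cd.cpp); with p = 54 the Gram form makes per-query refits cheap.

standardize_design <- function(X, standardize = TRUE) {
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (standardize) {
    scl <- sqrt(colSums(Xc^2) / n)
    scl[scl <= 0] <- 1
    Xs <- sweep(Xc, 2L, scl, "/")
  } else {
    scl <- rep(1, ncol(X))
    Xs <- Xc
  }
  list(Xs = Xs, center = ctr, scale = scl)
}

#' Fit an elastic-net regression at fixed penalty
#'
#' @param X Numeric design matrix (rows = motifs, columns = features).
#' @param y Numeric response (affinities, arbitrary intensity units).
#' @param alpha Mixing parameter in `[0, 1]`: 0 = ridge, 1 = LASSO.
#' @param lam Non-negative penalty weight (on the scale of the objective
#'   above, i.e. multiplying the summed per-coefficient penalty next to an
#'   unnormalized residual sum of squares).
#' @param standardize Z-score columns before penalization (default TRUE).
#' @param tol,maxit Coordinate-descent convergence controls.
#' @return An object of class `en_model`: `intercept` and `coefficients`
#'   on the original feature scale, `beta_std` on the standardized scale,
#'   `alpha`, `lambda`, and the standardization constants.
#' @examples
#' X <- matrix(rnorm(100), 20, 5); y <- X[, 1] - 2 * X[, 3] + rnorm(20, 0, .1)
#' m <- fit_elastic_net(X, y, alpha = 0.5, lam = 1)
#' predict(m, X[1:2, ])
#' @export
fit_elastic_net <- function(X, y, alpha, lam, standardize = TRUE,
                            tol = 1e-9, maxit = 100000L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L,
            is.finite(alpha), alpha >= 0, alpha <= 1,
            is.finite(lam), lam >= 0)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("design and response must be finite")
  }
  sd_ <- standardize_design(X, standardize)
  ym <- mean(y)
  G <- crossprod(sd_$Xs)
  yc <- y - ym
  b <- drop(crossprod(sd_$Xs, yc))
  # short warm-start path into the target lambda for stable convergence;
  # fdev = 0 disables early stopping so the target lambda is always solved
  path <- unique(sort(lam * c(64, 16, 4, 1), decreasing = TRUE))
  B <- en_path_gram_cpp(G, b, sum(yc^2), alpha, path, tol,
                        as.integer(maxit), 0)
  beta_std <- B[, ncol(B)]
  coefs <- beta_std / sd_$scale
  structure(
    list(intercept = ym - sum(coefs * sd_$center),
         coefficients = stats::setNames(coefs, colnames(X)),
         beta_std = beta_std, alpha = alpha, lambda = lam,
         standardize = standardize,
         std = list(center = sd_$center, scale = sd_$scale, y_center = ym)),
    class = "en_model")
}

#' Predict affinities from a fitted model
#'
#' @param object An `en_model`.
#' @param newdata Feature matrix (or a single feature vector of matching
#'   length).
#' @param ... Unused.
#' @return Numeric vector of predictions on the original intensity scale.
#' @export
predict.en_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  drop(object$intercept + as.matrix(newdata) %*% object$coefficients)
}

#' @export
print.en_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "Elastic-net affinity model: alpha = %.2f, lambda = %.4g, %d/%d nonzero\n",
    x$alpha, x$lambda, nz, length(x$coefficients)))
  invisible(x)
}

#' Configuration for cross-validated model selection
#'
#' @param alpha_grid Candidate mixing parameters; default 0, 0.1, ..., 1
#'   (11 values).
#' @param nfolds Cross-validation folds (default 10).
#' @param nlambda Length of the geometric lambda path (default 100).
#' @param lambda_min_ratio Smallest path lambda as a fraction of the
#'   all-zero lambda (default 1e-4).
#' @param seed Integer seed controlling fold assignment (and, in
#'   [predict_library()], per-query fold seeds); `NULL` leaves the RNG
#'   stream alone.
#' @param shared_hyperparams In [predict_library()]: select one
#'   (alpha, lambda) pair on the pooled training set and reuse it for every
#'   query, instead of re-selecting per query (default FALSE).
#' @param tol,maxit Coordinate-descent controls used during CV (looser than
#'   the final fit: CV only needs the error curve, not certified optima).
#' @param fdev Early path-termination threshold: descending the lambda path
#'   stops once the training RSS improves by less than `fdev` of the null
#'   RSS (remaining path points reuse the saturated solution, as in
#'   standard lasso-path software); 0 disables.
#' @param min_train Minimum same-terminal training records required by
#'   [loocv_evaluate()].
#' @return A list of class `en_config`.
#' @export
en_config <- function(alpha_grid = seq(0, 1, by = 0.1), nfolds = 10L,
                      nlambda = 100L, lambda_min_ratio = 1e-4, seed = NULL,
                      shared_hyperparams = FALSE, tol = 1e-3,
                      maxit = 1000L, fdev = 1e-5, min_train = 20L) {
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1), nfolds >= 2L,
            nlambda >= 2L, lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(alpha_grid = alpha_grid, nfolds = as.integer(nfolds),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio, seed = seed,
                 shared_hyperparams = isTRUE(shared_hyperparams),
                 tol = tol, maxit = as.integer(maxit), fdev = fdev,
                 min_train = as.integer(min_train)),
            class = "en_config")
}

# lambda path for one alpha: geometric grid from the smallest lambda that
# zeroes every coefficient (on standardized data) down by lambda_min_ratio.
lambda_path <- function(b, alpha, nlambda, lambda_min_ratio) {
  lmax <- 2 * max(abs(b)) / max(alpha, 1e-3)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# Round-robin fold assignment after a seeded shuffle.
fold_assignment <- function(n, nfolds, seed = NULL) {
  perm <- with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(nfolds), n)
  folds
}

#' Select (alpha, lambda) by cross-validation
#'
#' For each alpha on the grid a geometric lambda path is built from the full
#' training set, and mean CV squared error is measured over `nfolds`
#' round-robin folds (fold assignment is a deterministic function of
#' `seed`).  Per alpha the lambda with the lowest CV error wins, ties going
#' to the larger lambda (more regularization); across alphas the pair with
#' the lowest CV error wins, ties going to the smaller alpha (more
#' ridge-like, stabler on correlated features).
#'
#' @inheritParams fit_elastic_net
#' @param config An [en_config()].
#' @return List with `alpha`, `lambda`, `cv_error` (the winning mean CV
#'   MSE), and `cvm` (alpha x lambda-index matrix of mean CV MSE).
#' @export
select_hyperparameters <- function(X, y, config = en_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (config$nfolds > n) stop("more folds than observations")
  folds <- fold_assignment(n, config$nfolds, config$seed)

  sd_all <- standardize_design(X)
  b_all <- drop(crossprod(sd_all$Xs, y - mean(y)))
  paths <- lapply(config$alpha_grid, function(a)
    lambda_path(b_all, a, config$nlambda, config$lambda_min_ratio))

  na <- length(config$alpha_grid)
  sse <- matrix(0, na, config$nlambda)
  for (f in seq_len(config$nfolds)) {
    tr <- folds != f
    sd_tr <- standardize_design(X[tr, , drop = FALSE])
    ytr <- y[tr]
    ym <- mean(ytr)
    G <- crossprod(sd_tr$Xs)
    b <- drop(crossprod(sd_tr$Xs, ytr - ym))
    Xva <- sweep(sweep(X[!tr, , drop = FALSE], 2L, sd_tr$center), 2L,
                 sd_tr$scale, "/")
    yty <- sum((ytr - ym)^2)
    for (ai in seq_len(na)) {
      B <- en_path_gram_cpp(G, b, yty, config$alpha_grid[ai], paths[[ai]],
                            config$tol, config$maxit, config$fdev)
      pred <- Xva %*% B + ym
      sse[ai, ] <- sse[ai, ] + colSums((pred - y[!tr])^2)
    }
  }
  cvm <- sse / n
  # per alpha: first index along the decreasing path = largest lambda
  li <- apply(cvm, 1L, which.min)
  best_per_alpha <- cvm[cbind(seq_len(na), li)]
  ai <- which.min(best_per_alpha)  # first = smallest alpha on ties
  list(alpha = config$alpha_grid[ai], lambda = paths[[ai]][li[ai]],
       cv_error = best_per_alpha[ai], cvm = cvm)
}
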