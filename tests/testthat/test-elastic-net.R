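# The solver is checked against three independent routes: the closed-form
# ridge solution, ordinary least squares at zero penalty, and (for sparse
# fits) glmnet; general (alpha, lambda) fits are certified by the
# subgradient optimality conditions of the penalized objective.

en_objective <- function(X, y, beta0, beta, alpha, lam) {
  sum((y - beta0 - drop(X %*% beta))^2) +
    lam * sum(0.5 * (1 - alpha) * beta^2 + alpha * abs(beta))
}

test_that("ridge fits match the closed-form penalized normal equations", {
  set.seed(1)
  X <- matrix(rnorm(10), 5, 2)
  y <- rnorm(5)
  lam <- 3
  m <- fit_elastic_net(X, y, alpha = 0, lam = lam, standardize = FALSE,
                       tol = 1e-12)
  Xc <- scale(X, scale = FALSE)
  oracle <- solve(crossprod(Xc) + diag(lam / 2, 2),
                  crossprod(Xc, y - mean(y)))
  expect_lt(max(abs(m$coefficients - drop(oracle))), 1e-6)
  # and with standardization the closed form holds on the scaled design
  ms <- fit_elastic_net(X, y, alpha = 0, lam = lam, tol = 1e-12)
  scl <- sqrt(colMeans(Xc^2))
  Xs <- sweep(Xc, 2, scl, "/")
  os <- solve(crossprod(Xs) + diag(lam / 2, 2), crossprod(Xs, y - mean(y)))
  expect_lt(max(abs(ms$coefficients - drop(os) / scl)), 1e-6)
})

test_that("zero penalty reproduces ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40)
  m <- fit_elastic_net(X, y, alpha = 0.5, lam = 0, tol = 1e-12)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_lt(max(abs(m$coefficients - ols[-1])), 1e-7)
  expect_lt(abs(m$intercept - ols[1]), 1e-7)
  # training predictions equal the least-squares fitted values
  expect_lt(max(abs(predict(m, X) - (cbind(1, X) %*% ols))), 1e-6)
})

test_that("solutions satisfy the subgradient optimality conditions", {
  set.seed(3)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- drop(X %*% c(3, -2, 0, 0, 1, 0, 0, 0)) + rnorm(60)
  for (alpha in c(0.2, 0.5, 0.8, 1)) {
    lam <- 20
    m <- fit_elastic_net(X, y, alpha = alpha, lam = lam, tol = 1e-12)
    # KKT on the standardized problem the solver actually minimizes
    scl <- sqrt(colMeans(scale(X, scale = FALSE)^2))
    Xs <- scale(X, scale = scl)
    r <- y - mean(y) - drop(Xs %*% m$beta_std)
    grad <- -2 * drop(crossprod(Xs, r)) + lam * (1 - alpha) * m$beta_std
    active <- m$beta_std != 0
    expect_lt(max(abs(grad[active] + lam * alpha * sign(m$beta_std[active]))),
              1e-4)
    if (any(!active)) {
      expect_true(all(abs(grad[!active]) <= lam * alpha + 1e-4))
    }
  }
})

test_that("lasso fits agree with glmnet under the objective rescaling", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  n <- 50
  X <- matrix(rnorm(n * 10), n, 10)
  y <- drop(X %*% c(2, -3, rep(0, 8))) + rnorm(n)
  lam <- 30
  m <- fit_elastic_net(X, y, alpha = 1, lam = lam, tol = 1e-12)
  scl <- sqrt(colMeans(scale(X, scale = FALSE)^2))
  Xs <- scale(X, scale = scl)
  g <- glmnet::glmnet(Xs, y, alpha = 1,
                      lambda = lam / (2 * n) * c(8, 4, 2, 1),
                      standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(m$beta_std - as.numeric(stats::coef(g)[-1, 4]))), 1e-5)
})

test_that("alpha endpoints reduce to ridge and lasso penalties", {
  set.seed(5)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- rnorm(50)
  # at alpha = 1, a large enough penalty zeroes every coefficient
  big <- fit_elastic_net(X, y, alpha = 1,
                         lam = 4 * max(abs(crossprod(scale(X), y))))
  expect_true(all(big$coefficients == 0))
  expect_equal(big$intercept, mean(y))
  # at alpha = 0 no finite penalty gives exact zeros
  r0 <- fit_elastic_net(X, y, alpha = 0, lam = 1000)
  expect_true(all(r0$coefficients != 0))
})

test_that("the L1 norm shrinks monotonically along a lambda path", {
  set.seed(6)
  X <- matrix(rnorm(80 * 10), 80, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(80)
  for (alpha in c(0.3, 1)) {
    l1 <- vapply(c(1, 5, 20, 100, 500, 2000), function(lam) {
      sum(abs(fit_elastic_net(X, y, alpha = alpha, lam = lam)$beta_std))
    }, numeric(1))
    expect_true(all(diff(l1) <= 1e-8))
  }
})

test_that("degenerate constant-response input yields a flat model", {
  X <- matrix(c(1, 1, 2, 2, 3, 3), 3, 2)  # collinear columns
  y <- c(5, 5, 5)
  m <- fit_elastic_net(X, y, alpha = 0.5, lam = 0)
  expect_equal(unname(m$coefficients), c(0, 0))
  expect_equal(predict(m, X), rep(5, 3))
})

test_that("prediction is linear in the features", {
  set.seed(7)
  X <- matrix(rnorm(30 * 54), 30, 54)
  y <- rnorm(30)
  m <- fit_elastic_net(X, y, alpha = 0.5, lam = 10)
  f1 <- X[1, ]; f2 <- X[2, ]
  expect_equal(predict(m, (f1 + f2) / 2),
               mean(predict(m, rbind(f1, f2))))
})

test_that("noiseless sparse signals are recovered at small penalty", {
  # the full-alphabet design is full-rank in the 54 features (the
  # building-block sublibrary is not, so coefficients are only
  # identifiable here); the intercept keeps the signal off the zero clip
  lib <- enumerate_sublibrary("N", "full")
  truth <- ground_truth("linear-sparse", intercept = 4000, seed = 9)
  recs <- simulate_affinities(lib, truth, seed = 9)
  X <- featurize_motifs(recs$sequence)
  m <- fit_elastic_net(X, recs$affinity, alpha = 0.5, lam = 1e-4,
                       tol = 1e-10)
  expect_lt(max(abs(m$coefficients - truth$coefficients)), 1e-3)
})

test_that("hyperparameter search is deterministic in the seed", {
  dat <- small_library(n = 80, noise_sd = 20, seed = 3)
  X <- featurize_motifs(dat$sequence)
  cfg <- fast_config(seed = 42)
  h1 <- select_hyperparameters(X, dat$affinity, cfg)
  h2 <- select_hyperparameters(X, dat$affinity, cfg)
  expect_identical(h1[c("alpha", "lambda")], h2[c("alpha", "lambda")])
  expect_length(en_config()$alpha_grid, 11L)
  expect_error(select_hyperparameters(X[1:4, ], dat$affinity[1:4],
                                      en_config(nfolds = 10)),
               "more folds")
})

test_that("dense signals select more ridge-like alpha than sparse ones", {
  set.seed(11)
  n <- 80; p <- 30
  alphas <- sapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(n * p), n, p)
    b_dense <- rnorm(p, 0, 1 / sqrt(p))
    b_sparse <- c(rep(0, p - 3), c(2, -2, 2) / sqrt(3))
    noise <- rnorm(n)
    cfg <- en_config(nfolds = 5, nlambda = 20, tol = 1e-2, seed = s)
    c(dense = select_hyperparameters(
        X, drop(X %*% b_dense) + noise, cfg)$alpha,
      sparse = select_hyperparameters(
        X, drop(X %*% b_sparse) + noise, cfg)$alpha)
  })
  expect_lt(mean(alphas["dense", ]), mean(alphas["sparse", ]))
})

test_that("per-query prediction memorizes noiseless training motifs", {
  dat <- small_library(n = 120, noise_sd = 0, seed = 5)
  q <- dat[7, c("motif_id", "terminal", "sequence")]
  out <- predict_library(dat, q, fast_config(seed = 1))
  expect_equal(out$affinity, dat$affinity[7], tolerance = 0.02)
  expect_true(out$n_relevant >= 1)
  # purity: identical queries get identical models
  out2 <- predict_library(dat, rbind(q, q), fast_config(seed = 1))
  expect_equal(out2$affinity[1], out2$affinity[2], tolerance = 1e-10)
})

test_that("shared hyperparameters reuse one (alpha, lambda) for all queries", {
  dat <- small_library(n = 60, noise_sd = 10, seed = 6)
  out <- predict_library(dat, dat$sequence[1:4],
                         fast_config(seed = 2, shared_hyperparams = TRUE))
  expect_equal(length(unique(out$alpha)), 1L)
  expect_equal(length(unique(out$lambda)), 1L)
})
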