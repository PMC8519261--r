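random_instance <- function(seed, n = 12, m = 5, p = 2) {
  set.seed(seed)
  list(X = matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("g", 1:m))),
       Y = matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("y", 1:p))))
}

test_that("a noiseless single factor is reproduced exactly", {
  set.seed(1)
  X <- matrix(rnorm(15 * 6), 15, 6)
  cvec <- rnorm(6)
  y <- X %*% cvec
  # rank-1 structured X so one component suffices
  X1 <- tcrossprod(rnorm(15), rnorm(6))
  y1 <- X1 %*% cvec
  f <- fit_pls(X1, y1, 1)
  expect_lt(max(abs(predict(f, X1) - y1)), 1e-8)
  expect_equal(abs(as.numeric(cor(f$T[, 1], y1))), 1, tolerance = 1e-10)
})

test_that("single-response weights equal the normalised cross-covariance", {
  for (seed in 1:5) {
    inst <- random_instance(seed, p = 1)
    f <- fit_pls(inst$X, inst$Y, 1)
    Xc <- scale(inst$X, scale = FALSE)
    yc <- inst$Y - mean(inst$Y)
    w_ref <- crossprod(Xc, yc)
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    expect_equal(unname(f$W[, 1]), unname(w_ref[, 1]), tolerance = 1e-10)
  }
})

test_that("at full rank the PLS fit equals least squares", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n = 12, m = 5, p = 2)
    f <- fit_pls(inst$X, inst$Y, 5)
    expect_lt(max(abs(predict(f, inst$X) - ols_predict(inst$X, inst$Y))),
              1e-8)
  }
})

test_that("rotated weights satisfy T = Xc R and zero-variance genes get 0", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n = 14, m = 8, p = 2)
    f <- fit_pls(inst$X, inst$Y, 3)
    Xc <- scale(inst$X, scale = FALSE)
    expect_lt(max(abs(Xc %*% f$R - f$T)), 1e-8)
    # K = 1, p = 1: R is proportional to W
    f1 <- fit_pls(inst$X, inst$Y[, 1], 1)
    expect_equal(cor(f1$R[, 1], f1$W[, 1]), 1, tolerance = 1e-12)
  }
  inst <- random_instance(99, m = 6)
  inst$X[, 4] <- 7   # constant gene
  f <- fit_pls(inst$X, inst$Y, 2)
  expect_equal(unname(f$W[4, ]), c(0, 0))
  expect_equal(unname(gene_weights(f, 1)[4]), 0)
  expect_error(gene_weights(f, 3), "component")
})

test_that("scores are orthogonal, weights unit-norm, signs canonical", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n = 16, m = 10, p = 3)
    f <- fit_pls(inst$X, inst$Y, 4)
    G <- crossprod(f$T)
    offdiag <- G - diag(diag(G))
    expect_lt(max(abs(offdiag)), 1e-10 * max(diag(G)))
    expect_equal(unname(colSums(f$W^2)), rep(1, 4), tolerance = 1e-12)
    for (k in 1:4) expect_gte(cor(f$T[, k], f$U[, k]), 0)
  }
})

test_that("explained variance behaves like a decomposition", {
  set.seed(3)
  X1 <- tcrossprod(rnorm(12), rnorm(7))   # exact rank 1
  y <- X1 %*% rnorm(7) + 0
  f1 <- fit_pls(X1 + 0, y, 1)
  expect_equal(f1$explained_x_pct, 100, tolerance = 1e-8)

  inst <- random_instance(4, n = 12, m = 5, p = 2)
  f <- fit_pls(inst$X, inst$Y, 5)
  expect_equal(sum(f$explained_x_pct), 100, tolerance = 1e-6)
  expect_lte(sum(f$explained_y_pct), 100 + 1e-8)
  ev <- explained_variance(f)
  expect_equal(ev$x_cum_pct[5], 100, tolerance = 1e-6)

  # appending a pure-noise response dilutes component-1 Y variance
  worse <- 0
  for (seed in 1:40) {
    inst <- random_instance(seed + 500, n = 20, m = 6, p = 1)
    y_sig <- inst$X %*% rnorm(6) * 0.5 + inst$Y
    f_one <- fit_pls(inst$X, y_sig, 1)
    set.seed(seed)
    f_two <- fit_pls(inst$X, cbind(y_sig, rnorm(20, sd = sd(y_sig))), 1)
    if (f_two$explained_y_pct[1] < f_one$explained_y_pct[1]) worse <- worse + 1
  }
  expect_gte(worse, 38)  # monotone in >= 95% of draws
})

test_that("predictions are invariant to column shifts (centering contract)", {
  inst <- random_instance(11, n = 15, m = 6, p = 2)
  f <- fit_pls(inst$X, inst$Y, 3)
  X2 <- sweep(inst$X, 2, c(5, -3, 0, 100, 1, 2), "+")
  Y2 <- sweep(inst$Y, 2, c(-7, 4), "+")
  f2 <- fit_pls(X2, Y2, 3)
  p1 <- predict(f, inst$X)
  p2 <- sweep(predict(f2, X2), 2, c(-7, 4))
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("NIPALS agrees with an established reference implementation", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(8:20, 1); m <- sample(4:15, 1); p <- sample(1:3, 1)
    K <- sample(1:3, 1)
    X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("g", 1:m)))
    Y <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("y", 1:p)))
    f <- fit_pls(X, Y, K)
    fm <- mixOmics::pls(X, Y, ncomp = K, scale = FALSE, mode = "regression")
    pm <- predict(fm, X)$predict[, , K, drop = FALSE]
    expect_lt(max(abs(predict(f, X) - pm[, , 1])), 1e-8)
    # scores agree up to sign
    expect_equal(abs(cor(f$T[, K], fm$variates$X[, K])), 1, tolerance = 1e-8)
  }
})

test_that("input validation catches bad shapes and values", {
  inst <- random_instance(1)
  expect_error(fit_pls(inst$X[1:2, ], inst$Y[1:2, ], 1), "3 samples")
  expect_error(fit_pls(inst$X, inst$Y, 50), "n_components")
  Xb <- inst$X; Xb[2, 2] <- NA
  expect_error(fit_pls(Xb, inst$Y, 1), "non-finite")
  expect_error(fit_pls(inst$X, matrix(1, 12, 1), 1), "no variance")
})

test_that("leave-one-out selects the planted component count", {
  # rank-1 predictor block with a noisy response: one component is all the
  # data supports, and the tie-break floor keeps the selection at k = 1
  set.seed(77)
  for (s in 1:10) {
    g <- rnorm(20); a <- rnorm(100)
    X <- tcrossprod(g, a)
    y <- g + rnorm(20, sd = sd(g) / 2)
    cv <- loo_cv(X, y, max_components = 3)
    expect_identical(cv$optimal, 1L)
    expect_identical(nrow(cv$table), 4L)
    expect_equal(cv$table$rmsep,
                 sqrt(cv$table$press / cv$n_folds_used), tolerance = 1e-12)
  }
})

test_that("leave-one-out on pure noise prefers few components", {
  set.seed(88)
  small <- 0
  for (s in 1:10) {
    X <- matrix(rnorm(18 * 30), 18, 30)
    y <- rnorm(18)
    cv <- loo_cv(X, y, max_components = 4)
    if (cv$optimal <= 2) small <- small + 1
  }
  expect_gte(small, 6)
  expect_error(loo_cv(matrix(rnorm(9), 3), rnorm(3), 1), "at least 4")
})

test_that("score-response report matches direct correlations", {
  inst <- random_instance(21, n = 18, m = 7, p = 3)
  f <- fit_pls(inst$X, inst$Y, 2)
  rep <- score_response_report(f, inst$Y)
  # single response: reported r is the plain model correlation
  f1 <- fit_pls(inst$X, inst$Y[, 1, drop = FALSE], 1)
  rep1 <- score_response_report(f1, inst$Y[, 1, drop = FALSE])
  expect_equal(rep1$responses$pearson_r[1], cor(f1$T[, 1], inst$Y[, 1]),
               tolerance = 1e-12)

  # sign of Q matches sign of the component-response correlation
  for (i in seq_len(nrow(rep$responses))) {
    r <- rep$responses$pearson_r[i]
    q <- rep$responses$q_loading[i]
    if (abs(r) > 1e-8) expect_identical(sign(q), sign(r))
  }

  # duplicated response column: identical r and Q
  Y2 <- cbind(inst$Y, dup = inst$Y[, 1])
  f2 <- fit_pls(inst$X, Y2, 2)
  rep2 <- score_response_report(f2, Y2)
  r1 <- rep2$responses[rep2$responses$response == "y1", ]
  rd <- rep2$responses[rep2$responses$response == "dup", ]
  expect_equal(r1$pearson_r, rd$pearson_r, tolerance = 1e-10)
  expect_equal(r1$q_loading, rd$q_loading, tolerance = 1e-10)
})
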