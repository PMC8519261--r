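#' Partial least squares regression by NIPALS
#'
#' Extracts `n_components` paired latent components from predictors `X`
#' (n samples x m variables) and responses `Y` (n x p): per component, a unit
#' X-weight vector `w` maximising covariance between the X-score `t = X w`
#' and the Y-score `u`, X-loadings `p = X't/t't`, Y-loadings `q = Y't/t't`,
#' and the inner-relation coefficient `beta = u't/t't`, followed by deflation
#' of both blocks by the rank-one component. For a single response the inner
#' loop closes in one pass with `w` proportional to `X'y`.
#'
#' The rotated weights `R = W (P'W)^{-1}` map centred predictors directly to
#' scores (`T = Xc R`) and define the per-variable ("gene") weights used for
#' ranking. Prediction coefficients are `B = R Q'`.
#'
#' Columns of both blocks are mean-centred; unit-variance scaling is optional
#' and recorded in the fit. Zero-variance predictor columns are retained and
#' receive exactly zero weight, preserving variable indexing. Components are
#' sign-fixed so that `cor(t_k, u_k) >= 0`; if that correlation is zero the
#' component is flipped, when needed, so its largest-magnitude weight entry
#' is positive.
#'
#' @param X Numeric matrix (n x m), n >= 3, finite.
#' @param Y Numeric matrix or vector (n x p), finite.
#' @param n_components Number of components K, `K <= min(n - 1, m)`.
#' @param scale Logical; divide columns by their SD after centring
#'   (zero-variance columns are left unscaled). Default `FALSE`.
#' @param tol Convergence tolerance on the change of the weight vector.
#' @param max_iter Maximum inner-loop iterations per component. The default
#'   is generous because the inner power iteration converges slowly when the
#'   leading eigenvalues of the cross-covariance block are close.
#' @return Object of class `pls_fit`: list with `W`, `T`, `P`, `U`, `Q`, `R`
#'   (all with K columns), `beta` (inner coefficients), `coefficients`
#'   (m x p, centred scale), `x_means`, `y_means`, `x_scales`, `y_scales`,
#'   `explained_x_pct`, `explained_y_pct` (per-component percentages),
#'   `ncomp`, `scale`, and dimension metadata.
#' @seealso [gene_weights()], [explained_variance()], [loo_cv()],
#'   [score_response_report()], [predict.pls_fit()]
#' @export
#' @examples
#' X <- matrix(rnorm(60), 12, 5)
#' y <- X %*% rnorm(5)
#' f <- fit_pls(X, y, 1)
#' cor(f$T[, 1], y)
fit_pls <- function(X, Y, n_components, scale = FALSE, tol = 1e-12,
                    max_iter = 5000L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X); m <- ncol(X); p <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 3) stop("need at least 3 samples")
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("non-finite entries in X or Y")
  K <- as.integer(n_components)
  if (K < 1 || K > min(n - 1, m))
    stop(sprintf("n_components must be in [1, %d]", min(n - 1, m)))

  x_means <- colMeans(X); y_means <- colMeans(Y)
  Xc <- sweep(X, 2, x_means)
  Yc <- sweep(Y, 2, y_means)
  if (scale) {
    x_scales <- apply(Xc, 2, sd); x_scales[x_scales == 0] <- 1
    y_scales <- apply(Yc, 2, sd); y_scales[y_scales == 0] <- 1
    Xc <- sweep(Xc, 2, x_scales, "/")
    Yc <- sweep(Yc, 2, y_scales, "/")
  } else {
    x_scales <- rep(1, m); y_scales <- rep(1, p)
  }
  ssx_total <- sum(Xc^2); ssy_total <- sum(Yc^2)
  if (ssy_total == 0) stop("Y has no variance")

  W <- matrix(0, m, K); P <- matrix(0, m, K); Tm <- matrix(0, n, K)
  U <- matrix(0, n, K); Q <- matrix(0, p, K)
  beta <- numeric(K)
  exp_x <- numeric(K); exp_y <- numeric(K)
  Xk <- Xc; Yk <- Yc

  for (k in seq_len(K)) {
    # deflation exhausts the X block once k exceeds its effective rank; the
    # residual is then numerical noise whose rotated weights would explode
    if (sum(Xk^2) < 1e-18 * ssx_total)
      stop(sprintf("X block exhausted at component %d (rank < K)", k))
    if (p == 1L) {
      # single response: the inner loop closes in one pass, w proportional
      # to the cross-covariance X'y
      w <- crossprod(Xk, Yk[, 1])
      nw <- sqrt(sum(w^2))
      if (nw == 0)
        stop(sprintf("X block exhausted at component %d (rank < K)", k))
      w <- w / nw
      u <- Yk[, 1]
    } else {
      u <- Yk[, which.max(colSums(Yk^2))]
      w <- numeric(m)
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        w_new <- crossprod(Xk, u)
        nw <- sqrt(sum(w_new^2))
        if (nw == 0)
          stop(sprintf("X block exhausted at component %d (rank < K)", k))
        w_new <- w_new / nw
        tvec <- Xk %*% w_new
        cvec <- crossprod(Yk, tvec)
        cvec <- cvec / sqrt(sum(cvec^2))   # unit-norm Y-weights
        u <- Yk %*% cvec
        if (sqrt(sum((w_new - w)^2)) < tol) {
          w <- w_new; converged <- TRUE; break
        }
        w <- w_new
      }
      if (!converged)
        stop(sprintf("NIPALS did not converge within %d iterations at component %d",
                     max_iter, k))
    }
    tvec <- Xk %*% w
    tt <- sum(tvec^2)
    pvec <- crossprod(Xk, tvec) / tt
    qvec <- crossprod(Yk, tvec) / tt

    # sign convention: cor(t, u) >= 0; flip the X side (t, w, p and hence q)
    su <- sd(u); st <- sd(tvec)
    r_tu <- if (su > 0 && st > 0) cor(tvec, u) else 0
    if (r_tu < 0) {
      w <- -w; tvec <- -tvec; pvec <- -pvec; qvec <- -qvec
    } else if (r_tu == 0 && w[which.max(abs(w))] < 0) {
      w <- -w; tvec <- -tvec; pvec <- -pvec; qvec <- -qvec
    }

    W[, k] <- w; Tm[, k] <- tvec; P[, k] <- pvec; Q[, k] <- qvec
    U[, k] <- u
    beta[k] <- sum(u * tvec) / sum(tvec^2)
    tt <- sum(tvec^2)
    exp_x[k] <- 100 * tt * sum(pvec^2) / ssx_total
    exp_y[k] <- 100 * tt * sum(qvec^2) / ssy_total

    Xk <- Xk - tcrossprod(tvec, pvec)
    Yk <- Yk - tcrossprod(tvec, qvec)
  }

  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)
  dimnames(R) <- list(colnames(X), paste0("comp", seq_len(K)))
  dimnames(W) <- dimnames(R)
  dimnames(P) <- dimnames(R)
  dimnames(B) <- list(colnames(X), colnames(Y))
  dimnames(Q) <- list(colnames(Y), paste0("comp", seq_len(K)))
  dimnames(Tm) <- list(rownames(X), paste0("comp", seq_len(K)))
  dimnames(U) <- dimnames(Tm)

  structure(list(W = W, T = Tm, P = P, U = U, Q = Q, R = R, beta = beta,
                 coefficients = B, x_means = x_means, y_means = y_means,
                 x_scales = x_scales, y_scales = y_scales,
                 explained_x_pct = exp_x, explained_y_pct = exp_y,
                 ncomp = K, scale = scale, n = n, m = m, p = p,
                 y_names = colnames(Y)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("PLS fit (NIPALS): %d components, X %d x %d, Y %d x %d%s\n",
              x$ncomp, x$n, x$m, x$n, x$p,
              if (x$scale) ", unit-scaled" else ""))
  ev <- rbind(`X var explained (%)` = round(x$explained_x_pct, 1),
              `Y var explained (%)` = round(x$explained_y_pct, 1))
  colnames(ev) <- paste0("comp", seq_len(x$ncomp))
  print(ev)
  invisible(x)
}

#' Predict responses from a PLS fit
#'
#' @param object A `pls_fit`.
#' @param newdata Numeric matrix with the same predictor columns as the
#'   training data.
#' @param n_components Use the first k components (default: all fitted).
#' @param ... Unused.
#' @return Matrix of predicted responses (n x p).
#' @export
predict.pls_fit <- function(object, newdata, n_components = object$ncomp,
                            ...) {
  k <- as.integer(n_components)
  stopifnot(k >= 1, k <= object$ncomp)
  newdata <- as.matrix(newdata)
  Xc <- sweep(sweep(newdata, 2, object$x_means), 2, object$x_scales, "/")
  Bk <- object$R[, seq_len(k), drop = FALSE] %*%
    t(object$Q[, seq_len(k), drop = FALSE])
  Yp <- Xc %*% Bk
  Yp <- sweep(Yp, 2, object$y_scales, "*")
  sweep(Yp, 2, object$y_means, "+")
}

#' Extract per-gene weights for one component
#'
#' Returns column `component` of the rotated weight matrix
#' `R = W (P'W)^{-1}`, the vector that maps centred predictors to the
#' component score (`t_k = Xc R[, k]`). These are the weights by which genes
#' are ranked for enrichment analysis. Zero-variance genes carry weight
#' exactly 0.
#'
#' @param fit A `pls_fit`.
#' @param component Component index, `1 <= k <= ncomp`.
#' @return Named numeric vector of length m.
#' @export
gene_weights <- function(fit, component = 1L) {
  k <- as.integer(component)
  if (k < 1 || k > fit$ncomp)
    stop(sprintf("component must be in [1, %d]", fit$ncomp))
  w <- fit$R[, k]
  if (is.null(names(w)) && !is.null(rownames(fit$R))) names(w) <- rownames(fit$R)
  w
}

#' Per-component explained variance
#'
#' Fraction of the centred X (and Y) sum of squares reconstructed by each
#' component: `||t_k p_k'||_F^2 / ||Xc||_F^2` and the analogous Y quantity,
#' reported in percent with cumulative totals.
#'
#' @param fit A `pls_fit`.
#' @return Data frame: `component`, `x_pct`, `y_pct`, `x_cum_pct`,
#'   `y_cum_pct`.
#' @export
explained_variance <- function(fit) {
  data.frame(component = seq_len(fit$ncomp),
             x_pct = fit$explained_x_pct,
             y_pct = fit$explained_y_pct,
             x_cum_pct = cumsum(fit$explained_x_pct),
             y_cum_pct = cumsum(fit$explained_y_pct))
}

#' Leave-one-out cross-validation for component selection
#'
#' Refits the model on each leave-one-out fold (re-centring, and re-scaling
#' if requested, inside the fold so no information leaks), predicts the
#' held-out response with k = 0..`max_components` components (k = 0 is the
#' training-mean prediction), and accumulates the predictive residual sum of
#' squares. `RMSEP(k) = sqrt(PRESS(k) / (n p))`; the optimal component count
#' is the k >= 1 minimising RMSEP, ties resolved towards the smaller k.
#'
#' Folds whose training predictors are constant are skipped and counted; if
#' a fold supports fewer than `max_components` components (deflation
#' exhausts the X block), predictions for the missing k reuse the largest
#' available component count.
#'
#' @param X,Y As in [fit_pls()]; requires `n >= 4`.
#' @param max_components Largest k to evaluate;
#'   `<= min(n - 2, m)`.
#' @param scale Passed to [fit_pls()].
#' @return Object of class `pls_cv`: list with `table` (data frame
#'   `components`, `press`, `rmsep`), `optimal` (k), `n_folds_used`,
#'   `n_folds_skipped`.
#' @export
loo_cv <- function(X, Y, max_components, scale = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(Y)
  if (n < 4) stop("need at least 4 samples for leave-one-out")
  K <- as.integer(max_components)
  if (K < 1 || K > min(n - 2, ncol(X)))
    stop(sprintf("max_components must be in [1, %d]", min(n - 2, ncol(X))))

  press <- numeric(K + 1)   # index 1 = k0
  used <- 0L; skipped <- 0L
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; Yi <- Y[-i, , drop = FALSE]
    if (all(apply(Xi, 2, var) == 0)) { skipped <- skipped + 1L; next }
    fit <- tryCatch(fit_pls(Xi, Yi, K, scale = scale), error = function(e) e)
    kmax <- K
    while (inherits(fit, "error") && kmax > 1) {
      kmax <- kmax - 1L
      fit <- tryCatch(fit_pls(Xi, Yi, kmax, scale = scale),
                      error = function(e) e)
    }
    if (inherits(fit, "error")) { skipped <- skipped + 1L; next }
    used <- used + 1L
    press[1] <- press[1] + sum((Y[i, ] - colMeans(Yi))^2)
    for (k in seq_len(K)) {
      pred <- predict(fit, X[i, , drop = FALSE],
                      n_components = min(k, kmax))
      press[k + 1] <- press[k + 1] + sum((Y[i, ] - pred)^2)
    }
  }
  if (used == 0) stop("all leave-one-out folds degenerate")
  rmsep <- sqrt(press / (used * p))
  tab <- data.frame(components = 0:K, press = press, rmsep = rmsep)
  optimal <- which.min(rmsep[-1])   # ties -> smaller k
  structure(list(table = tab, optimal = optimal, n_folds_used = used,
                 n_folds_skipped = skipped),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out CV over %d folds (%d skipped); optimal k = %d\n",
              x$n_folds_used, x$n_folds_skipped, x$optimal))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Score-response correlation and loading report
#'
#' For each component k: the Pearson correlation between the X-score `t_k`
#' and the Y-score `u_k` (the within-model latent correlation). For each raw
#' response column: the Pearson correlation between `t_k` and that column
#' together with the Y-loading `Q[j, k]` — both carry the sign and magnitude
#' of the component-response association. Zero-variance responses are
#' flagged with `NA` correlation.
#'
#' @param fit A `pls_fit`.
#' @param Y The response matrix the model was trained on (n x p).
#' @return List with `components` (data frame `component`, `r_tu`, `beta`)
#'   and `responses` (data frame `component`, `response`, `pearson_r`,
#'   `q_loading`).
#' @export
score_response_report <- function(fit, Y) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == fit$n, ncol(Y) == fit$p)
  resp_names <- if (!is.null(colnames(Y))) colnames(Y) else
    paste0("y", seq_len(ncol(Y)))
  comp <- data.frame(
    component = seq_len(fit$ncomp),
    r_tu = vapply(seq_len(fit$ncomp), function(k) {
      if (sd(fit$U[, k]) == 0 || sd(fit$T[, k]) == 0) NA_real_
      else cor(fit$T[, k], fit$U[, k])
    }, numeric(1)),
    beta = fit$beta)
  rows <- expand.grid(component = seq_len(fit$ncomp),
                      response = resp_names, stringsAsFactors = FALSE)
  rows$pearson_r <- mapply(function(k, j) {
    y <- Y[, match(j, resp_names)]
    if (sd(y) == 0 || sd(fit$T[, k]) == 0) NA_real_ else cor(fit$T[, k], y)
  }, rows$component, rows$response)
  rows$q_loading <- mapply(function(k, j) fit$Q[match(j, resp_names), k],
                           rows$component, rows$response)
  list(components = comp, responses = rows)
}

#' Write PLS fit artifacts as TSV tables
#'
#' @param fit A `pls_fit`.
#' @param dir Output directory.
#' @param cv Optional `pls_cv` result to include.
#' @return Invisibly, the written paths.
#' @export
write_pls <- function(fit, dir, cv = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(df, name) {
    pth <- file.path(dir, name)
    write.table(df, pth, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, pth)
  }
  wt(data.frame(region = rownames(fit$T), fit$T, check.names = FALSE),
     "scores.tsv")
  wt(data.frame(gene = rownames(fit$R), fit$R, check.names = FALSE),
     "gene_weights.tsv")
  wt(data.frame(response = rownames(fit$Q), fit$Q, check.names = FALSE),
     "y_loadings.tsv")
  wt(explained_variance(fit), "explained_variance.tsv")
  if (!is.null(cv)) wt(cv$table, "cv.tsv")
  invisible(paths)
}
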