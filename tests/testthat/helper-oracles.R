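# Independent oracles used across the test files. Each deliberately takes a
# different computational route than the package implementation it checks.

# Non-iterative kernel PLS: per component the X-weight vector is the dominant
# eigenvector of X'YY'X (computed via an eigendecomposition of the small
# p x p matrix M'M), followed by the same rank-one deflation. Returns
# training predictions using k components.
kernel_pls_predict <- function(X, Y, K) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xk <- sweep(X, 2, xm); Yk <- sweep(Y, 2, ym)
  m <- ncol(X); p <- ncol(Y)
  W <- matrix(0, m, K); P <- matrix(0, m, K); Q <- matrix(0, p, K)
  for (k in seq_len(K)) {
    M <- crossprod(Xk, Yk)                       # m x p
    if (p == 1) {
      w <- M[, 1]
    } else {
      e <- eigen(crossprod(M), symmetric = TRUE) # p x p
      w <- M %*% e$vectors[, 1]
    }
    w <- w / sqrt(sum(w^2))
    tv <- Xk %*% w
    tt <- sum(tv^2)
    pv <- crossprod(Xk, tv) / tt
    qv <- crossprod(Yk, tv) / tt
    W[, k] <- w; P[, k] <- pv; Q[, k] <- qv
    Xk <- Xk - tcrossprod(tv, pv)
    Yk <- Yk - tcrossprod(tv, qv)
  }
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  sweep(sweep(X, 2, xm) %*% B, 2, ym, "+")
}

# X-scores of the kernel reference (same algorithm as kernel_pls_predict)
kernel_pls_scores <- function(X, Y, K) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xk <- sweep(X, 2, colMeans(X)); Yk <- sweep(Y, 2, colMeans(Y))
  p <- ncol(Y)
  Tm <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    M <- crossprod(Xk, Yk)
    w <- if (p == 1) M[, 1] else M %*% eigen(crossprod(M),
                                             symmetric = TRUE)$vectors[, 1]
    w <- w / sqrt(sum(w^2))
    tv <- Xk %*% w
    tt <- sum(tv^2)
    pv <- crossprod(Xk, tv) / tt
    qv <- crossprod(Yk, tv) / tt
    Tm[, k] <- tv
    Xk <- Xk - tcrossprod(tv, pv)
    Yk <- Yk - tcrossprod(tv, qv)
  }
  Tm
}

# ordinary least-squares predictions of Y on [1, X]
ols_predict <- function(X, Y) {
  Xd <- cbind(1, as.matrix(X))
  Xd %*% solve(crossprod(Xd), crossprod(Xd, as.matrix(Y)))
}

# closed-form OLS t-statistic of the coefficient on x1 in y ~ 1 + x1 + x2
ols_t_beta1 <- function(y, x1, x2) {
  X <- cbind(1, x1, x2)
  XtXi <- solve(crossprod(X))
  b <- XtXi %*% crossprod(X, y)
  res <- y - X %*% b
  df <- length(y) - 3
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * XtXi[2, 2])
  tval <- b[2] / se
  list(estimate = b[2], t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df))
}

# literal step-up Benjamini-Hochberg definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, p[o[i]] * m / i)
    q[o[i]] <- min(1, run)
  }
  q
}

# brute-force running-sum ES over the full trace of the ranked list
es_brute <- function(weights, set, exponent = 1) {
  ord <- order(-weights, names(weights), method = "radix")
  ranked <- weights[ord]
  hit <- names(ranked) %in% set
  n <- length(ranked); nh <- sum(hit)
  wexp <- abs(ranked)^exponent
  S <- sum(wexp[hit])
  inc <- if (S == 0) hit / nh else wexp * hit / S
  run <- cumsum(inc - (!hit) / (n - nh))
  unname(run[which.max(abs(run))])
}

# exhaustive nearest-labelled-voxel assignment over every voxel of the grid
assign_brute <- function(annot, parcellation, tolerance_mm = 2) {
  idx <- which(parcellation$labels > 0, arr.ind = TRUE)
  centers <- cbind(idx - 1, 1) %*% t(parcellation$affine)
  centers <- centers[, 1:3, drop = FALSE]
  labs <- parcellation$labels[idx]
  inv <- solve(parcellation$affine)
  out <- data.frame(sample_id = annot$sample_id, region = NA_integer_,
                    distance_mm = NA_real_)
  for (s in seq_len(nrow(annot))) {
    xyz <- as.numeric(annot[s, c("mni_x", "mni_y", "mni_z")])
    v <- round((inv %*% c(xyz, 1))[1:3])
    dims <- dim(parcellation$labels)
    if (all(v >= 0) && all(v < dims) &&
        parcellation$labels[v[1] + 1, v[2] + 1, v[3] + 1] > 0) {
      out$region[s] <- parcellation$labels[v[1] + 1, v[2] + 1, v[3] + 1]
      out$distance_mm[s] <- 0
      next
    }
    d <- sqrt(rowSums(sweep(centers, 2, xyz)^2))
    dmin <- min(d)
    out$distance_mm[s] <- dmin
    if (dmin <= tolerance_mm + 1e-12)
      out$region[s] <- min(labs[d <= dmin + 1e-9])
  }
  out
}

# small default scenario used by several files
tiny_scenario <- function(seed = 1, n_patients = 30, n_controls = 40, ...) {
  synthetic_scenario(n_regions = 8, n_genes = 60, n_donors = 3,
                     n_patients = n_patients, n_controls = n_controls,
                     seed = seed, ...)
}

# random gene-set collection over a gene panel
random_sets <- function(gene_ids, n_sets, size, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) sample(gene_ids, size))
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  sets
}
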