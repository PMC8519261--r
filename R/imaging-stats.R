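#' Welch's unequal-variance t-test
#'
#' Two-sided t-test without the equal-variance assumption:
#' \eqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}} with
#' Welch-Satterthwaite degrees of freedom. A thin validating wrapper around
#' [stats::t.test()] that also resolves the degenerate zero-variance cases
#' `t.test` refuses: both groups constant and equal means gives a flagged
#' undefined result (`t = NaN`), constant but different means a flagged
#' infinite statistic with `p = 0`.
#'
#' @param a,b Numeric vectors, each of length >= 2, finite.
#' @return Named list: `t`, `df`, `p`, and `flag` (`NA_character_` for a
#'   regular result, `"zero_variance"` for the degenerate cases).
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = NaN, df = NA_real_, p = NA_real_,
                  flag = "zero_variance"))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0,
                flag = "zero_variance"))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, flag = NA_character_)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with sorted p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, the adjusted value is
#' \eqn{q_{(i)} = \min_{k \ge i} \min(1, p_{(k)} m / k)}, returned in input
#' order. Validates the input and delegates to
#' `stats::p.adjust(method = "BH")`. `NA` entries are propagated (and not
#' counted in `m`).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Regional group contrast of cortical thickness
#'
#' One Welch t-test per region, oriented control minus patient so that a
#' positive t-statistic means thinner cortex in patients (atrophy).
#' Benjamini-Hochberg correction is applied across exactly the supplied
#' region set (e.g. 68 bilateral or 34 unilateral regions).
#'
#' @param ct A `ct_table` data frame (columns `group` plus CT columns).
#' @param regions Character vector of CT column names to test.
#' @param group_col Name of the group column. Values must be `"patient"` /
#'   `"control"`.
#' @return Data frame: `region`, `t`, `df`, `p`, `q`, `n_control`,
#'   `n_patient`, `flag`. Regions absent from the table are recorded in the
#'   `"excluded"` attribute and omitted.
#' @export
regional_group_contrast <- function(ct, regions, group_col = "group") {
  grp <- ct[[group_col]]
  if (!all(c("patient", "control") %in% grp))
    stop("both groups must be present")
  missing_cols <- setdiff(regions, names(ct))
  regions_use <- setdiff(regions, missing_cols)
  if (length(regions_use) == 0) stop("none of the requested regions present")

  res <- lapply(regions_use, function(r) {
    a <- ct[[r]][grp == "control"]
    b <- ct[[r]][grp == "patient"]
    w <- welch_t(a, b)
    data.frame(region = r, t = w$t, df = w$df, p = w$p,
               n_control = length(a), n_patient = length(b), flag = w$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out <- out[, c("region", "t", "df", "p", "q", "n_control", "n_patient",
                 "flag")]
  attr(out, "excluded") <- missing_cols
  out
}

#' Hemispheric contrast of cortical thickness
#'
#' Per-region contrast of right minus left hemisphere CT, so a positive
#' t-statistic means thinner cortex on the left. Paired t-test by default
#' (the same subjects contribute both hemispheres); an unpaired Welch test is
#' available via `paired = FALSE`. BH correction across the supplied region
#' set. Subjects missing either hemisphere in a region are dropped and
#' counted.
#'
#' @param ct A `ct_table` with `lh_<region>` / `rh_<region>` columns.
#' @param regions Base region names (without hemisphere prefix).
#' @param paired Logical; paired test (default) or Welch unpaired.
#' @param group Optional group label to subset on (e.g. `"patient"`);
#'   `NULL` uses all rows.
#' @return Data frame: `region`, `t`, `df`, `p`, `q`, `n`, `n_dropped`,
#'   `mode`.
#' @export
hemispheric_contrast <- function(ct, regions, paired = TRUE, group = NULL) {
  if (!is.null(group)) ct <- ct[ct$group == group, , drop = FALSE]
  res <- lapply(regions, function(r) {
    lh <- ct[[paste0("lh_", r)]]
    rh <- ct[[paste0("rh_", r)]]
    if (is.null(lh) || is.null(rh))
      stop("missing hemisphere column for region ", r)
    ok <- is.finite(lh) & is.finite(rh)
    lh <- lh[ok]; rh <- rh[ok]
    if (paired) {
      d <- rh - lh
      if (var(d) == 0) {
        t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        out <- list(t = t, df = length(d) - 1,
                    p = if (mean(d) == 0) 1 else 0)
      } else {
        ht <- stats::t.test(rh, lh, paired = TRUE)
        out <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                    p = ht$p.value)
      }
    } else {
      w <- welch_t(rh, lh)
      out <- list(
        t = if (is.nan(w$t)) 0 else w$t,
        df = w$df,
        p = if (is.na(w$p)) 1 else w$p)
    }
    data.frame(region = r, t = out$t, df = out$df, p = out$p,
               n = length(lh), n_dropped = sum(!ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$mode <- if (paired) "paired" else "welch"
  out[, c("region", "t", "df", "p", "q", "n", "n_dropped", "mode")]
}

#' Region-wise regression of cortical thickness on clinical scores
#'
#' For every (region, clinical feature) pair, fits the ordinary
#' least-squares model
#' \deqn{CT_i = \alpha + \beta_1 K_j + \beta_2 Age + \varepsilon}
#' on complete cases among patients and reports the estimate, t-statistic
#' and two-sided p-value of \eqn{\beta_1} (null hypothesis
#' \eqn{\beta_1 = 0}). BH correction is applied jointly across all tested
#' (region, feature) cells. Cells with fewer than 4 complete cases or a
#' singular design (e.g. constant age or constant score) are flagged and
#' excluded from the BH family.
#'
#' @param ct A `ct_table`; only rows with `group == "patient"` are used.
#' @param clinical Data frame with `subject` and one numeric column per
#'   feature (`NA` = missing).
#' @param regions Base region names; CT is taken from the `lh_<region>`
#'   columns (the hemisphere matching a left-only expression matrix).
#' @param features Feature column names; default all non-`subject` columns.
#' @param hemisphere Prefix of the CT columns to model (`"lh"` or `"rh"`).
#' @return Data frame of class `regression_stats`: `region`, `feature`,
#'   `estimate` (beta1), `t`, `df`, `p`, `q`, `n`, `flag`.
#' @export
ct_clinical_regression <- function(ct, clinical, regions,
                                   features = setdiff(names(clinical),
                                                      "subject"),
                                   hemisphere = "lh") {
  pats <- ct[ct$group == "patient", , drop = FALSE]
  if (nrow(pats) == 0) stop("no patients in ct table")
  m <- match(pats$subject, clinical$subject)
  cl <- clinical[m, , drop = FALSE]

  grid <- expand.grid(feature = features, region = regions,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- grid$region[i]; f <- grid$feature[i]
    y <- pats[[paste0(hemisphere, "_", r)]]
    if (is.null(y)) stop("missing CT column for region ", r)
    k <- cl[[f]]
    ok <- complete.cases(y, k, pats$age)
    n <- sum(ok)
    if (n < 4) {
      rows[[i]] <- data.frame(region = r, feature = f, estimate = NA_real_,
                              t = NA_real_, df = NA_real_, p = NA_real_,
                              n = n, flag = "insufficient_n",
                              stringsAsFactors = FALSE)
      next
    }
    X <- cbind(1, k[ok], pats$age[ok])
    if (qr(X)$rank < 3) {
      rows[[i]] <- data.frame(region = r, feature = f, estimate = NA_real_,
                              t = NA_real_, df = NA_real_, p = NA_real_,
                              n = n, flag = "singular_design",
                              stringsAsFactors = FALSE)
      next
    }
    fit <- lm(y[ok] ~ k[ok] + pats$age[ok])
    sm <- summary(fit)$coefficients
    rows[[i]] <- data.frame(region = r, feature = f,
                            estimate = sm[2, "Estimate"],
                            t = sm[2, "t value"], df = fit$df.residual,
                            p = sm[2, "Pr(>|t|)"], n = n,
                            flag = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- is.na(out$flag)
  if (any(!tested))
    warning(sum(!tested), " (region, feature) cell(s) flagged and excluded ",
            "from the BH family")
  out$q[tested] <- bh_adjust(out$p[tested])
  out <- out[, c("region", "feature", "estimate", "t", "df", "p", "q", "n",
                 "flag")]
  class(out) <- c("regression_stats", "data.frame")
  out
}

#' Reshape regression statistics into a regions-by-features t-matrix
#'
#' Convenience accessor for the multi-response PLS layer: pivots a
#' [ct_clinical_regression()] result into a numeric matrix of t-statistics
#' with regions in rows and clinical features in columns.
#'
#' @param reg A `regression_stats` data frame.
#' @param value Which column to pivot (default `"t"`).
#' @return Numeric matrix, rows named by region, columns by feature.
#' @export
regression_t_matrix <- function(reg, value = "t") {
  regions <- unique(reg$region)
  features <- unique(reg$feature)
  M <- matrix(NA_real_, length(regions), length(features),
              dimnames = list(regions, features))
  M[cbind(match(reg$region, regions), match(reg$feature, features))] <-
    reg[[value]]
  M
}
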