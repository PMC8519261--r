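#' Read a gene-set collection from a GMT file
#'
#' Tab-separated lines: set name, description, then member gene ids.
#' Duplicate genes within a set are collapsed; empty lines are skipped.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (class `gene_set_collection`),
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad))
    stop(sprintf("GMT parse error: line %d has fewer than 3 fields",
                 keep[which(bad)[1]]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  attr(sets, "descriptions") <- setNames(vapply(fields, `[[`, "", 2),
                                         names(sets))
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set descriptions (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

# ranking order used throughout: descending signed weight, ties broken by
# gene id in C-locale lexicographic order (recorded in result metadata)
gsea_rank_order <- function(weights) {
  order(-weights, names(weights), method = "radix")
}

# ES from sorted hit positions in a ranked list of n_total genes.
# wabs_exp = |weight|^exponent of the ranked list. The running sum increases
# by wabs_exp/sum(at hits) at each hit and decreases by 1/(n - h) per miss;
# its extrema occur at hit positions (just after) or just before hits, so
# only those 2h candidates are examined. The signed maximum deviation is
# returned; an exact tie between the positive and negative extremum resolves
# to the positive one.
es_from_positions <- function(pos, wabs_exp, n_total) {
  h <- length(pos)
  S <- sum(wabs_exp[pos])
  cw <- if (S == 0) seq_len(h) / h else cumsum(wabs_exp[pos]) / S
  miss <- if (n_total == h) 0 else 1 / (n_total - h)
  d <- (pos - seq_len(h)) * miss
  after <- cw - d
  before <- c(0, cw[-h]) - d
  mx <- max(after); mn <- min(before)
  if (mx >= -mn) mx else mn
}

#' Weighted running-sum enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov-style statistic: genes are ranked by
#' descending signed weight (ties by gene id); walking down the list, the
#' running sum gains \eqn{|w|^{exponent} / \sum_{set} |w|^{exponent}} at each
#' set member and loses \eqn{1/(N - N_H)} at each non-member. The enrichment
#' score is the signed maximum deviation of this walk from zero, always in
#' `[-1, 1]`. With `exponent = 0` it reduces to the unweighted KS statistic
#' between hit and miss positions.
#'
#' @param weights Named numeric vector of per-gene weights (the universe).
#' @param set Character vector of member gene ids; genes outside the
#'   universe are ignored.
#' @param exponent Weighting exponent (default 1, the classic statistic).
#' @return List: `es`, `running` (the full running-sum trace in rank order),
#'   `positions` (ranks of the set members), `ranked_genes`.
#' @export
#' @examples
#' w <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
#' enrichment_score(w, c("g1", "g3"))$es  # 2/3
enrichment_score <- function(weights, set, exponent = 1) {
  if (is.null(names(weights))) stop("weights must be named by gene id")
  if (any(!is.finite(weights))) stop("weights must be finite")
  ord <- gsea_rank_order(weights)
  ranked <- weights[ord]
  n <- length(ranked)
  pos <- sort(match(intersect(unique(set), names(ranked)), names(ranked)))
  if (length(pos) == 0) stop("set has empty intersection with the universe")
  wabs <- abs(ranked)^exponent
  es <- es_from_positions(pos, wabs, n)

  hit <- logical(n); hit[pos] <- TRUE
  S <- sum(wabs[pos])
  inc <- if (S == 0) as.numeric(hit) / length(pos) else wabs * hit / S
  dec <- if (n == length(pos)) 0 else (!hit) / (n - length(pos))
  running <- unname(cumsum(inc - dec))
  list(es = es, running = running, positions = pos,
       ranked_genes = names(ranked))
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' Ranks genes by descending signed weight, computes the weighted
#' running-sum enrichment score for every set (after intersection with the
#' universe and size filtering), and builds a null distribution per set size
#' from `n_perm` random same-size gene draws. The two-sided p-value is the
#' tail frequency \eqn{(1 + \#\{|ES_{null}| \ge |ES|\}) / (n_{perm} + 1)};
#' the normalised score divides ES by the mean `|null ES|` of matching sign.
#' Benjamini-Hochberg correction is applied across all tested sets, and each
#' set is labelled `+`/`-` by the median signed weight of its members.
#' Results are fully reproducible given the seed.
#'
#' @param weights Named numeric vector of per-gene weights.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations, >= 100. Default 10000.
#' @param seed Integer RNG seed for the permutation draws.
#' @param min_size,max_size Set-size filter applied after universe
#'   intersection. Defaults 10 and 500.
#' @param exponent Passed to the running-sum statistic.
#' @return Data frame of class `gsea_result`: `set`, `size`, `es`, `nes`,
#'   `p`, `q`, `median_weight`, `direction`; parameters in attributes.
#' @export
gsea_preranked <- function(weights, sets, n_perm = 10000L, seed = 1L,
                           min_size = 10L, max_size = 500L, exponent = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (is.null(names(weights))) stop("weights must be named by gene id")
  ord <- gsea_rank_order(weights)
  ranked <- weights[ord]
  n <- length(ranked)
  wabs <- abs(ranked)^exponent

  members <- lapply(sets, function(s)
    sort(match(intersect(unique(s), names(ranked)), names(ranked))))
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    warning("no gene set survives the size filter")
    out <- data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), q = numeric(0),
                      median_weight = numeric(0), direction = character(0))
    class(out) <- c("gsea_result", "data.frame")
    return(out)
  }
  members <- members[keep]
  sizes <- sizes[keep]

  es_obs <- vapply(members, es_from_positions, numeric(1),
                   wabs_exp = wabs, n_total = n)

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed) %% 2147483647)
  null_by_size <- list()
  for (s in sort(unique(sizes))) {
    null_by_size[[as.character(s)]] <- vapply(seq_len(n_perm), function(b)
      es_from_positions(sort(sample.int(n, s)), wabs, n), numeric(1))
  }

  p <- numeric(length(members)); nes <- numeric(length(members))
  for (i in seq_along(members)) {
    nulls <- null_by_size[[as.character(sizes[i])]]
    p[i] <- (1 + sum(abs(nulls) >= abs(es_obs[i]))) / (n_perm + 1)
    same <- nulls[sign(nulls) == sign(es_obs[i])]
    nes[i] <- if (es_obs[i] == 0) 0
      else if (length(same) == 0) NA_real_
      else es_obs[i] / mean(abs(same))
  }

  med <- vapply(seq_along(members), function(i)
    median(ranked[members[[i]]]), numeric(1))
  out <- data.frame(set = names(members), size = sizes, es = es_obs,
                    nes = nes, p = p, q = bh_adjust(p), median_weight = med,
                    direction = ifelse(med > 0, "+", ifelse(med < 0, "-", "0")),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gsea_result", "data.frame")
  attr(out, "params") <- list(n_perm = n_perm, seed = seed,
                              min_size = min_size, max_size = max_size,
                              exponent = exponent,
                              tie_break = "descending weight, then gene id")
  out
}

#' Direction of a pathway relative to the ranked weights
#'
#' `"+"` if the median signed weight of the set's members (after universe
#' intersection) is positive, `"-"` if negative, `"0"` if exactly zero (for
#' an even member count the median is the mean of the middle two weights).
#'
#' @param set Character vector of gene ids.
#' @param weights Named numeric weight vector.
#' @return `"+"`, `"-"` or `"0"`.
#' @export
pathway_direction <- function(set, weights) {
  w <- weights[intersect(unique(set), names(weights))]
  if (length(w) == 0) stop("set has empty intersection with the universe")
  m <- median(w)
  if (m > 0) "+" else if (m < 0) "-" else "0"
}
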