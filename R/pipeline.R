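#' Pipeline configuration
#'
#' Collects every input path and tunable of the two end-to-end analyses into
#' a validated list. All defaults are recorded so the run manifest documents
#' the exact settings used.
#'
#' @param parcellation Path to the NIfTI label volume (with its
#'   `_labels.tsv` sidecar).
#' @param donor_dir Directory holding per-donor `SampleAnnot.csv` /
#'   `Expression.csv` pairs.
#' @param ct_table Path to the TSV cortical-thickness table.
#' @param clinical_table Path to the TSV clinical score table (model-2).
#' @param gmt Path to the gene-set GMT file.
#' @param out_dir Output directory.
#' @param tolerance_mm Sample-to-parcel assignment tolerance (mm).
#' @param n_components_model2 Components fitted in the multi-response model.
#' @param retain_model2 Components carried into enrichment for model-2.
#' @param cv_max_components Largest k examined by leave-one-out CV.
#' @param gsea_nperm,gsea_min_size,gsea_max_size Enrichment settings.
#' @param seed Master seed (drives the permutation null).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(parcellation, donor_dir, ct_table,
                            clinical_table = NULL, gmt, out_dir,
                            tolerance_mm = 2, n_components_model2 = 3L,
                            retain_model2 = 2L, cv_max_components = 5L,
                            gsea_nperm = 10000L, gsea_min_size = 10L,
                            gsea_max_size = 500L, seed = 1L) {
  cfg <- list(parcellation = parcellation, donor_dir = donor_dir,
              ct_table = ct_table, clinical_table = clinical_table,
              gmt = gmt, out_dir = out_dir, tolerance_mm = tolerance_mm,
              n_components_model2 = as.integer(n_components_model2),
              retain_model2 = as.integer(retain_model2),
              cv_max_components = as.integer(cv_max_components),
              gsea_nperm = as.integer(gsea_nperm),
              gsea_min_size = as.integer(gsea_min_size),
              gsea_max_size = as.integer(gsea_max_size),
              seed = as.integer(seed))
  for (f in c("parcellation", "ct_table", "gmt")) {
    if (!file.exists(cfg[[f]])) stop("missing input file: ", cfg[[f]])
  }
  if (!dir.exists(cfg$donor_dir)) stop("missing donor directory")
  if (!is.null(cfg$clinical_table) && !file.exists(cfg$clinical_table))
    stop("missing clinical table")
  class(cfg) <- "pipeline_config"
  cfg
}

# join a region-expression matrix with a named response on region names;
# returns the common-region X and Y plus a reconciliation record
join_regions <- function(region_expr, y_names) {
  x_names <- rownames(region_expr$X)
  common <- intersect(x_names, y_names)
  if (length(common) < 10)
    stop(sprintf("only %d regions common to expression and response; >= 10 required",
                 length(common)))
  list(common = common,
       dropped_x = setdiff(x_names, common),
       dropped_y = setdiff(y_names, common))
}

#' Single-response analysis: expression versus cortical-thickness change
#'
#' The model-1 core, operating on in-memory objects: computes the bilateral
#' regional group contrast for reporting and the single-hemisphere contrast
#' whose t-statistics form the PLS response, joins regions between the
#' expression matrix and the response, fits a one-component single-response
#' PLS, runs leave-one-out component selection, reports score-response
#' correlations, and tests gene sets on the component-1 weights.
#'
#' @param region_expr A `region_expression` object (rows named by region).
#' @param ct A `ct_table` with both groups.
#' @param gene_sets Named list of gene sets.
#' @param hemisphere CT hemisphere joined to the (single-hemisphere)
#'   expression matrix. Default `"lh"`.
#' @param cv_max_components Largest k examined by LOO CV.
#' @param gsea_nperm,gsea_seed,gsea_min_size,gsea_max_size Enrichment
#'   settings.
#' @return List of class `model1_result`: `contrast_bilateral`,
#'   `contrast_hemi`, `join` (region reconciliation), `fit`, `cv`, `report`,
#'   `weights`, `gsea`.
#' @export
model1_analysis <- function(region_expr, ct, gene_sets, hemisphere = "lh",
                            cv_max_components = 5L, gsea_nperm = 10000L,
                            gsea_seed = 1L, gsea_min_size = 10L,
                            gsea_max_size = 500L) {
  region_names <- rownames(region_expr$X)
  ct_cols <- grep("^(lh|rh)_", names(ct), value = TRUE)
  contrast_bilateral <- regional_group_contrast(ct, ct_cols)

  hemi_cols <- paste0(hemisphere, "_", region_names)
  hemi_cols <- hemi_cols[hemi_cols %in% names(ct)]
  contrast_hemi <- regional_group_contrast(ct, hemi_cols)
  y <- setNames(contrast_hemi$t,
                sub(paste0("^", hemisphere, "_"), "", contrast_hemi$region))
  y <- y[is.finite(y)]

  join <- join_regions(region_expr, names(y))
  X <- region_expr$X[join$common, , drop = FALSE]
  yv <- y[join$common]

  fit <- fit_pls(X, yv, n_components = 1L)
  kmax <- min(cv_max_components, nrow(X) - 2, ncol(X))
  cv <- loo_cv(X, matrix(yv, ncol = 1), max_components = kmax)
  report <- score_response_report(fit, matrix(yv, ncol = 1,
                                              dimnames = list(NULL, "t_dCT")))
  w <- gene_weights(fit, 1L)
  gsea <- gsea_preranked(w, gene_sets, n_perm = gsea_nperm, seed = gsea_seed,
                         min_size = gsea_min_size, max_size = gsea_max_size)

  structure(list(contrast_bilateral = contrast_bilateral,
                 contrast_hemi = contrast_hemi, join = join, fit = fit,
                 cv = cv, report = report, weights = w, gsea = gsea,
                 response = yv),
            class = "model1_result")
}

#' Multi-response analysis: expression versus CT-clinical couplings
#'
#' The model-2 core: builds the regions-by-features matrix of t-statistics
#' from the region-wise CT-on-clinical-score regressions, joins regions with
#' the expression matrix, fits a multi-response PLS, reports per-response
#' correlations and Y-loadings, and runs enrichment on each retained
#' component's gene weights. Features whose t-statistic is undefined in any
#' common region (flagged regression cells) are dropped with a warning.
#'
#' @inheritParams model1_analysis
#' @param clinical Clinical score data frame (`subject` + feature columns).
#' @param n_components Components to fit (capped by the data dimensions).
#' @param retain Components carried into enrichment (default 2).
#' @return List of class `model2_result`: `regression`, `t_matrix`, `join`,
#'   `fit`, `cv`, `report`, `gsea` (one result per retained component),
#'   `dropped_features`.
#' @export
model2_analysis <- function(region_expr, ct, clinical, gene_sets,
                            hemisphere = "lh", n_components = 3L,
                            retain = 2L, cv_max_components = 5L,
                            gsea_nperm = 10000L, gsea_seed = 1L,
                            gsea_min_size = 10L, gsea_max_size = 500L) {
  region_names <- rownames(region_expr$X)
  reg <- ct_clinical_regression(ct, clinical, regions = region_names,
                                hemisphere = hemisphere)
  tmat <- regression_t_matrix(reg)

  join <- join_regions(region_expr, rownames(tmat))
  X <- region_expr$X[join$common, , drop = FALSE]
  Y <- tmat[join$common, , drop = FALSE]

  bad <- colSums(!is.finite(Y)) > 0
  if (any(bad)) {
    warning("dropping feature(s) with undefined t-statistics: ",
            paste(colnames(Y)[bad], collapse = ", "))
    Y <- Y[, !bad, drop = FALSE]
  }
  if (ncol(Y) == 0) stop("no usable clinical features")

  K <- min(n_components, nrow(X) - 1, ncol(X))
  fit <- fit_pls(X, Y, n_components = K)
  kmax <- min(cv_max_components, nrow(X) - 2, ncol(X))
  cv <- loo_cv(X, Y, max_components = kmax)
  report <- score_response_report(fit, Y)

  retain <- min(retain, K)
  gsea <- lapply(seq_len(retain), function(k)
    gsea_preranked(gene_weights(fit, k), gene_sets, n_perm = gsea_nperm,
                   seed = gsea_seed + k - 1L, min_size = gsea_min_size,
                   max_size = gsea_max_size))
  names(gsea) <- paste0("comp", seq_len(retain))

  structure(list(regression = reg, t_matrix = tmat, join = join, fit = fit,
                 cv = cv, report = report, gsea = gsea,
                 dropped_features = colnames(tmat)[bad]),
            class = "model2_result")
}

read_ct_table <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  class(ct) <- c("ct_table", "data.frame")
  ct
}

run_manifest <- function(cfg, extra) {
  c(list(package = "ctxpls",
         version = as.character(utils::packageVersion("ctxpls")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(cfg)),
    extra)
}

#' Run the single-response pipeline from a configuration
#'
#' Reads all inputs, maps samples to parcels, aggregates the region-by-gene
#' matrix, executes [model1_analysis()], and writes tidy TSV outputs plus a
#' JSON manifest under `out_dir/model1`. One log line per stage reports the
#' in/out counts.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return The `model1_result`, invisibly (with an `out_dir` attribute).
#' @export
run_model1 <- function(cfg, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  parc <- read_parcellation(cfg$parcellation)
  samples <- read_donor_samples(cfg$donor_dir)
  say("loaded %d samples from %d donors", nrow(samples$annot),
      length(unique(samples$annot$donor)))
  asg <- assign_samples(samples, parc, tolerance_mm = cfg$tolerance_mm)
  say("assigned %d / %d samples (tolerance %.1f mm)",
      sum(!is.na(asg$region)), nrow(asg), cfg$tolerance_mm)
  rex <- aggregate_expression(samples, asg,
                              region_ids = seq_along(parc$region_names),
                              region_names = parc$region_names)
  say("aggregated %d regions x %d genes (%d regions dropped)",
      nrow(rex$X), ncol(rex$X), length(rex$dropped_regions))
  ct <- read_ct_table(cfg$ct_table)
  sets <- read_gmt(cfg$gmt)
  res <- model1_analysis(rex, ct, sets,
                         cv_max_components = cfg$cv_max_components,
                         gsea_nperm = cfg$gsea_nperm, gsea_seed = cfg$seed,
                         gsea_min_size = cfg$gsea_min_size,
                         gsea_max_size = cfg$gsea_max_size)
  say("model-1: r(t1, y) = %.3f; %d/%d sets at FDR < 0.05",
      res$report$responses$pearson_r[1],
      sum(res$gsea$q < 0.05), nrow(res$gsea))

  out <- file.path(cfg$out_dir, "model1")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_mapping(rex, asg, out)
  wt <- function(df, name) write.table(df, file.path(out, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  wt(res$contrast_bilateral, "contrast_bilateral.tsv")
  wt(res$contrast_hemi, "contrast_hemisphere.tsv")
  write_pls(res$fit, out, cv = res$cv)
  wt(res$report$responses, "score_response.tsv")
  wt(res$gsea, "gsea.tsv")
  manifest <- run_manifest(cfg, list(
    stage = "model1",
    n_samples = nrow(asg), n_assigned = sum(!is.na(asg$region)),
    regions_common = length(res$join$common),
    regions_dropped_x = res$join$dropped_x,
    regions_dropped_y = res$join$dropped_y,
    cv_optimal = res$cv$optimal))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  attr(res, "out_dir") <- out
  invisible(res)
}

#' Run the multi-response pipeline from a configuration
#'
#' As [run_model1()], but the response is the regions-by-features matrix of
#' t-statistics from the CT-clinical regressions, the PLS is multi-response,
#' and enrichment runs once per retained component. Outputs land under
#' `out_dir/model2`.
#'
#' @inheritParams run_model1
#' @return The `model2_result`, invisibly (with an `out_dir` attribute).
#' @export
run_model2 <- function(cfg, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(cfg$clinical_table))
    stop("model-2 needs a clinical table in the configuration")
  parc <- read_parcellation(cfg$parcellation)
  samples <- read_donor_samples(cfg$donor_dir)
  say("loaded %d samples from %d donors", nrow(samples$annot),
      length(unique(samples$annot$donor)))
  asg <- assign_samples(samples, parc, tolerance_mm = cfg$tolerance_mm)
  say("assigned %d / %d samples", sum(!is.na(asg$region)), nrow(asg))
  rex <- aggregate_expression(samples, asg,
                              region_ids = seq_along(parc$region_names),
                              region_names = parc$region_names)
  ct <- read_ct_table(cfg$ct_table)
  clinical <- read.delim(cfg$clinical_table, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  sets <- read_gmt(cfg$gmt)
  res <- model2_analysis(rex, ct, clinical, sets,
                         n_components = cfg$n_components_model2,
                         retain = cfg$retain_model2,
                         cv_max_components = cfg$cv_max_components,
                         gsea_nperm = cfg$gsea_nperm, gsea_seed = cfg$seed,
                         gsea_min_size = cfg$gsea_min_size,
                         gsea_max_size = cfg$gsea_max_size)
  say("model-2: fitted %d components over %d features; CV optimum %d",
      res$fit$ncomp, res$fit$p, res$cv$optimal)

  out <- file.path(cfg$out_dir, "model2")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_mapping(rex, asg, out)
  wt <- function(df, name) write.table(df, file.path(out, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  wt(res$regression, "ct_clinical_regression.tsv")
  write_pls(res$fit, out, cv = res$cv)
  wt(res$report$responses, "score_response.tsv")
  for (k in names(res$gsea)) wt(res$gsea[[k]], sprintf("gsea_%s.tsv", k))
  manifest <- run_manifest(cfg, list(
    stage = "model2",
    n_samples = nrow(asg), n_assigned = sum(!is.na(asg$region)),
    regions_common = length(res$join$common),
    dropped_features = res$dropped_features,
    cv_optimal = res$cv$optimal))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  attr(res, "out_dir") <- out
  invisible(res)
}
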