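#' Define a synthetic imaging-transcriptomics scenario
#'
#' A scenario bundles every parameter of the synthetic data generator:
#' cohort sizes, the planted spatial expression gradient, per-gene loadings
#' onto that gradient, per-region group effects on cortical thickness (CT),
#' the coefficients linking clinical scores to regional CT, and all noise
#' scales. Together with its `seed` it fully determines every generated
#' dataset, so downstream recovery tests can compare estimates against the
#' stored ground truth.
#'
#' Default cohort sizes follow a typical single-centre Parkinson's disease
#' imaging study (149 patients, 369 controls) and six expression donors.
#' The default gradient is a zero-mean linear ramp across region index;
#' regions are laid out by [make_parcellation()] so that region index
#' increases along the first (x) grid axis, i.e. the ramp is a
#' caudal-to-rostral spatial axis. The default CT effect is proportional to
#' the gradient (`0.1 mm` per gradient unit), so atrophy co-varies with the
#' planted expression axis.
#'
#' Any vector argument left `NULL` is drawn once, deterministically, under
#' `seed`, and stored in the returned object.
#'
#' @param n_regions Number of cortical regions (one hemisphere). Default 34.
#' @param n_genes Number of genes on the shared panel.
#' @param n_donors Number of expression donors. Default 6.
#' @param n_patients,n_controls Cohort sizes for the CT tables.
#' @param region_gradient Numeric length `n_regions`; the planted spatial
#'   axis `g_i`. Centred to zero mean (identifiability convention).
#' @param gene_loadings Numeric length `n_genes`; how strongly each gene
#'   follows the gradient (`a_j`). Default `N(0, 0.5)` draws.
#' @param ct_effect Numeric length `n_regions`; planted patient-minus-control
#'   CT decrease in mm (`delta_i`, positive = atrophy). Default
#'   `0.1 * region_gradient`.
#' @param ct_hemi_effect Numeric length `n_regions`; additional left-hemisphere
#'   thinning (mm) planted in patients only. Default 0.
#' @param clinical_coefficients Matrix `n_features x n_regions` of true
#'   coefficients linking each clinical score to left-hemisphere regional CT.
#'   Default: three regions per feature with coefficients of magnitude 2.
#' @param clinical_features Character vector of clinical feature names.
#'   Defaults to the nine numeric severity/dose/cognition scores of a
#'   standard Parkinson assessment battery.
#' @param age_coefficients Numeric, one per feature; contribution of age to
#'   each score. Default small `U(-0.1, 0.1)` draws.
#' @param mean_expression Numeric length `n_genes`; baseline (log-intensity
#'   scale) expression `mu_j`. Default `N(7, 1)` draws.
#' @param ct_base Numeric length `n_regions`; control-group mean CT in mm.
#'   Default `U(2.2, 3.0)` draws, the usual cortical range.
#' @param noise_sd_expression Expression noise SD (log-intensity units).
#' @param noise_sd_ct CT noise SD in mm.
#' @param noise_sd_clinical Clinical score noise SD.
#' @param zero_cell_prob Probability that a donor contributes no sample to a
#'   region (exercises the missing-donor averaging path). Default 0.1.
#' @param samples_per_cell Mean (Poisson) sample count per non-empty
#'   donor-region cell. Default 5.
#' @param missing_rate Fraction of clinical score entries set missing
#'   completely at random. Default 0.2.
#' @param ct_truncation_mm Lower truncation bound for CT draws (mm);
#'   thickness is physically positive. Default 0.5.
#' @param seed Integer master seed; every generator derives its RNG state
#'   from it.
#'
#' @return An object of class `synthetic_scenario` (a list with the fields
#'   above, all defaults materialised).
#' @seealso [make_parcellation()], [make_donor_samples()],
#'   [make_ct_cohort()], [make_clinical()]
#' @export
#' @examples
#' sc <- synthetic_scenario(n_regions = 8, n_genes = 50, seed = 42)
#' mean(sc$region_gradient)  # 0 by convention
synthetic_scenario <- function(n_regions = 34,
                               n_genes = 1000,
                               n_donors = 6,
                               n_patients = 149,
                               n_controls = 369,
                               region_gradient = NULL,
                               gene_loadings = NULL,
                               ct_effect = NULL,
                               ct_hemi_effect = NULL,
                               clinical_coefficients = NULL,
                               clinical_features = c("AGEONSET", "SENSPDSC",
                                 "MDS_UPDRS_1", "MDS_UPDRS_2", "MDS_UPDRS_3",
                                 "MDS_UPDRS_4", "UPDRSTOTSCR", "MMSE", "LED"),
                               age_coefficients = NULL,
                               mean_expression = NULL,
                               ct_base = NULL,
                               noise_sd_expression = 0.5,
                               noise_sd_ct = 0.25,
                               noise_sd_clinical = 2,
                               zero_cell_prob = 0.1,
                               samples_per_cell = 5,
                               missing_rate = 0.2,
                               ct_truncation_mm = 0.5,
                               seed = 1L) {
  counts <- c(n_regions = n_regions, n_genes = n_genes, n_donors = n_donors,
              n_patients = n_patients, n_controls = n_controls)
  if (any(counts < 1))
    stop("all counts must be >= 1; offending: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  sds <- c(noise_sd_expression, noise_sd_ct, noise_sd_clinical)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("noise SDs must be finite and >= 0")
  if (zero_cell_prob < 0 || zero_cell_prob >= 1)
    stop("zero_cell_prob must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  seed <- as.integer(seed)

  n_features <- length(clinical_features)

  # materialise defaulted random fields deterministically
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stage_seed(seed, 0L))

  if (is.null(region_gradient)) {
    region_gradient <- if (n_regions == 1) 0 else
      seq(-1, 1, length.out = n_regions)
  }
  stopifnot(length(region_gradient) == n_regions)
  region_gradient <- region_gradient - mean(region_gradient)

  if (is.null(gene_loadings)) gene_loadings <- rnorm(n_genes, 0, 0.5)
  stopifnot(length(gene_loadings) == n_genes)

  if (is.null(ct_effect)) ct_effect <- 0.1 * region_gradient
  stopifnot(length(ct_effect) == n_regions)

  if (is.null(ct_hemi_effect)) ct_hemi_effect <- rep(0, n_regions)
  stopifnot(length(ct_hemi_effect) == n_regions)

  if (is.null(mean_expression)) mean_expression <- rnorm(n_genes, 7, 1)
  stopifnot(length(mean_expression) == n_genes)

  if (is.null(ct_base)) ct_base <- runif(n_regions, 2.2, 3.0)
  stopifnot(length(ct_base) == n_regions)

  if (is.null(clinical_coefficients)) {
    clinical_coefficients <- matrix(0, n_features, n_regions)
    k <- min(3L, n_regions)
    for (j in seq_len(n_features)) {
      idx <- sample.int(n_regions, k)
      clinical_coefficients[j, idx] <- sample(c(-2, 2), k, replace = TRUE)
    }
  }
  clinical_coefficients <- as.matrix(clinical_coefficients)
  stopifnot(nrow(clinical_coefficients) == n_features,
            ncol(clinical_coefficients) == n_regions)

  if (is.null(age_coefficients)) age_coefficients <- runif(n_features, -0.1, 0.1)
  stopifnot(length(age_coefficients) == n_features)

  region_names <- region_name_set(n_regions)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  rownames(clinical_coefficients) <- clinical_features
  colnames(clinical_coefficients) <- region_names

  structure(list(
    n_regions = n_regions, n_genes = n_genes, n_donors = n_donors,
    n_patients = n_patients, n_controls = n_controls,
    region_names = region_names, gene_ids = gene_ids,
    region_gradient = setNames(region_gradient, region_names),
    gene_loadings = setNames(gene_loadings, gene_ids),
    ct_effect = setNames(ct_effect, region_names),
    ct_hemi_effect = setNames(ct_hemi_effect, region_names),
    clinical_features = clinical_features,
    clinical_coefficients = clinical_coefficients,
    age_coefficients = setNames(age_coefficients, clinical_features),
    mean_expression = setNames(mean_expression, gene_ids),
    ct_base = setNames(ct_base, region_names),
    noise_sd_expression = noise_sd_expression,
    noise_sd_ct = noise_sd_ct,
    noise_sd_clinical = noise_sd_clinical,
    zero_cell_prob = zero_cell_prob,
    samples_per_cell = samples_per_cell,
    missing_rate = missing_rate,
    ct_truncation_mm = ct_truncation_mm,
    seed = seed
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic imaging-transcriptomics scenario\n")
  cat(sprintf("  regions: %d  genes: %d  donors: %d\n",
              x$n_regions, x$n_genes, x$n_donors))
  cat(sprintf("  cohort: %d patients / %d controls\n",
              x$n_patients, x$n_controls))
  cat(sprintf("  noise SD: expression %.3g, CT %.3g mm, clinical %.3g\n",
              x$noise_sd_expression, x$noise_sd_ct, x$noise_sd_clinical))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# save/restore the global RNG state so generators are pure functions of the
# scenario seed without clobbering the caller's RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
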