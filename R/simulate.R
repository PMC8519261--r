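#' Generate donor expression samples inside a parcellation
#'
#' Emulates the layout of multi-donor microarray atlas data: each donor
#' contributes a random number of point samples per region (possibly zero;
#' the zero-cell probability is a scenario parameter), each with mm
#' coordinates drawn uniformly inside the region's voxels and an expression
#' vector
#' \deqn{x_{sj} = \mu_j + a_j g_{i(s)} + \varepsilon,\qquad
#'       \varepsilon \sim N(0, \sigma_e^2),}
#' where \eqn{g_i} is the planted region gradient and \eqn{a_j} the gene
#' loading. Fully deterministic in the scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param parcellation A [make_parcellation()] result (or compatible object).
#' @return Object of class `donor_samples`: list with `annot` (data frame:
#'   `donor`, `sample_id`, `mni_x`, `mni_y`, `mni_z`, `region_truth`),
#'   `expression` (genes x samples matrix, columns named by sample id),
#'   `gene_ids`, and `cell_counts` (donors x regions sample-count matrix).
#' @export
make_donor_samples <- function(scenario, parcellation) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  nd <- scenario$n_donors
  nr <- scenario$n_regions
  if (length(parcellation$region_names) < nr)
    stop("parcellation has fewer regions than the scenario")

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stage_seed(scenario$seed, 1L))

  # per-(donor, region) sample counts, drawn in one fixed order
  zero <- matrix(rbinom(nd * nr, 1, scenario$zero_cell_prob), nd, nr)
  counts <- matrix(rpois(nd * nr, scenario$samples_per_cell), nd, nr)
  counts[zero == 1] <- 0L
  dimnames(counts) <- list(sprintf("donor_%02d", seq_len(nd)),
                           scenario$region_names[seq_len(nr)])

  # voxel lists per region (1-based array indices)
  vox <- lapply(seq_len(nr), function(r)
    which(parcellation$labels == r, arr.ind = TRUE))

  total <- sum(counts)
  coords <- matrix(NA_real_, total, 3)
  donor <- integer(total)
  region <- integer(total)
  pos <- 0L
  for (d in seq_len(nd)) {
    for (r in seq_len(nr)) {
      k <- counts[d, r]
      if (k == 0L) next
      pick <- vox[[r]][sample.int(nrow(vox[[r]]), k, replace = TRUE), ,
                       drop = FALSE]
      # uniform inside the voxel cube, in voxel space, then to mm (0-based)
      u <- matrix(runif(3 * k, -0.5, 0.5), k, 3)
      mm <- cbind(pick - 1 + u, 1) %*% t(parcellation$affine)
      coords[pos + seq_len(k), ] <- mm[, 1:3]
      donor[pos + seq_len(k)] <- d
      region[pos + seq_len(k)] <- r
      pos <- pos + k
    }
  }

  g <- as.numeric(scenario$region_gradient)[region]
  mu <- as.numeric(scenario$mean_expression)
  a <- as.numeric(scenario$gene_loadings)
  expr <- matrix(mu, scenario$n_genes, total) +
    outer(a, g) +
    matrix(rnorm(scenario$n_genes * total, 0, scenario$noise_sd_expression),
           scenario$n_genes, total)

  sample_id <- sprintf("d%02d_s%04d", donor, stats::ave(donor, donor,
                                                        FUN = seq_along))
  rownames(expr) <- scenario$gene_ids
  colnames(expr) <- sample_id

  structure(list(
    annot = data.frame(donor = sprintf("donor_%02d", donor),
                       sample_id = sample_id,
                       mni_x = coords[, 1], mni_y = coords[, 2],
                       mni_z = coords[, 3],
                       region_truth = region,
                       stringsAsFactors = FALSE),
    expression = expr,
    gene_ids = scenario$gene_ids,
    cell_counts = counts
  ), class = "donor_samples")
}

#' @export
print.donor_samples <- function(x, ...) {
  cat(sprintf("Donor expression samples: %d samples, %d genes, %d donors\n",
              nrow(x$annot), length(x$gene_ids),
              length(unique(x$annot$donor))))
  invisible(x)
}

#' Generate a two-group cortical thickness cohort
#'
#' Controls draw regional CT from `N(base_i, noise_sd_ct)`; patients from
#' `N(base_i - delta_i, noise_sd_ct)` where `delta_i` is the planted group
#' effect, so positive `delta` means thinner cortex in patients (atrophy).
#' Both hemispheres are generated; the scenario's `ct_hemi_effect` is an
#' additional left-hemisphere thinning planted in patients only. Draws are
#' truncated below at the scenario's `ct_truncation_mm` (thickness is
#' physically positive). Patient and control ages are drawn around the
#' cohort means 64.8 and 65.7 years (SD 8, clamped to 40-90); sex is drawn
#' with the cohort male fractions 0.657 and 0.481.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A data frame of class `ct_table`: `subject`, `group`
#'   (`"patient"`/`"control"`), `age`, `sex`, then one CT column (mm) per
#'   region and hemisphere, named `lh_<region>` / `rh_<region>`.
#' @export
make_ct_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stage_seed(scenario$seed, 2L))

  np <- scenario$n_patients; nc <- scenario$n_controls
  nr <- scenario$n_regions
  n <- np + nc
  group <- rep(c("patient", "control"), c(np, nc))
  subject <- c(sprintf("pd_%03d", seq_len(np)), sprintf("hc_%03d", seq_len(nc)))
  age <- pmin(90, pmax(40, rnorm(n, ifelse(group == "patient", 64.8, 65.7), 8)))
  sex <- ifelse(rbinom(n, 1, ifelse(group == "patient", 0.657, 0.481)) == 1,
                "M", "F")

  base <- as.numeric(scenario$ct_base)
  delta <- as.numeric(scenario$ct_effect)
  asym <- as.numeric(scenario$ct_hemi_effect)
  pat <- as.numeric(group == "patient")

  mean_lh <- outer(pat, delta + asym, function(p, e) -p * e) +
    matrix(base, n, nr, byrow = TRUE)
  mean_rh <- outer(pat, delta, function(p, e) -p * e) +
    matrix(base, n, nr, byrow = TRUE)
  lh <- pmax(mean_lh + matrix(rnorm(n * nr, 0, scenario$noise_sd_ct), n, nr),
             scenario$ct_truncation_mm)
  rh <- pmax(mean_rh + matrix(rnorm(n * nr, 0, scenario$noise_sd_ct), n, nr),
             scenario$ct_truncation_mm)
  colnames(lh) <- paste0("lh_", scenario$region_names)
  colnames(rh) <- paste0("rh_", scenario$region_names)

  out <- data.frame(subject = subject, group = group, age = age, sex = sex,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(lh), as.data.frame(rh))
  class(out) <- c("ct_table", "data.frame")
  attr(out, "region_names") <- scenario$region_names
  out
}

#' Generate clinical scores coupled to regional cortical thickness
#'
#' Patient score for feature `j` is
#' \deqn{K_j(s) = \sum_i \beta_1(j,i)\, CT_{lh}(s,i) + \gamma_j\,Age(s)
#'       + \varepsilon,}
#' using the scenario's true coefficient matrix and age coefficients, plus
#' Gaussian noise. Entries are then set missing completely at random at the
#' scenario `missing_rate` (written as empty fields in TSV output, never
#' zero).
#'
#' @param scenario A [synthetic_scenario()].
#' @param ct_table A [make_ct_cohort()] table containing the patient group.
#' @return Data frame: `subject`, then one numeric column per clinical
#'   feature (patients only; `NA` = missing).
#' @export
make_clinical <- function(scenario, ct_table) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  pats <- ct_table[ct_table$group == "patient", , drop = FALSE]
  if (nrow(pats) == 0) stop("ct_table contains no patients")

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stage_seed(scenario$seed, 3L))

  ct_lh <- as.matrix(pats[, paste0("lh_", scenario$region_names),
                          drop = FALSE])
  B <- scenario$clinical_coefficients        # features x regions
  scores <- ct_lh %*% t(B) +
    outer(pats$age, as.numeric(scenario$age_coefficients)) +
    matrix(rnorm(nrow(pats) * nrow(B), 0, scenario$noise_sd_clinical),
           nrow(pats), nrow(B))
  colnames(scores) <- scenario$clinical_features
  if (scenario$missing_rate > 0) {
    drop <- matrix(rbinom(length(scores), 1, scenario$missing_rate) == 1,
                   nrow(scores))
    scores[drop] <- NA_real_
  }
  data.frame(subject = pats$subject, scores,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a full synthetic dataset to disk in the consumed layouts
#'
#' Produces everything the pipeline reads: a NIfTI label volume (plus label
#' TSV), per-donor `SampleAnnot.csv` / `Expression.csv` pairs mirroring the
#' Allen atlas packaging, TSV cortical-thickness and clinical tables (missing
#' clinical values as empty fields), and a JSON sidecar with the complete
#' scenario ground truth.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory (created if needed).
#' @param parcellation Optional pre-built parcellation; default
#'   `make_parcellation(scenario)`.
#' @return Invisibly, a named list of the generated objects and paths.
#' @export
write_scenario_data <- function(scenario, dir,
                                parcellation = make_parcellation(scenario)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- make_donor_samples(scenario, parcellation)
  ct <- make_ct_cohort(scenario)
  clinical <- make_clinical(scenario, ct)

  nii <- file.path(dir, "parcellation.nii")
  write_parcellation(parcellation, nii)
  write_donor_samples(samples, dir)
  write.table(ct, file.path(dir, "ct.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  truth <- scenario
  class(truth) <- NULL
  truth$clinical_coefficients <- as.data.frame(truth$clinical_coefficients)
  jsonlite::write_json(truth, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(parcellation = parcellation, samples = samples, ct = ct,
                 clinical = clinical, dir = dir, nifti = nii))
}

#' Write / read donor samples in the Allen-atlas-style layout
#'
#' One sub-directory per donor, holding `SampleAnnot.csv` (sample id and MNI
#' coordinates) and `Expression.csv` (genes in rows, samples in columns, gene
#' id in the first column).
#'
#' @param samples A `donor_samples` object.
#' @param dir Parent directory.
#' @return `write_donor_samples`: `dir`, invisibly. `read_donor_samples`: a
#'   `donor_samples` object (without ground-truth region or cell counts).
#' @export
write_donor_samples <- function(samples, dir) {
  for (d in unique(samples$annot$donor)) {
    dd <- file.path(dir, d)
    dir.create(dd, recursive = TRUE, showWarnings = FALSE)
    rows <- samples$annot$donor == d
    write.csv(samples$annot[rows, c("donor", "sample_id", "mni_x", "mni_y",
                                    "mni_z")],
              file.path(dd, "SampleAnnot.csv"), row.names = FALSE,
              quote = FALSE)
    ex <- data.frame(gene_id = rownames(samples$expression),
                     samples$expression[, rows, drop = FALSE],
                     check.names = FALSE)
    write.csv(ex, file.path(dd, "Expression.csv"), row.names = FALSE,
              quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_donor_samples
#' @export
read_donor_samples <- function(dir) {
  donors <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  donors <- donors[file.exists(file.path(dir, donors, "SampleAnnot.csv"))]
  if (length(donors) == 0) stop("no donor sub-directories under ", dir)
  annot <- list(); exprs <- list()
  for (d in donors) {
    a <- read.csv(file.path(dir, d, "SampleAnnot.csv"),
                  stringsAsFactors = FALSE)
    e <- read.csv(file.path(dir, d, "Expression.csv"), check.names = FALSE,
                  stringsAsFactors = FALSE)
    m <- as.matrix(e[, -1, drop = FALSE])
    rownames(m) <- e[[1]]
    annot[[d]] <- a
    exprs[[d]] <- m
  }
  gene_ids <- rownames(exprs[[1]])
  expr <- do.call(cbind, lapply(exprs, function(m) m[gene_ids, , drop = FALSE]))
  structure(list(annot = do.call(rbind, c(annot, make.row.names = FALSE)),
                 expression = expr, gene_ids = gene_ids,
                 cell_counts = NULL),
            class = "donor_samples")
}
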