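#' Assign point expression samples to parcellation regions
#'
#' Each sample is assigned to the region of the voxel containing its mm
#' coordinate when that voxel is labelled (distance recorded as 0: the point
#' lies inside the parcel). Otherwise it is assigned to the region of the
#' nearest labelled voxel centre within `tolerance_mm` (Euclidean distance in
#' mm); ties at equal distance go to the lower region id. Samples farther
#' than the tolerance from every labelled voxel centre stay unassigned.
#'
#' @param samples A `donor_samples` object, or a data frame with columns
#'   `sample_id`, `mni_x`, `mni_y`, `mni_z`.
#' @param parcellation A `parcellation` object (invertible affine mapping
#'   0-based voxel indices to mm).
#' @param tolerance_mm Non-negative assignment tolerance in mm. Default 2,
#'   the conventional mapping tolerance for atlas expression samples.
#' @return Data frame of class `sample_assignment`: `sample_id`, `region`
#'   (integer id, `NA` when unassigned), `region_name`, `distance_mm`, and
#'   `method` (`"containment"`, `"nearest"` or `"unassigned"`).
#' @export
assign_samples <- function(samples, parcellation, tolerance_mm = 2) {
  annot <- if (inherits(samples, "donor_samples")) samples$annot else samples
  stopifnot(all(c("sample_id", "mni_x", "mni_y", "mni_z") %in% names(annot)))
  if (tolerance_mm < 0) stop("tolerance_mm must be >= 0")
  xyz <- as.matrix(annot[, c("mni_x", "mni_y", "mni_z")])
  if (any(!is.finite(xyz))) stop("non-finite sample coordinates")

  inv <- solve(parcellation$affine)
  vox <- cbind(xyz, 1) %*% t(inv)          # continuous 0-based voxel coords
  idx <- round(vox[, 1:3, drop = FALSE])   # containing voxel
  dims <- dim(parcellation$labels)

  n <- nrow(xyz)
  region <- rep(NA_integer_, n)
  dist <- rep(NA_real_, n)
  method <- rep("unassigned", n)

  inb <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
         idx[, 2] >= 0 & idx[, 2] < dims[2] &
         idx[, 3] >= 0 & idx[, 3] < dims[3]
  lab <- rep(0L, n)
  if (any(inb)) {
    lin <- idx[inb, 1] + dims[1] * (idx[inb, 2] + dims[2] * idx[inb, 3]) + 1
    lab[inb] <- parcellation$labels[lin]
  }
  contained <- lab > 0L
  region[contained] <- lab[contained]
  dist[contained] <- 0
  method[contained] <- "containment"

  todo <- which(!contained)
  if (length(todo) > 0) {
    lv <- labelled_voxel_centers(parcellation)
    for (s in todo) {
      d2 <- (lv$mm[, 1] - xyz[s, 1])^2 + (lv$mm[, 2] - xyz[s, 2])^2 +
            (lv$mm[, 3] - xyz[s, 3])^2
      dmin <- sqrt(min(d2))
      if (dmin <= tolerance_mm + 1e-12) {
        ties <- which(sqrt(d2) <= dmin + 1e-9)
        region[s] <- min(lv$region[ties])
        dist[s] <- dmin
        method[s] <- "nearest"
      } else {
        dist[s] <- dmin
      }
    }
  }

  out <- data.frame(sample_id = annot$sample_id, region = region,
                    region_name = ifelse(is.na(region), NA_character_,
                                         parcellation$region_names[region]),
                    distance_mm = dist, method = method,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_assignment", "data.frame")
  attr(out, "tolerance_mm") <- tolerance_mm
  out
}

#' Aggregate sample expression into a region-by-gene matrix
#'
#' Two-level averaging: per donor and region, expression is averaged across
#' that donor's assigned samples; per region, the donor means are then
#' averaged across donors that contributed at least one sample there (donors
#' with no samples in a region are excluded from its mean, never imputed as
#' zero). Regions with no samples from any donor are dropped and reported.
#' Genes are returned in canonical (sorted id) order, so permuting the input
#' panel does not change the result.
#'
#' @param samples A `donor_samples` object (annotation plus genes-x-samples
#'   expression matrix).
#' @param assignments The matching [assign_samples()] result.
#' @param region_ids Integer region ids to tabulate; defaults to all ids that
#'   received at least one sample.
#' @param region_names Optional names for `region_ids` (used as matrix row
#'   names); defaults to names found in `assignments`.
#' @return Object of class `region_expression`: list with `X` (regions x
#'   genes mean-expression matrix, rows named by region), `counts`
#'   (donors x regions contributing-sample counts), `region_ids`,
#'   `dropped_regions` (ids with zero samples overall), `gene_ids`.
#' @export
aggregate_expression <- function(samples, assignments, region_ids = NULL,
                                 region_names = NULL) {
  stopifnot(inherits(samples, "donor_samples"))
  annot <- samples$annot
  if (nrow(annot) != nrow(assignments))
    stop("assignments must cover all samples")
  if (!identical(annot$sample_id, assignments$sample_id))
    assignments <- assignments[match(annot$sample_id,
                                     assignments$sample_id), ]

  if (is.null(region_ids))
    region_ids <- sort(unique(assignments$region[!is.na(assignments$region)]))
  if (length(region_ids) == 0) stop("no regions to aggregate")
  if (is.null(region_names)) {
    region_names <- assignments$region_name[match(region_ids,
                                                  assignments$region)]
    region_names[is.na(region_names)] <- as.character(
      region_ids[is.na(region_names)])
  }

  genes <- sort(rownames(samples$expression))
  expr <- samples$expression[genes, , drop = FALSE]
  donors <- sort(unique(annot$donor))

  keep <- !is.na(assignments$region) & assignments$region %in% region_ids
  cell <- interaction(factor(annot$donor[keep], levels = donors),
                      factor(assignments$region[keep], levels = region_ids),
                      drop = FALSE)
  counts <- matrix(tabulate(cell, nbins = length(donors) * length(region_ids)),
                   nrow = length(donors),
                   dimnames = list(donors, region_names))
  if (all(counts == 0)) stop("all regions empty: no sample mapped to any requested region")

  # per-(donor, region) means: sum columns per cell, divide by counts
  sums <- rowsum(t(expr[, keep, drop = FALSE]), cell)  # cells x genes (levels kept)
  full <- matrix(0, length(donors) * length(region_ids), length(genes),
                 dimnames = list(levels(cell), genes))
  full[rownames(sums), ] <- sums
  cnt_vec <- as.vector(counts)
  donor_means <- full / ifelse(cnt_vec == 0, NA, cnt_vec)

  X <- matrix(NA_real_, length(region_ids), length(genes),
              dimnames = list(region_names, genes))
  for (r in seq_along(region_ids)) {
    rows <- (r - 1) * length(donors) + seq_along(donors)
    contributing <- cnt_vec[rows] > 0
    if (any(contributing))
      X[r, ] <- colMeans(donor_means[rows[contributing], , drop = FALSE])
  }

  dropped <- region_ids[colSums(counts) == 0]
  if (length(dropped) > 0) {
    keep_r <- colSums(counts) > 0
    X <- X[keep_r, , drop = FALSE]
    counts <- counts[, keep_r, drop = FALSE]
    region_ids_kept <- region_ids[keep_r]
    message(sprintf("dropped %d region(s) with no mapped samples: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  } else region_ids_kept <- region_ids

  structure(list(X = X, counts = counts, region_ids = region_ids_kept,
                 dropped_regions = dropped, gene_ids = genes),
            class = "region_expression")
}

#' @export
print.region_expression <- function(x, ...) {
  cat(sprintf("Region expression matrix: %d regions x %d genes (%d dropped)\n",
              nrow(x$X), ncol(x$X), length(x$dropped_regions)))
  invisible(x)
}

#' Write mapping artifacts as TSV
#'
#' Writes the assignment table, the region-by-gene matrix, and the QC table
#' of per-(donor, region) contributing-sample counts.
#'
#' @param region_expr A `region_expression` object.
#' @param assignments A `sample_assignment` data frame.
#' @param dir Output directory.
#' @return Invisibly, the three file paths.
#' @export
write_mapping <- function(region_expr, assignments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "sample_assignments.tsv")
  write.table(assignments, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "region_expression.tsv")
  write.table(data.frame(region = rownames(region_expr$X), region_expr$X,
                         check.names = FALSE),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "donor_region_counts.tsv")
  write.table(data.frame(donor = rownames(region_expr$counts),
                         region_expr$counts, check.names = FALSE),
              p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
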