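make_test_parcellation <- function(n_regions = 4, dim = c(9, 9, 9), seed = 1) {
  sc <- synthetic_scenario(n_regions = n_regions, n_genes = 5, seed = seed)
  make_parcellation(sc, dim = dim)
}

sample_df <- function(xyz) {
  data.frame(sample_id = sprintf("s%02d", seq_len(nrow(xyz))),
             mni_x = xyz[, 1], mni_y = xyz[, 2], mni_z = xyz[, 3])
}

test_that("containment and tolerance boundaries behave exactly", {
  sc <- synthetic_scenario(n_regions = 1, n_genes = 5, seed = 1)
  p <- make_parcellation(sc, dim = c(5, 5, 5))   # block at voxels 2:4, 2 mm
  # voxel (0-based 1,2,2) is labelled; its centre is (-2, 0, 0)
  expect_identical(p$labels[2, 3, 3], 1L)
  pts <- rbind(
    c(-2, 0, 0),     # exactly at a labelled voxel centre -> containment
    c(-4, 0, 0),     # background voxel centre exactly 2 mm away
    c(-4.5, 0, 0),   # 2.5 mm from every labelled centre
    c(-4 - 1e-6, 0, 0))  # just beyond the 2 mm tolerance
  asg <- assign_samples(sample_df(pts), p, tolerance_mm = 2)
  expect_identical(asg$region, c(1L, 1L, NA_integer_, NA_integer_))
  expect_identical(asg$method,
                   c("containment", "nearest", "unassigned", "unassigned"))
  expect_equal(asg$distance_mm[1:2], c(0, 2))
  expect_equal(asg$distance_mm[3], 2.5)
})

test_that("a sample within tolerance maps to its nearest labelled voxel", {
  p <- make_test_parcellation(n_regions = 3)
  lv <- which(p$labels == 3, arr.ind = TRUE)
  face <- lv[which.min(lv[, 1]), ]              # x-low face voxel of region 3
  ctr <- (cbind(rbind(face - 1), 1) %*% t(p$affine))[1:3]
  pt <- ctr - c(1.5, 0, 0)                      # 1.5 mm outside, if background
  vox <- round(solve(p$affine) %*% c(pt, 1))[1:3]
  stopifnot(p$labels[vox[1] + 1, vox[2] + 1, vox[3] + 1] == 0)
  asg <- assign_samples(sample_df(rbind(pt)), p, tolerance_mm = 2)
  brute <- assign_brute(sample_df(rbind(pt)), p, tolerance_mm = 2)
  expect_identical(asg$region, brute$region)
  expect_equal(asg$distance_mm, brute$distance_mm)
  expect_equal(asg$distance_mm, 1.5)
})

test_that("assignments match the exhaustive search oracle on random grids", {
  for (seed in 1:3) {
    set.seed(seed)
    p <- make_test_parcellation(n_regions = sample(2:6, 1),
                                dim = c(13, 13, 13), seed = seed)
    half <- 13  # grid half-extent in mm, points partly outside
    pts <- matrix(runif(3 * 120, -half - 4, half + 4), ncol = 3)
    df <- sample_df(pts)
    for (tol in c(0, 1, 2, 5)) {
      got <- assign_samples(df, p, tolerance_mm = tol)
      want <- assign_brute(df, p, tolerance_mm = tol)
      expect_identical(got$region, want$region)
      expect_equal(got$distance_mm, want$distance_mm, tolerance = 1e-9)
    }
  }
})

test_that("assignment counts are conserved and monotone in tolerance", {
  sc <- tiny_scenario(seed = 9)
  p <- make_parcellation(sc)
  ds <- make_donor_samples(sc, p)
  # jitter samples so some fall outside parcels
  df <- ds$annot
  set.seed(1)
  df[, c("mni_x", "mni_y", "mni_z")] <-
    df[, c("mni_x", "mni_y", "mni_z")] + matrix(rnorm(nrow(df) * 3, 0, 2),
                                                ncol = 3)
  prev <- character(0)
  for (tol in c(0, 0.5, 1, 2, 4)) {
    asg <- assign_samples(df, p, tolerance_mm = tol)
    expect_identical(sum(!is.na(asg$region)) + sum(is.na(asg$region)),
                     nrow(df))
    now <- asg$sample_id[!is.na(asg$region)]
    expect_true(all(prev %in% now))   # assigned set grows with tolerance
    prev <- now
  }
})

test_that("assignment rejects non-finite coordinates and negative tolerance", {
  p <- make_test_parcellation()
  df <- sample_df(rbind(c(0, 0, NA)))
  expect_error(assign_samples(df, p), "non-finite")
  expect_error(assign_samples(sample_df(rbind(c(0, 0, 0))), p,
                              tolerance_mm = -1), ">= 0")
})

test_that("aggregation averages within donor then across contributing donors", {
  expr <- matrix(c(1, 3, 3, 5, 10, 20), nrow = 1,
                 dimnames = list("gA", sprintf("s%d", 1:6)))
  ds <- structure(list(
    annot = data.frame(donor = c("d1", "d1", "d2", "d2", "d3", "d3"),
                       sample_id = sprintf("s%d", 1:6)),
    expression = expr, gene_ids = "gA"), class = "donor_samples")

  # one donor, one region: plain mean of [1, 3] is 2
  asg1 <- data.frame(sample_id = sprintf("s%d", 1:6),
                     region = c(1L, 1L, NA, NA, NA, NA),
                     region_name = c("r1", "r1", NA, NA, NA, NA),
                     distance_mm = 0, method = "containment")
  agg1 <- aggregate_expression(ds, asg1, region_ids = 1L,
                               region_names = "r1")
  expect_equal(unname(agg1$X["r1", "gA"]), 2)

  # donor means 2 and 4; third donor absent from the region: mean is 3, not 2
  asg2 <- data.frame(sample_id = sprintf("s%d", 1:6),
                     region = c(1L, 1L, 1L, 1L, 2L, 2L),
                     region_name = c(rep("r1", 4), "r2", "r2"),
                     distance_mm = 0, method = "containment")
  agg2 <- aggregate_expression(ds, asg2, region_ids = 1:2,
                               region_names = c("r1", "r2"))
  expect_equal(unname(agg2$X["r1", "gA"]), 3)
  expect_equal(unname(agg2$X["r2", "gA"]), 15)
  expect_identical(unname(agg2$counts[, "r1"]), c(2L, 2L, 0L))
})

test_that("gene panel order does not affect the aggregated matrix", {
  sc <- tiny_scenario(seed = 13)
  p <- make_parcellation(sc)
  ds <- make_donor_samples(sc, p)
  asg <- assign_samples(ds, p)
  agg <- aggregate_expression(ds, asg)

  perm <- sample(nrow(ds$expression))
  ds_perm <- ds
  ds_perm$expression <- ds$expression[perm, , drop = FALSE]
  ds_perm$gene_ids <- ds$gene_ids[perm]
  agg_perm <- aggregate_expression(ds_perm, asg)
  expect_identical(agg$X, agg_perm$X)
})

test_that("empty regions are dropped and fully empty input errors", {
  sc <- tiny_scenario(seed = 14)
  p <- make_parcellation(sc)
  ds <- make_donor_samples(sc, p)
  asg <- assign_samples(ds, p)
  expect_message(
    agg <- aggregate_expression(ds, asg, region_ids = 1:9,
                                region_names = c(sc$region_names, "ghost")),
    "dropped 1 region")
  expect_identical(agg$dropped_regions, 9L)
  expect_identical(nrow(agg$X), 8L)

  asg_none <- asg
  asg_none$region <- NA_integer_
  expect_error(suppressMessages(
    aggregate_expression(ds, asg_none, region_ids = 1:8)), "empty|no regions")
})
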