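test_that("parcellation lays out the requested number of disjoint blocks", {
  sc1 <- synthetic_scenario(n_regions = 1, n_genes = 5, seed = 1)
  p1 <- make_parcellation(sc1, dim = c(5, 5, 5))
  expect_identical(sort(unique(as.vector(p1$labels))), c(0L, 1L))
  expect_identical(dim(p1$labels), c(5L, 5L, 5L))

  sc <- synthetic_scenario(n_regions = 34, n_genes = 5, seed = 1)
  p <- make_parcellation(sc)
  # brute-force scan: count distinct positive labels and check block sizes
  labs <- as.vector(p$labels)
  expect_identical(sort(unique(labs[labs > 0])), 1:34)
  expect_true(all(table(labs[labs > 0]) == 27))

  big <- synthetic_scenario(n_regions = 1000, n_genes = 5, seed = 1)
  expect_error(make_parcellation(big, dim = c(5, 5, 5)), "too small")
})

test_that("region ids ascend along the first grid axis (planted gradient axis)", {
  sc <- synthetic_scenario(n_regions = 8, n_genes = 5, seed = 1)
  p <- make_parcellation(sc)
  cx <- vapply(1:8, function(r)
    mean(which(p$labels == r, arr.ind = TRUE)[, 1]), numeric(1))
  expect_true(all(diff(cx) >= 0))
})

test_that("donor samples are deterministic and carry the planted structure", {
  sc <- tiny_scenario(seed = 3)
  p <- make_parcellation(sc)
  ds1 <- make_donor_samples(sc, p)
  ds2 <- make_donor_samples(sc, p)
  expect_identical(ds1, ds2)
  # bookkeeping: total samples equals the sum of per-cell counts
  expect_identical(nrow(ds1$annot), sum(ds1$cell_counts))

  # zero noise, unit loadings: all samples in a region share one profile
  sc0 <- tiny_scenario(seed = 3, noise_sd_expression = 0,
                       gene_loadings = rep(1, 60))
  ds0 <- make_donor_samples(sc0, p)
  for (r in unique(ds0$annot$region_truth)) {
    cols <- ds0$annot$region_truth == r
    block <- ds0$expression[, cols, drop = FALSE]
    # every gene is constant across the region's samples
    expect_lt(max(apply(block, 1, function(z) max(z) - min(z))), 1e-12)
    expect_equal(block[, 1],
                 setNames(as.numeric(sc0$mean_expression) +
                            as.numeric(sc0$region_gradient)[r],
                          sc0$gene_ids))
  }
})

test_that("region-mean expression recovers the gradient as noise shrinks", {
  cors <- vapply(c(1, 0.1, 0.001), function(ns) {
    sc <- tiny_scenario(seed = 5, noise_sd_expression = ns)
    p <- make_parcellation(sc)
    ds <- make_donor_samples(sc, p)
    j <- which.max(abs(sc$gene_loadings))   # a strongly loaded gene
    rm <- tapply(ds$expression[j, ], ds$annot$region_truth, mean)
    cor(rm, as.numeric(sc$region_gradient)[as.integer(names(rm))]) *
      sign(sc$gene_loadings[j])
  }, numeric(1))
  expect_true(all(diff(cors) >= -0.02))  # improves as noise drops
  expect_gt(cors[3], 0.999)
})

test_that("ct cohort honours the planted group effect and determinism", {
  sc <- tiny_scenario(seed = 11)
  expect_identical(make_ct_cohort(sc), make_ct_cohort(sc))

  # null effect: t-statistics centred near zero
  sc0 <- synthetic_scenario(n_regions = 10, n_genes = 5, n_patients = 200,
                            n_controls = 200, ct_effect = rep(0, 10),
                            seed = 2)
  ct0 <- make_ct_cohort(sc0)
  con0 <- regional_group_contrast(ct0, paste0("lh_", sc0$region_names))
  expect_lt(abs(mean(con0$t)), 0.8)

  # single planted effect dominates
  delta <- rep(0, 10); delta[4] <- 0.5
  sc1 <- synthetic_scenario(n_regions = 10, n_genes = 5, n_patients = 100,
                            n_controls = 100, ct_effect = delta,
                            noise_sd_ct = 0.1, seed = 2)
  ct1 <- make_ct_cohort(sc1)
  con1 <- regional_group_contrast(ct1, paste0("lh_", sc1$region_names))
  expect_identical(which.max(abs(con1$t)), 4L)
  expect_gt(con1$t[4], 0)          # atrophy -> positive (control - patient)
  expect_lt(con1$q[4], 0.05)
  expect_true(all(as.matrix(ct1[, -(1:4)]) >= 0.5))  # positivity
})

test_that("clinical scores reflect the planted coefficients and missingness", {
  # null coefficients: Eq.1-style regression finds nothing
  sc0 <- synthetic_scenario(n_regions = 6, n_genes = 5, n_patients = 120,
                            clinical_coefficients = matrix(0, 9, 6),
                            age_coefficients = rep(0, 9),
                            noise_sd_clinical = 1, missing_rate = 0,
                            seed = 4)
  ct0 <- make_ct_cohort(sc0)
  cl0 <- make_clinical(sc0, ct0)
  reg0 <- ct_clinical_regression(ct0, cl0, sc0$region_names)
  expect_lt(mean(abs(reg0$t) > 2), 0.10)   # ~5% expected

  # one strong coefficient: that (feature, region) pair is most significant
  B <- matrix(0, 9, 6); B[3, 5] <- 4
  sc1 <- synthetic_scenario(n_regions = 6, n_genes = 5, n_patients = 120,
                            clinical_coefficients = B,
                            age_coefficients = rep(0, 9),
                            noise_sd_clinical = 0.2, missing_rate = 0,
                            seed = 4)
  ct1 <- make_ct_cohort(sc1)
  cl1 <- make_clinical(sc1, ct1)
  reg1 <- ct_clinical_regression(ct1, cl1, sc1$region_names)
  top <- reg1[which.max(abs(reg1$t)), ]
  expect_identical(top$region, sc1$region_names[5])
  expect_identical(top$feature, sc1$clinical_features[3])

  # missingness rate lands in the configured band
  sc2 <- tiny_scenario(seed = 8, missing_rate = 0.3, n_patients = 200)
  cl2 <- make_clinical(sc2, make_ct_cohort(sc2))
  avail <- colMeans(!is.na(as.matrix(cl2[, -1])))
  expect_true(all(avail > 0.6 & avail < 0.8))
})

test_that("scenario validation rejects impossible settings", {
  expect_error(synthetic_scenario(n_regions = 0), "counts")
  expect_error(synthetic_scenario(noise_sd_ct = -1), "noise")
  sc <- tiny_scenario()
  expect_equal(mean(sc$region_gradient), 0)
})

test_that("scenario data round-trips through the on-disk layout", {
  dir <- withr::local_tempdir()
  sc <- tiny_scenario(seed = 21)
  out <- write_scenario_data(sc, dir)
  expect_true(file.exists(file.path(dir, "parcellation.nii")))
  expect_true(file.exists(file.path(dir, "scenario.json")))

  p2 <- read_parcellation(file.path(dir, "parcellation.nii"))
  expect_identical(p2$labels, out$parcellation$labels)
  expect_equal(p2$affine, out$parcellation$affine, tolerance = 1e-5)
  expect_identical(p2$region_names, out$parcellation$region_names)

  ds2 <- read_donor_samples(dir)
  expect_equal(nrow(ds2$annot), nrow(out$samples$annot))
  expect_equal(sort(colnames(ds2$expression)),
               sort(colnames(out$samples$expression)))
  common <- colnames(out$samples$expression)
  expect_equal(ds2$expression[, common], out$samples$expression[, common],
               tolerance = 1e-12)

  # missing clinical values are written as empty fields, read back as NA
  cl <- read.delim(file.path(dir, "clinical.tsv"), na.strings = "",
                   check.names = FALSE)
  expect_equal(mean(is.na(as.matrix(cl[, -1]))),
               mean(is.na(as.matrix(out$clinical[, -1]))))
})
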