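test_that("identical config and seed give byte-identical simulations", {
  cfg <- simulation_config(n_ocrs = 300, n_specific_per_cell = 10,
                           n_region_specific = 2, seed = 9)
  a <- simulate_sorted_experiment(cfg)
  b <- simulate_sorted_experiment(cfg)
  expect_identical(a, b)
  d <- simulate_sorted_experiment(simulation_config(
    n_ocrs = 300, n_specific_per_cell = 10, n_region_specific = 2,
    seed = 10))
  expect_false(identical(a$counts, d$counts))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_ocrs = 0), "positive")
  expect_error(simulation_config(frac_promoter = 1.4), "\\[0, 1\\]")
  expect_error(simulation_config(nb_dispersion = 0), "> 0")
  expect_error(simulation_config(effect_log2fc = Inf), "finite")
  expect_error(simulation_config(frip_range = c(0.5, 0.2)), "increasing")
  expect_error(simulation_config(n_ocrs = 100, n_specific_per_cell = 100),
               "exceed")
})

test_that("planted truth matches its construction", {
  cfg <- simulation_config(n_ocrs = 600, n_specific_per_cell = 10,
                           n_region_specific = 3, seed = 12)
  sim <- simulate_sorted_experiment(cfg)
  expect_true(all(lengths(sim$truth$true_specific_ocrs) == 10))
  expect_length(sim$truth$true_region_ocrs, 12)
  expect_true(all(lengths(sim$truth$true_region_ocrs) == 3))
  # specific sets are disjoint and reference existing OCRs
  all_ids <- unlist(sim$truth$true_specific_ocrs)
  expect_false(any(duplicated(all_ids)))
  expect_true(all(all_ids %in% sim$ocrs$name))
  # a planted GLU OCR has ~4x the counts of other cells at the expectation
  glu <- sim$truth$true_specific_ocrs$GLU[1]
  mu <- sim$truth$expected_mu[glu, ]
  is_glu <- sim$metadata$cell_type == "GLU"
  expect_equal(mean(mu[is_glu]) / mean(mu[!is_glu]), 4, tolerance = 0.15)
  # sex OCRs live on chrX
  expect_true(all(sim$ocrs$chrom[sim$ocrs$name %in% sim$truth$sex_ocrs] ==
                    "chrX"))
  # metadata carries FRiP, sex and three pure-noise QC metrics
  expect_true(all(c("frip", "sex", "qc_noise_a", "qc_noise_b",
                    "qc_noise_c") %in% names(sim$metadata)))
})

test_that("group means converge to the planted expectation at high depth", {
  cfg <- simulation_config(n_ocrs = 300, nb_dispersion = 0.001,
                           n_specific_per_cell = 10, n_region_specific = 2,
                           library_size_range = c(1e6, 1e6), seed = 13)
  sim <- simulate_sorted_experiment(cfg)
  keep <- rowMeans(sim$truth$expected_mu) > 100
  rel <- abs(rowMeans(sim$counts[keep, ]) /
               rowMeans(sim$truth$expected_mu[keep, ]) - 1)
  expect_lt(max(rel), 0.05)
})

test_that("bulk mixtures honour proportions, depth and case effects", {
  refs <- simulate_reference_profiles(n_ocrs = 300, n_markers_per_cell = 20,
                                      n_specific_per_cell = 20,
                                      seed = 3)$profiles
  # degenerate alpha: all samples pure in one cell type
  pure <- simulate_bulk_mixtures(refs, 6, c(3, 0, 0, 0), gc_effect = FALSE,
                                 seed = 4)
  theta <- as.matrix(pure$truth$true_proportions[, colnames(refs)])
  expect_equal(unname(theta[, 1]), rep(1, 6))
  expect_equal(unname(rowSums(theta)), rep(1, 6), tolerance = 1e-9)

  # doubling depth doubles expected column sums
  b1 <- simulate_bulk_mixtures(refs, 5, rep(1, 4), depth = 1e5,
                               gc_effect = FALSE, seed = 5)
  b2 <- simulate_bulk_mixtures(refs, 5, rep(1, 4), depth = 2e5,
                               gc_effect = FALSE, seed = 5)
  expect_equal(colSums(b2$truth$expected_mu),
               2 * colSums(b1$truth$expected_mu), tolerance = 1e-9)

  # no case effect: case and control expected counts identical in law
  expect_null(b1$truth$case_effect)
  d <- b1$metadata$diagnosis
  expect_equal(sort(unique(d)), c("case", "control"))

  # unknown case OCR ids are refused
  expect_error(simulate_bulk_mixtures(refs, 4, rep(1, 4),
                                      case_effect = list(ocr_ids = "nope",
                                                         log2fc = 1)),
               "not in the reference")
  # a planted case effect touches only case samples
  glu_id <- rownames(refs)[1]
  b3 <- simulate_bulk_mixtures(refs, 6, rep(1, 4), gc_effect = FALSE,
                               case_effect = list(ocr_ids = glu_id,
                                                  log2fc = 1), seed = 6)
  b0 <- simulate_bulk_mixtures(refs, 6, rep(1, 4), gc_effect = FALSE,
                               seed = 6)
  cases <- b3$metadata$diagnosis == "case"
  expect_equal(b3$truth$expected_mu[glu_id, cases],
               2 * b0$truth$expected_mu[glu_id, cases], tolerance = 1e-9)
  expect_equal(b3$truth$expected_mu[glu_id, !cases],
               b0$truth$expected_mu[glu_id, !cases], tolerance = 1e-9)
})

test_that("balanced composition equalizes proportions across diagnosis groups", {
  refs <- simulate_reference_profiles(n_ocrs = 200, n_markers_per_cell = 10,
                                      n_specific_per_cell = 10,
                                      seed = 3)$profiles
  b <- simulate_bulk_mixtures(refs, 20, rep(1, 4), gc_effect = FALSE,
                              balance_composition = TRUE, seed = 8)
  theta <- as.matrix(b$truth$true_proportions[, colnames(refs)])
  cases <- b$metadata$diagnosis == "case"
  expect_equal(colMeans(theta[cases, ]), colMeans(theta[!cases, ]),
               tolerance = 1e-12)
})

test_that("footprint sites respect OCR bounds, per-motif counts and redundancy", {
  sim <- shared_sim()
  ocrs <- sim$ocrs[1:200, ]
  spec <- tibble::tibble(motif_id = c("M1", "M2", "M3"),
                         n_sites = c(40L, 30L, 25L))
  pairs <- tibble::tibble(motif_a = "M1", motif_b = "M2", share = 0.6)
  sites <- simulate_footprints(ocrs, spec, redundant_pairs = pairs, seed = 21)
  expect_equal(unname(table(sites$motif_id)[spec$motif_id]),
               spec$n_sites, ignore_attr = TRUE)
  expect_true(all(sites$p_bind >= 0 & sites$p_bind <= 1))
  # every site inside an OCR (brute force)
  expect_true(all(oracle_overlaps(sites, ocrs)))
  inside <- vapply(seq_len(nrow(sites)), function(i) {
    any(ocrs$chrom == sites$chrom[i] & ocrs$start <= sites$start[i] &
          sites$end[i] <= ocrs$end)
  }, logical(1))
  expect_true(all(inside))
  # declared redundant pair shares >= 50% of positions (interval oracle)
  m1 <- sites[sites$motif_id == "M1", ]
  m2 <- sites[sites$motif_id == "M2", ]
  shared <- mean(vapply(seq_len(nrow(m2)), function(i) {
    any(m1$chrom == m2$chrom[i] & m1$start == m2$start[i] &
          m1$end == m2$end[i])
  }, logical(1)))
  expect_gte(shared, 0.5)
  expect_identical(sites,
                   simulate_footprints(ocrs, spec, redundant_pairs = pairs,
                                       seed = 21))
  expect_error(simulate_footprints(ocrs[0, ], spec), "empty OCR set")
})

test_that("simulated p-value mixtures are calibrated", {
  # pure null: uniform by KS
  p0 <- simulate_pvalues(10000, pi0 = 1, seed = 30)
  expect_gt(stats::ks.test(p0, "punif")$p.value, 0.01)
  # strong alternatives concentrate near zero
  p1 <- simulate_pvalues(2000, pi0 = 0, alt_shape = 0.01, seed = 31)
  expect_gt(mean(p1 < 0.5), 0.99)
  expect_identical(p1, simulate_pvalues(2000, 0, alt_shape = 0.01, seed = 31))
  expect_error(simulate_pvalues(100, 0.5, alt_shape = 1.2), "alt_shape")
  expect_error(simulate_pvalues(100, -0.1), "pi0")
})
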