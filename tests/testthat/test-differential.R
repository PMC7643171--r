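test_that("precision weights are positive and track the mean-variance trend", {
  v <- shared_voom()
  expect_true(all(v$weights > 0))
  expect_true(all(v$sample_weights > 0))
  # NB counts: abundant OCRs get larger weights than sparse ones
  ab <- rowMeans(shared_sim()$counts)
  top <- ab >= quantile(ab, 0.9)
  bottom <- ab <= quantile(ab, 0.1)
  expect_gt(median(v$weights[top, ]), median(v$weights[bottom, ]))
})

test_that("homoskedastic Gaussian input gives nearly flat weights", {
  set.seed(41)
  n_s <- 24
  design <- cbind(intercept = rep(1, n_s),
                  grp = rep(0:1, each = n_s / 2))
  # counts with equal mean so the trend has nothing to fit
  counts <- matrix(rpois(800 * n_s, 500), 800, n_s,
                   dimnames = list(paste0("o", 1:800), paste0("s", 1:n_s)))
  v <- voom_weights(counts, design, sample_weights = FALSE)
  expect_lt(sd(v$weights) / mean(v$weights), 0.2)
})

test_that("contrast fitting recovers planted effects and refuses bad input", {
  sim <- shared_sim()
  res <- shared_results()
  glu <- sim$truth$true_specific_ocrs$GLU
  est <- res$log2fc[res$contrast == "GLU_vs_GABA" &
                      res$ocr_id %in% glu]
  expect_equal(mean(est), 2, tolerance = 0.1)
  # FDR is monotone nondecreasing in p within a contrast
  one <- res[res$contrast == "GLU_vs_OLIG", ]
  ord <- order(one$p)
  expect_true(all(diff(one$fdr[ord]) >= -1e-12))
  expect_error(fit_contrasts(shared_voom(),
                             c(zero = "GLU_ACC - GLU_ACC")),
               "zeros")
  expect_error(fit_contrasts(shared_voom(), c("GLU_ACC - GABA_ACC")),
               "named")
})

test_that("null OCR p-values are calibrated", {
  sim <- shared_sim()
  res <- shared_results()
  planted <- unique(c(unlist(sim$truth$true_specific_ocrs),
                      unlist(sim$truth$true_region_ocrs),
                      sim$truth$sex_ocrs))
  nulls <- setdiff(rownames(sim$counts), planted)
  pn <- res$p[res$contrast == "GABA_vs_OLIG" & res$ocr_id %in% nulls]
  expect_gt(stats::ks.test(pn, "punif")$p.value, 0.01)
  fdrn <- res$fdr[res$contrast == "GABA_vs_OLIG" & res$ocr_id %in% nulls]
  expect_lte(mean(fdrn < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(fdrn)))
})

test_that("specificity set algebra matches brute force on all 2^6 patterns", {
  cells <- c("GLU", "GABA", "OLIG", "MGAS")
  pairs <- utils::combn(cells, 2, simplify = FALSE)
  grid <- expand.grid(rep(list(c(-1, 1)), 6))  # sign of each pairwise call
  # one OCR per pattern; significance always on, direction from the pattern
  results <- purrr::map_dfr(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    tibble::tibble(
      contrast = paste0(p[1], "_vs_", p[2]),
      ocr_id = sprintf("pat%02d", seq_len(nrow(grid))),
      log2fc = grid[[k]],
      t = grid[[k]],
      p = 0.001,
      fdr = 0.01
    )
  })
  sets <- cell_specific_sets(results)
  gsets <- group_specific_sets(results)
  for (i in seq_len(nrow(grid))) {
    up <- list()
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      up[[paste0(p[1], ">", p[2])]] <- grid[i, k] > 0
      up[[paste0(p[2], ">", p[1])]] <- grid[i, k] < 0
    }
    oracle <- oracle_cell_sets(up)
    id <- sprintf("pat%02d", i)
    expect_setequal(sets$set[sets$ocr_id == id], oracle$cells)
    expect_identical(id %in% gsets$ocr_id[gsets$set == "Neuron"],
                     oracle$neuron)
    expect_identical(id %in% gsets$ocr_id[gsets$set == "nonNeuron"],
                     oracle$non_neuron)
  }
  # the four cell sets are pairwise disjoint and nested in the group sets
  expect_false(any(duplicated(sets$ocr_id)))
  neuron <- gsets$ocr_id[gsets$set == "Neuron"]
  non_neuron <- gsets$ocr_id[gsets$set == "nonNeuron"]
  expect_true(all(sets$ocr_id[sets$set %in% c("GLU", "GABA")] %in% neuron))
  expect_true(all(sets$ocr_id[sets$set %in% c("OLIG", "MGAS")] %in%
                    non_neuron))
})

test_that("an OCR equally high in both neuronal types is Neuron- but not cell-specific", {
  cells <- c("GLU", "GABA", "OLIG", "MGAS")
  pairs <- utils::combn(cells, 2, simplify = FALSE)
  # GLU = GABA (not significant), both above OLIG and MGAS
  results <- purrr::map_dfr(pairs, function(p) {
    neuronal <- c("GLU", "GABA")
    sig <- xor(p[1] %in% neuronal, p[2] %in% neuronal)
    up <- p[1] %in% neuronal  # contrasts oriented first-vs-second
    tibble::tibble(contrast = paste0(p[1], "_vs_", p[2]), ocr_id = "shared",
                   log2fc = ifelse(sig, ifelse(up, 2, -2), 0),
                   t = 0, p = ifelse(sig, 1e-5, 0.9),
                   fdr = ifelse(sig, 1e-4, 0.95))
  })
  expect_equal(nrow(cell_specific_sets(results)), 0)
  g <- group_specific_sets(results)
  expect_identical(g$set[g$ocr_id == "shared"], "Neuron")
})

test_that("least significant pairwise comparison is the one reported", {
  sim <- shared_sim()
  res <- shared_results()
  sets <- cell_specific_sets(res)
  one <- sets[sets$set == "GLU", ][1, ]
  glu_rows <- res[res$ocr_id == one$ocr_id &
                    res$contrast %in% paste0("GLU_vs_",
                                             c("GABA", "OLIG", "MGAS")), ]
  expect_equal(unname(one$p), max(glu_rows$p))
})

test_that("region specificity respects the cell mask and finds planted effects", {
  sim <- shared_sim()
  v <- shared_voom()
  fit <- fit_contrasts(v, region_contrasts("GLU"))
  res <- tidy(fit)
  planted <- sim$truth$true_region_ocrs$GLU_ACC
  # mask: GLU-open OCRs = everything but another cell's specific set
  mask <- setdiff(rownames(sim$counts), sim$truth$true_specific_ocrs$MGAS)
  sets <- region_specific_sets(res, mask)
  acc <- sets$ocr_id[sets$set == "GLU_ACC"]
  expect_gt(mean(planted %in% acc), 0.8)
  # an OCR outside the mask is never reported, whatever its effect
  sets2 <- region_specific_sets(res, setdiff(mask, planted[1]))
  expect_false(planted[1] %in% sets2$ocr_id)
  expect_error(region_specific_sets(res[res$contrast ==
                                          "GLU_ACC_vs_rest", ], mask),
               ">= 2 regions")
})

test_that("residualization removes nuisance effects idempotently", {
  sim <- shared_sim()
  v <- shared_voom()
  adj <- residualize(v, c("sex", "frip"))
  # refitting the full model on the adjusted matrix: FRiP coefficients vanish
  refit <- limma::lmFit(adj, v$design, weights = v$weights)
  expect_lt(abs(median(refit$coefficients[, "frip"])), 1e-8)
  expect_lt(max(abs(refit$coefficients[, "frip"])), 1e-6)
  # idempotence
  adj2 <- residualize(adj, c("sex", "frip"), design = v$design,
                      weights = v$weights)
  expect_equal(adj, adj2, tolerance = 1e-8)
  # planted cell differences survive
  glu <- sim$truth$true_specific_ocrs$GLU
  is_glu <- sim$metadata$cell_type == "GLU"
  diffs <- rowMeans(adj[glu, is_glu]) - rowMeans(adj[glu, !is_glu])
  expect_equal(mean(diffs), 2, tolerance = 0.25)
  expect_error(residualize(v, "nonexistent"), "unknown covariate")
})
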