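genes_fixture <- tibble::tibble(
  gene_id = c("g1", "g2"),
  gene_name = c("GeneA", "GeneB"),
  chrom = c("chr1", "chr1"),
  tss = c(10000L, 50000L),
  strand = c("+", "-"),
  biotype = "protein_coding"
)

test_that("genomic context labels follow the stated priority", {
  ocrs <- tibble::tibble(
    chrom = "chr1",
    start = c(9000L, 30000L, 200000L),
    end = c(9500L, 30400L, 200500L),
    name = c("prom", "intronic", "far"))
  features <- tibble::tibble(chrom = "chr1", start = 25000L, end = 35000L,
                             type = "intron")
  out <- annotate_context(ocrs, genes_fixture, features)
  expect_equal(out$context, c("promoter", "intron", "distal_intergenic"))
  # promoter beats exon/intron when both apply
  feat2 <- dplyr::bind_rows(features,
                            tibble::tibble(chrom = "chr1", start = 8000L,
                                           end = 12000L, type = "exon"))
  out2 <- annotate_context(ocrs, genes_fixture, feat2)
  expect_equal(out2$context[1], "promoter")
})

test_that("duplicate gene names get version suffixes", {
  g <- tibble::tibble(gene_id = c("a", "b", "c"),
                      gene_name = c("X", "X", "Y"))
  out <- dedupe_gene_names(g)
  expect_setequal(out$gene_name, c("X_v1", "X_v2", "Y"))
})

test_that("base-pair Jaccard matches closed forms and the per-bp oracle", {
  a <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  b <- tibble::tibble(chrom = "chr1", start = 5L, end = 15L)
  expect_equal(jaccard_bp(a, b), 5 / 15)
  expect_equal(jaccard_bp(a, a), 1)
  expect_equal(jaccard_bp(a, tibble::tibble(chrom = "chr1", start = 100L,
                                            end = 110L)), 0)
  expect_equal(jaccard_bp(a[0, ], b[0, ]), 0)
  set.seed(61)
  for (rep in 1:5) {
    x <- random_intervals(40, max_pos = 800)
    y <- random_intervals(40, max_pos = 800)
    expect_equal(jaccard_bp(x, y), oracle_jaccard(x, y), tolerance = 1e-12)
  }
})

test_that("regulatory domains contain the basal window and stop at neighbors", {
  g <- tibble::tibble(gene_id = c("g1", "g2"), gene_name = c("A", "B"),
                      chrom = "chr1", tss = c(100000L, 120000L),
                      strand = c("+", "+"))
  dom <- regulatory_domains(g, extension = 1e6)
  d1 <- dom[dom$gene_id == "g1", ]
  expect_lte(d1$start, 100000 - 5000)
  expect_gte(d1$end, 100000 + 1000)
  # g1 extension stops at g2's basal start
  expect_equal(d1$end, 120000 - 5000)
  d2 <- dom[dom$gene_id == "g2", ]
  expect_equal(d2$start, 100000 + 1000)
})

test_that("gene-set enrichment reproduces the exact binomial tail", {
  # 4 domain-hitting OCRs, 2 in a set covering 25% of the domain bp
  dom <- tibble::tibble(
    gene_id = c("s", "o1", "o2", "o3"),
    chrom = "chr1",
    start = c(0L, 1000L, 2000L, 3000L),
    end = c(1000L, 2000L, 3000L, 4000L))
  ocrs <- tibble::tibble(chrom = "chr1",
                         start = c(100L, 200L, 1100L, 3100L),
                         end = c(150L, 260L, 1150L, 3150L))
  out <- great_enrichment(ocrs, dom, "s")
  expect_equal(out$n_total, 4)
  expect_equal(out$n_set, 2)
  expect_equal(out$bp_fraction, 0.25)
  expect_equal(out$fold, 2)
  expect_equal(out$p, stats::pbinom(1, 4, 0.25, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(out$p, 4), 0.2617)
  # degenerate cases
  all_g <- great_enrichment(ocrs, dom, dom$gene_id)
  expect_equal(all_g$fold, 1)
  expect_equal(all_g$p, 1)
  none <- great_enrichment(tibble::tibble(chrom = "chr1", start = 1100L,
                                          end = 1150L), dom, "s")
  expect_equal(none$fold, 0)
  expect_equal(none$p, 1)
  expect_error(great_enrichment(ocrs, dom, character()), "empty gene set")
})

test_that("TSS direct mapping yields per-gene cell fractions", {
  ocrs <- tibble::tibble(chrom = "chr1", start = c(9900L, 49900L),
                         end = c(10100L, 50100L), name = c("oc1", "oc2"))
  md <- tibble::tibble(sample_id = paste0("s", 1:4),
                       cell_type = c("GLU", "GABA", "OLIG", "MGAS"))
  adjusted <- rbind(oc1 = c(10, 0, 0, 0),   # log2 scale
                    oc2 = c(3, 3, 3, 3))
  colnames(adjusted) <- md$sample_id
  sets <- tibble::tibble(set = "GLU", ocr_id = "oc1")
  out <- tss_direct_map(adjusted, md, ocrs, genes_fixture, sets)
  expect_setequal(out$gene_id, c("g1", "g2"))
  g1 <- out[out$gene_id == "g1", ]
  expect_gt(g1$GLU, 0.99)  # 2^10 vs 2^0 elsewhere
  expect_equal(g1$GLU + g1$GABA + g1$OLIG + g1$MGAS, 1, tolerance = 1e-9)
  expect_identical(g1$specific_in[[1]], "GLU")
  g2 <- out[out$gene_id == "g2", ]
  expect_equal(unname(unlist(g2[, c("GLU", "GABA", "OLIG", "MGAS")])),
               rep(0.25, 4), tolerance = 1e-9)
  # a gene with no TSS-overlapping OCR is absent
  out2 <- tss_direct_map(adjusted, md, ocrs[1, ], genes_fixture, sets)
  expect_false("g2" %in% out2$gene_id)
})

test_that("credible-variant enrichment matches the exact Fisher oracle", {
  # table: credible 10 in / 0 out, other 100 in / 900 out
  ocrs <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  variants <- tibble::tibble(
    chrom = "chr1",
    pos = c(seq(10, 910, length.out = 10),            # credible, inside
            seq(20, 920, length.out = 100),           # other, inside
            seq(2000, 20000, length.out = 900)),      # other, outside
    credible = rep(c(1, 0, 0), c(10, 100, 900)))
  variants$pos <- as.integer(variants$pos)
  out <- eqtl_enrichment(ocrs, variants)
  expect_equal(out$in_ocr_credible, 10)
  expect_equal(out$out_ocr_credible, 0)
  fisher <- stats::fisher.test(matrix(c(10, 0, 100, 900), 2))
  expect_equal(out$fisher_p, fisher$p.value, tolerance = 1e-12)
  expect_true(out$haldane)  # zero cell flagged, Haldane-corrected OR
  expect_equal(out$odds_ratio, (10.5 * 900.5) / (0.5 * 100.5))

  # padding 0 is identical to the plain call
  expect_equal(eqtl_enrichment(ocrs, variants, padding = 0), out)
  # padding pulls nearby variants inside
  out_pad <- eqtl_enrichment(ocrs, variants, padding = 1500)
  expect_gt(out_pad$in_ocr_other, out$in_ocr_other)
  expect_error(eqtl_enrichment(ocrs, dplyr::mutate(variants, credible = 0)),
               "credible")
})

test_that("random credible flags show no enrichment in permutations", {
  set.seed(62)
  ocrs <- build_consensus(random_intervals(40, max_pos = 5000,
                                           max_width = 200))
  fails <- vapply(1:10, function(s) {
    set.seed(s + 700)
    variants <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 400, replace = TRUE),
      pos = sample.int(6000, 400),
      credible = sample(c(0, 1), 400, replace = TRUE))
    out <- eqtl_enrichment(ocrs, variants, n_perm = 60, seed = s)
    out$empirical_p <= 0.05
  }, logical(1))
  expect_lte(mean(fails), 0.2)
  # empirical p respects its permutation bounds
  variants <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 5000L, 5100L),
                             credible = c(1, 1, 0, 0))
  out <- eqtl_enrichment(ocrs, variants, n_perm = 19, seed = 1)
  expect_gte(out$empirical_p, 1 / 20)
  expect_lte(out$empirical_p, 1)
})

test_that("GMT gene sets round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg9"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  writeLines("broken\tonly_desc", path)
  expect_error(read_gmt(path), "GMT")
})
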