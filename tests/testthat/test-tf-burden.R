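site <- function(motif, start, end, p_bind, chrom = "chr1", group = "all") {
  tibble::tibble(motif_id = motif, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), p_bind = p_bind, group = group)
}

test_that("overlapping same-motif sites keep the highest binding probability", {
  s <- dplyr::bind_rows(site("M", 100, 120, 0.8), site("M", 110, 130, 0.9))
  out <- dedupe_sites(s)
  expect_equal(nrow(out), 1)
  expect_equal(out$p_bind, 0.9)
  # non-overlapping sites are untouched
  s2 <- dplyr::bind_rows(site("M", 100, 120, 0.8), site("M", 500, 520, 0.2))
  expect_equal(nrow(dedupe_sites(s2)), 2)
  # different motifs never collide
  s3 <- dplyr::bind_rows(site("M1", 100, 120, 0.8), site("M2", 110, 130, 0.9))
  expect_equal(nrow(dedupe_sites(s3)), 2)
})

test_that("chains of overlapping sites match the greedy-by-probability oracle", {
  # A-B overlap, B-C overlap, A-C disjoint; B has the top probability:
  # keeping B eliminates both neighbours
  chain <- dplyr::bind_rows(site("M", 100, 120, 0.5),
                            site("M", 115, 135, 0.95),
                            site("M", 130, 150, 0.6))
  out <- dedupe_sites(chain)
  expect_equal(out$start, 115L)
  # same chain with the ends strongest: both ends survive
  chain2 <- dplyr::bind_rows(site("M", 100, 120, 0.9),
                             site("M", 115, 135, 0.5),
                             site("M", 130, 150, 0.8))
  out2 <- dedupe_sites(chain2)
  expect_setequal(out2$start, c(100L, 130L))
  # exhaustive small-case check against a brute-force oracle
  set.seed(71)
  for (rep in 1:20) {
    n <- 6
    starts <- sort(sample.int(80, n))
    s <- site("M", starts, starts + sample(5:20, n, TRUE),
              round(runif(n), 3))
    got <- dedupe_sites(s)
    # oracle: greedy by descending p, then leftmost
    ord <- order(-s$p_bind, s$start)
    kept <- integer()
    for (i in ord) {
      if (!any(s$start[kept] < s$end[i] & s$start[i] < s$end[kept])) {
        kept <- c(kept, i)
      }
    }
    expect_setequal(got$start, s$start[sort(kept)])
  }
})

test_that("motif pruning removes redundant motifs with the stated keep rule", {
  a <- site("A", c(100, 300, 500), c(120, 320, 520), 0.9)
  dup <- dplyr::mutate(a, motif_id = "B")
  expect_length(prune_motifs(dplyr::bind_rows(a, dup)), 1)
  # disjoint motifs both survive
  c_ <- site("C", c(1000, 1200), c(1020, 1220), 0.9)
  expect_setequal(prune_motifs(dplyr::bind_rows(a, c_)), c("A", "C"))
  # chain A~B, B~C with A,C disjoint: iterative removal by the keep rule
  b <- site("B", c(105, 305, 1005), c(125, 325, 1025), 0.9)
  cc <- site("C", c(1000, 1200, 1400), c(1020, 1220, 1420), 0.9)
  sites <- dplyr::bind_rows(a, b, cc)
  kept <- prune_motifs(sites)
  # oracle: B overlaps A on 2/3 sites (>=50%) and C on 1/3 (<50%); only the
  # A-B pair is redundant; equal site counts, keep the lexicographically
  # first (A)
  expect_setequal(kept, c("A", "C"))
})

test_that("site-gene weights follow the exponential decay closed form", {
  expect_equal(site_gene_weight(0, 0.7), 0.7)
  expect_equal(site_gene_weight(10000, 1), exp(-1), tolerance = 1e-12)
  expect_equal(round(site_gene_weight(10000, 1), 4), 0.3679)
  d <- seq(0, 99000, by = 1000)
  w <- site_gene_weight(d, 1)
  expect_true(all(diff(w) < 0))
  expect_equal(site_gene_weight(100001, 1), 0)   # hard cutoff at 10x scale
  expect_equal(site_gene_weight(5000, 0), 0)
})

test_that("gene burden sums non-redundant site weights", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), gene_name = c("A", "B"),
                          chrom = "chr1", tss = c(10000L, 500000L),
                          strand = "+")
  s <- dplyr::bind_rows(site("M1", 10990, 11010, 0.8),
                        site("M1", 590000, 590020, 0.5))
  b <- burden_matrix(s, genes, decay_scale = 10000)
  g1 <- b$all[b$gene_id == "g1"]
  # only the nearby site contributes: the other lies beyond the hard cutoff
  expect_equal(g1, 0.8 * exp(-1000 / 10000), tolerance = 1e-9)
  g2 <- b$all[b$gene_id == "g2"]
  expect_equal(g2, 0.5 * exp(-(590010 - 500000) / 10000), tolerance = 1e-9)
  # duplicating a motif's sites under a new id leaves burden unchanged
  s_dup <- dplyr::bind_rows(s, dplyr::mutate(s, motif_id = "M1copy"))
  b2 <- burden_matrix(s_dup, genes, decay_scale = 10000)
  expect_equal(b2$all, b$all, tolerance = 1e-12)
})

test_that("rank aggregation produces centered ranks that sum to zero", {
  burden <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                           s1 = c(5, 1, 3), s2 = c(0, 2, 1))
  rs <- rank_aggregate(burden, "s1", "s2")
  # n = 3: ranks are exactly {-1, 0, 1}
  expect_setequal(rs$score, c(-1, 0, 1))
  expect_equal(sum(rs$score), 0)
  expect_equal(rs$gene_id[rs$score == 1], "g1")  # largest difference
  # antisymmetry
  rs_swap <- rank_aggregate(burden, "s2", "s1")
  expect_equal(rs$score[match(burden$gene_id, rs$gene_id)],
               -rs_swap$score[match(burden$gene_id, rs_swap$gene_id)])
  # multi-pair aggregation: mean of per-pair centered ranks, still sums to 0
  burden$s3 <- c(2, 2, 2)
  rs2 <- rank_aggregate(burden, c("s1", "s3"), "s2")
  expect_equal(sum(rs2$score), 0, tolerance = 1e-12)
  expect_true(all(abs(rs2$score) <= 1))
  expect_error(rank_aggregate(burden, character(), "s1"), ">= 1 group")
  expect_error(rank_aggregate(burden, "s1", "nope"), "absent")
})

test_that("motif enrichment reproduces exact binomial tails with Bonferroni", {
  target <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L)
  background <- tibble::tibble(chrom = "chr2", start = 0L, end = 10000L)
  # all 20 bound sites of one motif inside the target covering 50% of bp
  s <- site("M1", seq(100, 2000, by = 100), seq(100, 2000, by = 100) + 10,
            0.95)
  s2 <- site("M2", c(100, 300), c(110, 310), 0.95, chrom = "chr2")
  out <- motif_enrichment(dplyr::bind_rows(s, s2), target, background)
  m1 <- out[out$motif_id == "M1", ]
  expect_equal(m1$fold, 2)
  expect_equal(m1$p, 0.5^20, tolerance = 1e-12)
  expect_equal(m1$p_bonferroni, min(1, 0.5^20 * 2))
  # low-probability sites are not counted as bound
  weak <- site("M3", 500, 510, 0.5)
  out2 <- motif_enrichment(dplyr::bind_rows(s, weak), target, background)
  expect_true(out2$skipped[out2$motif_id == "M3"])
  expect_error(motif_enrichment(s, target, background[0, ]),
               "empty background")
  expect_error(motif_enrichment(s, target, target), "disjoint")
})

test_that("uniformly placed sites show no motif enrichment", {
  set.seed(72)
  target <- tibble::tibble(chrom = "chr1", start = 0L, end = 30000L)
  background <- tibble::tibble(chrom = "chr1", start = 40000L, end = 130000L)
  hits <- vapply(1:20, function(s) {
    set.seed(s + 900)
    # uniform over the 120 kb of covered bases: 25% land in the target
    u <- sample.int(118000, 60)
    pos <- as.integer(ifelse(u <= 29500, u, u + 10500))
    sites <- tibble::tibble(motif_id = "M", chrom = "chr1", start = pos,
                            end = pos + 10L, p_bind = 0.95, group = "all")
    out <- motif_enrichment(sites, target, background)
    out$p_bonferroni < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.15)
})
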