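# Footprinted TF binding sites -> gene-level regulatory burden, centered-rank
# aggregation of pairwise burden differences, and coverage-aware binomial
# motif enrichment in cell-specific OCRs.
#
# Binding-site convention: tibble with `motif_id`, `chrom`, `start`, `end`,
# `p_bind` in [0, 1] and optionally `group` (sample-group label).

#' Remove overlapping same-motif binding sites
#'
#' Among mutually overlapping sites of the same motif (and group, when a
#' group column is present) the site with the highest binding probability is
#' kept (ties broken by leftmost start); e.g. palindromic motif calls on
#' opposite strands collapse to one site. Non-overlapping sites are untouched.
#'
#' @param sites Binding-site tibble.
#' @return Filtered binding-site tibble.
#' @export
dedupe_sites <- function(sites) {
  validate_intervals(sites, "sites")
  keys <- if ("group" %in% names(sites)) {
    paste(sites$motif_id, sites$group, sep = "\r")
  } else {
    sites$motif_id
  }
  keep <- unlist(lapply(split(seq_len(nrow(sites)), keys), function(idx) {
    sub <- sites[idx, ]
    ord <- order(-sub$p_bind, sub$start)
    kept_rows <- integer(0)
    for (i in ord) {
      overlaps <- FALSE
      if (length(kept_rows) > 0) {
        k <- sub[kept_rows, ]
        overlaps <- any(k$chrom == sub$chrom[i] &
                          k$start < sub$end[i] & sub$start[i] < k$end)
      }
      if (!overlaps) kept_rows <- c(kept_rows, i)
    }
    idx[kept_rows]
  }), use.names = FALSE)
  dplyr::arrange(sites[sort(keep), ], .data$motif_id, .data$chrom, .data$start)
}

# Fraction of motif m1's sites that overlap a site of m2 by >= overlap_frac
# of the shorter site's length.
redundancy_fraction <- function(s1, s2, overlap_frac = 0.5) {
  g1 <- intervals_to_granges(s1)
  g2 <- intervals_to_granges(s2)
  hits <- GenomicRanges::findOverlaps(g1, g2)
  if (length(hits) == 0) return(0)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(s1$end[qi], s2$end[si]) - pmax(s1$start[qi], s2$start[si])
  shorter <- pmin(s1$end[qi] - s1$start[qi], s2$end[si] - s2$start[si])
  good <- unique(qi[ov >= overlap_frac * shorter])
  length(good) / nrow(s1)
}

#' Prune redundant motifs
#'
#' Transcription factors share motifs; counting shared sites once per motif
#' would bias gene-level burden. Two motifs are redundant when at least
#' `site_frac` of the smaller motif's sites each overlap a site of the other
#' motif by at least `overlap_frac` of the shorter site's length. Motifs are
#' removed iteratively from the most redundant pair — keeping the motif with
#' more sites (ties broken lexicographically, keeping the first id) — until
#' no redundant pair remains.
#'
#' @param sites Binding-site tibble (deduplicated).
#' @param site_frac,overlap_frac The two 50% thresholds (defaults 0.5).
#' @return Character vector of retained motif ids.
#' @export
prune_motifs <- function(sites, site_frac = 0.5, overlap_frac = 0.5) {
  motifs <- sort(unique(sites$motif_id))
  if (length(motifs) <= 1) return(motifs)
  bym <- split(sites, sites$motif_id)
  repeat {
    worst <- NULL; worst_red <- -Inf
    for (i in seq_along(motifs)) {
      for (j in seq_along(motifs)) {
        if (j <= i) next
        m1 <- motifs[i]; m2 <- motifs[j]
        small <- if (nrow(bym[[m1]]) <= nrow(bym[[m2]])) m1 else m2
        big <- setdiff(c(m1, m2), small)
        red <- redundancy_fraction(bym[[small]], bym[[big]], overlap_frac)
        if (red >= site_frac && red > worst_red) {
          worst_red <- red
          worst <- c(m1, m2)
        }
      }
    }
    if (is.null(worst)) break
    n1 <- nrow(bym[[worst[1]]]); n2 <- nrow(bym[[worst[2]]])
    drop <- if (n1 < n2) worst[1] else if (n2 < n1) worst[2] else
      sort(worst)[2]  # tie: keep the lexicographically first id
    motifs <- setdiff(motifs, drop)
    if (length(motifs) <= 1) break
  }
  motifs
}

#' Weight of a binding site on a gene
#'
#' The probability that the factor bound at a site regulates the gene is
#' approximated as the binding probability times an exponential decay in the
#' distance from the site midpoint to the gene's nearest TSS:
#' `w = p_bind * exp(-d / decay_scale)`, zero beyond a hard cutoff of
#' `10 * decay_scale`.
#'
#' @param distance Distance(s) in bp (site midpoint to nearest TSS).
#' @param p_bind Binding probability in `[0, 1]`.
#' @param decay_scale Decay constant in bp (default 10000).
#' @return Weight(s) in `[0, 1]`.
#' @export
site_gene_weight <- function(distance, p_bind, decay_scale = 10000) {
  stopifnot(decay_scale > 0)
  ifelse(distance <= 10 * decay_scale,
         p_bind * exp(-distance / decay_scale), 0)
}

#' Gene x group regulatory burden
#'
#' `burden(gene, group)` sums [site_gene_weight()] over the binding sites of
#' the retained (non-redundant) motifs in the group. Sites beyond
#' `10 * decay_scale` of all of a gene's TSSs contribute nothing.
#'
#' @param sites Binding-site tibble with a `group` column (deduplicated).
#' @param genes Gene annotation tibble (one row per TSS).
#' @param decay_scale Decay constant in bp (default 10000).
#' @param keep_motifs Motif ids to use; defaults to [prune_motifs()] on
#'   `sites`.
#' @return An `ocr_burden` tibble: `gene_id` plus one numeric column per
#'   group; attributes `decay_scale` and `motifs`.
#' @export
burden_matrix <- function(sites, genes, decay_scale = 10000,
                          keep_motifs = NULL) {
  keep_motifs <- keep_motifs %||% prune_motifs(sites)
  sites <- sites[sites$motif_id %in% keep_motifs, ]
  if (!"group" %in% names(sites)) sites$group <- "all"
  groups <- sort(unique(sites$group))
  gene_ids <- unique(genes$gene_id)
  cutoff <- 10 * decay_scale
  burden <- matrix(0, length(gene_ids), length(groups),
                   dimnames = list(gene_ids, groups))
  if (nrow(sites) > 0) {
    mid <- floor((sites$start + sites$end) / 2)
    site_gr <- GenomicRanges::GRanges(sites$chrom,
                                      IRanges::IRanges(mid + 1, mid + 1))
    tss_gr <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(pmax(genes$tss + 1 - cutoff, 1), genes$tss + 1 + cutoff))
    hits <- GenomicRanges::findOverlaps(site_gr, tss_gr)
    if (length(hits) > 0) {
      si <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
      d <- abs(mid[si] - genes$tss[gi])
      pairs <- tibble::tibble(site = si, gene_id = genes$gene_id[gi], d = d)
      # nearest TSS of each gene per site
      pairs <- dplyr::summarise(
        dplyr::group_by(pairs, .data$site, .data$gene_id),
        d = min(.data$d), .groups = "drop")
      pairs$w <- site_gene_weight(pairs$d, sites$p_bind[pairs$site],
                                  decay_scale)
      pairs$group <- sites$group[pairs$site]
      agg <- dplyr::summarise(
        dplyr::group_by(pairs, .data$gene_id, .data$group),
        w = sum(.data$w), .groups = "drop")
      burden[cbind(match(agg$gene_id, gene_ids),
                   match(agg$group, groups))] <- agg$w
    }
  }
  out <- tibble::as_tibble(burden)
  out <- tibble::add_column(out, gene_id = gene_ids, .before = 1)
  attr(out, "decay_scale") <- decay_scale
  attr(out, "motifs") <- keep_motifs
  class(out) <- c("ocr_burden", class(out))
  out
}

#' Aggregate centered ranks of pairwise burden differences
#'
#' For each pair of samples (one from each side) genes are ranked by the
#' burden difference and assigned centered ranks `-(n-1)/2 ... (n-1)/2`
#' (average ranks on ties, so each pair's ranks sum to 0); the final score per
#' gene is the mean over all pairs. Swapping the sides negates the scores.
#'
#' @param burden `ocr_burden` tibble from [burden_matrix()].
#' @param side_a,side_b Group column names on each side of the comparison.
#' @return Tibble `gene_id`, `score`, sorted by decreasing score.
#' @export
rank_aggregate <- function(burden, side_a, side_b) {
  if (length(side_a) == 0 || length(side_b) == 0) {
    stop("both sides need >= 1 group", call. = FALSE)
  }
  missing <- setdiff(c(side_a, side_b), names(burden))
  if (length(missing) > 0) {
    stop("groups absent from burden: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(burden)
  if (n < 2) stop("need >= 2 genes", call. = FALSE)
  scores <- numeric(n)
  n_pairs <- 0L
  for (a in side_a) {
    for (b in side_b) {
      d <- burden[[a]] - burden[[b]]
      scores <- scores + (rank(d, ties.method = "average") - (n + 1) / 2)
      n_pairs <- n_pairs + 1L
    }
  }
  out <- tibble::tibble(gene_id = burden$gene_id, score = scores / n_pairs)
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' Coverage-aware binomial motif enrichment
#'
#' For each motif, bound sites (`p_bind >= p_bind_threshold`) falling in the
#' target or background OCR sets are counted; under the null a site lands in
#' the target with probability equal to the target's share of covered base
#' pairs. Fold = observed/expected target share; p is the one-sided binomial
#' tail `P(X >= k)`; Bonferroni over the motifs tested.
#'
#' @param sites Binding-site tibble.
#' @param target_ocrs,background_ocrs Disjoint interval tibbles (e.g. one
#'   cell type's specific OCRs against the union of the other cell types').
#' @param p_bind_threshold Bound-site threshold (default 0.9).
#' @return Tibble per motif: `motif_id`, `n_target`, `n_total`,
#'   `bp_fraction`, `fold`, `p`, `p_bonferroni`, `skipped`.
#' @export
motif_enrichment <- function(sites, target_ocrs, background_ocrs,
                             p_bind_threshold = 0.9) {
  if (nrow(background_ocrs) == 0) stop("empty background", call. = FALSE)
  if (nrow(target_ocrs) == 0) stop("empty target", call. = FALSE)
  gt <- GenomicRanges::reduce(intervals_to_granges(target_ocrs))
  gb <- GenomicRanges::reduce(intervals_to_granges(background_ocrs))
  if (sum(IRanges::width(suppressWarnings(
        GenomicRanges::intersect(gt, gb)))) > 0) {
    stop("target and background OCR sets must be disjoint", call. = FALSE)
  }
  prop <- sum(IRanges::width(gt)) /
    (sum(IRanges::width(gt)) + sum(IRanges::width(gb)))
  bound <- sites[sites$p_bind >= p_bind_threshold, ]
  motifs <- sort(unique(sites$motif_id))
  rows <- purrr::map_dfr(motifs, function(m) {
    ms <- bound[bound$motif_id == m, ]
    if (nrow(ms) > 0) {
      g <- intervals_to_granges(ms)
      in_t <- suppressWarnings(GenomicRanges::countOverlaps(g, gt)) > 0
      in_b <- suppressWarnings(GenomicRanges::countOverlaps(g, gb)) > 0
      k <- sum(in_t)
      n <- sum(in_t | in_b)
    } else {
      k <- 0L; n <- 0L
    }
    if (n == 0) {
      return(tibble::tibble(motif_id = m, n_target = 0L, n_total = 0L,
                            bp_fraction = prop, fold = NA_real_,
                            p = NA_real_, skipped = TRUE))
    }
    tibble::tibble(motif_id = m, n_target = k, n_total = n,
                   bp_fraction = prop, fold = (k / n) / prop,
                   p = stats::pbinom(k - 1, n, prop, lower.tail = FALSE),
                   skipped = FALSE)
  })
  n_tested <- sum(!rows$skipped)
  rows$p_bonferroni <- pmin(rows$p * n_tested, 1)
  rows
}
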