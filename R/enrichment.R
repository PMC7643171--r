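# Genomic-context annotation, base-pair Jaccard overlap, regulatory-domain
# gene-set enrichment, TSS direct mapping and credible-variant enrichment.
#
# Gene annotation convention: one row per TSS with columns `gene_id`,
# `gene_name`, `chrom`, `tss` (0-based position), `strand`, `biotype`.
# Duplicate gene names are expected to be disambiguated upstream with
# "_v1"/"_v2" suffixes (see dedupe_gene_names()).

#' Disambiguate duplicate gene names
#'
#' Genes sharing a name get `_v1`, `_v2`, ... suffixes (in order of
#' appearance) so names can serve as keys.
#'
#' @param genes Gene annotation tibble with a `gene_name` column.
#' @return The tibble with unique gene names.
#' @export
dedupe_gene_names <- function(genes) {
  ids <- unique(genes[, c("gene_id", "gene_name")])
  dup_names <- unique(ids$gene_name[duplicated(ids$gene_name)])
  if (length(dup_names) == 0) return(genes)
  for (nm in dup_names) {
    gids <- unique(ids$gene_id[ids$gene_name == nm])
    for (k in seq_along(gids)) {
      genes$gene_name[genes$gene_id == gids[k]] <- sprintf("%s_v%d", nm, k)
    }
  }
  genes
}

#' Assign a genomic context label to each OCR
#'
#' Single label per OCR with priority promoter (within `promoter_window` of
#' any TSS) > 5'UTR > 3'UTR > exon > intron > distal intergenic. Feature
#' structure is optional; with TSS-only annotation the labels reduce to
#' promoter / distal_intergenic.
#'
#' @param ocrs OCR interval tibble (with `name` ids).
#' @param genes Gene annotation tibble (one row per TSS).
#' @param features Optional feature tibble: `chrom`, `start`, `end`, `type`
#'   with type in five_utr, three_utr, exon, intron.
#' @param promoter_window Promoter half-window around a TSS in bp
#'   (default 3000).
#' @return `ocrs` with an added `context` column.
#' @export
annotate_context <- function(ocrs, genes, features = NULL,
                             promoter_window = 3000) {
  validate_intervals(ocrs, "ocrs")
  gr <- intervals_to_granges(ocrs)
  context <- rep("distal_intergenic", nrow(ocrs))
  priority <- c("intron", "exon", "three_utr", "five_utr")
  if (!is.null(features) && nrow(features) > 0) {
    for (ft in priority) {
      sub <- features[features$type == ft, ]
      if (nrow(sub) == 0) next
      hit <- GenomicRanges::countOverlaps(gr, intervals_to_granges(sub)) > 0
      context[hit] <- ft
    }
  }
  prom <- tibble::tibble(chrom = genes$chrom,
                         start = pmax(genes$tss - promoter_window, 0),
                         end = genes$tss + promoter_window + 1)
  hit <- GenomicRanges::countOverlaps(gr, intervals_to_granges(prom)) > 0
  context[hit] <- "promoter"
  dplyr::mutate(ocrs, context = context)
}

#' Base-pair Jaccard index of two interval sets
#'
#' Intersection base pairs divided by union base pairs; 0 when the union is
#' empty.
#'
#' @param a,b Interval tibbles.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_bp <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ga <- GenomicRanges::reduce(intervals_to_granges(a))
  gb <- GenomicRanges::reduce(intervals_to_granges(b))
  inter <- sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(IRanges::width(GenomicRanges::union(ga, gb)))
  if (uni == 0) return(0)
  inter / uni
}

#' Basal-plus-extension regulatory domains
#'
#' Each gene gets a basal window around its (first) TSS — `basal_up` bp
#' upstream and `basal_down` bp downstream, strand aware — extended up to
#' `extension` bp in both directions but stopping at the nearest neighboring
#' gene's basal window.
#'
#' @param genes Gene annotation tibble (one row per TSS; the first TSS per
#'   gene anchors the domain).
#' @param basal_up,basal_down Basal window in bp (defaults 5000 / 1000).
#' @param extension Maximum extension in bp (default 1e6).
#' @return Tibble `gene_id`, `chrom`, `start`, `end`.
#' @export
regulatory_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                               extension = 1e6) {
  anchor <- dplyr::slice(dplyr::group_by(genes, .data$gene_id), 1) |>
    dplyr::ungroup()
  strand <- if ("strand" %in% names(anchor)) anchor$strand else rep("+", nrow(anchor))
  minus <- strand == "-"
  basal_start <- ifelse(minus, anchor$tss - basal_down + 1,
                        anchor$tss - basal_up)
  basal_end <- ifelse(minus, anchor$tss + basal_up + 1,
                      anchor$tss + basal_down)
  basal_start <- pmax(basal_start, 0)
  dom <- tibble::tibble(gene_id = anchor$gene_id, chrom = anchor$chrom,
                        basal_start = basal_start, basal_end = basal_end)
  dom <- dplyr::arrange(dom, .data$chrom, .data$basal_start)
  out <- dplyr::group_modify(dplyr::group_by(dom, .data$chrom),
    function(d, key) {
      n <- nrow(d)
      prev_end <- c(-Inf, d$basal_end[-n])
      next_start <- c(d$basal_start[-1], Inf)
      start <- pmax(d$basal_start - extension, prev_end, 0)
      end <- pmin(d$basal_end + extension, next_start)
      # the domain always contains its own basal window
      tibble::tibble(gene_id = d$gene_id,
                     start = pmin(start, d$basal_start),
                     end = pmax(end, d$basal_end))
    }) |> dplyr::ungroup()
  out[, c("gene_id", "chrom", "start", "end")]
}

#' Gene-set enrichment of OCRs in regulatory domains
#'
#' Compares the OCR density in the union of the gene set's regulatory domains
#' with the density in the union of all domains: with `k` OCRs overlapping the
#' set union out of `n` overlapping the all-gene union and `prop` the
#' base-pair fraction the set union covers, `fold = (k/n)/prop` and the
#' p-value is the one-sided binomial tail `P(X >= k)`, `X ~ Bin(n, prop)`.
#'
#' @param ocrs OCR interval tibble.
#' @param domains Regulatory-domain tibble from [regulatory_domains()].
#' @param gene_set Character vector of gene ids (non-empty subset).
#' @return One-row tibble: `n_set`, `n_total`, `bp_fraction`, `fold`, `p`.
#' @export
great_enrichment <- function(ocrs, domains, gene_set) {
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  set_dom <- domains[domains$gene_id %in% gene_set, ]
  if (nrow(set_dom) == 0) stop("gene set matches no domains", call. = FALSE)
  gr_ocr <- intervals_to_granges(ocrs)
  g_all <- GenomicRanges::reduce(intervals_to_granges(domains))
  g_set <- GenomicRanges::reduce(intervals_to_granges(set_dom))
  n <- sum(GenomicRanges::countOverlaps(gr_ocr, g_all) > 0)
  k <- sum(GenomicRanges::countOverlaps(gr_ocr, g_set) > 0)
  prop <- sum(IRanges::width(g_set)) / sum(IRanges::width(g_all))
  fold <- if (n == 0) NA_real_ else (k / n) / prop
  p <- stats::pbinom(k - 1, n, prop, lower.tail = FALSE)
  tibble::tibble(n_set = k, n_total = n, bp_fraction = prop,
                 fold = fold, p = p)
}

#' Map genes to cell types through TSS-overlapping OCRs
#'
#' For each gene, sums linear-scale accessibility (2^residualized log-CPM,
#' averaged per cell type) over all OCRs overlapping any of the gene's TSSs,
#' then row-normalizes to per-cell-type read fractions. Genes with no
#' TSS-overlapping OCR are excluded. A gene is called specific to a cell type
#' iff at least one of its TSS-overlapping OCRs lies in that cell type's
#' specificity set.
#'
#' @param adjusted OCR x sample residualized log-CPM matrix (rownames =
#'   OCR ids).
#' @param metadata Sample metadata aligned to the columns (needs
#'   `cell_type`).
#' @param ocrs OCR interval tibble with `name` matching the matrix rownames.
#' @param genes Gene annotation tibble (one row per TSS).
#' @param specificity_sets Optional `ocr_specificity` tibble from
#'   [cell_specific_sets()].
#' @return Tibble: `gene_id`, `gene_name`, one fraction column per cell type,
#'   `ocr_ids` (list column) and `specific_in` (list column of cell labels).
#' @export
tss_direct_map <- function(adjusted, metadata, ocrs, genes,
                           specificity_sets = NULL) {
  stopifnot(is.matrix(adjusted), ncol(adjusted) == nrow(metadata))
  cells <- unique(as.character(metadata$cell_type))
  linear <- 2^adjusted
  cellmean <- vapply(cells, function(ct) {
    rowMeans(linear[, metadata$cell_type == ct, drop = FALSE])
  }, numeric(nrow(adjusted)))
  rownames(cellmean) <- rownames(adjusted)
  tss_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$tss + 1,
                                                    genes$tss + 1))
  hits <- GenomicRanges::findOverlaps(tss_gr, intervals_to_granges(ocrs))
  if (length(hits) == 0) {
    return(tibble::tibble(gene_id = character(), gene_name = character()))
  }
  map <- tibble::tibble(
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    gene_name = genes$gene_name[S4Vectors::queryHits(hits)],
    ocr_id = ocrs$name[S4Vectors::subjectHits(hits)]
  )
  map <- dplyr::distinct(map, .data$gene_id, .data$ocr_id, .keep_all = TRUE)
  set_lookup <- if (!is.null(specificity_sets) && nrow(specificity_sets) > 0) {
    split(specificity_sets$ocr_id, specificity_sets$set)
  } else {
    list()
  }
  out <- dplyr::group_modify(dplyr::group_by(map, .data$gene_id),
    function(d, key) {
      acc <- colSums(cellmean[d$ocr_id, , drop = FALSE])
      frac <- acc / sum(acc)
      specific <- names(set_lookup)[vapply(set_lookup, function(s) {
        any(d$ocr_id %in% s)
      }, logical(1))]
      specific <- intersect(specific, cells)
      tibble::tibble(gene_name = d$gene_name[1],
                     !!!stats::setNames(as.list(frac), cells),
                     ocr_ids = list(d$ocr_id),
                     specific_in = list(specific))
    }) |> dplyr::ungroup()
  out
}

#' Enrichment of credible-set variants in (padded) OCRs
#'
#' Builds the 2x2 table of variant membership in padded OCRs against the
#' credible-set flag, reports the sample odds ratio and a two-sided Fisher
#' exact p, and optionally an empirical p from permutations that shift each
#' OCR to a uniform random position on its own chromosome (length preserved).
#'
#' @param ocrs OCR interval tibble.
#' @param variants Tibble `chrom`, `pos` (0-based), `credible` (logical or
#'   0/1).
#' @param padding Pad OCRs by this many bp on each side (default 0).
#' @param n_perm Number of OCR-position permutations (default 0 = none).
#' @param seed Seed for the permutations.
#' @param chrom_sizes Optional named vector of chromosome lengths; defaults
#'   to the maximum coordinate seen per chromosome.
#' @return One-row tibble: table counts, `odds_ratio`, `fisher_p`,
#'   `empirical_p` (NA without permutations), `haldane` flag.
#' @export
eqtl_enrichment <- function(ocrs, variants, padding = 0, n_perm = 0,
                            seed = NULL, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "pos", "credible") %in% names(variants)))
  cred <- as.logical(variants$credible)
  if (!any(cred) || !any(!cred)) {
    stop("need at least one credible and one non-credible variant",
         call. = FALSE)
  }
  var_gr <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos + 1,
                                                    variants$pos + 1))
  pad_ocrs <- function(o) {
    tibble::tibble(chrom = o$chrom, start = pmax(o$start - padding, 0),
                   end = o$end + padding)
  }
  tab_or <- function(o) {
    inside <- GenomicRanges::countOverlaps(
      var_gr, intervals_to_granges(pad_ocrs(o))) > 0
    a <- sum(inside & cred); b <- sum(!inside & cred)
    c_ <- sum(inside & !cred); d <- sum(!inside & !cred)
    degenerate <- any(c(a, b, c_, d) == 0)
    if (degenerate) {
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else {
      or <- (a * d) / (b * c_)
    }
    list(a = a, b = b, c = c_, d = d, or = or, haldane = degenerate)
  }
  obs <- tab_or(ocrs)
  fp <- stats::fisher.test(matrix(c(obs$a, obs$b, obs$c, obs$d), 2))$p.value
  emp <- NA_real_
  if (n_perm > 0) {
    sizes <- chrom_sizes %||% {
      lims <- tapply(c(ocrs$end, variants$pos + 1),
                     c(ocrs$chrom, variants$chrom), max)
      stats::setNames(as.numeric(lims), names(lims))
    }
    run <- function() {
      width <- ocrs$end - ocrs$start
      maxstart <- pmax(sizes[ocrs$chrom] - width, 0)
      newstart <- floor(stats::runif(nrow(ocrs)) * (maxstart + 1))
      shifted <- tibble::tibble(chrom = ocrs$chrom, start = newstart,
                                end = newstart + width)
      tab_or(shifted)$or
    }
    perms <- if (is.null(seed)) {
      replicate(n_perm, run())
    } else {
      with_seed(seed, replicate(n_perm, run()))
    }
    emp <- (1 + sum(perms >= obs$or)) / (1 + n_perm)
  }
  tibble::tibble(in_ocr_credible = obs$a, out_ocr_credible = obs$b,
                 in_ocr_other = obs$c, out_ocr_other = obs$d,
                 odds_ratio = obs$or, fisher_p = fp, empirical_p = emp,
                 haldane = obs$haldane)
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated — set name, description, then member
#' gene ids.
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("GMT line needs name, description and >= 1 gene", call. = FALSE)
    }
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}
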