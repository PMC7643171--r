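# Reading/writing genomic intervals, consensus OCR construction and the
# per-sample quality metrics the accessibility model consumes.

#' Read a BED file into an interval tibble
#'
#' Coordinates are kept in BED's native 0-based half-open convention, which is
#' also the package-internal convention for all interval tables.
#'
#' @param path Path to a tab-separated BED3/BED4/BED6 file without header.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(raw) < 3) stop("BED needs >= 3 tab-separated columns", call. = FALSE)
  out <- tibble::tibble(
    chrom = raw[[1]],
    start = suppressWarnings(as.integer(raw[[2]])),
    end = suppressWarnings(as.integer(raw[[3]]))
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                 out$start >= out$end | out$chrom == "")
  if (length(bad) > 0) {
    stop(sprintf("BED parse error at line %d of %s: need 0 <= start < end",
                 bad[1], path), call. = FALSE)
  }
  if (ncol(raw) >= 4) out$name <- raw[[4]]
  if (ncol(raw) >= 5) out$score <- suppressWarnings(as.numeric(raw[[5]]))
  if (ncol(raw) >= 6) out$strand <- raw[[6]]
  out
}

#' Write an interval tibble as BED
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, optional
#'   `name`, `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(intervals)) cols <- c(cols, extra) else break
  }
  utils::write.table(intervals[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build the consensus OCR set from per-group peak sets
#'
#' Peaks called in any input set are unioned and overlapping peaks merged into
#' maximal non-overlapping intervals; any merged interval that overlaps a
#' blacklisted region by at least one base pair is dropped entirely (not
#' trimmed). Applying the function to its own output is the identity.
#'
#' @param peak_sets A single interval tibble or a list of them (one per
#'   sample group).
#' @param blacklist Optional interval tibble of regions to exclude.
#' @param prefix Prefix for the consensus OCR identifiers.
#' @return Interval tibble of non-overlapping consensus OCRs, sorted by
#'   (chrom, start), with a `name` column of stable OCR ids.
#' @export
build_consensus <- function(peak_sets, blacklist = NULL, prefix = "OCR") {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  peak_sets <- purrr::keep(peak_sets, ~ nrow(.x) > 0)
  if (length(peak_sets) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character()))
  }
  all_gr <- do.call(c, purrr::map(peak_sets, intervals_to_granges))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(all_gr))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    hits <- GenomicRanges::countOverlaps(merged, intervals_to_granges(blacklist))
    merged <- merged[hits == 0]
  }
  out <- granges_to_intervals(merged)
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$name <- sprintf("%s_%05d", prefix, seq_len(nrow(out)))
  out
}

#' Count fragments overlapping each OCR
#'
#' A fragment contributes one count to every OCR it overlaps by at least one
#' base pair; consensus OCRs are non-overlapping so a fragment adds at most
#' one count per OCR.
#'
#' @param fragments Interval tibble of sequenced fragments for one sample.
#' @param ocrs Consensus OCR interval tibble.
#' @return Integer vector of counts, one per OCR row, named by `ocrs$name`
#'   when available.
#' @export
count_fragments <- function(fragments, ocrs) {
  validate_intervals(ocrs, "ocrs")
  if (nrow(fragments) == 0) {
    out <- integer(nrow(ocrs))
  } else {
    out <- GenomicRanges::countOverlaps(intervals_to_granges(ocrs),
                                        intervals_to_granges(fragments))
  }
  if ("name" %in% names(ocrs)) names(out) <- ocrs$name
  out
}

#' Fraction of reads in peaks (FRiP)
#'
#' @param fragments Interval tibble of fragments for one sample.
#' @param ocrs Peak/OCR interval tibble.
#' @return Fraction of fragments overlapping at least one OCR.
#' @export
frip <- function(fragments, ocrs) {
  if (nrow(fragments) == 0) {
    stop("FRiP is undefined for zero fragments", call. = FALSE)
  }
  if (nrow(ocrs) == 0) return(0)
  hits <- GenomicRanges::countOverlaps(intervals_to_granges(fragments),
                                       intervals_to_granges(ocrs))
  mean(hits > 0)
}

#' PCR bottleneck coefficient (PBC)
#'
#' Distinct read positions divided by the number of reads; an approximate
#' library-complexity measure in `[1/n, 1]`.
#'
#' @param reads Tibble with columns `chrom`, `start` and optionally `strand`.
#' @return Fraction of reads at distinct (chrom, start, strand) positions.
#' @export
pbc <- function(reads) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0) stop("PBC is undefined for zero reads", call. = FALSE)
  strand <- if ("strand" %in% names(reads)) reads$strand else rep(".", nrow(reads))
  keys <- paste(reads$chrom, reads$start, strand, sep = "\r")
  length(unique(keys)) / nrow(reads)
}

#' TSS enrichment score
#'
#' Aggregates per-base-pair fragment coverage over `[tss - flank, tss + flank)`
#' across all provided TSSs and scores the coverage at the TSS position
#' against the mean coverage of the outermost 100 bp on each side of the
#' window. A uniform coverage profile scores ~1; when no fragment falls in
#' any window the score is 0 (and `Inf` if there is signal at the TSS but a
#' completely empty flank baseline).
#'
#' @param fragments Interval tibble of fragments.
#' @param tss Tibble with columns `chrom` and `pos` (0-based TSS positions).
#' @param flank Half-window size in bp (default 1000, i.e. fragments up to
#'   1 kb from the TSS in both directions).
#' @param edge_bp Width of the per-side baseline region (default 100 bp).
#' @return A single enrichment score.
#' @export
tss_enrichment <- function(fragments, tss, flank = 1000, edge_bp = 100) {
  stopifnot(is.data.frame(tss), nrow(tss) >= 1, flank > edge_bp)
  width <- 2L * as.integer(flank)
  cov <- numeric(width)
  if (nrow(fragments) > 0) {
    validate_intervals(fragments, "fragments")
    windows <- tibble::tibble(chrom = tss$chrom,
                              start = pmax(tss$pos - flank, 0),
                              end = tss$pos + flank)
    hits <- GenomicRanges::findOverlaps(intervals_to_granges(fragments),
                                        intervals_to_granges(windows))
    if (length(hits) > 0) {
      fi <- S4Vectors::queryHits(hits)
      wi <- S4Vectors::subjectHits(hits)
      # window coordinate system: 1 .. 2*flank maps to [tss-flank, tss+flank)
      win_origin <- tss$pos[wi] - flank
      rel_start <- pmax(fragments$start[fi], win_origin) - win_origin + 1L
      rel_end <- pmin(fragments$end[fi], win_origin + width) - win_origin
      delta <- numeric(width + 1L)
      add_s <- tabulate(rel_start, nbins = width + 1L)
      add_e <- tabulate(rel_end + 1L, nbins = width + 1L)
      delta <- add_s - add_e
      cov <- cumsum(delta)[seq_len(width)]
    }
  }
  if (sum(cov) == 0) return(0)
  center <- cov[flank + 1L]
  baseline <- mean(cov[c(seq_len(edge_bp), (width - edge_bp + 1L):width)])
  center / baseline
}
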