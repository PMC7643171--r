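# Low-accessibility filtering and the promoter-anchored TMM normalization.
#
# Between-sample scaling factors are computed with the trimmed mean of
# M-values, but only over OCRs directly overlapping an autosomal
# protein-coding TSS. Non-promoter OCRs carry systematically lower counts and
# their cell-type-dependent share distorts whole-matrix TMM; anchoring the
# factor on promoter OCRs keeps housekeeping promoters balanced across cell
# types. Because the choice of TMM reference sample is arbitrary, the factor
# for each sample is the mean over every other sample taken as reference.

#' Filter lowly accessible OCRs
#'
#' Keeps an OCR iff its counts-per-million reach `cpm_threshold` in at least
#' `ceiling(sample_fraction * n_samples)` samples.
#'
#' @param counts OCR x sample integer matrix with dimnames.
#' @param cpm_threshold Minimum CPM (default 1).
#' @param sample_fraction Minimum fraction of samples (default 0.1).
#' @return Integer vector of kept row indices, named by OCR id.
#' @export
filter_low <- function(counts, cpm_threshold = 1, sample_fraction = 0.1) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero total counts", call. = FALSE)
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  need <- ceiling(sample_fraction * ncol(counts))
  keep <- which(rowSums(cpm >= cpm_threshold) >= need)
  if (length(keep) == 0) stop("all OCRs removed by the CPM filter", call. = FALSE)
  keep
}

# One pairwise TMM factor (obs vs ref), doubly trimmed weighted mean of
# M-values with delta-method precision weights.
tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref,
                            trim_m = 0.3, trim_a = 0.05, weighted = TRUE) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  lib_obs <- as.numeric(lib_obs); lib_ref <- as.numeric(lib_ref)
  yo <- obs / lib_obs
  yr <- ref / lib_ref
  keep <- obs > 0 & ref > 0
  if (sum(keep) == 0) return(NA_real_)
  m <- log2(yo[keep] / yr[keep])
  a <- 0.5 * log2(yo[keep] * yr[keep])
  w <- (lib_obs - obs[keep]) / (lib_obs * obs[keep]) +
    (lib_ref - ref[keep]) / (lib_ref * ref[keep])
  fin <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  kept <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(kept)) return(1)
  f <- if (weighted) {
    sum(m[kept] / w[kept]) / sum(1 / w[kept])
  } else {
    mean(m[kept])
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Promoter-anchored TMM normalization factors
#'
#' Computes TMM scaling factors on the promoter-OCR submatrix only, using the
#' promoter-submatrix column sums as library sizes (so that adding or removing
#' non-promoter OCRs leaves the factors unchanged). TMM normalization is
#' defined between a sample and a reference; instead of fixing one reference,
#' each sample's factor is the arithmetic mean of its factors against every
#' other sample as reference. Factors are rescaled to geometric mean 1, and
#' the per-sample standard deviation over reference choices is reported as a
#' robustness diagnostic.
#'
#' @param counts OCR x sample count matrix.
#' @param promoter_mask Logical vector (one per OCR row): does the OCR
#'   directly overlap an autosomal protein-coding TSS?
#' @param lib_size Optional per-sample library sizes; defaults to the
#'   promoter-submatrix column sums.
#' @param trim_m,trim_a Two-sided trim fractions for M and A values
#'   (defaults 0.3 and 0.05, the published TMM settings).
#' @param weighted Use delta-method precision weights (default TRUE).
#' @return A tibble with `sample_id`, `norm_factor` (geometric mean 1) and
#'   `ref_sd` (sd of the factor over reference-sample choices).
#' @export
promoter_tmm <- function(counts, promoter_mask, lib_size = NULL,
                         trim_m = 0.3, trim_a = 0.05, weighted = TRUE) {
  stopifnot(is.matrix(counts), length(promoter_mask) == nrow(counts))
  prom <- counts[promoter_mask, , drop = FALSE]
  nz <- colSums(prom) > 0
  if (any(!nz)) {
    stop("sample(s) with all-zero promoter counts: ",
         paste(colnames(counts)[!nz], collapse = ", "), call. = FALSE)
  }
  if (sum(rowSums(prom) > 0) < 2) {
    stop("need >= 2 promoter OCRs with nonzero counts", call. = FALSE)
  }
  lib <- lib_size %||% colSums(prom)
  ns <- ncol(prom)
  # factor of sample j against every reference r; the self-reference is
  # exactly 1. Every sample must average over the same reference set
  # (including itself), otherwise the per-sample reference means are not on
  # a common scale and the averaged factors are distorted.
  fmat <- diag(1, ns)  # [sample, reference]
  for (j in seq_len(ns)) {
    for (r in seq_len(ns)) {
      if (r == j) next
      fmat[j, r] <- tmm_pair_factor(prom[, j], prom[, r], lib[j], lib[r],
                                    trim_m = trim_m, trim_a = trim_a,
                                    weighted = weighted)
    }
  }
  f <- rowMeans(fmat)
  ref_sd <- apply(fmat, 1, stats::sd)
  f <- f / exp(mean(log(f)))
  tibble::tibble(
    sample_id = colnames(counts) %||% as.character(seq_len(ns)),
    norm_factor = f,
    ref_sd = ref_sd
  )
}

#' Whole-matrix TMM factors against an automatically chosen reference
#'
#' Standard single-reference TMM (the reference is the sample whose upper
#' count quartile is closest to the mean upper quartile), for data without a
#' promoter annotation, e.g. bulk case-control matrices where the trimmed
#' mean absorbs compositional shifts from strong disease or composition
#' effects. For the cell-sorted pipeline use [promoter_tmm()].
#'
#' @inheritParams promoter_tmm
#' @return Tibble with `sample_id` and `norm_factor` (geometric mean 1).
#' @export
tmm_factors <- function(counts, lib_size = NULL, trim_m = 0.3, trim_a = 0.05,
                        weighted = TRUE) {
  stopifnot(is.matrix(counts))
  lib <- lib_size %||% colSums(counts)
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j] / lib[j], 0.75)
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    trim_m = trim_m, trim_a = trim_a, weighted = weighted)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble::tibble(sample_id = colnames(counts) %||%
                   as.character(seq_len(ncol(counts))),
                 norm_factor = f)
}

#' Log2 counts-per-million with TMM effective library sizes
#'
#' `logcpm[i, s] = log2((count + prior) / (lib_s * factor_s + 2 * prior) * 1e6)`.
#'
#' @param counts OCR x sample count matrix.
#' @param norm_factors Output of [promoter_tmm()] (or a bare positive numeric
#'   vector, optionally named by sample).
#' @param prior_count Pseudo-count stabilising low counts (default 0.5).
#' @return An object of class `ocr_norm`: list with `logcpm` matrix,
#'   `norm_factors`, `effective_lib_sizes`, `prior_count`.
#' @export
log_cpm <- function(counts, norm_factors = NULL, prior_count = 0.5) {
  stopifnot(is.matrix(counts), prior_count > 0)
  nf <- if (is.null(norm_factors)) rep(1, ncol(counts)) else
    as_norm_factors(norm_factors, colnames(counts))
  eff <- colSums(counts) * nf
  if (any(eff <= 0)) stop("nonpositive effective library size", call. = FALSE)
  logcpm <- log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
  structure(
    list(logcpm = logcpm, norm_factors = nf, effective_lib_sizes = eff,
         prior_count = prior_count),
    class = "ocr_norm"
  )
}

#' @export
print.ocr_norm <- function(x, ...) {
  cat(sprintf("<ocr_norm> %d OCRs x %d samples (prior count %.2g)\n",
              nrow(x$logcpm), ncol(x$logcpm), x$prior_count))
  invisible(x)
}
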