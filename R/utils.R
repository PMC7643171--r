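# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulation functions are reproducible
#' without disturbing the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }, add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Convert an interval tibble (0-based half-open) to GRanges (1-based closed)
#' @noRd
intervals_to_granges <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' @noRd
granges_to_intervals <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' @noRd
validate_intervals <- function(x, what = "intervals") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s must have columns %s", what, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!(x$start < x$end) | x$start < 0 | is.na(x$chrom) | x$chrom == "")
  if (length(bad) > 0) {
    stop(sprintf("invalid interval at row %d: need 0 <= start < end and non-empty chrom",
                 bad[1]), call. = FALSE)
  }
  invisible(x)
}

#' Total number of distinct base pairs covered by an interval set
#' @noRd
covered_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(IRanges::width(GenomicRanges::reduce(intervals_to_granges(x))))
}

#' Coerce norm-factor input (tibble from promoter_tmm() or bare numeric)
#' @noRd
as_norm_factors <- function(norm_factors, sample_ids) {
  if (is.data.frame(norm_factors)) {
    nf <- norm_factors$norm_factor
    names(nf) <- norm_factors$sample_id
  } else {
    nf <- norm_factors
  }
  if (!is.null(names(nf)) && !is.null(sample_ids)) {
    if (!all(sample_ids %in% names(nf))) {
      stop("norm_factors do not cover all samples", call. = FALSE)
    }
    nf <- nf[sample_ids]
  }
  if (any(!is.finite(nf)) || any(nf <= 0)) {
    stop("normalization factors must be positive and finite", call. = FALSE)
  }
  unname(nf)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
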