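# Precision-weighted differential accessibility and the cell / neuronal /
# regional specificity set algebra.
#
# The accessibility model is `~ 0 + group + sex + frip` where group is the
# cell-type-by-region factor (12 levels in the full design). Cell contrasts
# compare cells within the same brain region and average over regions, so
# overall regional differences cancel; e.g. the GLU-vs-GABA contrast is
# mean_r(GLU_r - GABA_r).

#' Build the group design matrix for the accessibility model
#'
#' @param metadata Sample metadata with `cell_type`, `region` and the named
#'   extra covariates.
#' @param extra Character vector of additional metadata columns entering the
#'   model (factors contribute levels - 1 columns; default
#'   `c("sex", "frip")`).
#' @return Model matrix with one column per cell-by-region group (named
#'   `CELL_REGION`) plus the extra covariate columns.
#' @export
build_design <- function(metadata, extra = c("sex", "frip")) {
  stopifnot(all(c("cell_type", "region") %in% names(metadata)))
  md <- as.data.frame(metadata)
  md$group <- factor(paste(md$cell_type, md$region, sep = "_"))
  extra <- intersect(extra, names(md))
  rhs <- paste(c("0", "group", extra), collapse = " + ")
  design <- stats::model.matrix(stats::as.formula(paste("~", rhs)), md)
  colnames(design) <- sub("^group", "", colnames(design))
  design
}

#' Pairwise cell-type contrast expressions
#'
#' One contrast per unordered cell-type pair, comparing cells within the same
#' region and averaging across regions (so the log2 fold change is the mean
#' within-region difference).
#'
#' @param cell_types,regions Factor level vectors.
#' @return Named character vector of contrast expressions
#'   (names `"A_vs_B"`).
#' @export
cell_pair_contrasts <- function(cell_types = c("GLU", "GABA", "OLIG", "MGAS"),
                                regions = c("ACC", "DLPFC", "PVC")) {
  pairs <- utils::combn(cell_types, 2, simplify = FALSE)
  out <- vapply(pairs, function(p) {
    terms <- paste(sprintf("(%s_%s - %s_%s)", p[1], regions, p[2], regions),
                   collapse = " + ")
    sprintf("(%s) / %d", terms, length(regions))
  }, character(1))
  names(out) <- vapply(pairs, function(p) paste(p, collapse = "_vs_"),
                       character(1))
  out
}

#' Region contrast expressions within one cell type
#'
#' Each region against the average of the other regions, within the cell.
#'
#' @param cell_type Single cell-type label.
#' @param regions Region labels (>= 2).
#' @return Named character vector (names `"CELL_REGION_vs_rest"`).
#' @export
region_contrasts <- function(cell_type, regions = c("ACC", "DLPFC", "PVC")) {
  if (length(regions) < 2) stop("need >= 2 regions", call. = FALSE)
  out <- vapply(regions, function(r) {
    others <- setdiff(regions, r)
    sprintf("%s_%s - (%s) / %d", cell_type, r,
            paste(sprintf("%s_%s", cell_type, others), collapse = " + "),
            length(others))
  }, character(1))
  names(out) <- sprintf("%s_%s_vs_rest", cell_type, regions)
  out
}

#' Precision weights from the mean-variance trend plus sample weights
#'
#' Thin wrapper around the voom-with-quality-weights machinery: counts are
#' converted to log-CPM with the supplied normalization factors, a lowess
#' mean-variance trend provides observation-level weights, and per-sample
#' quality weights down-weight noisy samples; the final weight is their
#' product. Quantile normalization is deliberately not used: cell types with
#' different promoter/non-promoter compositions must not be forced onto a
#' common count distribution.
#'
#' @param counts OCR x sample count matrix.
#' @param design Model matrix (full rank).
#' @param norm_factors Output of [promoter_tmm()] or a numeric vector;
#'   NULL for library-size-only normalization.
#' @param span Lowess span for the mean-variance trend (default 0.5).
#' @param sample_weights Estimate per-sample quality weights (default TRUE).
#' @return An `ocr_voom` object: list with `logcpm`, `weights` (OCR x sample),
#'   `sample_weights`, `trend` (tibble of the lowess curve) and `design`.
#' @export
voom_weights <- function(counts, design, norm_factors = NULL, span = 0.5,
                         sample_weights = TRUE) {
  stopifnot(is.matrix(counts))
  if (qr(design)$rank < ncol(design)) stop("design is not full rank", call. = FALSE)
  if (nrow(counts) < 2 || ncol(counts) - ncol(design) < 2) {
    stop("need >= 2 residual degrees of freedom", call. = FALSE)
  }
  nf <- if (is.null(norm_factors)) rep(1, ncol(counts)) else
    as_norm_factors(norm_factors, colnames(counts))
  lib <- colSums(counts) * nf
  if (sample_weights) {
    v <- limma::voomWithQualityWeights(counts, design, lib.size = lib,
                                       normalize.method = "none",
                                       span = span, save.plot = TRUE)
    sw <- v$targets$sample.weights
    if (is.null(sw)) sw <- v$sample.weights
  } else {
    v <- limma::voom(counts, design, lib.size = lib,
                     normalize.method = "none", span = span, save.plot = TRUE)
    sw <- rep(1, ncol(counts))
  }
  structure(
    list(logcpm = v$E, weights = v$weights, sample_weights = sw,
         trend = tibble::tibble(mean_logcount = v$voom.xy$x,
                                sqrt_sd = v$voom.xy$y),
         design = design),
    class = "ocr_voom"
  )
}

#' @export
print.ocr_voom <- function(x, ...) {
  cat(sprintf("<ocr_voom> %d OCRs x %d samples; sample weights in [%.2f, %.2f]\n",
              nrow(x$logcpm), ncol(x$logcpm),
              min(x$sample_weights), max(x$sample_weights)))
  invisible(x)
}

#' Fit contrasts with weighted least squares and moderated statistics
#'
#' Per-OCR weighted least-squares fits of the accessibility model, followed by
#' empirical-Bayes variance moderation (inverse-chi-square shrinkage of the
#' residual variances toward a common prior) and moderated t-tests of each
#' contrast; Benjamini-Hochberg FDR within each contrast. Set
#' `moderate = FALSE` for plain WLS t-tests.
#'
#' @param v An `ocr_voom` object, or a bare log-CPM matrix.
#' @param contrasts Named character vector of contrast expressions in terms
#'   of design column names (e.g. from [cell_pair_contrasts()]), or a numeric
#'   contrast matrix with one column per contrast.
#' @param design Model matrix; defaults to `v$design`.
#' @param weights OCR x sample weights; defaults to `v$weights`.
#' @param moderate Apply empirical-Bayes moderation (default TRUE).
#' @return An `ocr_fit` object; use [tidy()] for the per-OCR results table
#'   with columns `contrast`, `ocr_id`, `log2fc`, `t`, `p`, `fdr`.
#' @export
fit_contrasts <- function(v, contrasts, design = NULL, weights = NULL,
                          moderate = TRUE) {
  if (inherits(v, "ocr_voom")) {
    logcpm <- v$logcpm
    design <- design %||% v$design
    weights <- weights %||% v$weights
  } else {
    logcpm <- v
    if (is.null(design)) stop("design required", call. = FALSE)
  }
  if (is.character(contrasts)) {
    if (is.null(names(contrasts)) || any(names(contrasts) == "")) {
      stop("contrast expressions must be named", call. = FALSE)
    }
    cm <- limma::makeContrasts(contrasts = contrasts, levels = design)
    colnames(cm) <- names(contrasts)
  } else {
    cm <- as.matrix(contrasts)
    if (nrow(cm) != ncol(design)) {
      stop("contrast vectors must have one entry per design column",
           call. = FALSE)
    }
  }
  if (any(colSums(abs(cm)) == 0)) stop("contrast of all zeros", call. = FALSE)
  fit <- limma::lmFit(logcpm, design, weights = weights)
  cfit <- limma::contrasts.fit(fit, cm)
  if (moderate) {
    cfit <- limma::eBayes(cfit)
  } else {
    # ordinary t-statistics from the unmoderated residual variance
    cfit$t <- cfit$coefficients / (cfit$stdev.unscaled * cfit$sigma)
    cfit$df.total <- cfit$df.residual
    cfit$p.value <- 2 * stats::pt(-abs(cfit$t), df = cfit$df.total)
  }
  structure(
    list(fit = cfit, lmfit = fit, design = design,
         contrast_names = colnames(cm), moderated = moderate),
    class = "ocr_fit"
  )
}

#' @export
print.ocr_fit <- function(x, ...) {
  cat(sprintf("<ocr_fit> %d OCRs, %d contrast(s): %s\n",
              nrow(x$fit$coefficients), length(x$contrast_names),
              paste(x$contrast_names, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.ocr_fit <- function(x, ...) {
  ids <- rownames(x$fit$coefficients) %||%
    as.character(seq_len(nrow(x$fit$coefficients)))
  purrr::map_dfr(x$contrast_names, function(cn) {
    p <- x$fit$p.value[, cn]
    tibble::tibble(
      contrast = cn,
      ocr_id = ids,
      log2fc = unname(x$fit$coefficients[, cn]),
      t = unname(x$fit$t[, cn]),
      p = unname(p),
      fdr = stats::p.adjust(unname(p), method = "BH")
    )
  })
}

#' @export
glance.ocr_fit <- function(x, fdr = 0.05, ...) {
  res <- tidy(x)
  dplyr::summarise(
    dplyr::group_by(res, .data$contrast),
    n_tests = dplyr::n(),
    n_significant = sum(.data$fdr < !!fdr),
    .groups = "drop"
  )
}

# Oriented significance lookup: sig_up[[X]][[Y]] marks OCRs significantly MORE
# accessible in X than Y at the given FDR, read off the pairwise results.
oriented_significance <- function(results, cells, fdr) {
  stopifnot(all(c("contrast", "ocr_id", "log2fc", "fdr") %in% names(results)))
  ids <- unique(results$ocr_id)
  sig <- lapply(cells, function(x) {
    stats::setNames(vector("list", length(cells)), cells)
  })
  names(sig) <- cells
  for (a in cells) {
    for (b in cells) {
      if (a == b) next
      fwd <- results[results$contrast == paste0(a, "_vs_", b), ]
      if (nrow(fwd) > 0) {
        hit <- fwd[fwd$fdr < fdr & fwd$log2fc > 0, ]
      } else {
        rev <- results[results$contrast == paste0(b, "_vs_", a), ]
        if (nrow(rev) == 0) {
          stop("missing contrast between ", a, " and ", b, call. = FALSE)
        }
        hit <- rev[rev$fdr < fdr & rev$log2fc < 0, ]
      }
      sig[[a]][[b]] <- unique(hit$ocr_id)
    }
  }
  list(sig = sig, ids = ids)
}

# Statistics of the least significant comparison among `vs` for OCRs `ids`
# in favour of cell `a`; ties in p broken by smallest |log2fc|.
least_significant_stats <- function(results, a, vs, ids) {
  rows <- purrr::map_dfr(vs, function(b) {
    fwd <- results[results$contrast == paste0(a, "_vs_", b) &
                     results$ocr_id %in% ids, ]
    if (nrow(fwd) == 0) {
      rev <- results[results$contrast == paste0(b, "_vs_", a) &
                       results$ocr_id %in% ids, ]
      fwd <- dplyr::mutate(rev, log2fc = -.data$log2fc, t = -.data$t,
                           contrast = paste0(a, "_vs_", b))
    }
    fwd
  })
  dplyr::slice(
    dplyr::arrange(dplyr::group_by(rows, .data$ocr_id),
                   dplyr::desc(.data$p), abs(.data$log2fc)),
    1
  ) |> dplyr::ungroup()
}

#' Cell-type-specific OCR sets
#'
#' An OCR is specific to cell type X iff it is significantly more accessible
#' in X than in each of the other cell types (FDR below the cutoff in every
#' pairwise comparison, with positive fold change toward X). An OCR that is
#' equally high in two cell types is therefore specific to neither. The
#' reported statistics per OCR are those of the least significant of its
#' pairwise comparisons.
#'
#' @param results Tidy pairwise results (from `tidy()` on a fit of
#'   [cell_pair_contrasts()]), with contrast names `"A_vs_B"`.
#' @param cells Cell-type labels (default the four sorted populations).
#' @param fdr FDR cutoff (default 0.05).
#' @return An `ocr_specificity` tibble: `set`, `ocr_id`, and the
#'   least-significant-comparison statistics (`contrast`, `log2fc`, `t`,
#'   `p`, `fdr`).
#' @export
cell_specific_sets <- function(results,
                               cells = c("GLU", "GABA", "OLIG", "MGAS"),
                               fdr = 0.05) {
  os <- oriented_significance(results, cells, fdr)
  out <- purrr::map_dfr(cells, function(a) {
    others <- setdiff(cells, a)
    member <- Reduce(intersect, lapply(others, function(b) os$sig[[a]][[b]]))
    if (length(member) == 0) return(NULL)
    stats <- least_significant_stats(results, a, others, member)
    tibble::add_column(stats, set = a, .before = 1)
  })
  class(out) <- c("ocr_specificity", class(out))
  out
}

#' Neuronal and non-neuronal group-specific OCR sets
#'
#' Neuron-specific OCRs are the union of (GLU more accessible than both
#' non-neuronal types) and (GABA more accessible than both non-neuronal
#' types); non-neuron-specific OCRs analogously with OLIG/MGAS against the
#' neuronal types. These sets include OCRs shared between the two constituent
#' subtypes, which the per-cell sets exclude. The reported statistics come
#' from the least significant comparison of the most significant satisfied
#' branch.
#'
#' @inheritParams cell_specific_sets
#' @param neuronal,non_neuronal The two cell groups
#'   (defaults `c("GLU", "GABA")` and `c("OLIG", "MGAS")`).
#' @return An `ocr_specificity` tibble with sets `Neuron` and `nonNeuron`.
#' @export
group_specific_sets <- function(results, neuronal = c("GLU", "GABA"),
                                non_neuronal = c("OLIG", "MGAS"),
                                fdr = 0.05) {
  cells <- c(neuronal, non_neuronal)
  os <- oriented_significance(results, cells, fdr)
  one_side <- function(side, other, label) {
    branches <- lapply(side, function(a) {
      Reduce(intersect, lapply(other, function(b) os$sig[[a]][[b]]))
    })
    member <- Reduce(union, branches)
    if (length(member) == 0) return(NULL)
    per_branch <- purrr::map_dfr(seq_along(side), function(i) {
      ids <- intersect(branches[[i]], member)
      if (length(ids) == 0) return(NULL)
      least_significant_stats(results, side[i], other, ids)
    })
    # most significant satisfied branch per OCR
    best <- dplyr::slice(
      dplyr::arrange(dplyr::group_by(per_branch, .data$ocr_id),
                     .data$p, abs(.data$log2fc)),
      1
    ) |> dplyr::ungroup()
    tibble::add_column(best, set = label, .before = 1)
  }
  out <- dplyr::bind_rows(
    one_side(neuronal, non_neuronal, "Neuron"),
    one_side(non_neuronal, neuronal, "nonNeuron")
  )
  class(out) <- c("ocr_specificity", class(out))
  out
}

#' Region-specific OCR sets within a cell type
#'
#' Takes the tidy results of the within-cell region contrasts (each region
#' against the mean of the others, from [region_contrasts()]), restricts them
#' to the OCRs called open in the cell type in question, recomputes the
#' Benjamini-Hochberg FDR over that restricted set only (the power gain of
#' the restriction), and reports OCRs significantly more accessible in the
#' region.
#'
#' @param results Tidy results of the region contrasts for one cell type.
#' @param cell_ocr_mask Character vector of OCR ids called open in the cell
#'   type (or a logical vector over the result OCR ids).
#' @param fdr FDR cutoff (default 0.05).
#' @return An `ocr_specificity` tibble with one set per region contrast.
#' @export
region_specific_sets <- function(results, cell_ocr_mask, fdr = 0.05) {
  contrasts <- unique(results$contrast)
  if (length(contrasts) < 2) {
    stop("need region contrasts for >= 2 regions", call. = FALSE)
  }
  if (is.logical(cell_ocr_mask)) {
    ids <- unique(results$ocr_id)
    stopifnot(length(cell_ocr_mask) == length(ids))
    cell_ocr_mask <- ids[cell_ocr_mask]
  }
  out <- purrr::map_dfr(contrasts, function(cn) {
    sub <- results[results$contrast == cn &
                     results$ocr_id %in% cell_ocr_mask, ]
    if (nrow(sub) == 0) return(NULL)
    sub$fdr <- stats::p.adjust(sub$p, method = "BH")
    hit <- sub[sub$fdr < fdr & sub$log2fc > 0, ]
    if (nrow(hit) == 0) return(NULL)
    tibble::add_column(hit, set = sub("_vs_rest$", "", cn), .before = 1)
  })
  class(out) <- c("ocr_specificity", class(out))
  out
}

#' Remove nuisance covariate effects from the accessibility matrix
#'
#' Subtracts the estimated effect of the named covariates (e.g. sex and FRiP)
#' from the log-CPM matrix, retaining the cell-type and brain-region signal:
#' `adjusted = logcpm - X_remove %*% t(beta_remove)` from the full weighted
#' fit. The operation is idempotent and the adjusted matrix is orthogonal to
#' the removed covariates under the fit weights.
#'
#' @param v `ocr_voom` object or log-CPM matrix.
#' @param remove Covariate labels; all design columns whose name starts with
#'   a label are removed (so `"sex"` matches `"sexM"`).
#' @param design,weights Used when `v` is a bare matrix.
#' @return Adjusted OCR x sample matrix.
#' @export
residualize <- function(v, remove, design = NULL, weights = NULL) {
  if (inherits(v, "ocr_voom")) {
    logcpm <- v$logcpm
    design <- design %||% v$design
    weights <- weights %||% v$weights
  } else {
    logcpm <- v
    if (is.null(design)) stop("design required", call. = FALSE)
  }
  cols <- unlist(lapply(remove, function(r) {
    hits <- which(startsWith(colnames(design), r))
    if (length(hits) == 0) stop("unknown covariate label: ", r, call. = FALSE)
    hits
  }))
  cols <- sort(unique(cols))
  fit <- limma::lmFit(logcpm, design, weights = weights)
  beta <- fit$coefficients[, cols, drop = FALSE]
  beta[is.na(beta)] <- 0
  logcpm - beta %*% t(design[, cols, drop = FALSE])
}
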