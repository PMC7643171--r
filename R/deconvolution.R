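# Marker-OCR selection, linear-mixing deconvolution of bulk chromatin data,
# and the case-control pi1 power workflow.

#' Select marker OCRs per cell type
#'
#' An OCR is a marker for cell type X iff it is significant (FDR below
#' `fdr`) with log2 fold change above `min_log2fc` in X against *each* other
#' cell type. With `min_log2fc > 0` the marker sets are disjoint by
#' construction.
#'
#' @param results Tidy pairwise cell-contrast results (contrasts `"A_vs_B"`
#'   covering all unordered pairs).
#' @param cells Cell-type labels.
#' @param fdr FDR threshold (default 0.05).
#' @param min_log2fc Minimum log2 fold change against every other cell type
#'   (default 2).
#' @return An `ocr_marker_panel` tibble: `cell_type`, `ocr_id`,
#'   `min_pair_log2fc`, `max_pair_fdr`; thresholds kept as attributes.
#' @export
select_markers <- function(results, cells = c("GLU", "GABA", "OLIG", "MGAS"),
                           fdr = 0.05, min_log2fc = 2) {
  oriented <- purrr::map_dfr(cells, function(a) {
    purrr::map_dfr(setdiff(cells, a), function(b) {
      fwd <- results[results$contrast == paste0(a, "_vs_", b), ]
      if (nrow(fwd) == 0) {
        rev <- results[results$contrast == paste0(b, "_vs_", a), ]
        if (nrow(rev) == 0) {
          stop("missing contrast between ", a, " and ", b, call. = FALSE)
        }
        fwd <- dplyr::mutate(rev, log2fc = -.data$log2fc)
      }
      tibble::tibble(cell_type = a, ocr_id = fwd$ocr_id,
                     log2fc = fwd$log2fc, fdr = fwd$fdr)
    })
  })
  panel <- dplyr::filter(
    dplyr::summarise(
      dplyr::group_by(oriented, .data$cell_type, .data$ocr_id),
      n_pass = sum(.data$fdr < !!fdr & .data$log2fc > !!min_log2fc),
      n_pairs = dplyr::n(),
      min_pair_log2fc = min(.data$log2fc),
      max_pair_fdr = max(.data$fdr),
      .groups = "drop"
    ),
    .data$n_pass == .data$n_pairs
  )[, c("cell_type", "ocr_id", "min_pair_log2fc", "max_pair_fdr")]
  empty <- setdiff(cells, unique(panel$cell_type))
  if (length(empty) > 0) {
    stop("no marker OCRs for: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  attr(panel, "fdr") <- fdr
  attr(panel, "min_log2fc") <- min_log2fc
  class(panel) <- c("ocr_marker_panel", class(panel))
  panel
}

# Simplex mixing estimate via nonnegative least squares with a profiled-out
# overall scale: min over beta >= 0 of ||y - R beta||^2, theta = beta /
# sum(beta). Profiling the scale makes the estimate invariant to the overall
# scale of both the bulk CPM vector and the reference matrix, so unit
# mismatches between the two cannot bias the proportions.
solve_mixing <- function(R, y) {
  k <- ncol(R)
  # rescale for numerical stability; the minimizer is unchanged
  s <- sqrt(mean(R^2))
  Rs <- R / s
  dmat <- crossprod(Rs)
  dmat <- dmat + diag(k) * (mean(diag(dmat)) * 1e-8)
  sol <- quadprog::solve.QP(Dmat = dmat, dvec = crossprod(Rs, y / s),
                            Amat = diag(k), bvec = rep(0, k))
  beta <- pmax(sol$solution, 0)
  if (sum(beta) == 0) beta <- rep(1, k)
  theta <- beta / sum(beta)
  fitted <- (Rs %*% beta) * s
  list(theta = theta, residual_norm = sqrt(sum((y - fitted)^2)))
}

#' Estimate cell-type proportions in bulk samples
#'
#' Linear mixing model on linear-scale CPM over the marker OCRs: for each
#' bulk sample, solves `min || y - R theta ||^2` subject to `theta >= 0`,
#' `sum(theta) = 1`, where `y` is the sample's marker-OCR CPM vector and `R`
#' the reference profile matrix (mean linear-scale marker accessibility per
#' cell type). Estimates are invariant to rescaling a sample's counts.
#'
#' @param bulk_counts OCR x sample count matrix containing all marker OCRs.
#' @param reference Marker-OCR x cell-type matrix of linear-scale reference
#'   accessibility (rownames = OCR ids), or a tibble with `ocr_id` plus one
#'   column per cell type.
#' @param panel Optional `ocr_marker_panel`; defaults to all reference rows.
#' @return An `ocr_mixing` tibble: `sample_id`, one proportion column per
#'   cell type (rows sum to 1), `residual_norm`.
#' @export
estimate_proportions <- function(bulk_counts, reference, panel = NULL) {
  if (is.data.frame(reference)) {
    ref <- as.matrix(reference[, setdiff(names(reference), "ocr_id")])
    rownames(ref) <- reference$ocr_id
  } else {
    ref <- reference
  }
  markers <- if (!is.null(panel)) {
    intersect(panel$ocr_id, rownames(ref))
  } else {
    rownames(ref)
  }
  missing <- setdiff(markers, rownames(bulk_counts))
  if (length(missing) > 0) {
    stop(length(missing), " marker OCRs absent from bulk counts",
         call. = FALSE)
  }
  R <- ref[markers, , drop = FALSE]
  if (qr(R)$rank < ncol(R)) {
    stop("reference profile matrix is rank deficient", call. = FALSE)
  }
  cpm <- sweep(bulk_counts, 2, colSums(bulk_counts), "/") * 1e6
  y <- cpm[markers, , drop = FALSE]
  fits <- lapply(seq_len(ncol(y)), function(s) solve_mixing(R, y[, s]))
  props <- do.call(rbind, lapply(fits, `[[`, "theta"))
  colnames(props) <- colnames(R)
  out <- tibble::as_tibble(props)
  out <- tibble::add_column(
    out,
    sample_id = colnames(bulk_counts) %||% as.character(seq_len(ncol(y))),
    .before = 1)
  out$residual_norm <- vapply(fits, `[[`, numeric(1), "residual_norm")
  class(out) <- c("ocr_mixing", class(out))
  out
}

#' @export
glance.ocr_mixing <- function(x, ...) {
  cells <- setdiff(names(x), c("sample_id", "residual_norm"))
  tibble::tibble(
    n_samples = nrow(x),
    n_cell_types = length(cells),
    mean_residual_norm = mean(x$residual_norm)
  )
}

#' Case-control differential accessibility with and without cell composition
#'
#' Reruns the diagnosis contrast twice on bulk counts: once with the base
#' model only, and once adding the composition covariates that pass net-BIC
#' forward selection among the estimated cell-type proportions (one
#' proportion column is implicitly redundant given the intercept; singular
#' candidates are skipped with a warning). pi1 of the diagnosis p-values
#' quantifies the detectable case-control signal in each model; pi1 is also
#' reported restricted to each cell type's specificity-set OCRs (on the
#' composition-adjusted model).
#'
#' @param bulk_counts OCR x sample count matrix.
#' @param metadata Bulk metadata tibble with a 2-level `diagnosis` column and
#'   any base covariates.
#' @param proportions `ocr_mixing` tibble aligned to the samples.
#' @param specificity_sets Optional `ocr_specificity` tibble; adds
#'   cell-restricted pi1 rows.
#' @param base_covariates Metadata columns always in the model (default
#'   intersects `c("sex", "gc")` with the metadata).
#' @param norm_factors Normalization factors for the bulk matrix; the default
#'   computes whole-matrix TMM factors with [tmm_factors()] so compositional
#'   shifts (strong disease or composition effects changing the read share of
#'   other OCRs at fixed depth) do not masquerade as differential signal.
#' @param net_threshold,bic_delta Net-BIC selection parameters.
#' @param pi1_method pi0 estimator (default `"smoother"`).
#' @return An `ocr_casecontrol` tibble: `scenario`, `pi1`, `pi0`, `n_tests`;
#'   the selected composition covariates are kept in the
#'   `"composition_covariates"` attribute.
#' @export
casecontrol_workflow <- function(bulk_counts, metadata, proportions,
                                 specificity_sets = NULL,
                                 base_covariates = intersect(
                                   c("sex", "gc"), names(metadata)),
                                 norm_factors = tmm_factors(bulk_counts),
                                 net_threshold = 0.05, bic_delta = 2,
                                 pi1_method = "smoother") {
  stopifnot("diagnosis" %in% names(metadata),
            ncol(bulk_counts) == nrow(metadata))
  if (length(unique(metadata$diagnosis)) != 2) {
    stop("diagnosis must have exactly 2 levels", call. = FALSE)
  }
  cells <- setdiff(names(proportions), c("sample_id", "residual_norm"))
  prop_cols <- paste0("prop_", cells)
  pcols <- proportions[, cells]
  names(pcols) <- prop_cols
  md <- dplyr::bind_cols(metadata, pcols)

  base_rhs <- paste(c("diagnosis", base_covariates), collapse = " + ")
  base_formula <- stats::as.formula(paste("~", base_rhs))

  diagnosis_pvalues <- function(extra_cols) {
    rhs <- paste(c("diagnosis", base_covariates, extra_cols), collapse = " + ")
    design <- stats::model.matrix(stats::as.formula(paste("~", rhs)),
                                  as.data.frame(md))
    keep_col <- qr(design)$rank
    if (keep_col < ncol(design)) {
      warning("composition covariate collinear with the design; dropped",
              call. = FALSE)
      qrd <- qr(design)
      design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    }
    v <- voom_weights(bulk_counts, design, norm_factors = norm_factors)
    fit <- limma::eBayes(limma::lmFit(v$logcpm, design, weights = v$weights))
    dcol <- grep("^diagnosis", colnames(design))[1]
    fit$p.value[, dcol]
  }

  # model without composition
  p_base <- diagnosis_pvalues(character())
  # select composition covariates by net BIC on the base-model log-CPM
  lc <- log_cpm(bulk_counts, norm_factors)
  sel <- bic_forward_select(lc$logcpm, md, base_formula, prop_cols,
                            net_threshold = net_threshold,
                            bic_delta = bic_delta, test_squares = FALSE)
  p_comp <- diagnosis_pvalues(sel$selected)

  pi1_row <- function(p, scenario) {
    est <- suppressWarnings(
      estimate_pi0(pmax(p, .Machine$double.xmin), method = pi1_method))
    tibble::tibble(scenario = scenario, pi1 = est$pi1, pi0 = est$pi0,
                   n_tests = est$n_tests)
  }
  out <- dplyr::bind_rows(
    pi1_row(p_base, "no_composition"),
    pi1_row(p_comp, "with_composition")
  )
  if (!is.null(specificity_sets) && nrow(specificity_sets) > 0) {
    ids <- rownames(bulk_counts)
    for (set in sort(unique(specificity_sets$set))) {
      sub <- intersect(specificity_sets$ocr_id[specificity_sets$set == set],
                       ids)
      if (length(sub) == 0) next
      out <- dplyr::bind_rows(
        out, pi1_row(p_comp[match(sub, ids)], paste0(set, "_specific")))
    }
  }
  attr(out, "composition_covariates") <- sel$selected
  attr(out, "selection_rounds") <- sel$rounds
  class(out) <- c("ocr_casecontrol", class(out))
  out
}
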