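# Covariate preparation, PCA candidate screening, net-BIC forward selection
# and per-OCR variance decomposition.

#' Center QC metrics on the per-cell-type median
#'
#' Technical metrics (FRiP, PBC, insert metrics, ...) can sit on different
#' scales in different cell types; each metric is normalized to the median of
#' its cell type. The default `ratio` mode divides by the group median (all
#' the usual metrics are positive ratios); `offset` mode subtracts it.
#'
#' @param metadata Sample metadata tibble.
#' @param metric_names Character vector of numeric metadata columns.
#' @param group_by Grouping column (default `"cell_type"`).
#' @param mode `"ratio"` (divide) or `"offset"` (subtract).
#' @return `metadata` with the named columns replaced by adjusted values.
#' @export
center_metrics <- function(metadata, metric_names, group_by = "cell_type",
                           mode = c("ratio", "offset")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(metadata), group_by %in% names(metadata),
            all(metric_names %in% names(metadata)))
  if (mode == "ratio") {
    bad <- metric_names[vapply(metric_names,
                               function(m) any(metadata[[m]] <= 0), logical(1))]
    if (length(bad) > 0) {
      stop("nonpositive values in ", paste(bad, collapse = ", "),
           "; use mode = \"offset\"", call. = FALSE)
    }
  }
  dplyr::mutate(
    dplyr::group_by(metadata, dplyr::across(dplyr::all_of(group_by))),
    dplyr::across(dplyr::all_of(metric_names), function(v) {
      if (mode == "ratio") v / stats::median(v) else v - stats::median(v)
    })
  ) |> dplyr::ungroup()
}

#' Screen candidate covariates against high-variance principal components
#'
#' Runs a PCA on the normalized accessibility matrix separately within each
#' cell type (a pooled PCA mostly recovers the cell-type differences), keeps
#' components explaining more than `var_threshold` of the variance, Pearson-
#' correlates every candidate with every kept component, and applies
#' Benjamini-Hochberg across all (candidate, PC, cell type) tests. A candidate
#' passes the screen if any adjusted p-value is at or below `fdr`.
#'
#' @param logcpm OCR x sample matrix (or an `ocr_norm` object).
#' @param metadata Sample metadata tibble aligned to the columns of `logcpm`;
#'   must contain the `group_by` column and all candidate columns.
#' @param candidates Character vector of numeric metadata columns to screen.
#' @param var_threshold Minimum explained-variance fraction for a PC to be
#'   tested (default 0.01).
#' @param fdr BH threshold for candidate selection (default 0.2, deliberately
#'   lenient: this is a screen, not the final selection).
#' @param group_by Cell-type column (default `"cell_type"`).
#' @return List with `selected` (character vector) and `tests` (tibble of all
#'   correlation tests with adjusted p-values).
#' @export
pca_screen <- function(logcpm, metadata, candidates, var_threshold = 0.01,
                       fdr = 0.2, group_by = "cell_type") {
  if (inherits(logcpm, "ocr_norm")) logcpm <- logcpm$logcpm
  stopifnot(is.matrix(logcpm), ncol(logcpm) == nrow(metadata),
            all(candidates %in% names(metadata)))
  groups <- unique(metadata[[group_by]])
  tests <- purrr::map_dfr(groups, function(g) {
    idx <- which(metadata[[group_by]] == g)
    if (length(idx) < 3) {
      warning("PCA screen skipped for group '", g, "' (< 3 samples)",
              call. = FALSE)
      return(NULL)
    }
    pc <- stats::prcomp(t(logcpm[, idx, drop = FALSE]), center = TRUE)
    varexp <- pc$sdev^2 / sum(pc$sdev^2)
    keep_pc <- which(varexp > var_threshold)
    purrr::map_dfr(keep_pc, function(k) {
      purrr::map_dfr(candidates, function(cand) {
        v <- metadata[[cand]][idx]
        if (stats::sd(v) == 0) return(NULL)
        ct <- stats::cor.test(v, pc$x[, k], method = "pearson")
        tibble::tibble(group = as.character(g), pc = k,
                       var_explained = varexp[k], candidate = cand,
                       cor = unname(ct$estimate), p = ct$p.value)
      })
    })
  })
  if (nrow(tests) == 0) {
    return(list(selected = character(), tests = tests))
  }
  tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  sel <- sort(unique(tests$candidate[tests$p_adj <= fdr]))
  list(selected = sel, tests = tests)
}

# Per-OCR residual sums of squares for a fixed design (unweighted fast path
# via one QR; weighted path loops per OCR because the design scaling differs).
rss_per_ocr <- function(y, design, weights = NULL) {
  qx <- qr(design)
  if (qx$rank < ncol(design)) return(NULL)  # singular design
  if (is.null(weights)) {
    res <- t(qr.resid(qx, t(y)))
    rowSums(res^2)
  } else {
    vapply(seq_len(nrow(y)), function(i) {
      w <- weights[i, ]
      fit <- stats::lm.wfit(design, y[i, ], w)
      sum(w * fit$residuals^2)
    }, numeric(1))
  }
}

#' Net-BIC forward selection of covariates
#'
#' For each candidate covariate, per-OCR linear models are fitted with and
#' without the candidate on top of the current base model. An OCR counts as
#' improved (worse) when its BIC decreases (increases) by at least
#' `bic_delta` - 2 being the conventional lower boundary of positive
#' evidence. The candidate's net share is (improved - worse) / n_OCRs; the
#' candidate with the largest net share at or above `net_threshold` is added,
#' and the remaining candidates are re-tested against the grown model until
#' none qualifies. Squared terms of selected numeric covariates are then
#' tested the same way. Ties in net share are broken lexicographically by
#' candidate name.
#'
#' @param logcpm OCR x sample matrix (or `ocr_norm` object).
#' @param metadata Sample metadata tibble with the base-model and candidate
#'   columns.
#' @param base Base-model formula on `metadata`, e.g.
#'   `~ cell_type:region + sex`.
#' @param candidates Character vector of candidate metadata columns (numeric
#'   or factor).
#' @param weights Optional OCR x sample precision-weight matrix.
#' @param net_threshold Minimum net share for inclusion (default 0.05).
#' @param bic_delta BIC change counted as evidence (default 2).
#' @param test_squares Also test squared terms of selected numeric
#'   covariates (default TRUE).
#' @return List with `selected` (ordered character vector; squared terms are
#'   reported as `"<name>^2"`), `rounds` (tibble of per-candidate net shares
#'   per selection round) and `design` (the final model matrix).
#' @export
bic_forward_select <- function(logcpm, metadata, base, candidates,
                               weights = NULL, net_threshold = 0.05,
                               bic_delta = 2, test_squares = TRUE) {
  if (inherits(logcpm, "ocr_norm")) logcpm <- logcpm$logcpm
  stopifnot(is.matrix(logcpm), ncol(logcpm) == nrow(metadata))
  n <- ncol(logcpm)
  n_ocr <- nrow(logcpm)
  md <- as.data.frame(metadata)

  candidate_design <- function(cand) {
    if (grepl("\\^2$", cand)) {
      v <- md[[sub("\\^2$", "", cand)]]
      mm <- matrix(v^2, ncol = 1, dimnames = list(NULL, cand))
    } else if (is.numeric(md[[cand]])) {
      mm <- matrix(md[[cand]], ncol = 1, dimnames = list(NULL, cand))
    } else {
      mm <- stats::model.matrix(stats::as.formula(paste("~", cand)), md)
      mm <- mm[, -1, drop = FALSE]
    }
    mm
  }

  design0 <- stats::model.matrix(base, md)
  if (n <= ncol(design0)) stop("base model not estimable", call. = FALSE)
  rss0 <- rss_per_ocr(logcpm, design0, weights)
  if (is.null(rss0)) stop("base design is singular", call. = FALSE)
  k0 <- ncol(design0)

  remaining <- sort(candidates)
  selected <- character()
  rounds <- list()
  round_no <- 0L
  stage <- "linear"
  repeat {
    if (length(remaining) == 0) break
    round_no <- round_no + 1L
    shares <- purrr::map_dfr(remaining, function(cand) {
      x1 <- cbind(design0, candidate_design(cand))
      rss1 <- rss_per_ocr(logcpm, x1, weights)
      if (is.null(rss1)) {
        warning("candidate '", cand, "' gives a singular design; skipped",
                call. = FALSE)
        return(tibble::tibble(round = round_no, candidate = cand,
                              net_share = NA_real_, improved = NA_integer_,
                              worse = NA_integer_))
      }
      dk <- ncol(x1) - k0
      # delta BIC (with candidate minus without); weight terms cancel
      dbic <- n * log(rss1 / rss0) + dk * log(n)
      improved <- sum(dbic <= -bic_delta)
      worse <- sum(dbic >= bic_delta)
      tibble::tibble(round = round_no, candidate = cand,
                     net_share = (improved - worse) / n_ocr,
                     improved = improved, worse = worse)
    })
    rounds[[round_no]] <- shares
    ok <- shares[!is.na(shares$net_share) &
                   shares$net_share >= net_threshold, ]
    if (nrow(ok) == 0) {
      if (stage == "linear" && test_squares) {
        sq <- selected[!grepl("\\^2$", selected)]
        sq <- sq[vapply(sq, function(s) is.numeric(md[[s]]), logical(1))]
        sq <- paste0(sq, "^2")
        if (length(sq) > 0) {
          stage <- "squares"
          remaining <- sq
          next
        }
      }
      break
    }
    best <- ok$candidate[order(-ok$net_share, ok$candidate)][1]
    selected <- c(selected, best)
    design0 <- cbind(design0, candidate_design(best))
    rss0 <- rss_per_ocr(logcpm, design0, weights)
    k0 <- ncol(design0)
    remaining <- setdiff(remaining, best)
    if (length(remaining) == 0) {
      if (stage == "linear" && test_squares) {
        sq <- selected[!grepl("\\^2$", selected)]
        sq <- sq[vapply(sq, function(s) is.numeric(md[[s]]), logical(1))]
        if (length(sq) > 0) {
          stage <- "squares"
          remaining <- paste0(sq, "^2")
          next
        }
      }
      break
    }
  }
  list(selected = selected, rounds = dplyr::bind_rows(rounds),
       design = design0)
}

#' Degrees of freedom of a joint accessibility model
#'
#' A model with a cell-type-by-region group factor fitted on means
#' parameterization, plus extra factors and numeric covariates, spends
#' `n_groups + sum(levels - 1) + n_numeric` degrees of freedom on the mean
#' structure. The study design (4 cell types x 3 regions, sex, one numeric
#' QC covariate) spends 12 + 1 + 1 = 14.
#'
#' @param n_cell_types,n_regions Group factor dimensions.
#' @param extra_factor_levels Integer vector of level counts for additional
#'   factors (default `c(sex = 2)`).
#' @param n_numeric Number of numeric covariates (default 1).
#' @return Total model degrees of freedom (integer).
#' @export
model_df <- function(n_cell_types = 4, n_regions = 3,
                     extra_factor_levels = c(sex = 2), n_numeric = 1) {
  as.integer(n_cell_types * n_regions + sum(extra_factor_levels - 1) +
               n_numeric)
}

#' Per-OCR variance decomposition across covariates
#'
#' Decomposes each OCR's accessibility variance into fractions attributable
#' to each covariate plus a residual, using a sequential (type-I) ANOVA
#' decomposition in the order the covariates are given. Sequential sums of
#' squares partition the total exactly, so fractions plus residual sum to 1
#' for every OCR; on balanced designs (like the full cell-by-region layout)
#' the decomposition does not depend on the order.
#'
#' @param logcpm OCR x sample matrix (or `ocr_norm` object).
#' @param metadata Sample metadata tibble.
#' @param covariates Character vector of metadata columns, in decomposition
#'   order.
#' @return An `ocr_varfrac` tibble: one row per OCR with one fraction column
#'   per covariate plus `residual`.
#' @export
variance_fractions <- function(logcpm, metadata, covariates) {
  if (inherits(logcpm, "ocr_norm")) logcpm <- logcpm$logcpm
  stopifnot(is.matrix(logcpm), ncol(logcpm) == nrow(metadata),
            all(covariates %in% names(metadata)))
  md <- as.data.frame(metadata)
  n <- ncol(logcpm)
  designs <- list(matrix(1, n, 1))
  for (k in seq_along(covariates)) {
    f <- stats::as.formula(paste("~", paste(covariates[seq_len(k)],
                                            collapse = " + ")))
    designs[[k + 1]] <- stats::model.matrix(f, md)
  }
  ranks <- vapply(designs, function(x) qr(x)$rank, integer(1))
  if (any(diff(ranks) == 0)) {
    j <- which(diff(ranks) == 0)[1]
    stop(sprintf("covariate '%s' is collinear with '%s'",
                 covariates[j],
                 paste(c("(intercept)", covariates)[seq_len(j)], collapse = " + ")),
         call. = FALSE)
  }
  rss <- do.call(cbind, lapply(designs, function(x) rss_per_ocr(logcpm, x)))
  tss <- rss[, 1]
  tss[tss == 0] <- NA_real_
  frac <- -t(apply(rss, 1, diff)) / tss
  if (length(covariates) == 1) frac <- matrix(frac, ncol = 1)
  colnames(frac) <- covariates
  out <- tibble::as_tibble(frac)
  out$residual <- rss[, ncol(rss)] / tss
  out <- tibble::add_column(out,
                            ocr_id = rownames(logcpm) %||%
                              as.character(seq_len(nrow(logcpm))),
                            .before = 1)
  class(out) <- c("ocr_varfrac", class(out))
  out
}

#' @export
glance.ocr_varfrac <- function(x, ...) {
  num <- setdiff(names(x), "ocr_id")
  tibble::as_tibble(lapply(x[num], stats::median, na.rm = TRUE))
}
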