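# Proportion of non-null tests (pi1 = 1 - pi0) and the pairwise
# group-difference matrix used to quantify how different two sample groups
# are in chromatin accessibility.

#' Estimate the proportion of true null hypotheses (pi0) and pi1
#'
#' Default method is the lambda-grid smoother: `pi0(lambda) =
#' #\{p > lambda\} / ((1 - lambda) n)` is computed on a grid, smoothed with a
#' cubic smoothing spline, evaluated at the largest lambda and clamped to
#' `[0, 1]`. The convex-decreasing density estimator from limma is available
#' as `method = "convest"` (the two agree on calibrated inputs; neither is a
#' value the pipeline tunes).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param method `"smoother"` (default) or `"convest"`.
#' @param lambda Grid for the smoother (default `seq(0.05, 0.95, 0.05)`).
#' @return An `ocr_pi1` tibble with columns `pi0`, `pi1`, `n_tests`,
#'   `method` (`pi1 = 1 - pi0` exactly).
#' @export
estimate_pi0 <- function(pvalues, method = c("smoother", "convest"),
                         lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  n <- length(pvalues)
  if (n < 100) {
    warning("pi0 estimation is unreliable below 100 p-values", call. = FALSE)
  }
  if (method == "smoother") {
    pi0_l <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l),
                    numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  } else {
    pi0 <- limma::convest(pvalues)
  }
  pi0 <- min(max(pi0, 0), 1)
  out <- tibble::tibble(pi0 = pi0, pi1 = 1 - pi0, n_tests = n,
                        method = method)
  class(out) <- c("ocr_pi1", class(out))
  out
}

# Classify a group pair for the pi1 aggregations (cell labels as CELL_REGION).
classify_pair <- function(a, b, neuronal = c("GLU", "GABA"),
                          non_neuronal = c("OLIG", "MGAS")) {
  ca <- sub("_.*$", "", a); cb <- sub("_.*$", "", b)
  if (ca == cb) return(paste0("within_", ca))
  na_ <- ca %in% neuronal; nb <- cb %in% neuronal
  if (na_ != nb) return("neuronal_vs_non_neuronal")
  if (na_ && nb) return("between_neuronal")
  "between_non_neuronal"
}

#' pi1 for every pairwise group comparison
#'
#' Runs the differential contrast for each unordered pair of cell-type-by-
#' region groups (12 groups give 66 comparisons) and estimates pi1 from each
#' contrast's p-values. Pairs are also classified (within cell type /
#' neuronal vs non-neuronal / ...) so the category aggregations can be read
#' off directly.
#'
#' @param v `ocr_voom` object from [voom_weights()].
#' @param groups Group design-column names; defaults to all columns of the
#'   design that look like `CELL_REGION` (i.e. all non-covariate columns).
#' @param method pi0 estimator passed to [estimate_pi0()].
#' @return An `ocr_pi1_matrix` tibble: `group_a`, `group_b`, `category`,
#'   `pi1`, `pi0`, `n_tests`. Use [pi1_matrix()] for the symmetric matrix and
#'   `glance()` for per-category medians.
#' @export
pairwise_pi1 <- function(v, groups = NULL, method = "smoother") {
  stopifnot(inherits(v, "ocr_voom"))
  design <- v$design
  groups <- groups %||% grep("^[A-Za-z0-9]+_[A-Za-z0-9]+$",
                             colnames(design), value = TRUE)
  missing <- setdiff(groups, colnames(design))
  if (length(missing) > 0) {
    stop("groups absent from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  exprs <- vapply(pairs, function(p) paste(p[1], "-", p[2]), character(1))
  names(exprs) <- vapply(pairs, function(p) paste(p, collapse = "|"),
                         character(1))
  fit <- fit_contrasts(v, exprs)
  res <- tidy(fit)
  out <- purrr::map_dfr(names(exprs), function(nm) {
    p <- res$p[res$contrast == nm]
    est <- suppressWarnings(estimate_pi0(pmax(p, .Machine$double.xmin),
                                         method = method))
    ab <- strsplit(nm, "|", fixed = TRUE)[[1]]
    tibble::tibble(group_a = ab[1], group_b = ab[2],
                   category = classify_pair(ab[1], ab[2]),
                   pi1 = est$pi1, pi0 = est$pi0, n_tests = est$n_tests)
  })
  attr(out, "groups") <- groups
  class(out) <- c("ocr_pi1_matrix", class(out))
  out
}

#' Symmetric pi1 matrix from pairwise results
#'
#' @param x An `ocr_pi1_matrix` tibble from [pairwise_pi1()].
#' @return Symmetric numeric matrix (diagonal `NA`).
#' @export
pi1_matrix <- function(x) {
  groups <- attr(x, "groups") %||% unique(c(x$group_a, x$group_b))
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_len(nrow(x))) {
    m[x$group_a[i], x$group_b[i]] <- x$pi1[i]
    m[x$group_b[i], x$group_a[i]] <- x$pi1[i]
  }
  m
}

#' @export
glance.ocr_pi1_matrix <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$category),
    n_comparisons = dplyr::n(),
    median_pi1 = stats::median(.data$pi1),
    .groups = "drop"
  )
}
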