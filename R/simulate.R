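# Synthetic data with the statistical structure the pipeline assumes:
# negative-binomial counts over a 4-cell-type x 3-brain-region design with
# planted cell/region/sex effects, a FRiP-like signal-allocation covariate,
# bulk mixtures with known proportions, footprint sites with binding
# probabilities, and calibrated p-value mixtures. Every planted parameter is
# recorded in a truth object so downstream recovery is checkable without
# hidden state.

#' Configuration for the sorted-cell experiment simulator
#'
#' Defaults mirror the sorted-nuclei study layout: four cell types by three
#' cortical regions with a handful of subjects each, overdispersed counts,
#' and a FRiP range wide enough to act as a visible signal-to-noise covariate.
#'
#' @param n_ocrs Number of OCRs.
#' @param n_samples_per_group Subjects per cell-by-region group (each subject
#'   contributes one sample per group).
#' @param cell_types,regions Factor labels.
#' @param frac_promoter Fraction of OCRs overlapping a protein-coding TSS.
#' @param frac_background Fraction of OCRs acting as background (noise) peaks
#'   whose reads scale with 1 - FRiP rather than FRiP.
#' @param n_specific_per_cell Planted cell-specific OCRs per cell type.
#' @param n_region_specific Planted region-specific OCRs per (cell, region).
#' @param effect_log2fc Planted log2 fold change for cell/region effects.
#' @param sex_effect_log2fc Planted log2 fold change on the sex-chromosome
#'   OCRs.
#' @param n_sex_ocrs Number of sex-chromosome OCRs.
#' @param nb_dispersion Negative-binomial dispersion (shared across OCRs).
#' @param library_size_range Range of per-sample library sizes.
#' @param frip_range Range of per-sample FRiP values.
#' @param seed RNG seed.
#' @return A `sim_config` list, validated.
#' @export
simulation_config <- function(n_ocrs = 2000,
                              n_samples_per_group = 4,
                              cell_types = c("GLU", "GABA", "OLIG", "MGAS"),
                              regions = c("ACC", "DLPFC", "PVC"),
                              frac_promoter = 0.3,
                              frac_background = 0.25,
                              n_specific_per_cell = 50,
                              n_region_specific = 10,
                              effect_log2fc = 2,
                              sex_effect_log2fc = 2,
                              n_sex_ocrs = 10,
                              nb_dispersion = 0.05,
                              library_size_range = c(5e5, 1.5e6),
                              frip_range = c(0.2, 0.6),
                              seed = 1) {
  cfg <- list(n_ocrs = n_ocrs, n_samples_per_group = n_samples_per_group,
              cell_types = cell_types, regions = regions,
              frac_promoter = frac_promoter,
              frac_background = frac_background,
              n_specific_per_cell = n_specific_per_cell,
              n_region_specific = n_region_specific,
              effect_log2fc = effect_log2fc,
              sex_effect_log2fc = sex_effect_log2fc,
              n_sex_ocrs = n_sex_ocrs, nb_dispersion = nb_dispersion,
              library_size_range = library_size_range,
              frip_range = frip_range, seed = seed)
  with(cfg, {
    if (n_ocrs < 1 || n_samples_per_group < 1 || n_specific_per_cell < 0 ||
        n_region_specific < 0 || n_sex_ocrs < 0) {
      stop("counts must be nonnegative (and sizes positive)", call. = FALSE)
    }
    if (frac_promoter < 0 || frac_promoter > 1 ||
        frac_background < 0 || frac_background > 1) {
      stop("fractions must lie in [0, 1]", call. = FALSE)
    }
    if (!is.finite(effect_log2fc)) stop("effect_log2fc must be finite",
                                        call. = FALSE)
    if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
    if (any(frip_range <= 0) || any(frip_range >= 1) ||
        diff(frip_range) < 0) {
      stop("frip_range must be an increasing pair inside (0, 1)",
           call. = FALSE)
    }
    planted <- frac_promoter * n_ocrs +
      n_specific_per_cell * length(cell_types) +
      n_region_specific * length(cell_types) * length(regions) + n_sex_ocrs
    if (planted > n_ocrs) {
      stop("planted OCR classes exceed n_ocrs", call. = FALSE)
    }
  })
  class(cfg) <- "sim_config"
  cfg
}

# Non-overlapping OCR coordinates with stated widths on the given chromosome
# labels, returned in sorted order.
place_ocrs <- function(chroms, widths, gap_mean = 5000) {
  tabs <- split(seq_along(chroms), chroms)
  out <- vector("list", length(tabs))
  for (k in seq_along(tabs)) {
    idx <- tabs[[k]]
    gaps <- stats::rgeom(length(idx), 1 / gap_mean) + 100L
    starts <- cumsum(gaps + c(0L, widths[idx][-length(idx)]))
    out[[k]] <- tibble::tibble(chrom = names(tabs)[k], start = starts,
                               end = starts + widths[idx], row = idx)
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$row), ]
  res$row <- NULL
  res
}

#' Simulate a sorted-cell ATAC-seq experiment
#'
#' Generates negative-binomial counts whose expected value per OCR and sample
#' is baseline x cell effect x region effect x sex effect x FRiP allocation,
#' rescaled per sample to the drawn library size. The FRiP allocation scales
#' signal OCRs by `frip / mean(frip)` and background OCRs by
#' `(1 - frip) / (1 - mean(frip))`, so FRiP acts as a signal-to-noise
#' covariate. Sex effects sit on a small set of OCRs placed on chrX.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A `ocr_simulation` list: `counts` (OCR x sample), `metadata`
#'   (sample tibble with cell_type, region, sex, person, frip and three
#'   pure-noise QC metrics), `ocrs` (interval tibble with `name` and
#'   `promoter` flag), `genes` (one protein-coding gene per promoter OCR) and
#'   `truth` (planted parameters; see Details).
#'
#' @details `truth` records: `true_specific_ocrs` (per cell type),
#' `true_region_ocrs` (per cell_region), `sex_ocrs`, `background_ocrs`,
#' `true_norm_factors` (expected promoter-anchored scaling per sample,
#' geometric mean 1), `true_pi0` (fraction of OCRs with no planted group
#' effect), `planted_covariate_effects` and `expected_mu` (the full expected
#' count matrix).
#' @export
simulate_sorted_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_ocrs
    cells <- config$cell_types
    regions <- config$regions

    # --- OCR classes ------------------------------------------------------
    n_prom <- round(config$frac_promoter * n)
    ids <- sprintf("OCR_%05d", seq_len(n))
    promoter <- seq_len(n_prom)
    pool <- setdiff(seq_len(n), promoter)
    sex_ocrs <- sort(sample(pool, config$n_sex_ocrs))
    pool <- setdiff(pool, sex_ocrs)
    specific <- stats::setNames(vector("list", length(cells)), cells)
    for (ct in cells) {
      specific[[ct]] <- sort(sample(pool, config$n_specific_per_cell))
      pool <- setdiff(pool, specific[[ct]])
    }
    region_specific <- list()
    for (ct in cells) {
      for (rg in regions) {
        key <- paste(ct, rg, sep = "_")
        region_specific[[key]] <- sort(sample(pool, config$n_region_specific))
        pool <- setdiff(pool, region_specific[[key]])
      }
    }
    n_bg <- round(config$frac_background * n)
    background <- sort(sample(pool, min(n_bg, length(pool))))
    signal <- setdiff(seq_len(n), background)

    # --- coordinates and gene annotation ---------------------------------
    chroms <- rep(paste0("chr", 1:4), length.out = n)
    chroms[sex_ocrs] <- "chrX"
    widths <- as.integer(round(stats::runif(n, 200, 1500)))
    coords <- place_ocrs(chroms, widths)
    ocrs <- tibble::tibble(chrom = coords$chrom, start = coords$start,
                           end = coords$end, name = ids,
                           promoter = seq_len(n) %in% promoter)
    genes <- tibble::tibble(
      gene_id = sprintf("GENE_%05d", seq_along(promoter)),
      gene_name = sprintf("Gene%d", seq_along(promoter)),
      chrom = ocrs$chrom[promoter],
      tss = as.integer(floor((ocrs$start[promoter] + ocrs$end[promoter]) / 2)),
      strand = rep(c("+", "-"), length.out = length(promoter)),
      biotype = "protein_coding"
    )

    # --- samples ----------------------------------------------------------
    grid <- expand.grid(person = seq_len(config$n_samples_per_group),
                        region = regions, cell_type = cells,
                        stringsAsFactors = FALSE)
    ns <- nrow(grid)
    sex_by_person <- rep(c("M", "F"),
                         length.out = config$n_samples_per_group)
    metadata <- tibble::tibble(
      sample_id = sprintf("%s_%s_S%d", grid$cell_type, grid$region,
                          grid$person),
      cell_type = grid$cell_type,
      region = grid$region,
      person = sprintf("P%d", grid$person),
      sex = sex_by_person[grid$person],
      frip = stats::runif(ns, config$frip_range[1], config$frip_range[2]),
      lib_size = round(stats::runif(ns, config$library_size_range[1],
                                    config$library_size_range[2])),
      qc_noise_a = stats::rlnorm(ns, 0, 0.3),
      qc_noise_b = stats::rlnorm(ns, 2, 0.5),
      qc_noise_c = stats::runif(ns)
    )

    # --- expected counts --------------------------------------------------
    baseline <- stats::rlnorm(n, meanlog = 3, sdlog = 1)
    baseline[promoter] <- stats::rlnorm(length(promoter), meanlog = 4.5,
                                        sdlog = 0.8)
    eff <- matrix(1, n, ns)  # planted group effects
    for (ct in cells) {
      eff[specific[[ct]], metadata$cell_type == ct] <- 2^config$effect_log2fc
    }
    for (key in names(region_specific)) {
      parts <- strsplit(key, "_")[[1]]
      sel <- metadata$cell_type == parts[1] & metadata$region == parts[2]
      eff[region_specific[[key]], sel] <- 2^config$effect_log2fc
    }
    sex_eff <- matrix(1, n, ns)
    sex_eff[sex_ocrs, metadata$sex == "F"] <- 2^config$sex_effect_log2fc
    mean_frip <- mean(metadata$frip)
    alloc <- matrix(rep(metadata$frip / mean_frip, each = n), n, ns)
    alloc[background, ] <- matrix(
      rep((1 - metadata$frip) / (1 - mean_frip), each = length(background)),
      length(background), ns)
    w <- baseline * eff * sex_eff * alloc
    mu <- sweep(w, 2, metadata$lib_size / colSums(w), "*")
    counts <- matrix(
      stats::rnbinom(n * ns, mu = mu, size = 1 / config$nb_dispersion),
      n, ns, dimnames = list(ids, metadata$sample_id))
    dimnames(mu) <- dimnames(counts)

    # expected promoter-anchored scaling: promoters are signal OCRs, so a
    # sample's promoter counts scale with frip_alloc * lib / sum(w)
    tnf <- (metadata$frip / mean_frip) * metadata$lib_size / colSums(w)
    tnf <- tnf / exp(mean(log(tnf)))

    planted_any <- unique(c(unlist(specific), unlist(region_specific),
                            sex_ocrs))
    truth <- list(
      true_specific_ocrs = lapply(specific, function(i) ids[i]),
      true_region_ocrs = lapply(region_specific, function(i) ids[i]),
      sex_ocrs = ids[sex_ocrs],
      background_ocrs = ids[background],
      signal_ocrs = ids[signal],
      true_norm_factors = stats::setNames(tnf, metadata$sample_id),
      true_pi0 = 1 - length(planted_any) / n,
      planted_covariate_effects = list(
        frip = tibble::tibble(
          ocr_id = ids,
          class = ifelse(seq_len(n) %in% background, "background", "signal")),
        sex = tibble::tibble(ocr_id = ids[sex_ocrs],
                             log2fc = config$sex_effect_log2fc)
      ),
      expected_mu = mu,
      effect_log2fc = config$effect_log2fc
    )
    structure(list(counts = counts, metadata = metadata, ocrs = ocrs,
                   genes = genes, truth = truth, config = config),
              class = "ocr_simulation")
  })
}

#' @export
print.ocr_simulation <- function(x, ...) {
  cat(sprintf("<ocr_simulation> %d OCRs x %d samples (%s x %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$config$cell_types, collapse = "/"),
              paste(x$config$regions, collapse = "/")))
  invisible(x)
}

#' Simulate bulk mixtures of cell-type reference profiles
#'
#' Per-sample cell-type proportions are drawn from a Dirichlet distribution
#' and the expected counts are `depth` times the proportion-weighted mixture
#' of the (normalized) reference profiles; a planted case effect multiplies
#' selected OCRs in case samples, and an optional GC-like technical covariate
#' reallocates signal the way FRiP does in the sorted design. Counts are
#' negative binomial.
#'
#' @param reference_means OCR x cell-type matrix of nonnegative reference
#'   accessibility (rownames = OCR ids), or tibble with `ocr_id`.
#' @param n_samples Number of bulk samples (diagnosis alternates
#'   control/case).
#' @param dirichlet_alpha Nonnegative concentration vector, one per cell
#'   type, at least one positive (a degenerate vector gives pure samples).
#' @param case_effect List with `ocr_ids` and `log2fc`; NULL for no effect.
#' @param depth Expected reads per sample (default 1e6).
#' @param nb_dispersion NB dispersion (default 0.05).
#' @param gc_effect Plant a GC-content-like allocation covariate
#'   (default TRUE).
#' @param balance_composition Assign each drawn proportion vector to one
#'   control and one case so composition is exactly balanced across the
#'   diagnosis groups (default FALSE); use for power simulations where chance
#'   composition-diagnosis correlation must not masquerade as disease signal.
#' @param seed RNG seed.
#' @return List of class `ocr_bulk_sim`: `counts`, `metadata` (with
#'   `diagnosis` and `gc`), `truth` (`true_proportions` tibble, case ids,
#'   planted effect, gc classes, `expected_mu`).
#' @export
simulate_bulk_mixtures <- function(reference_means, n_samples,
                                   dirichlet_alpha, case_effect = NULL,
                                   depth = 1e6, nb_dispersion = 0.05,
                                   gc_effect = TRUE,
                                   balance_composition = FALSE, seed = 1) {
  if (is.data.frame(reference_means)) {
    ref <- as.matrix(reference_means[, setdiff(names(reference_means),
                                               "ocr_id")])
    rownames(ref) <- reference_means$ocr_id
  } else {
    ref <- reference_means
  }
  if (any(ref < 0)) stop("reference profiles must be nonnegative",
                         call. = FALSE)
  k <- ncol(ref)
  stopifnot(length(dirichlet_alpha) == k)
  if (any(dirichlet_alpha < 0) || sum(dirichlet_alpha) == 0) {
    stop("dirichlet_alpha must be nonnegative with positive sum",
         call. = FALSE)
  }
  if (!is.null(case_effect)) {
    missing <- setdiff(case_effect$ocr_ids, rownames(ref))
    if (length(missing) > 0) {
      stop("case_effect OCR ids not in the reference profile: ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    }
  }
  with_seed(seed, {
    n_draw <- if (balance_composition) ceiling(n_samples / 2) else n_samples
    gam <- matrix(stats::rgamma(n_draw * k,
                                shape = rep(dirichlet_alpha, each = n_draw),
                                rate = 1), n_draw, k)
    theta <- gam / rowSums(gam)
    if (balance_composition) {
      # each drawn composition goes to one control and one case, so sample
      # composition is independent of diagnosis by construction, not just in
      # distribution
      theta <- theta[rep(seq_len(n_draw), each = 2)[seq_len(n_samples)], ,
                     drop = FALSE]
    }
    colnames(theta) <- colnames(ref)
    diagnosis <- rep(c("control", "case"), length.out = n_samples)
    gc <- stats::runif(n_samples, 0.4, 0.6)
    # column-normalized reference: mixing acts on read proportions
    refn <- sweep(ref, 2, colSums(ref), "/")
    expected <- refn %*% t(theta)  # OCR x sample read proportions
    gc_class <- rep("signal", nrow(ref))
    if (gc_effect) {
      gc_class[sample(nrow(ref), floor(nrow(ref) / 2))] <- "background"
      galloc <- matrix(rep(gc / mean(gc), each = nrow(ref)),
                       nrow(ref), n_samples)
      bg <- gc_class == "background"
      galloc[bg, ] <- matrix(rep((1 - gc) / (1 - mean(gc)), each = sum(bg)),
                             sum(bg), n_samples)
      expected <- expected * galloc
    }
    mu <- sweep(expected, 2, depth / colSums(expected), "*")
    # the case effect multiplies the depth-normalized mixture, so control
    # expected counts are untouched by the planted disease signal
    if (!is.null(case_effect)) {
      rows <- match(case_effect$ocr_ids, rownames(ref))
      mu[rows, diagnosis == "case"] <-
        mu[rows, diagnosis == "case"] * 2^case_effect$log2fc
    }
    sample_ids <- sprintf("BULK_%03d", seq_len(n_samples))
    dimnames(mu) <- list(rownames(ref), sample_ids)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / nb_dispersion),
                     nrow(mu), ncol(mu), dimnames = dimnames(mu))
    metadata <- tibble::tibble(sample_id = sample_ids, diagnosis = diagnosis,
                               gc = gc)
    truth <- list(
      true_proportions = tibble::add_column(tibble::as_tibble(theta),
                                            sample_id = sample_ids,
                                            .before = 1),
      case_effect = case_effect,
      gc_class = tibble::tibble(ocr_id = rownames(ref), class = gc_class),
      expected_mu = mu
    )
    structure(list(counts = counts, metadata = metadata, truth = truth),
              class = "ocr_bulk_sim")
  })
}

#' Simulate footprinted binding sites inside OCRs
#'
#' Places per-motif binding sites uniformly inside randomly chosen OCRs
#' (width-weighted) with binding probabilities uniform on `p_bind_range`.
#' Declared redundant pairs copy a fraction of the first motif's site
#' positions into the second so pruning logic can be exercised.
#'
#' @param ocrs OCR interval tibble.
#' @param motif_spec Tibble `motif_id`, `n_sites`.
#' @param redundant_pairs Optional tibble `motif_a`, `motif_b`, `share`
#'   (fraction of b's sites copied from a; default 0.6 when column absent).
#' @param groups Sample-group labels; sites are generated per group
#'   (default a single `"all"` group).
#' @param site_width Site width in bp (default 15).
#' @param p_bind_range Binding-probability range (default `c(0.5, 1)`).
#' @param seed RNG seed.
#' @return Binding-site tibble: `motif_id`, `chrom`, `start`, `end`,
#'   `p_bind`, `group`.
#' @export
simulate_footprints <- function(ocrs, motif_spec, redundant_pairs = NULL,
                                groups = "all", site_width = 15,
                                p_bind_range = c(0.5, 1), seed = 1) {
  stopifnot(all(c("motif_id", "n_sites") %in% names(motif_spec)),
            all(motif_spec$n_sites >= 0))
  if (nrow(ocrs) == 0 && any(motif_spec$n_sites > 0)) {
    stop("cannot place sites in an empty OCR set", call. = FALSE)
  }
  with_seed(seed, {
    draw_sites <- function(n_sites) {
      if (n_sites == 0) {
        return(tibble::tibble(chrom = character(), start = integer(),
                              end = integer()))
      }
      widths <- ocrs$end - ocrs$start
      rows <- sample(nrow(ocrs), n_sites, replace = TRUE, prob = widths)
      w <- pmin(site_width, widths[rows])
      offset <- floor(stats::runif(n_sites) * (widths[rows] - w + 1))
      tibble::tibble(chrom = ocrs$chrom[rows],
                     start = ocrs$start[rows] + offset,
                     end = ocrs$start[rows] + offset + w)
    }
    copied_from <- list()
    if (!is.null(redundant_pairs) && nrow(redundant_pairs) > 0 &&
        !"share" %in% names(redundant_pairs)) {
      redundant_pairs$share <- 0.6
    }
    out <- purrr::map_dfr(groups, function(g) {
      pos <- list()
      purrr::map_dfr(seq_len(nrow(motif_spec)), function(i) {
        m <- motif_spec$motif_id[i]
        n_sites <- motif_spec$n_sites[i]
        src <- NULL
        if (!is.null(redundant_pairs)) {
          hit <- which(redundant_pairs$motif_b == m)
          if (length(hit) == 1 &&
              !is.null(pos[[redundant_pairs$motif_a[hit]]])) {
            src <- pos[[redundant_pairs$motif_a[hit]]]
            share <- redundant_pairs$share[hit]
          }
        }
        if (!is.null(src)) {
          n_copy <- min(ceiling(share * n_sites), nrow(src))
          copied <- src[sample(nrow(src), n_copy), c("chrom", "start", "end")]
          fresh <- draw_sites(n_sites - n_copy)
          sites <- dplyr::bind_rows(copied, fresh)
        } else {
          sites <- draw_sites(n_sites)
        }
        sites$motif_id <- m
        sites$p_bind <- stats::runif(nrow(sites), p_bind_range[1],
                                     p_bind_range[2])
        sites$group <- g
        pos[[m]] <<- sites
        sites[, c("motif_id", "chrom", "start", "end", "p_bind", "group")]
      })
    })
    dplyr::arrange(out, .data$group, .data$motif_id, .data$chrom, .data$start)
  })
}

#' Simulate a calibrated p-value mixture
#'
#' `round(pi0 * n)` p-values are Uniform(0, 1) (true nulls) and the rest are
#' Beta(`alt_shape`, 1) with `alt_shape < 1` (non-nulls concentrated near 0),
#' shuffled together.
#'
#' @param n Number of p-values.
#' @param pi0 True null fraction in `[0, 1]`.
#' @param alt_shape Beta shape for the alternatives (must be < 1; the default 0.02 concentrates non-null p-values well below the smoother lambda grid, matching the strongly non-null alternatives the calibration contract assumes).
#' @param seed RNG seed.
#' @return Numeric vector of p-values.
#' @export
simulate_pvalues <- function(n, pi0, alt_shape = 0.02, seed = 1) {
  stopifnot(n > 0)
  if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0, 1]", call. = FALSE)
  if (alt_shape >= 1 || alt_shape <= 0) {
    stop("alt_shape must lie in (0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    n0 <- round(pi0 * n)
    p <- c(stats::runif(n0), stats::rbeta(n - n0, alt_shape, 1))
    sample(p)
  })
}

#' Simulate per-cell-type reference accessibility profiles
#'
#' Builds linear-scale reference profiles with the two features real sorted
#' chromatin shows: broad genome-wide differences between cell types
#' (a lognormal per-cell perturbation of a shared baseline) and a set of
#' strong marker OCRs per cell type. The markers and the per-cell effects are
#' returned as truth.
#'
#' @param n_ocrs Number of OCRs.
#' @param cell_types Cell-type labels.
#' @param n_markers_per_cell Strong markers per cell type (the deconvolution
#'   panel).
#' @param marker_log2fc Marker boost over the other cell types (default 2.5).
#' @param n_specific_per_cell Additional cell-specific OCRs per cell type,
#'   distinct from the markers — the analogue of the (much larger, less
#'   stringent) specificity sets a sorted-cell study derives (default 100).
#' @param specific_log2fc Boost of the cell-specific OCRs (default 1.5,
#'   deliberately below a marker-grade fold change).
#' @param profile_sdlog Lognormal sd of the genome-wide per-cell perturbation
#'   (default 0.3, which puts the composition share of per-OCR variance near
#'   the ~10% reported for deconvolution covariates in bulk brain chromatin;
#'   0 gives identical non-marker profiles).
#' @param seed RNG seed.
#' @return List: `profiles` (OCR x cell-type matrix, columns on a common CPM
#'   scale), `markers` and `specific` (tibbles `cell_type`, `ocr_id`).
#' @export
simulate_reference_profiles <- function(n_ocrs = 2000,
                                        cell_types = c("GLU", "GABA",
                                                       "OLIG", "MGAS"),
                                        n_markers_per_cell = 100,
                                        marker_log2fc = 2.5,
                                        n_specific_per_cell = 100,
                                        specific_log2fc = 1.5,
                                        profile_sdlog = 0.3, seed = 1) {
  stopifnot((n_markers_per_cell + n_specific_per_cell) *
              length(cell_types) <= n_ocrs)
  with_seed(seed, {
    ids <- sprintf("OCR_%05d", seq_len(n_ocrs))
    baseline <- stats::rlnorm(n_ocrs, 3, 1)
    prof <- vapply(cell_types, function(ct) {
      baseline * stats::rlnorm(n_ocrs, 0, profile_sdlog)
    }, numeric(n_ocrs))
    pool <- seq_len(n_ocrs)
    boost <- function(n_per_cell, log2fc) {
      purrr::map_dfr(cell_types, function(ct) {
        sel <- sample(pool, n_per_cell)
        pool <<- setdiff(pool, sel)
        prof[sel, ct] <<- prof[sel, ct] * 2^log2fc
        tibble::tibble(cell_type = ct, ocr_id = ids[sel])
      })
    }
    markers <- boost(n_markers_per_cell, marker_log2fc)
    specific <- boost(n_specific_per_cell, specific_log2fc)
    prof <- sweep(prof, 2, 1e6 / colSums(prof), "*")
    rownames(prof) <- ids
    list(profiles = prof, markers = markers, specific = specific)
  })
}
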