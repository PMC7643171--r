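# Brute-force oracles and tiny fixtures shared across tests. The oracles are
# deliberately quadratic / per-base-pair so they stay independent of the
# IRanges-based implementation paths they check.

# per-bp representation of an interval set: set of "chrom:pos" keys
bp_set <- function(x) {
  if (nrow(x) == 0) return(character())
  unlist(lapply(seq_len(nrow(x)), function(i) {
    paste0(x$chrom[i], ":", seq(x$start[i], x$end[i] - 1))
  }))
}

oracle_jaccard <- function(a, b) {
  sa <- unique(bp_set(a)); sb <- unique(bp_set(b))
  u <- union(sa, sb)
  if (length(u) == 0) return(0)
  length(intersect(sa, sb)) / length(u)
}

oracle_overlaps <- function(a, b) {
  # does interval a[i] overlap any interval in b by >= 1 bp?
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  }, logical(1))
}

oracle_count_overlaps <- function(ocrs, frags) {
  vapply(seq_len(nrow(ocrs)), function(i) {
    sum(frags$chrom == ocrs$chrom[i] & frags$start < ocrs$end[i] &
          ocrs$start[i] < frags$end)
  }, integer(1))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 2000,
                             max_width = 120) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE)
  )
}

# Brute-force evaluation of the cell/group specificity equations on a single
# OCR given the 6 oriented significance indicators. `up` is a named logical
# vector with names like "GLU>GABA" for all ordered cell pairs.
oracle_cell_sets <- function(up, cells = c("GLU", "GABA", "OLIG", "MGAS")) {
  member <- character()
  for (a in cells) {
    others <- setdiff(cells, a)
    if (all(vapply(others, function(b) up[[paste0(a, ">", b)]], logical(1)))) {
      member <- c(member, a)
    }
  }
  neuron <- (up[["GLU>OLIG"]] && up[["GLU>MGAS"]]) ||
    (up[["GABA>OLIG"]] && up[["GABA>MGAS"]])
  non_neuron <- (up[["OLIG>GLU"]] && up[["OLIG>GABA"]]) ||
    (up[["MGAS>GLU"]] && up[["MGAS>GABA"]])
  list(cells = member, neuron = neuron, non_neuron = non_neuron)
}

# Small deterministic simulated experiment shared by several tests.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_sorted_experiment(simulation_config(
        n_ocrs = 1200, seed = 101, n_specific_per_cell = 40,
        n_region_specific = 5, n_sex_ocrs = 8))
    }
    cache
  }
})

shared_voom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- shared_sim()
      nf <- promoter_tmm(sim$counts, sim$ocrs$promoter)
      cache <<- voom_weights(sim$counts, build_design(sim$metadata), nf)
    }
    cache
  }
})

shared_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- tidy(fit_contrasts(shared_voom(), cell_pair_contrasts()))
    }
    cache
  }
})
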