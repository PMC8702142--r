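# In-code fixture builders shared across tests.

# minimal panel-shaped data frame; freqs recycled across the five populations
h_panel <- function(chrom, pos_cm, freq = 0.5, category = "kinship",
                    freq_by_pop = NULL, pos_bp = NULL, ids = NULL) {
  n <- max(length(chrom), length(pos_cm))
  chrom <- rep_len(as.character(chrom), n)
  pos_cm <- rep_len(pos_cm, n)
  d <- data.frame(
    snp_id = if (is.null(ids)) sprintf("ts%04d", seq_len(n)) else ids,
    chrom = chrom,
    pos_bp = if (is.null(pos_bp)) as.integer(round(pos_cm * 1e6)) + seq_len(n) else pos_bp,
    pos_cm = pos_cm,
    ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  if (is.null(freq_by_pop)) {
    for (pop in forcekin::FK_POPULATIONS) d[[paste0("freq_", pop)]] <- rep_len(freq, n)
  } else {
    stopifnot(ncol(freq_by_pop) == 5)
    for (i in seq_along(forcekin::FK_POPULATIONS))
      d[[paste0("freq_", forcekin::FK_POPULATIONS[i])]] <- freq_by_pop[, i]
  }
  d$category <- rep_len(category, n)
  d$n_baits <- 4L
  d
}

# marker table (chrom / pos_cm / freq) straight from a panel
h_markers <- function(panel, pop = "EUR") {
  data.frame(chrom = panel$chrom, pos_cm = panel$pos_cm,
             freq = panel[[paste0("freq_", pop)]])
}

# small shared fixture panel (~10% scale), built once per test run
h_fixture_panel <- local({
  pan <- NULL
  function() {
    if (is.null(pan)) pan <<- forcekin::synthetic_panel(
      n_kinship = 400, n_ii = 40, n_ai = 40, n_pi = 20, n_x = 30, n_y = 60,
      seed = 20260901)
    pan
  }
})

# full-scale panel for the acceptance-grade simulations
h_full_panel <- local({
  pan <- NULL
  function() {
    if (is.null(pan)) pan <<- forcekin::synthetic_panel(seed = 20260902)
    pan
  }
})
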