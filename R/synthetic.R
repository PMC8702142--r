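#' Synthetic genome-wide genetic map
#'
#' A deterministic map with 22 autosomes plus X, with chromosome lengths
#' approximating the human sex-averaged genetic map (about 3500 cM of autosome)
#' and a uniform 1 cM per Mb relation between physical and genetic position.
#' Anchors are placed every `anchor_cm` centimorgans.
#'
#' @param anchor_cm anchor spacing in cM.
#' @return an `fk_genetic_map` data frame (`chrom`, `pos_bp`, `pos_cm`).
#' @export
synthetic_genetic_map <- function(anchor_cm = 10) {
  len <- .fk_chrom_lengths_cm()
  out <- do.call(rbind, lapply(names(len), function(ch) {
    cm <- unique(c(seq(0, len[[ch]], by = anchor_cm), len[[ch]]))
    data.frame(chrom = ch, pos_bp = as.integer(round(cm * 1e6)) + 1L, pos_cm = cm,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("fk_genetic_map", "data.frame")
  out
}

# sex-averaged genetic lengths (cM), rounded from published human linkage maps
.fk_chrom_lengths_cm <- function() {
  c(`1` = 286, `2` = 269, `3` = 232, `4` = 214, `5` = 209, `6` = 194,
    `7` = 187, `8` = 169, `9` = 167, `10` = 174, `11` = 161, `12` = 176,
    `13` = 131, `14` = 125, `15` = 132, `16` = 134, `17` = 129, `18` = 117,
    `19` = 108, `20` = 108, `21` = 62, `22` = 74, X = 180)
}

#' Draw population allele frequencies under the Balding-Nichols model
#'
#' For each SNP an ancestral frequency p is drawn uniformly on `p_range`, and
#' each population's frequency is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F), so
#' that population frequencies have mean p and variance F p (1-p). Larger
#' divergence F yields the clear continental separation expected of
#' ancestry-informative markers.
#'
#' @param n number of SNPs.
#' @param fst divergence parameter F in (0, 1).
#' @param p_range range of the ancestral frequency draw.
#' @param pops population labels (default the five continental groups).
#' @param seed RNG seed (the generator is seed-deterministic).
#' @return data frame with column `p_anc` and one frequency column per
#'   population (`freq_AFR`, ...).
#' @export
generate_population_frequencies <- function(n, fst = 0.1, p_range = c(0.05, 0.95),
                                            pops = FK_POPULATIONS, seed = 1) {
  if (fst <= 0 || fst >= 1) .fk_stopf("fst must lie in (0, 1)")
  set.seed(seed)
  p <- runif(n, p_range[1], p_range[2])
  out <- data.frame(p_anc = p)
  for (pop in pops) {
    out[[paste0("freq_", pop)]] <-
      rbeta(n, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  }
  out
}

#' Generate a synthetic SNP panel
#'
#' Builds a panel manifest emulating a forensic all-in-one capture panel:
#' autosomal kinship SNPs spaced at least `min_cm` apart along the synthetic
#' genetic map, identity/ancestry/phenotype SNPs on autosomes, X SNPs, and Y
#' SNPs (no genetic position). Kinship-class markers get weakly differentiated
#' intermediate frequencies (as the design cascade would leave them); ancestry
#' markers get strongly differentiated frequencies.
#'
#' The defaults reproduce the scale of a 5422-SNP panel: 3931 kinship, 134
#' identity, 241 ancestry, 41 phenotype, 246 X and 829 Y SNPs.
#'
#' @param n_kinship,n_ii,n_ai,n_pi,n_x,n_y marker counts per category.
#' @param fst Balding-Nichols divergence for non-ancestry markers.
#' @param ai_fst divergence for ancestry-informative markers.
#' @param min_cm minimum kinship/X marker spacing in cM.
#' @param map genetic map (default [synthetic_genetic_map()]).
#' @param seed RNG seed.
#' @return an `fk_panel` data frame.
#' @export
synthetic_panel <- function(n_kinship = 3931, n_ii = 134, n_ai = 241, n_pi = 41,
                            n_x = 246, n_y = 829, fst = 0.05, ai_fst = 0.3,
                            min_cm = 0.5, map = synthetic_genetic_map(), seed = 1) {
  set.seed(seed)
  lens <- .fk_chrom_lengths_cm()
  auto <- lens[names(lens) != "X"]

  place <- function(n, chroms, spacing_min) {
    # allocate marker counts proportional to chromosome length, then space
    # them with gaps of spacing_min plus an exponential excess
    n_per <- as.integer(round(n * chroms / sum(chroms)))
    while (sum(n_per) < n) {
      i <- which.max(chroms / (n_per + 1))
      n_per[i] <- n_per[i] + 1L
    }
    while (sum(n_per) > n) {
      i <- which(n_per == max(n_per))[1]
      n_per[i] <- n_per[i] - 1L
    }
    do.call(rbind, lapply(seq_along(chroms), function(ci) {
      len <- chroms[ci]; k <- n_per[ci]
      if (k == 0L) return(NULL)
      mean_gap <- len / (k + 1)
      excess <- max(mean_gap - spacing_min, 0.05)
      ex <- stats::rexp(k, 1 / excess)
      # squeeze the random excess (never the guaranteed spacing) to fit
      room <- len * 0.98 - k * spacing_min
      if (room <= 0) .fk_stopf("cannot place %d markers at %.2f cM spacing on a %.0f cM chromosome",
                               k, spacing_min, len)
      if (sum(ex) > room) ex <- ex * room / sum(ex)
      cm <- cumsum(spacing_min + ex)
      data.frame(chrom = names(chroms)[ci], pos_cm = cm, stringsAsFactors = FALSE)
    }))
  }

  bases <- c("A", "C", "G", "T")
  mk <- function(prefix, pos, category, fst_use, p_range) {
    n <- nrow(pos)
    fr <- generate_population_frequencies(n, fst = fst_use, p_range = p_range,
                                          seed = sample.int(2^30, 1))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    data.frame(snp_id = sprintf("%s%06d", prefix, seq_len(n)),
               chrom = pos$chrom,
               pos_bp = as.integer(round(pos$pos_cm * 1e6)) + 1L,
               pos_cm = pos$pos_cm,
               ref = ref, alt = unname(alt),
               fr[, .fk_freq_cols],
               category = category,
               n_baits = ifelse(category %in% c("X", "Y"), 2L, 4L),
               stringsAsFactors = FALSE)
  }

  pan <- rbind(
    mk("rsk", place(n_kinship, auto, min_cm), "kinship", fst, c(0.3, 0.7)),
    mk("rsi", place(n_ii, auto, 0.01), "iiSNP", fst, c(0.3, 0.7)),
    mk("rsa", place(n_ai, auto, 0.01), "aiSNP", ai_fst, c(0.1, 0.9)),
    mk("rsp", place(n_pi, auto, 0.01), "piSNP", fst, c(0.05, 0.95)),
    mk("rsx", place(n_x, lens["X"], min_cm), "X", fst, c(0.3, 0.7))
  )
  ypos <- data.frame(chrom = "Y", pos_cm = sort(runif(n_y, 1, 57)))
  y <- mk("rsy", ypos, "Y", fst, c(0.05, 0.95))
  y$pos_cm <- NA_real_
  pan <- rbind(pan, y)
  # duplicate physical positions are possible at this density; nudge them apart
  dup <- duplicated(pan[, c("chrom", "pos_bp")])
  while (any(dup)) {
    pan$pos_bp[dup] <- pan$pos_bp[dup] + 1L
    dup <- duplicated(pan[, c("chrom", "pos_bp")])
  }
  .fk_validate_panel(pan, where = "synthetic_panel")
}

# ---------------------------------------------------------------------------
# gene-dropping pedigree simulation
# ---------------------------------------------------------------------------

# one recombinant gamete: chooses parental haplotype per marker, flipping with
# probability theta between adjacent markers within a chromosome (Haldane)
.fk_gamete_bits <- function(theta, chrom) {
  n <- length(chrom)
  bits <- integer(n)
  start <- !duplicated(chrom)
  flips <- runif(n) < c(0, theta)
  flips[start] <- runif(sum(start)) < 0.5
  as.integer(cumsum(flips) %% 2L)
}

#' Simulate pedigree genotypes by gene dropping
#'
#' Founders receive haplotypes drawn independently from the selected
#' population's allele frequencies (linkage equilibrium, Hardy-Weinberg);
#' non-founders receive recombinant parental gametes with inter-marker switch
#' probability given by the Haldane map function on the cM gaps. X markers
#' follow X inheritance (males hemizygous, father-to-daughter transmission
#' without recombination); Y markers are copied along patrilines without
#' mutation, with founder patrilines drawn from the population frequencies.
#'
#' @param ped a [pedigree()] object.
#' @param panel an `fk_panel` data frame (positions in cM required for
#'   autosomal/X markers).
#' @param pop population whose frequencies drive founder draws (`"EUR"`, ...).
#' @param seed RNG seed.
#' @param return_origins if `TRUE`, also return founder-allele origin labels
#'   per haplotype (for identity-by-descent audits).
#' @return list with `panel`, and matrices `hap1`, `hap2` (individuals x
#'   markers, alt-allele indicators; `hap2` is `NA` at hemizygous sites:
#'   male X and Y, and all Y entries for females), `dosage` (hap sum; equals
#'   `hap1` at hemizygous sites), and optionally `orig1`, `orig2`.
#' @export
simulate_pedigree_genotypes <- function(ped, panel, pop = "EUR", seed = 1,
                                        return_origins = FALSE) {
  set.seed(seed)
  n <- nrow(ped)
  nm <- nrow(panel)
  fcol <- paste0("freq_", pop)
  if (!fcol %in% names(panel)) .fk_stopf("panel has no frequency column for population %s", pop)
  p <- as.numeric(panel[[fcol]])
  auto <- !(panel$category %in% c("X", "Y")) & !(panel$chrom %in% c("X", "Y"))
  isX <- panel$chrom == "X"
  isY <- panel$chrom == "Y"
  if (any((auto | isX) & is.na(panel$pos_cm)))
    .fk_stopf("autosomal/X marker without cM position")
  male <- ped$sex == "M"
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)

  hap1 <- matrix(NA_integer_, n, nm, dimnames = list(ped$id, panel$snp_id))
  hap2 <- hap1
  orig1 <- matrix(NA_integer_, n, nm, dimnames = list(ped$id, panel$snp_id))
  orig2 <- orig1

  gaps <- function(sel) {
    cm <- panel$pos_cm[sel]
    ch <- panel$chrom[sel]
    th <- haldane_theta(pmax(diff(cm), 0))
    th[ch[-1] != ch[-length(ch)]] <- 0.5
    list(theta = th, chrom = ch)
  }
  ga <- gaps(auto)
  gx <- gaps(isX)

  draw_founder_hap <- function(sel) as.integer(runif(sum(sel)) < p[sel])
  gamete <- function(h1, h2, g) {
    bits <- .fk_gamete_bits(g$theta, g$chrom)
    ifelse(bits == 0L, h1, h2)
  }
  slot <- 0L
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      hap1[i, auto] <- draw_founder_hap(auto); orig1[i, auto] <- slot + 1L
      hap2[i, auto] <- draw_founder_hap(auto); orig2[i, auto] <- slot + 2L
      if (male[i]) {
        hap1[i, isX] <- draw_founder_hap(isX); orig1[i, isX] <- slot + 1L
        hap1[i, isY] <- draw_founder_hap(isY); orig1[i, isY] <- slot + 1L
      } else {
        hap1[i, isX] <- draw_founder_hap(isX); orig1[i, isX] <- slot + 1L
        hap2[i, isX] <- draw_founder_hap(isX); orig2[i, isX] <- slot + 2L
      }
      slot <- slot + 2L
    } else {
      # paternal then maternal autosomal gametes
      bitsP <- .fk_gamete_bits(ga$theta, ga$chrom)
      hap1[i, auto] <- ifelse(bitsP == 0L, hap1[fa[i], auto], hap2[fa[i], auto])
      orig1[i, auto] <- ifelse(bitsP == 0L, orig1[fa[i], auto], orig2[fa[i], auto])
      bitsM <- .fk_gamete_bits(ga$theta, ga$chrom)
      hap2[i, auto] <- ifelse(bitsM == 0L, hap1[mo[i], auto], hap2[mo[i], auto])
      orig2[i, auto] <- ifelse(bitsM == 0L, orig1[mo[i], auto], orig2[mo[i], auto])
      # X: maternal gamete recombines; fathers pass their single X to daughters
      bitsX <- .fk_gamete_bits(gx$theta, gx$chrom)
      mx <- ifelse(bitsX == 0L, hap1[mo[i], isX], hap2[mo[i], isX])
      ox <- ifelse(bitsX == 0L, orig1[mo[i], isX], orig2[mo[i], isX])
      if (male[i]) {
        hap1[i, isX] <- mx; orig1[i, isX] <- ox
        hap1[i, isY] <- hap1[fa[i], isY]; orig1[i, isY] <- orig1[fa[i], isY]
      } else {
        hap1[i, isX] <- hap1[fa[i], isX]; orig1[i, isX] <- orig1[fa[i], isX]
        hap2[i, isX] <- mx; orig2[i, isX] <- ox
      }
    }
  }
  hap1[!male, isY] <- NA_integer_
  dosage <- hap1
  both <- !is.na(hap2)
  dosage[both] <- hap1[both] + hap2[both]
  out <- list(panel = panel, hap1 = hap1, hap2 = hap2, dosage = dosage)
  if (return_origins) { out$orig1 <- orig1; out$orig2 <- orig2 }
  out
}

#' Sequencing-observation model parameters
#'
#' Coverage is negative-binomial with per-site dropout; each read reports one
#' of the true alleles uniformly and is flipped to the other allele with the
#' per-read error rate. Two presets bracket the observed data quality:
#' `"reference"` (high-quality samples, mean 225X) and `"bone"` (degraded
#' skeletal samples: low coverage, frequent dropout).
#'
#' @param mean_cov mean coverage (> 0).
#' @param dispersion negative-binomial size parameter (> 0).
#' @param error_rate per-read allele error in `[0, 0.5)`.
#' @param dropout_frac per-site dropout probability in `[0, 1]`.
#' @param lowq_flag_rate probability that an error-origin minor allele is
#'   flagged as low-quality (emulating base-quality/strand review).
#' @param seed RNG seed.
#' @return a `seq_params` list.
#' @export
seq_params <- function(mean_cov = 225, dispersion = 5, error_rate = 0.005,
                       dropout_frac = 0.005, lowq_flag_rate = 0.8, seed = 1) {
  stopifnot(mean_cov > 0, dispersion > 0, error_rate >= 0, error_rate < 0.5,
            dropout_frac >= 0, dropout_frac <= 1)
  structure(list(mean_cov = mean_cov, dispersion = dispersion,
                 error_rate = error_rate, dropout_frac = dropout_frac,
                 lowq_flag_rate = lowq_flag_rate, seed = seed),
            class = "seq_params")
}

#' @rdname seq_params
#' @param preset `"reference"` or `"bone"`.
#' @param ... overrides passed to [seq_params()].
#' @export
seq_preset <- function(preset = c("reference", "bone"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 reference = list(mean_cov = 225, dispersion = 5,
                                  error_rate = 0.005, dropout_frac = 0.005),
                 bone = list(mean_cov = 8, dispersion = 1,
                             error_rate = 0.01, dropout_frac = 0.3))
  do.call(seq_params, utils::modifyList(base, list(...)))
}

#' Simulate per-site sequencing observations for one sample
#'
#' Draws per-site coverage and allele read counts from true genotypes under a
#' [seq_params()] model. Counts always sum to coverage. Sites the sample does
#' not carry (female Y) are omitted.
#'
#' @param truth result of [simulate_pedigree_genotypes()].
#' @param individual id of the pedigree member observed.
#' @param params a [seq_params()] object.
#' @param sample_id label for the output rows (default the individual id).
#' @return data frame: `sample_id`, `snp_id`, `coverage`, `count_A`,
#'   `count_C`, `count_G`, `count_T`, `lowq_minor_flag`.
#' @export
simulate_observations <- function(truth, individual, params, sample_id = individual) {
  set.seed(params$seed + 7L * match(individual, rownames(truth$hap1), nomatch = 0L))
  panel <- truth$panel
  h1 <- truth$hap1[individual, ]
  h2 <- truth$hap2[individual, ]
  carried <- !is.na(h1)
  panel <- panel[carried, , drop = FALSE]
  h1 <- h1[carried]; h2 <- h2[carried]
  nm <- nrow(panel)

  cov <- rnbinom(nm, mu = params$mean_cov, size = params$dispersion)
  cov[runif(nm) < params$dropout_frac] <- 0L
  # probability a read reports the alt allele, averaging over the two gene
  # copies, with per-read flips to the other allele
  dip <- !is.na(h2)
  palt_true <- ifelse(dip, (h1 + h2) / 2, h1)
  palt <- palt_true * (1 - params$error_rate) + (1 - palt_true) * params$error_rate
  n_alt <- rbinom(nm, cov, palt)
  n_ref <- cov - n_alt

  counts <- matrix(0L, nm, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (b in c("A", "C", "G", "T")) {
    counts[, b] <- ifelse(panel$ref == b, n_ref, 0L) + ifelse(panel$alt == b, n_alt, 0L)
  }
  # flag error-origin minor alleles (true homozygote, minor reads present)
  hom_true <- palt_true %in% c(0, 1)
  minor_n <- pmin(n_alt, n_ref)
  flag <- hom_true & minor_n > 0 & runif(nm) < params$lowq_flag_rate
  data.frame(sample_id = sample_id, snp_id = panel$snp_id, coverage = cov,
             count_A = counts[, "A"], count_C = counts[, "C"],
             count_G = counts[, "G"], count_T = counts[, "T"],
             lowq_minor_flag = flag, stringsAsFactors = FALSE)
}

#' Subsample the kinship markers of a panel
#'
#' Retains a uniformly random subset of the kinship-category SNPs of size
#' `round(fraction * n_kinship)`; all other categories are untouched. Used to
#' emulate partial SNP profiles (75% and 25% in the simulation study).
#'
#' @param panel an `fk_panel` data frame.
#' @param fraction fraction of kinship SNPs to retain, in (0, 1].
#' @param seed RNG seed.
#' @return the subsampled panel.
#' @export
subsample_panel <- function(panel, fraction, seed = 1) {
  if (fraction <= 0 || fraction > 1) .fk_stopf("fraction must lie in (0, 1]")
  kin <- which(panel$category == "kinship")
  if (!length(kin)) .fk_stopf("panel has no kinship SNPs")
  if (fraction == 1) return(panel)
  set.seed(seed)
  keep_n <- round(fraction * length(kin))
  drop <- setdiff(kin, sort(sample(kin, keep_n)))
  if (!length(drop)) return(panel)
  panel[-drop, , drop = FALSE]
}
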