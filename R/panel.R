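#' Default kinship-SNP selection parameters
#'
#' Parameters of the kinship panel selection cascade: the per-population
#' alt-allele frequency window, the minimum genetic distance between retained
#' SNPs, the LD pruning threshold, and the maximum pairwise population
#' frequency difference.
#'
#' @param freq_lo,freq_hi inclusive alt-allele frequency bounds applied in each
#'   of the five continental populations.
#' @param min_cm minimum genetic distance (cM) between consecutive retained SNPs.
#' @param r2_max SNP pairs with squared dosage correlation at or above this are
#'   pruned.
#' @param max_pop_diff SNPs whose maximum pairwise population frequency
#'   difference reaches this value are removed (strict `<` retained).
#' @param ld_window_cm window (cM) within which LD is evaluated.
#' @param folded if `TRUE`, the frequency window is applied to the folded minor
#'   allele frequency `min(p, 1-p)` instead of the designated alt allele
#'   frequency.
#' @return a `design_params` list.
#' @export
design_params <- function(freq_lo = 0.2, freq_hi = 0.8, min_cm = 0.5,
                          r2_max = 0.1, max_pop_diff = 0.35,
                          ld_window_cm = 10, folded = FALSE) {
  stopifnot(freq_lo >= 0, freq_lo < freq_hi, freq_hi <= 1,
            min_cm > 0, r2_max > 0, r2_max < 1,
            max_pop_diff > 0, max_pop_diff < 1, ld_window_cm > 0)
  structure(list(freq_lo = freq_lo, freq_hi = freq_hi, min_cm = min_cm,
                 r2_max = r2_max, max_pop_diff = max_pop_diff,
                 ld_window_cm = ld_window_cm, folded = folded),
            class = "design_params")
}

.fk_categories <- c("kinship", "iiSNP", "aiSNP", "piSNP", "X", "Y")
.fk_freq_cols <- paste0("freq_", FK_POPULATIONS)
.fk_panel_cols <- c("snp_id", "chrom", "pos_bp", "pos_cm", "ref", "alt",
                    .fk_freq_cols, "category", "n_baits")

# validate a panel data frame; row numbers refer to the manifest file
.fk_validate_panel <- function(d, where = "panel") {
  miss <- setdiff(.fk_panel_cols, names(d))
  if (length(miss)) .fk_stopf("%s: missing columns: %s", where, paste(miss, collapse = ", "))
  if (anyDuplicated(d$snp_id))
    .fk_stopf("%s: duplicate snp_id: %s", where,
              paste(unique(d$snp_id[duplicated(d$snp_id)]), collapse = ", "))
  bad <- which(!d$category %in% .fk_categories)
  if (length(bad))
    .fk_stopf("%s row %d: unknown category '%s'", where, bad[1], d$category[bad[1]])
  for (cc in .fk_freq_cols) {
    bad <- which(!is.na(d[[cc]]) & (d[[cc]] < 0 | d[[cc]] > 1))
    if (length(bad))
      .fk_stopf("%s row %d: column %s value %g outside [0,1]", where, bad[1], cc, d[[cc]][bad[1]])
  }
  bad <- which(d$pos_bp < 1)
  if (length(bad)) .fk_stopf("%s row %d: pos_bp must be >= 1", where, bad[1])
  bad <- which(d$ref == d$alt)
  if (length(bad)) .fk_stopf("%s row %d: ref and alt alleles identical", where, bad[1])
  bad <- which(d$category == "Y" & !is.na(d$pos_cm))
  if (length(bad)) .fk_stopf("%s row %d: Y SNPs carry no genetic position", where, bad[1])
  d <- d[order(match(d$chrom, c(as.character(1:22), "X", "Y")), d$pos_bp), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("fk_panel", "data.frame")
  d
}

#' Read a panel manifest TSV
#'
#' Columns: `snp_id`, `chrom` (1-22, X, Y), `pos_bp` (1-based), `pos_cm`
#' (empty for Y), `ref`, `alt`, `freq_AFR` ... `freq_SAS` (alt allele
#' frequency per population), `category` (kinship, iiSNP, aiSNP, piSNP, X, Y),
#' `n_baits`. Malformed rows are rejected with a row-numbered message.
#'
#' @param path manifest file path.
#' @return a validated `fk_panel` data frame, sorted by chromosome and
#'   position, with a `category_counts` attribute.
#' @export
read_panel <- function(path) {
  d <- .fk_read_tsv(path)
  d$chrom <- as.character(d$chrom)
  p <- .fk_validate_panel(d, where = basename(path))
  attr(p, "category_counts") <- table(p$category)
  p
}

#' Write a panel manifest TSV
#' @param panel an `fk_panel` data frame.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  .fk_write_tsv(as.data.frame(panel)[, .fk_panel_cols], path)
}

#' Category counts of a panel
#' @param panel an `fk_panel` data frame.
#' @return named integer vector of SNP counts per category.
#' @export
category_counts <- function(panel) {
  vapply(.fk_categories, function(cc) sum(panel$category == cc), integer(1))
}

#' Sex-adjusted maximum number of callable SNPs
#'
#' Males can be called at every panel SNP; females at every SNP except the
#' Y-chromosomal ones.
#'
#' @param panel an `fk_panel` data frame.
#' @param sex `"M"` or `"F"`.
#' @return integer maximum callable SNP count.
#' @export
max_callable_snps <- function(panel, sex) {
  n <- nrow(panel)
  if (sex == "F") n - sum(panel$category == "Y") else n
}

#' Read a genetic map TSV
#'
#' Columns `chrom`, `pos_bp`, `pos_cm`; anchors must be non-decreasing in cM
#' within a chromosome.
#'
#' @param path map file.
#' @return `fk_genetic_map` data frame.
#' @export
read_genetic_map <- function(path) {
  d <- .fk_read_tsv(path)
  d$chrom <- as.character(d$chrom)
  d <- d[order(match(d$chrom, c(as.character(1:22), "X")), d$pos_bp), ]
  bad <- unlist(lapply(split(d$pos_cm, d$chrom), function(z) any(diff(z) < 0)))
  if (any(bad)) .fk_stopf("genetic map: pos_cm decreases within chromosome %s",
                          names(bad)[bad][1])
  rownames(d) <- NULL
  class(d) <- c("fk_genetic_map", "data.frame")
  d
}

#' Interpolate genetic positions from a map
#'
#' Linear interpolation of cM positions between flanking map anchors; positions
#' outside the anchored range get `NA` (such SNPs are excluded from design).
#'
#' @param map an `fk_genetic_map` data frame.
#' @param chrom,pos_bp vectors of physical positions to interpolate.
#' @return numeric cM positions (`NA` where not coverable).
#' @export
interpolate_cm <- function(map, chrom, pos_bp) {
  out <- rep(NA_real_, length(pos_bp))
  for (ch in unique(chrom)) {
    m <- map[map$chrom == ch, ]
    idx <- which(chrom == ch)
    if (nrow(m) >= 2L)
      out[idx] <- approx(m$pos_bp, m$pos_cm, xout = pos_bp[idx],
                         method = "linear", rule = 1)$y
  }
  out
}

# ---------------------------------------------------------------------------
# selection cascade filters
# ---------------------------------------------------------------------------

#' Intersect candidate SNP lists from genotyping chips
#'
#' @param chip_lists list of two or more character vectors of snp ids.
#' @return character vector of ids present on every chip.
#' @export
intersect_chip_candidates <- function(chip_lists) {
  if (!is.list(chip_lists) || length(chip_lists) < 2L)
    .fk_stopf("need at least two chip candidate lists")
  if (any(!lengths(chip_lists))) .fk_stopf("empty chip candidate list")
  out <- Reduce(intersect, chip_lists)
  if (!length(out)) .fk_warnf("chip candidate lists have an empty intersection")
  out
}

#' Filter SNPs to an allele-frequency window in all five populations
#'
#' Retains a SNP iff its alt-allele frequency (or folded MAF when
#' `params$folded`) lies in `[freq_lo, freq_hi]` in every one of the five
#' continental populations. SNPs with any missing population frequency are
#' excluded.
#'
#' @param panel an `fk_panel` (or compatible data frame).
#' @param params a [design_params()] list.
#' @return the retained subset.
#' @export
filter_frequency_range <- function(panel, params = design_params()) {
  f <- as.matrix(panel[, .fk_freq_cols])
  if (params$folded) f <- pmin(f, 1 - f)
  ok <- !apply(is.na(f), 1L, any) &
    apply(f >= params$freq_lo & f <= params$freq_hi, 1L, all)
  ok[is.na(ok)] <- FALSE
  dropped <- sum(apply(is.na(as.matrix(panel[, .fk_freq_cols])), 1L, any))
  if (dropped) message(sprintf("frequency filter: %d SNP(s) with missing population frequency excluded", dropped))
  panel[ok, , drop = FALSE]
}

#' Thin SNPs to a minimum genetic distance
#'
#' Greedy left-to-right scan per chromosome: the first SNP is kept and each
#' subsequent SNP is kept only if it lies at least `min_cm` centimorgans from
#' the last kept SNP (a gap of exactly `min_cm` is retained). Co-located SNPs
#' are ordered so the one with folded MAF (averaged over populations) closest
#' to 0.5 is considered first. SNPs without a cM position are excluded.
#'
#' @inheritParams filter_frequency_range
#' @return the retained subset.
#' @export
thin_by_genetic_distance <- function(panel, params = design_params()) {
  if (anyNA(panel$pos_cm)) {
    message(sprintf("distance thinning: %d SNP(s) not coverable by the genetic map excluded",
                    sum(is.na(panel$pos_cm))))
    panel <- panel[!is.na(panel$pos_cm), , drop = FALSE]
  }
  f <- as.matrix(panel[, .fk_freq_cols])
  inform <- rowMeans(pmin(f, 1 - f), na.rm = TRUE) # tie-break: MAF closest to 0.5
  keep <- logical(nrow(panel))
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    idx <- idx[order(panel$pos_cm[idx], -inform[idx])]
    last <- -Inf
    for (i in idx) {
      if (panel$pos_cm[i] - last >= params$min_cm) {
        keep[i] <- TRUE
        last <- panel$pos_cm[i]
      }
    }
  }
  panel[keep, , drop = FALSE]
}

#' Prune SNPs in linkage disequilibrium
#'
#' Composite (genotype-dosage) LD: within each chromosome, r-squared is the
#' squared Pearson correlation of dosage columns from a reference genotype
#' matrix, evaluated between pairs closer than the window. Scanning left to
#' right, a SNP is removed when its r-squared with any retained earlier SNP
#' reaches `r2_max`; zero-variance reference columns are removed with a logged
#' reason.
#'
#' @inheritParams filter_frequency_range
#' @param ref_genotypes numeric matrix of dosages in `{0,1,2}`, one column per
#'   panel SNP (columns named by `snp_id`), one row per reference individual.
#' @return the retained subset.
#' @export
prune_by_ld <- function(panel, ref_genotypes, params = design_params()) {
  idx_col <- match(panel$snp_id, colnames(ref_genotypes))
  if (anyNA(idx_col)) .fk_stopf("reference genotypes missing for %d panel SNP(s)",
                                sum(is.na(idx_col)))
  v <- apply(ref_genotypes[, idx_col, drop = FALSE], 2L, stats::var)
  if (any(v == 0)) {
    message(sprintf("LD pruning: %d zero-variance SNP(s) in reference removed", sum(v == 0)))
    panel <- panel[v > 0, , drop = FALSE]
    idx_col <- idx_col[v > 0]
  }
  keep <- logical(nrow(panel))
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    idx <- idx[order(panel$pos_cm[idx], panel$pos_bp[idx])]
    kept <- integer(0)
    for (i in idx) {
      win <- kept[panel$pos_cm[kept] >= panel$pos_cm[i] - params$ld_window_cm]
      r2 <- if (length(win))
        cor(ref_genotypes[, idx_col[i]], ref_genotypes[, idx_col[win], drop = FALSE])^2
      else numeric(0)
      if (!length(r2) || all(r2 < params$r2_max)) {
        keep[i] <- TRUE
        kept <- c(kept, i)
      }
    }
  }
  panel[keep, , drop = FALSE]
}

#' Filter SNPs by population frequency differentiation
#'
#' Retains a SNP iff the maximum pairwise absolute difference of its alt-allele
#' frequency between the five continental populations is strictly below
#' `max_pop_diff`.
#'
#' @inheritParams filter_frequency_range
#' @return the retained subset.
#' @export
filter_population_differentiation <- function(panel, params = design_params()) {
  f <- as.matrix(panel[, .fk_freq_cols])
  rng <- apply(f, 1L, function(z) if (anyNA(z)) NA_real_ else diff(range(z)))
  ok <- !is.na(rng) & rng < params$max_pop_diff
  panel[ok, , drop = FALSE]
}

#' Exclude SNPs falling in clinically relevant regions
#'
#' Removes SNPs whose position lies in any half-open interval
#' `[start_bp, end_bp)` of a user-supplied region blocklist (for example, genes
#' with reportable secondary findings).
#'
#' @inheritParams filter_frequency_range
#' @param blocklist data frame with `chrom`, `start_bp`, `end_bp` (half-open).
#' @return the retained subset.
#' @export
exclude_regions <- function(panel, blocklist) {
  if (!nrow(blocklist)) return(panel)
  if (any(blocklist$start_bp >= blocklist$end_bp))
    .fk_stopf("blocklist: malformed interval (start >= end)")
  hit <- rep(FALSE, nrow(panel))
  for (r in seq_len(nrow(blocklist))) {
    hit <- hit | (panel$chrom == as.character(blocklist$chrom[r]) &
                    panel$pos_bp >= blocklist$start_bp[r] &
                    panel$pos_bp < blocklist$end_bp[r])
  }
  panel[!hit, , drop = FALSE]
}

#' Read a BED region blocklist
#'
#' BED intervals are 0-based half-open; they are converted to the 1-based
#' half-open convention used by [exclude_regions()].
#'
#' @param path BED file (chrom, start, end in the first three columns).
#' @return data frame `chrom`, `start_bp`, `end_bp`.
#' @export
read_blocklist_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:3]
  names(d) <- c("chrom", "start", "end")
  data.frame(chrom = sub("^chr", "", as.character(d$chrom)),
             start_bp = d$start + 1L, end_bp = d$end + 1L,
             stringsAsFactors = FALSE)
}

#' Run the kinship-SNP selection cascade
#'
#' Applies the selection criteria in their canonical order -- chip
#' intersection, allele-frequency window, genetic-distance thinning, LD
#' pruning, population differentiation, clinical-region exclusion -- and
#' reports the number of SNPs remaining after each step.
#'
#' @param candidates candidate `fk_panel`-style data frame (category kinship).
#' @param chip_lists list of >= 2 chip snp-id vectors.
#' @param map an `fk_genetic_map`; used to fill missing `pos_cm` by
#'   interpolation.
#' @param ref_genotypes reference dosage matrix for LD pruning (columns named
#'   by snp id).
#' @param blocklist region blocklist (may have zero rows).
#' @param params a [design_params()] list.
#' @return list with `panel` (the selected SNPs) and `attrition` (data frame
#'   `step`, `n_remaining`).
#' @export
design_kinship_panel <- function(candidates, chip_lists, map, ref_genotypes,
                                 blocklist = data.frame(), params = design_params()) {
  steps <- character(0); counts <- integer(0)
  note <- function(step, panel) {
    steps <<- c(steps, step); counts <<- c(counts, nrow(panel))
    panel
  }
  p <- candidates[candidates$snp_id %in% intersect_chip_candidates(chip_lists), , drop = FALSE]
  p <- note("chip_intersection", p)
  p <- note("frequency_range", filter_frequency_range(p, params))
  fill <- is.na(p$pos_cm)
  if (any(fill)) p$pos_cm[fill] <- interpolate_cm(map, p$chrom[fill], p$pos_bp[fill])
  p <- note("genetic_distance", thin_by_genetic_distance(p, params))
  p <- note("ld_pruning", prune_by_ld(p, ref_genotypes, params))
  p <- note("population_differentiation", filter_population_differentiation(p, params))
  p <- note("clinical_exclusion", exclude_regions(p, blocklist))
  list(panel = p, attrition = data.frame(step = steps, n_remaining = counts,
                                         stringsAsFactors = FALSE))
}
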