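#' Call one SNP site from coverage and allele counts
#'
#' Applies the coverage and allele-balance thresholds: a site needs at least
#' `min_cov` reads to be analysed; with major-allele fraction `f` and minor
#' fraction `m = 1 - f` over the top two alleles, `m <= hom_max` is called
#' homozygote (the single allele, for haploid sites), `m >= het_min` is called
#' heterozygote (diploid only; a haploid site with `m >= hom_max` can never be
#' a heterozygote and is imbalanced), and `hom_max < m < het_min` is marked
#' imbalanced and excluded from downstream analyses. At the boundaries the
#' homozygote rule wins at exactly `m = hom_max` ("90% or greater") and the
#' heterozygote rule wins at exactly `m = het_min` ("at least 30%"). Alleles
#' are ranked by count with lexicographic tie-breaking; reads of a third
#' allele count toward coverage but not the genotype.
#'
#' @param counts named numeric vector of read counts per allele (e.g.
#'   `c(A = 95, G = 5)`).
#' @param ploidy `"diploid"` or `"haploid"` (Y, male X).
#' @param min_cov minimum coverage (default 10).
#' @param hom_max maximum minor fraction for a homozygote call (default 0.10).
#' @param het_min minimum minor fraction for a heterozygote call (default 0.30).
#' @return list: `status` (`"called"`, `"imbalanced"`, `"no_call"`),
#'   `allele1`, `allele2` (`NA` when absent; equal for homozygotes; `allele2`
#'   `NA` for haploid calls), `coverage`, `minor_fraction`.
#' @examples
#' call_site(c(A = 95, G = 5))   # called homozygote A/A
#' call_site(c(A = 60, G = 40))  # called heterozygote A/G
#' call_site(c(A = 85, G = 15))  # imbalanced
#' @export
call_site <- function(counts, ploidy = c("diploid", "haploid"),
                      min_cov = 10, hom_max = 0.10, het_min = 0.30) {
  ploidy <- match.arg(ploidy)
  if (any(counts < 0)) .fk_stopf("negative allele counts")
  coverage <- sum(counts)
  no_call <- list(status = "no_call", allele1 = NA_character_,
                  allele2 = NA_character_, coverage = coverage,
                  minor_fraction = NA_real_)
  if (coverage < min_cov) return(no_call)
  counts <- counts[order(-counts, names(counts))] # count rank, ties lexicographic
  top2 <- counts[seq_len(min(2L, length(counts)))]
  m <- if (length(top2) < 2L) 0 else unname(top2[2] / sum(top2))
  a1 <- names(top2)[1]
  if (m <= hom_max) {
    list(status = "called", allele1 = a1,
         allele2 = if (ploidy == "diploid") a1 else NA_character_,
         coverage = coverage, minor_fraction = m)
  } else if (m >= het_min && ploidy == "diploid") {
    het <- sort(names(top2)) # report heterozygote alleles in base order
    list(status = "called", allele1 = het[1], allele2 = het[2],
         coverage = coverage, minor_fraction = m)
  } else {
    list(status = "imbalanced", allele1 = a1,
         allele2 = if (ploidy == "diploid") names(top2)[2] else NA_character_,
         coverage = coverage, minor_fraction = m)
  }
}

#' Infer sample sex from Y-SNP coverage
#'
#' A sample is inferred male iff at least `min_sites` Y-SNP sites reach the
#' calling coverage threshold.
#'
#' @param obs observation data frame (see [call_profile()]).
#' @param panel an `fk_panel`.
#' @param min_sites minimum covered Y sites for a male call.
#' @param min_cov coverage threshold per site.
#' @return `"M"` or `"F"`.
#' @export
infer_sex <- function(obs, panel, min_sites = 50, min_cov = 10) {
  ysnps <- panel$snp_id[panel$category == "Y"]
  n <- sum(obs$snp_id %in% ysnps & obs$coverage >= min_cov)
  if (n >= min_sites) "M" else "F"
}

#' Call a full SNP profile from per-site observations
#'
#' Calls every panel site present in the observation table (panel sites
#' without observations become no-calls), computes completeness metrics
#' against the sex-adjusted maximum (females are not callable at Y SNPs,
#' which are excluded from their denominator), and the mean coverage of
#' called sites.
#'
#' @param obs data frame with columns `sample_id`, `snp_id`, `coverage`,
#'   `count_A`, `count_C`, `count_G`, `count_T`, and optionally
#'   `lowq_minor_flag`.
#' @param panel an `fk_panel` data frame.
#' @param sex `"M"`, `"F"`, or `"unknown"` (then inferred via [infer_sex()]).
#' @param min_cov,hom_max,het_min thresholds passed to [call_site()].
#' @return a `called_profile` list: `sample_id`, `sex`, `sites` (data frame
#'   `snp_id`, `category`, `status`, `allele1`, `allele2`, `coverage`,
#'   `minor_fraction`, `lowq_minor_flag`), `metrics` (`n_called`,
#'   `max_callable`, `pct_called`, `mean_cov_called`).
#' @export
call_profile <- function(obs, panel, sex = "unknown",
                         min_cov = 10, hom_max = 0.10, het_min = 0.30) {
  unknown_ids <- setdiff(obs$snp_id, panel$snp_id)
  if (length(unknown_ids)) {
    .fk_warnf("%d observation(s) for SNPs absent from the panel ignored", length(unknown_ids))
    obs <- obs[obs$snp_id %in% panel$snp_id, , drop = FALSE]
  }
  if (sex == "unknown") sex <- infer_sex(obs, panel, min_cov = min_cov)
  sample_id <- if (nrow(obs)) obs$sample_id[1] else NA_character_

  i <- match(panel$snp_id, obs$snp_id)
  cmat <- matrix(0, nrow(panel), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- !is.na(i)
  for (b in colnames(cmat)) cmat[ok, b] <- obs[[paste0("count_", b)]][i[ok]]
  flag <- rep(FALSE, nrow(panel))
  if ("lowq_minor_flag" %in% names(obs)) flag[ok] <- obs$lowq_minor_flag[i[ok]]

  haploid <- panel$category == "Y" | (sex == "M" & panel$chrom == "X")
  applicable <- !(sex == "F" & panel$category == "Y")

  sites <- vector("list", nrow(panel))
  for (r in seq_len(nrow(panel))) {
    if (!applicable[r]) {
      sites[[r]] <- list(status = "not_applicable", allele1 = NA_character_,
                         allele2 = NA_character_, coverage = NA_real_,
                         minor_fraction = NA_real_)
    } else {
      sites[[r]] <- call_site(cmat[r, ],
                              ploidy = if (haploid[r]) "haploid" else "diploid",
                              min_cov = min_cov, hom_max = hom_max, het_min = het_min)
    }
  }
  sites <- data.frame(snp_id = panel$snp_id, category = panel$category,
                      status = vapply(sites, `[[`, "", "status"),
                      allele1 = vapply(sites, `[[`, "", "allele1"),
                      allele2 = vapply(sites, `[[`, "", "allele2"),
                      coverage = vapply(sites, function(s) as.numeric(s$coverage), 0),
                      minor_fraction = vapply(sites, function(s) as.numeric(s$minor_fraction), 0),
                      lowq_minor_flag = flag,
                      stringsAsFactors = FALSE)
  n_called <- sum(sites$status == "called")
  max_callable <- max_callable_snps(panel, sex)
  metrics <- list(n_called = n_called, max_callable = max_callable,
                  pct_called = 100 * n_called / max_callable,
                  mean_cov_called = if (n_called) mean(sites$coverage[sites$status == "called"]) else NA_real_)
  structure(list(sample_id = sample_id, sex = sex, sites = sites, metrics = metrics),
            class = "called_profile")
}

#' @export
print.called_profile <- function(x, ...) {
  cat(sprintf("called_profile %s (sex %s): %d/%d called (%.1f%%), mean coverage %.0fX\n",
              x$sample_id, x$sex, x$metrics$n_called, x$metrics$max_callable,
              x$metrics$pct_called,
              ifelse(is.na(x$metrics$mean_cov_called), 0, x$metrics$mean_cov_called)))
  invisible(x)
}

#' Resolve artifact minor alleles at imbalanced sites
#'
#' For imbalanced sites whose minor allele carries the low-quality flag
#' (base quality/strand review indicating sequencing error), the minor allele
#' is removed and the noted genotype becomes the major-allele homozygote.
#' This noted genotype is recorded for concordance assessment only: the site
#' status stays `"imbalanced"` and it is never used downstream.
#'
#' @param profile a `called_profile`.
#' @return the profile with columns `noted_allele1`, `noted_allele2` added to
#'   `sites` (populated only at resolved imbalanced sites).
#' @export
resolve_artifact_minor <- function(profile) {
  s <- profile$sites
  s$noted_allele1 <- NA_character_
  s$noted_allele2 <- NA_character_
  fix <- s$status == "imbalanced" & s$lowq_minor_flag
  s$noted_allele1[fix] <- s$allele1[fix]
  s$noted_allele2[fix] <- s$allele1[fix]
  profile$sites <- s
  profile
}

#' Concordance of a called profile against known genotypes
#'
#' Compares called genotypes (and, separately, noted genotypes at resolved
#' imbalanced sites) with a reference genotype table. Sites with no call on
#' either side are non-comparable.
#'
#' @param profile a `called_profile` (optionally after
#'   [resolve_artifact_minor()]).
#' @param truth data frame with `snp_id`, `allele1`, `allele2` (`NA` alleles =
#'   no reference call at that site).
#' @return list of counts: `n_compared`, `n_concordant`, `n_discordant`,
#'   `pct_concordant`, the same for imbalanced noted genotypes
#'   (`imb_*`), combined totals (`total_*`), and `n_non_comparable`.
#' @export
concordance_report <- function(profile, truth) {
  s <- profile$sites
  i <- match(s$snp_id, truth$snp_id)
  if (all(is.na(i))) .fk_stopf("no overlapping SNPs between profile and reference")
  t1 <- truth$allele1[i]; t2 <- truth$allele2[i]
  has_truth <- !is.na(i) & !is.na(t1)
  norm <- function(a, b) {
    b <- ifelse(is.na(b), a, b) # haploid: compare the single allele
    paste(pmin(a, b), pmax(a, b))
  }
  called <- s$status == "called" & has_truth
  conc <- norm(s$allele1[called], s$allele2[called]) == norm(t1[called], t2[called])
  if ("noted_allele1" %in% names(s)) {
    noted <- !is.na(s$noted_allele1) & has_truth
    nconc <- norm(s$noted_allele1[noted], s$noted_allele2[noted]) == norm(t1[noted], t2[noted])
  } else {
    noted <- rep(FALSE, nrow(s)); nconc <- logical(0)
  }
  applicable <- s$status != "not_applicable"
  list(n_compared = sum(called), n_concordant = sum(conc),
       n_discordant = sum(!conc),
       pct_concordant = if (sum(called)) 100 * sum(conc) / sum(called) else NA_real_,
       imb_compared = sum(noted), imb_concordant = sum(nconc),
       imb_discordant = sum(!nconc),
       imb_pct_concordant = if (sum(noted)) 100 * sum(nconc) / sum(noted) else NA_real_,
       total_compared = sum(called) + sum(noted),
       total_concordant = sum(conc) + sum(nconc),
       total_pct_concordant = 100 * (sum(conc) + sum(nconc)) / max(1L, sum(called) + sum(noted)),
       n_non_comparable = sum(applicable & !(called | noted)))
}

#' Alt-allele dosages of a called profile
#'
#' Converts called genotypes to alt-allele dosages against the panel's
#' ref/alt annotation: diploid sites in `{0,1,2}`, hemizygous sites (Y, male
#' X) in `{0,1}`; no-calls, imbalanced sites and not-applicable sites are
#' `NA`. Only called genotypes are used downstream.
#'
#' @param profile a `called_profile`.
#' @param panel the `fk_panel` it was called against.
#' @return named numeric vector of dosages, one per panel SNP.
#' @export
profile_dosages <- function(profile, panel) {
  s <- profile$sites[match(panel$snp_id, profile$sites$snp_id), ]
  d <- rep(NA_real_, nrow(panel))
  called <- !is.na(s$status) & s$status == "called"
  hap <- called & is.na(s$allele2)
  d[called & !hap] <- (s$allele1 == panel$alt)[called & !hap] +
    (s$allele2 == panel$alt)[called & !hap]
  d[hap] <- as.numeric(s$allele1 == panel$alt)[hap]
  names(d) <- panel$snp_id
  d
}

#' Write a called profile as TSV
#' @param profile a `called_profile`.
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  .fk_write_tsv(profile$sites, path,
                comments = .fk_header_comment(
                  sprintf("sample=%s sex=%s called=%d/%d (%.2f%%)",
                          profile$sample_id, profile$sex, profile$metrics$n_called,
                          profile$metrics$max_callable, profile$metrics$pct_called)))
}

#' Write a called profile as VCF
#'
#' Minimal VCFv4.3 with a GT genotype field: no-calls are missing (`./.`),
#' imbalanced sites carry the `IMB` FILTER tag, and hemizygous sites emit a
#' single allele.
#'
#' @param profile a `called_profile`.
#' @param panel the `fk_panel` it was called against.
#' @param path output file.
#' @export
write_profile_vcf <- function(profile, panel, path) {
  s <- profile$sites[match(panel$snp_id, profile$sites$snp_id), ]
  gt_code <- function(a, ref, alt) ifelse(is.na(a), ".", ifelse(a == alt, "1", "0"))
  a1 <- gt_code(s$allele1, panel$ref, panel$alt)
  a2 <- gt_code(s$allele2, panel$ref, panel$alt)
  hap <- panel$category == "Y" | (profile$sex == "M" & panel$chrom == "X")
  gt <- ifelse(s$status == "called",
               ifelse(hap, a1, paste0(a1, "/", a2)),
               ifelse(hap, ".", "./."))
  filt <- ifelse(!is.na(s$status) & s$status == "imbalanced", "IMB", "PASS")
  lines <- c(
    "##fileformat=VCFv4.3",
    sprintf("##source=forcekin %s", packageVersion("forcekin")),
    "##FILTER=<ID=IMB,Description=\"Imbalanced allele ratio (minor fraction in (0.10,0.30)); excluded from analyses\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", profile$sample_id),
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t.\tGT:DP\t%s:%s",
            panel$chrom, panel$pos_bp, panel$snp_id, panel$ref, panel$alt,
            filt, gt, ifelse(is.na(s$coverage), 0, s$coverage))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read observations TSV
#'
#' Reads a per-site observation table (`sample_id`, `snp_id`, `coverage`,
#' `count_A`, `count_C`, `count_G`, `count_T`, `lowq_minor_flag`), checking
#' that counts sum to coverage.
#'
#' @param path file path.
#' @return observation data frame (possibly several samples).
#' @export
read_observations <- function(path) {
  d <- .fk_read_tsv(path)
  need <- c("sample_id", "snp_id", "coverage", "count_A", "count_C", "count_G", "count_T")
  miss <- setdiff(need, names(d))
  if (length(miss)) .fk_stopf("%s: missing columns %s", basename(path), paste(miss, collapse = ", "))
  tot <- d$count_A + d$count_C + d$count_G + d$count_T
  bad <- which(tot != d$coverage)
  if (length(bad)) .fk_stopf("%s row %d: allele counts do not sum to coverage",
                             basename(path), bad[1])
  if (!"lowq_minor_flag" %in% names(d)) d$lowq_minor_flag <- FALSE
  d$lowq_minor_flag <- as.logical(d$lowq_minor_flag)
  d
}
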