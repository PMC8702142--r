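test_that("site calling applies the coverage and allele-balance thresholds", {
  # below 10X: never analysed
  expect_equal(call_site(c(A = 5, G = 4))$status, "no_call")
  # >= 90% major: homozygote
  hom <- call_site(c(A = 95, G = 5))
  expect_equal(hom$status, "called")
  expect_equal(c(hom$allele1, hom$allele2), c("A", "A"))
  expect_equal(hom$minor_fraction, 0.05)
  # >= 30% minor: heterozygote
  het <- call_site(c(A = 60, G = 40))
  expect_equal(het$status, "called")
  expect_setequal(c(het$allele1, het$allele2), c("A", "G"))
  # 10-30% band: imbalanced, excluded downstream
  imb <- call_site(c(A = 85, G = 15))
  expect_equal(imb$status, "imbalanced")
  # boundaries: homozygote wins at exactly 10%, heterozygote at exactly 30%
  expect_equal(call_site(c(A = 90, G = 10))$status, "called")
  expect_equal(call_site(c(A = 90, G = 10))$allele2, "A")
  b30 <- call_site(c(A = 70, G = 30))
  expect_equal(b30$status, "called")
  expect_setequal(c(b30$allele1, b30$allele2), c("A", "G"))
  expect_error(call_site(c(A = -1, G = 11)), "negative")
})

test_that("site calling ranks alleles by count with lexicographic ties and a top-two minor fraction", {
  tie <- call_site(c(T = 50, C = 50))
  expect_setequal(c(tie$allele1, tie$allele2), c("C", "T"))
  # third-allele reads count toward coverage but not the genotype
  tri <- call_site(c(A = 58, G = 39, T = 3))
  expect_equal(tri$status, "called")
  expect_setequal(c(tri$allele1, tri$allele2), c("A", "G"))
  expect_equal(tri$minor_fraction, 39 / 97)
  expect_equal(tri$coverage, 100)
})

test_that("haploid sites never call heterozygotes", {
  expect_equal(call_site(c(A = 95, G = 5), ploidy = "haploid")$status, "called")
  expect_true(is.na(call_site(c(A = 95, G = 5), ploidy = "haploid")$allele2))
  expect_equal(call_site(c(A = 60, G = 40), ploidy = "haploid")$status, "imbalanced")
  expect_equal(call_site(c(A = 85, G = 15), ploidy = "haploid")$status, "imbalanced")
})

test_that("raising coverage of a no-call site above threshold never yields no_call", {
  set.seed(21)
  for (r in 1:50) {
    n1 <- sample(0:9, 1); n2 <- sample(0:(9 - n1), 1)
    low <- call_site(c(A = n1, G = n2))
    expect_equal(low$status, "no_call")
    f <- sample(2:20, 1)
    high <- call_site(c(A = n1 * f + 10, G = n2 * f))
    expect_true(high$status %in% c("called", "imbalanced"))
  }
})

test_that("profile calling adjusts the denominator by sex and recounts correctly", {
  pan <- h_fixture_panel()
  ped <- pedigree(id = c("u", "f"), sex = c("M", "F"))
  sim <- simulate_pedigree_genotypes(ped, pan, seed = 22)
  obs <- simulate_observations(sim, "u", seq_preset("bone", seed = 23))
  pr <- call_profile(obs, pan, sex = "M")
  # independent site-by-site oracle recount
  cnts <- as.matrix(obs[, c("count_A", "count_C", "count_G", "count_T")])
  top2 <- t(apply(cnts, 1, function(z) sort(z, decreasing = TRUE)[1:2]))
  minor <- ifelse(rowSums(top2) > 0, top2[, 2] / rowSums(top2), 0)
  called_oracle <- sum(obs$coverage >= 10 & (minor <= 0.10 | minor >= 0.30) &
                         !(minor >= 0.30 &
                             pan$category[match(obs$snp_id, pan$snp_id)] == "Y"))
  # male X is haploid too in the oracle
  hapx <- pan$category[match(obs$snp_id, pan$snp_id)] == "X"
  called_oracle <- called_oracle - sum(obs$coverage >= 10 & minor >= 0.30 & hapx)
  expect_equal(pr$metrics$n_called, called_oracle)
  expect_equal(pr$metrics$max_callable, nrow(pan))
  expect_equal(pr$metrics$pct_called, 100 * pr$metrics$n_called / nrow(pan))

  # female: Y SNPs are not applicable and leave the denominator
  obsf <- simulate_observations(sim, "f", seq_preset("reference", seed = 24))
  prf <- call_profile(obsf, pan, sex = "F")
  expect_equal(prf$metrics$max_callable, nrow(pan) - sum(pan$category == "Y"))
  expect_true(all(prf$sites$status[prf$sites$category == "Y"] == "not_applicable"))

  # all-zero coverage: 0 called, 0%
  obs0 <- obs; obs0$coverage <- 0L
  obs0$count_A <- obs0$count_C <- obs0$count_G <- obs0$count_T <- 0L
  pr0 <- call_profile(obs0, pan, sex = "M")
  expect_equal(pr0$metrics$n_called, 0L)
  expect_equal(pr0$metrics$pct_called, 0)

  expect_warning(call_profile(rbind(obs, data.frame(
    sample_id = "u", snp_id = "rs_not_here", coverage = 50, count_A = 50,
    count_C = 0, count_G = 0, count_T = 0, lowq_minor_flag = FALSE)), pan,
    sex = "M"), "absent from the panel")
})

test_that("sex inference requires covered Y sites", {
  pan <- h_fixture_panel()
  ped <- pedigree(id = c("m1", "f1"), sex = c("M", "F"))
  sim <- simulate_pedigree_genotypes(ped, pan, seed = 25)
  obs_m <- simulate_observations(sim, "m1", seq_preset("reference", seed = 26))
  expect_equal(infer_sex(obs_m, pan), "M")
  obs_f <- simulate_observations(sim, "f1", seq_preset("reference", seed = 27))
  expect_equal(infer_sex(obs_f, pan), "F")
})

test_that("artifact minor alleles resolve to noted homozygotes for concordance only", {
  pan <- h_panel("1", 1:3, ids = c("m1", "m2", "m3"))
  obs <- data.frame(sample_id = "s", snp_id = c("m1", "m2", "m3"),
                    coverage = c(100L, 100L, 100L),
                    count_A = c(85L, 85L, 60L), count_C = 0L,
                    count_G = c(15L, 15L, 40L), count_T = 0L,
                    lowq_minor_flag = c(TRUE, FALSE, FALSE))
  pr <- call_profile(obs, pan, sex = "F")
  pr2 <- resolve_artifact_minor(pr)
  s <- pr2$sites
  # flagged imbalanced: noted homozygote, status unchanged (never used downstream)
  expect_equal(s$status[1], "imbalanced")
  expect_equal(c(s$noted_allele1[1], s$noted_allele2[1]), c("A", "A"))
  # unflagged imbalanced and called sites: unchanged, nothing noted
  expect_equal(s$status[2], "imbalanced")
  expect_true(is.na(s$noted_allele1[2]))
  expect_equal(s$status[3], "called")
  expect_true(is.na(s$noted_allele1[3]))
  # dosages never use imbalanced sites
  d <- profile_dosages(pr2, pan)
  expect_true(is.na(d[["m1"]]) && is.na(d[["m2"]]))
  expect_equal(d[["m3"]], 1)
})

test_that("concordance accounting separates called, noted and non-comparable sites", {
  pan <- h_panel("1", 1:100, ids = sprintf("c%03d", 1:100))
  truth <- data.frame(snp_id = pan$snp_id, allele1 = "A", allele2 = "G",
                      stringsAsFactors = FALSE)
  obs <- data.frame(sample_id = "s", snp_id = pan$snp_id, coverage = 100L,
                    count_A = 60L, count_C = 0L, count_G = 40L, count_T = 0L,
                    lowq_minor_flag = FALSE)
  pr <- call_profile(obs, pan, sex = "F")
  rep0 <- concordance_report(pr, truth)
  expect_equal(rep0$n_compared, 100L)
  expect_equal(rep0$pct_concordant, 100)
  # one flipped reference genotype among 100
  truth1 <- truth; truth1$allele2[7] <- "A"
  rep1 <- concordance_report(pr, truth1)
  expect_equal(rep1$n_concordant, 99L)
  expect_equal(round(rep1$pct_concordant, 2), 99.00)
  # no-calls on either side are non-comparable
  obs2 <- obs; obs2$coverage[1:5] <- 4L
  obs2[1:5, c("count_A", "count_G")] <- cbind(rep(4L, 5), rep(0L, 5))
  pr2 <- call_profile(obs2, pan, sex = "F")
  rep2 <- concordance_report(pr2, truth)
  expect_equal(rep2$n_compared, 95L)
  expect_equal(rep2$n_non_comparable, 5L)
})

test_that("error-free high-coverage simulation recovers every true genotype", {
  pan <- h_fixture_panel()
  ped <- pedigree(id = "s", sex = "M")
  sim <- simulate_pedigree_genotypes(ped, pan, seed = 28)
  obs <- simulate_observations(sim, "s",
                               seq_params(mean_cov = 200, error_rate = 0,
                                          dropout_frac = 0, seed = 29))
  pr <- call_profile(obs, pan, sex = "M")
  d <- profile_dosages(pr, pan)
  called <- pr$sites$status == "called"
  expect_gt(mean(called), 0.95)
  expect_equal(unname(d[called]),
               unname(sim$dosage["s", pan$snp_id][called]),
               ignore_attr = TRUE, tolerance = 0)
})

test_that("heterozygote recovery degrades monotonically with falling coverage", {
  pan <- h_panel("1", seq_len(500), freq = 0.5)
  ped <- pedigree(id = "s", sex = "M")
  sim <- simulate_pedigree_genotypes(ped, pan, seed = 30)
  het <- which(sim$dosage["s", ] == 1)
  frac_het_called <- vapply(c(100, 30, 10), function(mu) {
    obs <- simulate_observations(sim, "s", seq_params(mean_cov = mu, seed = 31))
    pr <- call_profile(obs, pan, sex = "M")
    s <- pr$sites[match(pan$snp_id[het], pr$sites$snp_id), ]
    mean(s$status == "called" & s$allele1 != s$allele2)
  }, numeric(1))
  expect_true(all(diff(frac_het_called) <= 0))
})

test_that("profiles round-trip through the observation TSV and VCF writers", {
  pan <- h_fixture_panel()
  ped <- pedigree(id = "s", sex = "M")
  sim <- simulate_pedigree_genotypes(ped, pan, seed = 32)
  obs <- simulate_observations(sim, "s", seq_preset("reference", seed = 33))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(obs, f, sep = "\t", quote = FALSE, row.names = FALSE)
  obs2 <- read_observations(f)
  expect_equal(obs2$coverage, obs$coverage)
  expect_equal(obs2$count_G, obs$count_G)

  pr <- call_profile(obs, pan, sex = "M")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_profile_vcf(pr, pan, vcf)
  skip_if_not_installed("vcfR")
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  expect_equal(nrow(v@fix), nrow(pan))
  gt <- vcfR::extract.gt(v)
  called_dip <- pr$sites$status == "called" & !is.na(pr$sites$allele2)
  hom_alt <- called_dip & pr$sites$allele1 == pan$alt & pr$sites$allele2 == pan$alt
  expect_true(all(gt[hom_alt, 1] == "1/1"))
  imb <- pr$sites$status == "imbalanced"
  if (any(imb)) expect_true(all(v@fix[imb, "FILTER"] == "IMB"))
})
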