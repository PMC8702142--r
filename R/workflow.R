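#' Reference-family pedigrees of the bundled fixture
#'
#' Five family structures mirroring typical missing-person casework: each has
#' one missing person ("MP") and two or three typed references spanning first
#' to fifth degree relationships (daughter/son, sister, nephew, grandniece,
#' great-grandnephew/niece, first cousin twice removed).
#'
#' @return named list of [pedigree()] objects with attributes `typed`
#'   (reference ids), `missing` (`"MP"`), and `relationships` (reference id ->
#'   degree of relatedness to the missing person).
#' @export
fixture_pedigrees <- function() {
  fam <- list()

  # A: grandniece (3) + nephew (2)
  pA <- pedigree(
    id     = c("gf", "gm", "MP", "sib", "sibsp", "neph", "nephsp", "gniece"),
    father = c(NA, NA, "gf", "gf", NA, "sibsp", NA, "neph"),
    mother = c(NA, NA, "gm", "gm", NA, "sib", NA, "nephsp"),
    sex    = c("M", "F", "M", "F", "M", "M", "F", "F"))
  attr(pA, "typed") <- c("neph", "gniece")
  attr(pA, "relationships") <- c(neph = 2L, gniece = 3L)

  # B: nephew (2) + great-grandnephew (4) + great-grandniece (4)
  pB <- pedigree(
    id     = c("gf", "gm", "MP", "sib", "sibsp", "neph", "nephsp", "gn", "gnsp",
               "ggneph", "ggniece"),
    father = c(NA, NA, "gf", "gf", NA, "sibsp", NA, "neph", NA, "gn", "gn"),
    mother = c(NA, NA, "gm", "gm", NA, "sib", NA, "nephsp", NA, "gnsp", "gnsp"),
    sex    = c("M", "F", "M", "F", "M", "M", "F", "M", "F", "M", "F"))
  attr(pB, "typed") <- c("neph", "ggneph", "ggniece")
  attr(pB, "relationships") <- c(neph = 2L, ggneph = 4L, ggniece = 4L)

  # C: daughter (1) + nephew (2) + first cousin twice removed (5)
  pC <- pedigree(
    id     = c("ggf", "ggm", "gf", "gm", "uncle", "unclesp", "cous", "coussp",
               "c1r", "c1rsp", "c2r", "MP", "sib", "sibsp", "neph", "mpsp", "dau"),
    father = c(NA, NA, "ggf", NA, "ggf", NA, "uncle", NA, "cous", NA, "c1r",
               "gf", "gf", NA, "sibsp", NA, "MP"),
    mother = c(NA, NA, "ggm", NA, "ggm", NA, "unclesp", NA, "coussp", NA, "c1rsp",
               "gm", "gm", NA, "sib", NA, "mpsp"),
    sex    = c("M", "F", "M", "F", "M", "F", "M", "F", "M", "F", "M",
               "M", "F", "M", "M", "F", "F"))
  attr(pC, "typed") <- c("dau", "neph", "c2r")
  attr(pC, "relationships") <- c(dau = 1L, neph = 2L, c2r = 5L)

  # D: sister (1) + grandniece (3); the sister-brother pair is X-informative
  pD <- pedigree(
    id     = c("gf", "gm", "MP", "sis", "sissp", "niece", "niecesp", "gniece"),
    father = c(NA, NA, "gf", "gf", NA, "sissp", NA, "niecesp"),
    mother = c(NA, NA, "gm", "gm", NA, "sis", NA, "niece"),
    sex    = c("M", "F", "M", "F", "M", "F", "M", "F"))
  attr(pD, "typed") <- c("sis", "gniece")
  attr(pD, "relationships") <- c(sis = 1L, gniece = 3L)

  # E: son (1) + daughter (1)
  pE <- pedigree(
    id     = c("MP", "mpsp", "son", "dau"),
    father = c(NA, NA, "MP", "MP"),
    mother = c(NA, NA, "mpsp", "mpsp"),
    sex    = c("M", "F", "M", "F"))
  attr(pE, "typed") <- c("son", "dau")
  attr(pE, "relationships") <- c(son = 1L, dau = 1L)

  fam <- list(A = pA, B = pB, C = pC, D = pD, E = pE)
  for (nm in names(fam)) attr(fam[[nm]], "missing") <- "MP"
  fam
}

#' Generate a self-contained analysis fixture
#'
#' Writes a miniature but complete input set to a directory: a panel manifest
#' (about a tenth of full scale), the genetic map, the five reference-family
#' pedigrees, a Y-haplogroup table, a phenotype effect-allele table, and
#' simulated sequencing observations -- reference-quality samples for every
#' typed family member and a degraded ("bone") sample for every missing
#' person. Regenerating with the same seed reproduces the files byte for
#' byte.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param n_kinship,n_ii,n_ai,n_pi,n_x,n_y fixture panel scale.
#' @return invisibly, the directory path.
#' @export
make_fixture <- function(dir, seed = 1, n_kinship = 400, n_ii = 40, n_ai = 40,
                         n_pi = 20, n_x = 30, n_y = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- synthetic_panel(n_kinship = n_kinship, n_ii = n_ii, n_ai = n_ai,
                           n_pi = n_pi, n_x = n_x, n_y = n_y,
                           seed = .fk_child_seed(seed, 1))
  write_panel(panel, file.path(dir, "panel.tsv"))
  map <- synthetic_genetic_map()
  .fk_write_tsv(as.data.frame(map), file.path(dir, "map.tsv"))
  ytree <- synthetic_y_tree(panel, seed = .fk_child_seed(seed, 2))
  .fk_write_tsv(as.data.frame(ytree), file.path(dir, "y_tree.tsv"))

  # synthetic phenotype effect-allele table (alt allele as effect, ~1/4 on the
  # minus strand, as marker tables mix orientations)
  set.seed(.fk_child_seed(seed, 3))
  pis <- panel[panel$category == "piSNP", ]
  eff <- data.frame(snp_id = pis$snp_id,
                    effect_allele = pis$alt,
                    strand = sample(c("+", "-"), nrow(pis), TRUE, prob = c(0.75, 0.25)),
                    stringsAsFactors = FALSE)
  eff$effect_allele[eff$strand == "-"] <- unname(.fk_complement[eff$effect_allele[eff$strand == "-"]])
  .fk_write_tsv(eff, file.path(dir, "hirisplex_effect_alleles.tsv"))

  fams <- fixture_pedigrees()
  ped_lines <- character(0)
  obs <- list()
  for (nm in names(fams)) {
    ped <- fams[[nm]]
    f <- tempfile()
    write_pedigree(ped, f, family = nm)
    ped_lines <- c(ped_lines, readLines(f))
    truth <- simulate_pedigree_genotypes(ped, panel, pop = "EUR",
                                         seed = .fk_child_seed(seed, 10 + match(nm, names(fams))))
    for (id in attr(ped, "typed")) {
      obs[[paste0(nm, "_", id)]] <- simulate_observations(
        truth, id, seq_preset("reference", seed = .fk_child_seed(seed, 100 + length(obs))),
        sample_id = paste0(nm, "_", id))
    }
    obs[[paste0(nm, "_unknown")]] <- simulate_observations(
      truth, attr(ped, "missing"),
      seq_preset("bone", seed = .fk_child_seed(seed, 100 + length(obs))),
      sample_id = paste0(nm, "_unknown"))
  }
  writeLines(ped_lines, file.path(dir, "families.ped"))
  .fk_write_tsv(do.call(rbind, obs), file.path(dir, "observations.tsv"))

  sexes <- do.call(rbind, lapply(names(fams), function(nm) {
    ped <- fams[[nm]]
    ids <- c(attr(ped, "typed"), attr(ped, "missing"))
    data.frame(sample_id = paste0(nm, "_", ifelse(ids == "MP", "unknown", ids)),
               family = nm, individual = ids,
               sex = ped$sex[match(ids, ped$id)], stringsAsFactors = FALSE)
  }))
  .fk_write_tsv(sexes, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' Assemble and validate a run configuration
#'
#' Paths plus analysis thresholds with the workflow defaults: calling coverage
#' 10X, homozygote threshold 0.90, heterozygote minor-allele threshold 0.30,
#' strong-support criteria LR >= 10,000 and posterior >= 99.99%.
#'
#' @param fixture_dir directory holding `panel.tsv`, `map.tsv`,
#'   `families.ped`, `observations.tsv`, `samples.tsv`, `y_tree.tsv`,
#'   `hirisplex_effect_alleles.tsv` (as written by [make_fixture()]).
#' @param out_dir output directory for report tables.
#' @param pop analysis population.
#' @param min_cov,hom_max,het_min calling thresholds.
#' @param strong_log10_lr,strong_posterior strong-support criteria.
#' @param seed seed recorded with outputs.
#' @return a validated `run_config` list.
#' @export
run_config <- function(fixture_dir, out_dir, pop = "EUR",
                       min_cov = 10, hom_max = 0.10, het_min = 0.30,
                       strong_log10_lr = 4, strong_posterior = 0.9999, seed = 1) {
  need <- c("panel.tsv", "map.tsv", "families.ped", "observations.tsv",
            "samples.tsv", "y_tree.tsv", "hirisplex_effect_alleles.tsv")
  missing_files <- need[!file.exists(file.path(fixture_dir, need))]
  if (length(missing_files))
    .fk_stopf("run_config: missing input file(s): %s", paste(missing_files, collapse = ", "))
  structure(list(fixture_dir = fixture_dir, out_dir = out_dir, pop = pop,
                 min_cov = min_cov, hom_max = hom_max, het_min = het_min,
                 strong_log10_lr = strong_log10_lr,
                 strong_posterior = strong_posterior, seed = seed),
            class = "run_config")
}

#' Run the full workflow on a fixture directory
#'
#' Calls every sample's profile from its observations, tabulates completeness,
#' computes pairwise (unknown vs each family reference) and missing-person
#' pedigree likelihood ratios with linkage, an X-chromosomal sibling LR where
#' the family holds a typed sibling pair, and ancestry / Y-haplogroup /
#' phenotype-encoding predictions for the unknowns. All tables are written as
#' TSV with a header recording the package version and resolved thresholds;
#' results are deterministic given the fixture.
#'
#' @param config a [run_config()] object.
#' @return invisibly, a list with `completeness`, `pairwise`, `pedigree_lr`,
#'   `x_lr`, `ancestry`, `yhap`, `phenotype` tables.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .fk_header_comment(sprintf(
    "pop=%s min_cov=%d hom_max=%.2f het_min=%.2f strong: log10LR>=%g posterior>=%g seed=%d",
    config$pop, config$min_cov, config$hom_max, config$het_min,
    config$strong_log10_lr, config$strong_posterior, config$seed))
  fd <- config$fixture_dir

  panel <- read_panel(file.path(fd, "panel.tsv"))
  obs_all <- read_observations(file.path(fd, "observations.tsv"))
  samples <- .fk_read_tsv(file.path(fd, "samples.tsv"))
  ytree <- read_y_tree(file.path(fd, "y_tree.tsv"))
  eff <- .fk_read_tsv(file.path(fd, "hirisplex_effect_alleles.tsv"))
  fcol <- paste0("freq_", config$pop)
  markers_kin <- data.frame(chrom = panel$chrom, pos_cm = panel$pos_cm,
                            freq = panel[[fcol]])[panel$category == "kinship", ]
  kin_sel <- panel$category == "kinship"
  x_sel <- panel$category == "X"
  markers_x <- data.frame(chrom = panel$chrom, pos_cm = panel$pos_cm,
                          freq = panel[[fcol]])[x_sel, ]

  profiles <- list()
  for (sid in unique(obs_all$sample_id)) {
    sex <- samples$sex[match(sid, samples$sample_id)]
    profiles[[sid]] <- call_profile(obs_all[obs_all$sample_id == sid, ], panel,
                                    sex = ifelse(is.na(sex), "unknown", sex),
                                    min_cov = config$min_cov,
                                    hom_max = config$hom_max, het_min = config$het_min)
  }
  completeness <- do.call(rbind, lapply(profiles, function(pr)
    data.frame(sample_id = pr$sample_id, sex = pr$sex,
               n_called = pr$metrics$n_called,
               max_callable = pr$metrics$max_callable,
               pct_called = round(pr$metrics$pct_called, 2),
               mean_cov_called = round(pr$metrics$mean_cov_called, 1),
               stringsAsFactors = FALSE)))
  rownames(completeness) <- NULL
  .fk_write_tsv(completeness, file.path(config$out_dir, "completeness.tsv"), hdr)

  dosages <- lapply(profiles, profile_dosages, panel = panel)
  fams <- unique(samples$family)
  hyps <- relationship_hypotheses()
  deg2hyp <- function(d) hyps$name[match(d, hyps$degree)]

  pairwise <- list(); pedlr <- list(); xlr <- list()
  for (fam in fams) {
    sf <- samples[samples$family == fam, ]
    unk_sid <- sf$sample_id[sf$individual == "MP"]
    refs <- sf[sf$individual != "MP", ]
    ped <- read_pedigree(file.path(fd, "families.ped"), family = fam)
    unk <- dosages[[unk_sid]]
    for (r in seq_len(nrow(refs))) {
      rsid <- refs$sample_id[r]
      # test the expected relationship hypothesis for this reference
      hyp_name <- .fk_expected_hypothesis(ped, refs$individual[r], deg2hyp)
      res <- pairwise_lr(unk[kin_sel], dosages[[rsid]][kin_sel], hyp_name, markers_kin)
      res$strong_support <- is.finite(res$log10_lr) &
        res$log10_lr >= config$strong_log10_lr &
        res$posterior >= config$strong_posterior
      pairwise[[paste(fam, rsid)]] <- cbind(
        data.frame(family = fam, unknown = unk_sid, reference = rsid,
                   stringsAsFactors = FALSE), res)
    }
    refmat <- do.call(rbind, lapply(refs$sample_id, function(s) dosages[[s]][kin_sel]))
    rownames(refmat) <- refs$individual
    mp <- missing_person_lr(ped, refmat, "MP", unk[kin_sel], markers_kin)
    mp$strong_support <- is.finite(mp$log10_lr) &
      mp$log10_lr >= config$strong_log10_lr & mp$posterior >= config$strong_posterior
    pedlr[[fam]] <- cbind(data.frame(family = fam, unknown = unk_sid,
                                     stringsAsFactors = FALSE), mp)
    # X sibling comparison where a typed full sibling of the unknown exists
    sib <- refs$individual[.fk_is_full_sib(ped, "MP", refs$individual)]
    if (length(sib)) {
      rsid <- refs$sample_id[match(sib[1], refs$individual)]
      xres <- x_chromosome_lr(unk[x_sel], dosages[[rsid]][x_sel],
                              sexA = sf$sex[sf$individual == "MP"],
                              sexB = refs$sex[match(sib[1], refs$individual)],
                              markers = markers_x)
      xlr[[fam]] <- cbind(data.frame(family = fam, unknown = unk_sid,
                                     reference = rsid, stringsAsFactors = FALSE), xres)
    }
  }
  pairwise <- do.call(rbind, pairwise); rownames(pairwise) <- NULL
  pedlr <- do.call(rbind, pedlr); rownames(pedlr) <- NULL
  xlr <- if (length(xlr)) do.call(rbind, xlr) else NULL
  .fk_write_tsv(pairwise, file.path(config$out_dir, "pairwise_lr.tsv"), hdr)
  .fk_write_tsv(pedlr, file.path(config$out_dir, "pedigree_lr.tsv"), hdr)
  if (!is.null(xlr)) .fk_write_tsv(xlr, file.path(config$out_dir, "x_lr.tsv"), hdr)

  # predictions for the unknowns
  ai_ref <- panel[panel$category == "aiSNP", c("snp_id", .fk_freq_cols)]
  anc <- list(); yh <- list(); phe <- list()
  for (fam in fams) {
    sid <- samples$sample_id[samples$family == fam & samples$individual == "MP"]
    pr <- profiles[[sid]]
    d <- dosages[[sid]]
    ai <- d[panel$category == "aiSNP"]
    a <- tryCatch(ancestry_naive_bayes(ai, ai_ref), error = function(e) NULL)
    if (!is.null(a))
      anc[[fam]] <- data.frame(family = fam, sample_id = sid,
                               top = a$top, n_snps = a$n_snps_used,
                               t(round(a$posterior, 4)), stringsAsFactors = FALSE)
    ycalls <- pr$sites[pr$sites$category == "Y" & pr$sites$status == "called",
                       c("snp_id", "allele1")]
    names(ycalls) <- c("snp_id", "allele")
    if (nrow(ycalls)) {
      yres <- assign_y_haplogroup(ycalls, ytree)
      yh[[fam]] <- data.frame(family = fam, sample_id = sid,
                              haplogroup = yres$haplogroup,
                              n_derived = yres$n_derived,
                              n_conflicts = length(yres$conflicts),
                              stringsAsFactors = FALSE)
    }
    phe[[sid]] <- encode_hirisplex(pr, eff)
  }
  anc <- if (length(anc)) do.call(rbind, anc) else NULL
  yh <- if (length(yh)) do.call(rbind, yh) else NULL
  if (!is.null(anc)) .fk_write_tsv(anc, file.path(config$out_dir, "ancestry.tsv"), hdr)
  if (!is.null(yh)) .fk_write_tsv(yh, file.path(config$out_dir, "y_haplogroups.tsv"), hdr)
  write_hirisplex_batch(phe, file.path(config$out_dir, "hirisplex_batch.csv"))

  invisible(list(completeness = completeness, pairwise = pairwise,
                 pedigree_lr = pedlr, x_lr = xlr, ancestry = anc, yhap = yh,
                 phenotype = phe))
}

# degree of relatedness between a reference individual and the missing person
# slot "MP", from the kinship coefficient implied by the pedigree paths
.fk_ref_degree <- function(ped, ref_id) {
  # kinship coefficient by recursive pairwise formula
  n <- nrow(ped)
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  phi <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    phi[i, j] <- phi[j, i] <- if (i == j) {
      0.5 + 0.5 * (if (is.na(fa[i])) 0 else phi[fa[i], mo[i]])
    } else {
      # j precedes i in topological order
      if (is.na(fa[i])) 0 else 0.5 * (phi[fa[i], j] + phi[mo[i], j])
    }
  }
  k <- phi[match("MP", ped$id), match(ref_id, ped$id)]
  max(1L, round(-log2(k) - 1))
}

# expected pairwise hypothesis for a reference: distinguish the two
# first-degree templates, otherwise map the degree of relatedness
.fk_expected_hypothesis <- function(ped, ref_id, deg2hyp) {
  i <- match("MP", ped$id); j <- match(ref_id, ped$id)
  po <- identical(ped$father[j], "MP") || identical(ped$mother[j], "MP") ||
    identical(ped$father[i], ref_id) || identical(ped$mother[i], ref_id)
  if (po) return("parent_offspring")
  if (.fk_is_full_sib(ped, "MP", ref_id)) return("full_siblings")
  deg2hyp(min(6L, .fk_ref_degree(ped, ref_id)))
}

.fk_is_full_sib <- function(ped, a, ids) {
  ia <- match(a, ped$id); ib <- match(ids, ped$id)
  !is.na(ped$father[ib]) & !is.na(ped$father[ia]) &
    ped$father[ib] == ped$father[ia] & ped$mother[ib] == ped$mother[ia]
}
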