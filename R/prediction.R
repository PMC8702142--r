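#' Naive Bayes biogeographic ancestry prediction
#'
#' For each continental population, the log-likelihood of the called
#' ancestry-informative genotypes is the sum of log Hardy-Weinberg genotype
#' probabilities under that population's allele frequencies (clamped away from
#' 0 and 1); flat-prior posteriors normalize the likelihoods. Markers absent
#' from the reference are excluded.
#'
#' @param dosages named alt-allele dosage vector for the profile's aiSNPs
#'   (`NA` = not called).
#' @param ref data frame with `snp_id` and one `freq_<POP>` column per
#'   population (the ancestry reference).
#' @return list: `posterior` (named, sums to 1), `log10_lik`, `n_snps_used`,
#'   `top` (the highest-posterior population).
#' @export
ancestry_naive_bayes <- function(dosages, ref) {
  pops <- sub("^freq_", "", grep("^freq_", names(ref), value = TRUE))
  i <- match(names(dosages), ref$snp_id)
  usable <- !is.na(i) & !is.na(dosages)
  if (!any(usable)) .fk_stopf("no called aiSNPs overlap the ancestry reference")
  g <- as.integer(dosages[usable])
  ll <- vapply(pops, function(pop) {
    p <- .fk_clamp_freq(ref[[paste0("freq_", pop)]][i[usable]])
    sum(log10(.fk_hwe_prob(g, p)))
  }, numeric(1))
  post <- 10^(ll - .fk_log10_sum(ll))
  post <- post / sum(post)
  list(posterior = post, log10_lik = ll, n_snps_used = sum(usable),
       top = names(post)[which.max(post)])
}

#' Project profiles onto reference principal components
#'
#' Trains a PCA on a reference genotype matrix (individuals x markers,
#' dosages; missing entries mean-imputed per marker, columns centred and
#' scaled by the reference statistics) and projects query profiles into the
#' same space with reference-mean imputation of their missing markers.
#'
#' @param ref_matrix reference dosage matrix with column names = snp ids;
#'   optional `rownames` = individual ids.
#' @param ref_labels population label per reference row (optional, carried
#'   through to the output).
#' @param query named dosage vector, or matrix with one query per row.
#' @param n_pc number of components returned.
#' @param min_overlap minimum fraction of reference markers the query must
#'   share.
#' @return list: `reference` (data frame of reference coordinates + labels),
#'   `query` (data frame of query coordinates), `sdev` (component standard
#'   deviations).
#' @export
ancestry_pca <- function(ref_matrix, ref_labels = NULL, query = NULL,
                         n_pc = 2, min_overlap = 0.5) {
  mu <- colMeans(ref_matrix, na.rm = TRUE)
  X <- ref_matrix
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  sdv <- apply(X, 2, stats::sd)
  if (all(sdv == 0)) .fk_stopf("reference genotype matrix is constant")
  keep <- sdv > 0
  X <- X[, keep, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  n_pc <- min(n_pc, ncol(pc$x))
  refco <- as.data.frame(pc$x[, seq_len(n_pc), drop = FALSE])
  if (!is.null(ref_labels)) refco$population <- ref_labels
  out <- list(reference = refco, sdev = pc$sdev)
  if (!is.null(query)) {
    if (is.null(dim(query))) query <- matrix(query, nrow = 1,
                                             dimnames = list("query", names(query)))
    q <- query[, colnames(X), drop = FALSE]
    shared <- rowMeans(!is.na(q))
    if (any(shared < min_overlap))
      .fk_stopf("query shares only %.0f%% of reference markers (min %d%%)",
                100 * min(shared), round(100 * min_overlap))
    for (j in seq_len(ncol(q))) q[is.na(q[, j]), j] <- mu[keep][j]
    qs <- scale(q, center = pc$center, scale = pc$scale)
    out$query <- as.data.frame((qs %*% pc$rotation)[, seq_len(n_pc), drop = FALSE])
  }
  out
}

#' Simulate an ancestry reference genotype matrix
#'
#' Draws reference individuals per population under Hardy-Weinberg from the
#' panel's population frequencies (aiSNP rows), for PCA training and method
#' checks.
#'
#' @param panel an `fk_panel` (its aiSNP rows are used).
#' @param n_per_pop individuals per population.
#' @param seed RNG seed.
#' @return list: `matrix` (dosages), `labels` (population per row).
#' @export
synthetic_ancestry_reference <- function(panel, n_per_pop = 50, seed = 1) {
  set.seed(seed)
  ai <- panel[panel$category == "aiSNP", , drop = FALSE]
  mats <- lapply(FK_POPULATIONS, function(pop) {
    p <- ai[[paste0("freq_", pop)]]
    matrix(rbinom(n_per_pop * nrow(ai), 2, rep(p, each = n_per_pop)),
           nrow = n_per_pop, dimnames = list(NULL, ai$snp_id))
  })
  list(matrix = do.call(rbind, mats),
       labels = rep(FK_POPULATIONS, each = n_per_pop))
}

# ---------------------------------------------------------------------------
# Y haplogroup assignment
# ---------------------------------------------------------------------------

#' Read a Y-haplogroup marker table
#'
#' Rows of (`snp_id`, `haplogroup`, `parent`, `ancestral`, `derived`): each
#' Y-SNP defines one haplogroup whose derived allele marks membership; the
#' parent relation over haplogroup labels must form a tree with a single root
#' (parent = `"ROOT"`).
#'
#' @param path TSV path.
#' @return validated `fk_ytree` data frame.
#' @export
read_y_tree <- function(path) {
  d <- .fk_read_tsv(path)
  .fk_validate_ytree(d)
}

.fk_validate_ytree <- function(d) {
  need <- c("snp_id", "haplogroup", "parent", "ancestral", "derived")
  miss <- setdiff(need, names(d))
  if (length(miss)) .fk_stopf("Y tree: missing columns %s", paste(miss, collapse = ", "))
  hg <- unique(d$haplogroup)
  par <- d$parent[match(hg, d$haplogroup)]
  if (sum(par == "ROOT") < 1L) .fk_stopf("Y tree has no root")
  bad <- par[par != "ROOT" & !(par %in% hg)]
  if (length(bad)) .fk_stopf("Y tree: parent haplogroup(s) missing: %s",
                             paste(unique(bad), collapse = ", "))
  # acyclicity: walking up from every node must reach ROOT
  for (h in hg) {
    seen <- character(0); cur <- h
    while (cur != "ROOT") {
      if (cur %in% seen) .fk_stopf("Y tree: cycle at haplogroup %s", cur)
      seen <- c(seen, cur)
      cur <- par[match(cur, hg)]
    }
  }
  class(d) <- c("fk_ytree", "data.frame")
  d
}

# root path (ROOT-ward, inclusive) of a haplogroup label
.fk_y_path <- function(tree, h) {
  hg <- unique(tree$haplogroup)
  par <- tree$parent[match(hg, tree$haplogroup)]
  path <- character(0)
  while (h != "ROOT") {
    path <- c(h, path)
    h <- par[match(h, hg)]
  }
  path
}

#' Assign a Y-chromosome haplogroup from called Y-SNPs
#'
#' Marks every haplogroup with at least one derived call, then reports the
#' most refined haplogroup maximizing (derived markers on its root path) minus
#' (derived markers off the path); ties break toward the shallower haplogroup.
#' Off-path derived calls are listed as conflicts and on-path ancestral calls
#' as inconsistencies (possible back-mutations) for manual review.
#'
#' @param calls data frame with `snp_id` and `allele` (the called Y allele).
#' @param tree an `fk_ytree` table.
#' @return list: `haplogroup`, `score`, `n_derived`, `supporting`
#'   (on-path derived snp ids), `conflicts` (off-path derived),
#'   `inconsistencies` (on-path ancestral).
#' @export
assign_y_haplogroup <- function(calls, tree) {
  if (!nrow(calls)) .fk_stopf("no called Y-SNPs supplied")
  i <- match(calls$snp_id, tree$snp_id)
  use <- !is.na(i)
  calls <- calls[use, , drop = FALSE]; i <- i[use]
  derived <- calls$allele == tree$derived[i]
  ancestral <- calls$allele == tree$ancestral[i]
  hg_der <- unique(tree$haplogroup[i[derived]])
  if (!length(hg_der))
    return(list(haplogroup = "ROOT", score = 0L, n_derived = 0L,
                supporting = character(0), conflicts = character(0),
                inconsistencies = character(0)))
  der_by_hg <- table(tree$haplogroup[i[derived]])
  # candidates: haplogroups with derived support, scored along their root path
  depth <- vapply(hg_der, function(h) length(.fk_y_path(tree, h)), integer(1))
  score <- vapply(hg_der, function(h) {
    path <- .fk_y_path(tree, h)
    on <- sum(der_by_hg[names(der_by_hg) %in% path])
    sum(der_by_hg) - 2L * (sum(der_by_hg) - on) # on-path minus off-path
  }, integer(1))
  best <- hg_der[order(-score, depth)][1]
  path <- .fk_y_path(tree, best)
  on_path_snp <- tree$haplogroup[i] %in% path
  list(haplogroup = best,
       score = max(score),
       n_derived = sum(derived),
       supporting = calls$snp_id[derived & on_path_snp],
       conflicts = calls$snp_id[derived & !on_path_snp],
       inconsistencies = calls$snp_id[ancestral & on_path_snp])
}

#' Generate a synthetic Y-haplogroup tree for a panel
#'
#' Builds a balanced tree over major clade labels and assigns each panel Y-SNP
#' to one haplogroup, with ancestral = ref and derived = alt allele.
#'
#' @param panel an `fk_panel` (its Y rows are used).
#' @param n_major number of top-level clades.
#' @param depth tree depth below the major clades.
#' @param seed RNG seed.
#' @return an `fk_ytree` data frame.
#' @export
synthetic_y_tree <- function(panel, n_major = 5, depth = 3, seed = 1) {
  set.seed(seed)
  ysnp <- panel[panel$category == "Y", , drop = FALSE]
  # shrink the tree until every node can carry at least one defining SNP
  n_nodes <- function(d) n_major * (2^(d + 1) - 1)
  while (depth > 0 && n_nodes(depth) > nrow(ysnp)) depth <- depth - 1L
  labels <- LETTERS[seq_len(n_major)]
  nodes <- data.frame(haplogroup = labels, parent = "ROOT", stringsAsFactors = FALSE)
  frontier <- labels
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (h in frontier) for (k in 1:2) {
      child <- paste0(h, k)
      nodes <- rbind(nodes, data.frame(haplogroup = child, parent = h))
      nxt <- c(nxt, child)
    }
    frontier <- nxt
  }
  # one defining SNP per haplogroup, the remainder spread at random
  hg <- c(nodes$haplogroup,
          sample(nodes$haplogroup, nrow(ysnp) - nrow(nodes), replace = TRUE))
  hg <- sample(hg)
  .fk_validate_ytree(data.frame(
    snp_id = ysnp$snp_id, haplogroup = hg,
    parent = nodes$parent[match(hg, nodes$haplogroup)],
    ancestral = ysnp$ref, derived = ysnp$alt, stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
# phenotype genotype encoding
# ---------------------------------------------------------------------------

.fk_complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Encode phenotype-marker genotypes as effect-allele counts
#'
#' Converts called piSNP genotypes into the orientation of an effect-allele
#' table and counts effect alleles per marker: `0`, `1`, `2`, or `NA` for
#' no-call/imbalanced sites. Markers annotated on the minus strand are
#' complemented before counting, so the output matches the upload orientation
#' of the phenotype-prediction webtool.
#'
#' @param profile a `called_profile`.
#' @param effect_table data frame `snp_id`, `effect_allele`, `strand`
#'   (`"+"`/`"-"` relative to the panel's reported orientation).
#' @return named integer vector (one entry per effect-table marker).
#' @export
encode_hirisplex <- function(profile, effect_table) {
  s <- profile$sites
  i <- match(effect_table$snp_id, s$snp_id)
  if (anyNA(i)) .fk_stopf("profile lacks phenotype marker(s): %s",
                          paste(effect_table$snp_id[is.na(i)], collapse = ", "))
  out <- rep(NA_integer_, nrow(effect_table))
  for (r in seq_len(nrow(effect_table))) {
    site <- s[i[r], ]
    if (is.na(site$status) || site$status != "called") next
    a <- c(site$allele1, site$allele2)
    a <- a[!is.na(a)]
    if (effect_table$strand[r] == "-") a <- unname(.fk_complement[a])
    out[r] <- sum(a == effect_table$effect_allele[r])
  }
  names(out) <- effect_table$snp_id
  out
}

#' Write a phenotype-webtool batch upload file
#'
#' One row per sample, columns `sampleid` then one encoded genotype per
#' phenotype marker (`NA` written as `"NA"`).
#'
#' @param encodings named list: sample id -> vector from [encode_hirisplex()].
#' @param path output file (comma-separated).
#' @export
write_hirisplex_batch <- function(encodings, path) {
  stopifnot(length(encodings) > 0)
  snps <- names(encodings[[1]])
  rows <- vapply(names(encodings), function(id) {
    paste(c(id, ifelse(is.na(encodings[[id]]), "NA", encodings[[id]])), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("sampleid", snps), collapse = ","), rows), path)
  invisible(path)
}
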