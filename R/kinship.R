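#' Haldane map function
#'
#' Converts a genetic map distance in centimorgans to a recombination fraction
#' assuming no crossover interference: theta = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d non-negative map distance in cM (vectorised).
#' @return recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane_theta(c(0, 50))
#' @export
haldane_theta <- function(d) {
  if (any(d < 0)) .fk_stopf("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}

# ---------------------------------------------------------------------------
# descent structure: which founder allele each typed allele position carries,
# for every inheritance-vector state
# ---------------------------------------------------------------------------

.fk_ped_signature <- function(ped, typed, mode) {
  paste(c(mode, ped$id, ped$father, ped$mother, ped$sex, "|", typed), collapse = "\r")
}

# Builds, for a pedigree and a set of typed individuals, the matrix of founder
# allele slots occupied by each typed allele position under every inheritance
# vector. Autosomal mode: two bits per non-founder meiosis. X mode: one bit
# per non-founder (the maternal meiosis); father-to-daughter transmission is
# deterministic and males are hemizygous.
.fk_descent <- function(ped, typed, mode = "autosomal") {
  key <- .fk_ped_signature(ped, typed, mode)
  hit <- .fk_cache[[key]]
  if (!is.null(hit)) return(hit)

  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  founder <- is.na(fa)
  nf <- which(!founder)
  male <- ped$sex == "M"
  if (!mode %in% c("autosomal", "X")) .fk_stopf("unknown mode '%s'", mode)

  # A meiosis from an untyped founder with a single child is "silent": the
  # founder's two allele slots are reachable only through that one meiosis,
  # so either choice yields the same descent partition of typed alleles.
  # Silent meioses get no inheritance-vector bit (the choice is fixed), which
  # collapses e.g. every married-in spouse of a relationship template.
  n_children <- tabulate(c(fa, mo)[!is.na(c(fa, mo))], nbins = n)
  silent_parent <- founder & !(ped$id %in% typed) & n_children == 1L

  # assign bit indices to the non-silent meioses
  bit_pat <- rep(NA_integer_, n); bit_mat <- rep(NA_integer_, n)
  nbits <- 0L
  for (i in nf) {
    if (mode == "autosomal" && !silent_parent[fa[i]]) {
      nbits <- nbits + 1L; bit_pat[i] <- nbits
    }
    if (!silent_parent[mo[i]]) {
      nbits <- nbits + 1L; bit_mat[i] <- nbits
    }
  }
  if (nbits > 16L)
    .fk_stopf("pedigree has %d modeled meioses after spouse collapsing; the engine supports at most 16", nbits)
  ns <- bitwShiftL(1L, nbits)
  states <- 0:(ns - 1)
  bitval <- function(b) {
    if (is.na(b)) rep(FALSE, ns) else bitwAnd(states, bitwShiftL(1L, b - 1L)) != 0L
  }

  SP <- matrix(NA_integer_, ns, n) # paternal-origin slot per individual
  SM <- matrix(NA_integer_, ns, n) # maternal-origin slot
  if (mode == "autosomal") {
    slot <- 0L
    for (i in which(founder)) {
      SP[, i] <- slot + 1L; SM[, i] <- slot + 2L; slot <- slot + 2L
    }
    for (i in nf) {
      bp <- bitval(bit_pat[i]); bm <- bitval(bit_mat[i])
      SP[, i] <- ifelse(bp, SM[, fa[i]], SP[, fa[i]])
      SM[, i] <- ifelse(bm, SM[, mo[i]], SP[, mo[i]])
    }
  } else {
    # X: males carry a single maternally inherited X (stored in SM)
    slot <- 0L
    for (i in which(founder)) {
      if (male[i]) { SM[, i] <- slot + 1L; slot <- slot + 1L }
      else { SP[, i] <- slot + 1L; SM[, i] <- slot + 2L; slot <- slot + 2L }
    }
    for (i in nf) {
      bm <- bitval(bit_mat[i])
      SM[, i] <- ifelse(bm, SM[, mo[i]], SP[, mo[i]])
      if (!male[i]) SP[, i] <- SM[, fa[i]] # father's single X, unrecombined
    }
    SP[, male] <- NA_integer_
  }

  ti <- match(typed, ped$id)
  if (anyNA(ti)) .fk_stopf("typed individual absent from pedigree: %s",
                           paste(typed[is.na(ti)], collapse = ", "))
  pos <- list(); owner <- integer(0); haploid <- logical(0)
  for (q in seq_along(ti)) {
    i <- ti[q]
    if (mode == "X" && male[i]) {
      pos <- c(pos, list(SM[, i])); owner <- c(owner, q); haploid <- c(haploid, TRUE)
    } else {
      pos <- c(pos, list(SP[, i]), list(SM[, i]))
      owner <- c(owner, q, q); haploid <- c(haploid, FALSE, FALSE)
    }
  }
  out <- list(nbits = nbits, ns = ns, typed = typed,
              positions = do.call(cbind, pos), owner = owner, haploid = haploid,
              male = male[ti])
  .fk_cache[[key]] <- out
  out
}

# Partition classes of the typed allele positions for one missingness pattern
# (logical vector over typed individuals). Two states are equivalent iff their
# descent partitions of the present positions coincide; the emission then
# depends on the state only through the class.
.fk_classes <- function(descent, present, key = NULL) {
  if (!is.null(key)) {
    hit <- .fk_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  sel <- descent$owner %in% which(present)
  P <- descent$positions[, sel, drop = FALSE]
  np <- ncol(P)
  ns <- descent$ns
  if (np == 0L) {
    out <- list(cls = rep(1L, ns), blocks = list(list()), owner = integer(0),
                haploid = logical(0), nclass = 1L)
  } else {
    code <- rep(0, ns)
    bmat <- matrix(0L, ns, np)
    for (i in seq_len(np)) {
      b <- rep.int(i, ns)
      if (i > 1L) for (j in (i - 1L):1L) b[P[, j] == P[, i]] <- j
      bmat[, i] <- b
      code <- code * (np + 1) + b
    }
    uc <- unique(code)
    cls <- match(code, uc)
    rep_state <- match(uc, code)
    blocks <- lapply(rep_state, function(s) unname(split(seq_len(np), bmat[s, ])))
    out <- list(cls = cls, blocks = blocks,
                owner = match(descent$owner[sel], which(present)),
                haploid = descent$haploid[sel], nclass = length(uc))
  }
  if (!is.null(key)) .fk_cache[[key]] <- out
  out
}

# Emission probabilities per class, vectorised over markers.
# blocks: list (per class) of lists of position index blocks; G: k x nm dosage
# matrix for the present typed individuals (no NAs); p: alt allele frequency
# per marker; owner/haploid: per position. Sums over the phase orderings of
# each diploid genotype; each descent block contributes one founder allele
# frequency factor.
.fk_class_emissions <- function(blocks, G, p, owner, haploid) {
  nm <- length(p)
  nclass <- length(blocks)
  np <- length(owner)
  if (np == 0L) return(matrix(1, nclass, nm))
  ind_hap <- tapply(haploid, owner, any)[as.character(seq_len(nrow(G)))]
  dip <- which(!ind_hap)
  first_pos <- !duplicated(owner)
  # homozygous diploid genotypes are counted twice by the flip enumeration
  nhom <- if (length(dip)) colSums(G[dip, , drop = FALSE] != 1L) else rep(0L, nm)
  CP <- matrix(0, nclass, nm)
  A <- matrix(0L, np, nm)
  nflip <- bitwShiftL(1L, length(dip))
  for (f in 0:(nflip - 1L)) {
    flip <- as.logical(bitwAnd(f, bitwShiftL(1L, seq_along(dip) - 1L)))
    flip_of <- rep(FALSE, nrow(G)); flip_of[dip] <- flip
    for (q in seq_len(np)) {
      d <- G[owner[q], ]
      if (haploid[q]) { A[q, ] <- d; next }
      a1 <- ifelse(d == 2L, 1L, ifelse(d == 0L, 0L, if (flip_of[owner[q]]) 1L else 0L))
      A[q, ] <- if (first_pos[q]) a1 else d - a1
    }
    for (ci in seq_len(nclass)) {
      w <- rep(1, nm)
      for (blk in blocks[[ci]]) {
        a0 <- A[blk[1L], ]
        if (length(blk) > 1L) for (q in blk[-1L]) w[A[q, ] != a0] <- 0
        w <- w * ifelse(a0 == 1L, p, 1 - p)
      }
      CP[ci, ] <- CP[ci, ] + w
    }
  }
  sweep(CP, 2L, 0.5^nhom, `*`)
}

# Emission with a per-genotype error rate: with probability e the observed
# genotype is replaced by a uniform draw over the genotype space (3 diploid /
# 2 haploid states), absorbing Mendelian conflicts without modeling them.
.fk_class_emissions_err <- function(blocks, G, p, owner, haploid, e) {
  nm <- length(p)
  k <- nrow(G)
  ind_hap <- tapply(haploid, owner, any)[as.character(seq_len(k))]
  domains <- lapply(seq_len(k), function(r) if (isTRUE(ind_hap[r])) 0:1 else 0:2)
  combos <- as.matrix(expand.grid(domains))
  CP <- 0
  for (ri in seq_len(nrow(combos))) {
    tvec <- combos[ri, ]
    w <- rep(1, nm)
    for (r in seq_len(k)) {
      ng <- if (isTRUE(ind_hap[r])) 2 else 3
      w <- w * ((1 - e) * (G[r, ] == tvec[r]) + e / ng)
    }
    Gt <- matrix(rep(as.integer(tvec), nm), nrow = k)
    CPt <- .fk_class_emissions(blocks, Gt, p, owner, haploid)
    CP <- CP + sweep(CPt, 2L, w, `*`)
  }
  CP
}

# ---------------------------------------------------------------------------
# multipoint pedigree likelihood
# ---------------------------------------------------------------------------

#' Multipoint pedigree log-likelihood on linked biallelic SNPs
#'
#' Computes the natural-log likelihood of observed genotypes for typed pedigree
#' members, accounting for genetic linkage through a hidden Markov model on the
#' inheritance-vector state space (one bit per modeled meiosis; transitions
#' between adjacent markers factorize per meiosis with Haldane recombination
#' fractions). At each marker the emission marginalizes founder alleles over
#' the founder-allele descent graph, weighting founder alleles by population
#' frequencies under Hardy-Weinberg equilibrium. Chromosomes are independent
#' and combine additively in log space.
#'
#' @param ped a [pedigree()] object.
#' @param genotypes numeric matrix of alt-allele dosages; rows named by typed
#'   individual ids, one column per marker (in `markers` row order). Diploid
#'   entries in `{0,1,2}`, hemizygous X entries in `{0,1}`; `NA` for sites with
#'   no usable call (no-calls and imbalanced sites are dropped upstream).
#' @param markers data frame with columns `chrom`, `pos_cm`, `freq` (alt allele
#'   frequency in the analysis population), one row per marker.
#' @param mode `"autosomal"` or `"X"`.
#' @param error_rate optional per-genotype error probability; the default 0 is
#'   strict, so a Mendelian conflict at any marker yields `-Inf`.
#' @return scalar natural-log likelihood, with attributes `n_markers_used` and
#'   `n_conflicts` (markers whose emission is zero under every state).
#' @export
pedigree_loglik <- function(ped, genotypes, markers, mode = c("autosomal", "X"),
                            error_rate = 0) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(genotypes), nrow(markers) == ncol(genotypes))
  typed <- rownames(genotypes)
  if (is.null(typed)) .fk_stopf("genotype matrix must have individual ids as rownames")
  if (mode == "X" && any(markers$chrom == "Y"))
    .fk_stopf("Y markers supplied to the X-chromosomal likelihood")

  p <- .fk_clamp_freq(as.numeric(markers$freq))
  ord <- order(markers$chrom, markers$pos_cm)
  markers <- markers[ord, , drop = FALSE]
  genotypes <- genotypes[, ord, drop = FALSE]
  p <- p[ord]

  keep <- colSums(!is.na(genotypes)) > 0L
  n_used <- sum(keep)
  if (n_used == 0L) {
    out <- 0
    attr(out, "n_markers_used") <- 0L
    attr(out, "n_conflicts") <- 0L
    return(out)
  }
  markers <- markers[keep, , drop = FALSE]
  genotypes <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  if (anyNA(markers$pos_cm)) .fk_stopf("marker without genetic position (cM)")

  descent <- .fk_descent(ped, typed, mode)

  # group markers by missingness pattern; class structure is marker-free
  pres <- !is.na(genotypes) # typed x markers
  pat_key <- apply(pres, 2L, function(z) paste(as.integer(z), collapse = ""))
  upat <- unique(pat_key)
  pat_idx <- match(pat_key, upat)

  sig <- .fk_ped_signature(ped, typed, mode)
  infos <- lapply(upat, function(pk) {
    .fk_classes(descent, present = as.logical(as.integer(strsplit(pk, "")[[1]])),
                key = paste0(sig, "#", pk))
  })
  offsets <- cumsum(c(0L, vapply(infos, `[[`, 1L, "nclass")))
  nclass_total <- offsets[length(offsets)]
  cls_by_pattern <- vapply(seq_along(infos),
                           function(i) infos[[i]]$cls + offsets[i],
                           integer(descent$ns))
  if (!is.matrix(cls_by_pattern)) cls_by_pattern <- matrix(cls_by_pattern, nrow = 1L)

  # collapse meiosis bits that never change the descent partition of the
  # typed allele positions (e.g. founder-spouse meioses): the emission is
  # invariant along them, so they marginalize out of the HMM exactly
  nbits <- descent$nbits
  if (nbits > 0L) {
    states <- 0:(descent$ns - 1L)
    silent <- vapply(seq_len(nbits), function(b) {
      flip <- bitwXor(states, bitwShiftL(1L, b - 1L)) + 1L
      all(cls_by_pattern == cls_by_pattern[flip, , drop = FALSE])
    }, logical(1))
    if (any(silent)) {
      collapsed_mask <- sum(bitwShiftL(1L, which(silent) - 1L))
      keep_states <- which(bitwAnd(states, collapsed_mask) == 0L)
      cls_by_pattern <- cls_by_pattern[keep_states, , drop = FALSE]
      nbits <- nbits - sum(silent)
    }
  }

  CP <- matrix(1, nclass_total, ncol(genotypes))
  for (i in seq_along(infos)) {
    jj <- which(pat_idx == i)
    info <- infos[[i]]
    present <- as.logical(as.integer(strsplit(upat[i], "")[[1]]))
    G <- genotypes[present, jj, drop = FALSE]
    storage.mode(G) <- "integer"
    rows <- offsets[i] + seq_len(info$nclass)
    CP[rows, jj] <- if (error_rate > 0)
      .fk_class_emissions_err(info$blocks, G, p[jj], info$owner, info$haploid, error_rate)
    else
      .fk_class_emissions(info$blocks, G, p[jj], info$owner, info$haploid)
  }

  # Mendelian conflicts: markers with zero emission under every state (every
  # class of a pattern is realized by some state, so a zero column suffices)
  conflict <- logical(ncol(CP))
  for (i in seq_along(infos)) {
    jj <- which(pat_idx == i)
    rows <- offsets[i] + seq_len(infos[[i]]$nclass)
    conflict[jj] <- apply(CP[rows, jj, drop = FALSE], 2L, max) == 0
  }
  n_conflicts <- sum(conflict)

  total <- 0
  for (ch in unique(markers$chrom)) {
    jj <- which(markers$chrom == ch)
    theta <- haldane_theta(diff(markers$pos_cm[jj]))
    ll <- forward_loglik_cpp(CP[, jj, drop = FALSE],
                             cls_by_pattern,
                             pat_idx[jj], theta, nbits)
    total <- total + ll
    if (!is.finite(total)) break
  }
  attr(total, "n_markers_used") <- n_used
  attr(total, "n_conflicts") <- n_conflicts
  total
}

# log-likelihood of independent individuals under HWE (the unrelated model)
.fk_unrelated_loglik <- function(genotypes, p, mode = "autosomal", male = NULL) {
  p <- .fk_clamp_freq(p)
  total <- 0
  for (r in seq_len(nrow(genotypes))) {
    g <- genotypes[r, ]
    ok <- !is.na(g)
    if (!any(ok)) next
    pr <- if (mode == "X" && isTRUE(male[r])) .fk_hap_prob(g[ok], p[ok])
          else .fk_hwe_prob(g[ok], p[ok])
    total <- total + sum(log(pr))
  }
  total
}

 # two-hypothesis flat-prior posterior LR/(1+LR), stable for extreme log10 LRs
.fk_two_hyp_posterior <- function(l) 1 / (1 + 10^(-l))

.fk_lr_result <- function(hypothesis, log10_lr, posterior, n_markers) {
  data.frame(hypothesis = hypothesis,
             log10_lr = log10_lr,
             posterior = posterior,
             n_markers_used = n_markers,
             strong_support = is.finite(log10_lr) & log10_lr >= 4 & posterior >= 0.9999,
             stringsAsFactors = FALSE)
}

#' Pairwise kinship likelihood ratio
#'
#' Likelihood ratio LR = Pr(genotypes | related hypothesis) / Pr(genotypes |
#' unrelated) for two typed individuals on autosomal kinship markers, with
#' genetic linkage accounted for through the multipoint pedigree likelihood of
#' the relationship's template pedigree. The reported posterior is the
#' flat-prior two-hypothesis posterior LR / (1 + LR).
#'
#' @param genoA,genoB alt-allele dosage vectors (`NA` = no usable call), one
#'   entry per row of `markers`.
#' @param hypothesis relationship name from [relationship_hypotheses()].
#' @param markers data frame with `chrom`, `pos_cm`, `freq`.
#' @param error_rate passed to [pedigree_loglik()].
#' @return one-row data frame: `hypothesis`, `log10_lr`, `posterior`,
#'   `n_markers_used`, `strong_support` (log10 LR >= 4 and posterior >= 0.9999).
#' @export
pairwise_lr <- function(genoA, genoB, hypothesis, markers, error_rate = 0) {
  if (hypothesis == "unrelated")
    return(.fk_lr_result("unrelated", 0, 0.5, sum(!is.na(genoA) & !is.na(genoB))))
  tpl <- relationship_template(hypothesis)
  G <- rbind(A = genoA, B = genoB)
  shared <- sum(!is.na(genoA) & !is.na(genoB))
  if (shared == 0L) return(.fk_lr_result(hypothesis, 0, 0.5, 0L))
  l1 <- pedigree_loglik(tpl, G, markers, mode = "autosomal", error_rate = error_rate)
  l0 <- .fk_unrelated_loglik(G, as.numeric(markers$freq))
  log10_lr <- (as.numeric(l1) - l0) / log(10)
  .fk_lr_result(hypothesis, log10_lr, .fk_two_hyp_posterior(log10_lr), shared)
}

#' X-chromosomal pairwise likelihood ratio
#'
#' As [pairwise_lr()] but under X-chromosomal inheritance: males are hemizygous,
#' fathers transmit their single X to daughters without recombination, and only
#' maternal meioses contribute inheritance-vector bits.
#'
#' @param genoA,genoB X dosage vectors (males `{0,1}`, females `{0,1,2}`).
#' @param sexA,sexB sexes of the two individuals (`"M"`/`"F"`).
#' @param hypothesis relationship name; default full siblings, the canonical
#'   X-informative case.
#' @param markers X marker table (`chrom`, `pos_cm`, `freq`).
#' @inherit pairwise_lr return
#' @export
x_chromosome_lr <- function(genoA, genoB, sexA, sexB,
                            hypothesis = "full_siblings", markers,
                            error_rate = 0) {
  if (any(markers$chrom == "Y")) .fk_stopf("Y-category markers supplied to X analysis")
  if (hypothesis == "unrelated")
    return(.fk_lr_result("unrelated", 0, 0.5, sum(!is.na(genoA) & !is.na(genoB))))
  tpl <- relationship_template(hypothesis, sexA = sexA, sexB = sexB)
  G <- rbind(A = genoA, B = genoB)
  shared <- sum(!is.na(genoA) & !is.na(genoB))
  if (shared == 0L) return(.fk_lr_result(hypothesis, 0, 0.5, 0L))
  l1 <- pedigree_loglik(tpl, G, markers, mode = "X", error_rate = error_rate)
  l0 <- .fk_unrelated_loglik(G, as.numeric(markers$freq), mode = "X",
                             male = c(sexA, sexB) == "M")
  log10_lr <- (as.numeric(l1) - l0) / log(10)
  .fk_lr_result(hypothesis, log10_lr, .fk_two_hyp_posterior(log10_lr), shared)
}

#' Missing-person pedigree likelihood ratio
#'
#' Tests H1 "the unknown sample comes from the missing person in this reference
#' pedigree" against H2 "the unknown comes from an individual unrelated to the
#' reference pedigree": log10 LR = logL(pedigree with the unknown placed in the
#' missing-person slot) minus logL(pedigree with the slot untyped) minus
#' logL(unknown as a lone unrelated individual).
#'
#' @param ped reference family [pedigree()] containing the missing person.
#' @param refs dosage matrix for the typed reference individuals (rownames =
#'   ids present in `ped`).
#' @param missing_id id of the missing-person slot in `ped`.
#' @param unknown dosage vector of the unknown sample.
#' @param markers data frame with `chrom`, `pos_cm`, `freq`.
#' @param error_rate passed to [pedigree_loglik()].
#' @inherit pairwise_lr return
#' @export
missing_person_lr <- function(ped, refs, missing_id, unknown, markers,
                              error_rate = 0) {
  if (!missing_id %in% ped$id) .fk_stopf("missing person '%s' not in pedigree", missing_id)
  if (missing_id %in% rownames(refs)) .fk_stopf("missing person slot already typed")
  n_unk <- sum(!is.na(unknown))
  if (n_unk == 0L) .fk_stopf("unknown sample has no usable genotypes")
  if (nrow(refs) == 0L || sum(!is.na(refs)) == 0L)
    return(.fk_lr_result("missing_person", 0, 0.5, n_unk))
  G1 <- rbind(refs, matrix(unknown, nrow = 1, dimnames = list(missing_id, NULL)))
  l1 <- pedigree_loglik(ped, G1, markers, error_rate = error_rate)
  l0 <- pedigree_loglik(ped, refs, markers, error_rate = error_rate) +
    .fk_unrelated_loglik(matrix(unknown, nrow = 1), as.numeric(markers$freq))
  log10_lr <- (as.numeric(l1) - as.numeric(l0)) / log(10)
  .fk_lr_result("missing_person", log10_lr, .fk_two_hyp_posterior(log10_lr), n_unk)
}

#' Flat-prior posterior probabilities over a hypothesis set
#'
#' Normalizes hypothesis likelihoods (given as log10 likelihood ratios against
#' the unrelated hypothesis) into posterior probabilities under equal priors,
#' computed in log space. The unrelated hypothesis (log10 LR = 0) is appended
#' if absent.
#'
#' @param lr data frame with columns `hypothesis` and `log10_lr`, or a named
#'   numeric vector of log10 LRs.
#' @return data frame `hypothesis`, `log10_lr`, `posterior`; posteriors sum
#'   to 1.
#' @examples
#' posteriors(c(parent_offspring = 4)) # LR 10,000 vs unrelated
#' @export
posteriors <- function(lr) {
  if (is.numeric(lr)) lr <- data.frame(hypothesis = names(lr), log10_lr = unname(lr),
                                       stringsAsFactors = FALSE)
  if (!"unrelated" %in% lr$hypothesis)
    lr <- rbind(lr[, c("hypothesis", "log10_lr")],
                data.frame(hypothesis = "unrelated", log10_lr = 0))
  if (nrow(lr) < 2L) .fk_stopf("need at least two hypotheses")
  tot <- .fk_log10_sum(lr$log10_lr)
  if (!is.finite(tot)) .fk_stopf("all hypothesis likelihoods are zero")
  lr$posterior <- ifelse(is.finite(lr$log10_lr), 10^(lr$log10_lr - tot), 0)
  lr
}

#' Blind-search pairwise kinship classification
#'
#' For every unordered pair of profiles, computes likelihood ratios for all
#' relationship hypotheses up to `max_degree` against the unrelated hypothesis,
#' normalizes flat-prior posteriors over the tested set (including unrelated),
#' and reports the best related hypothesis with its strong-support flag
#' (log10 LR >= 4 and posterior >= 0.9999).
#'
#' @param profiles dosage matrix, one row per sample (rownames = sample ids),
#'   one column per row of `markers`.
#' @param markers autosomal kinship marker table (`chrom`, `pos_cm`, `freq`).
#' @param max_degree maximum degree of relatedness searched (3 or 6).
#' @param error_rate passed to [pedigree_loglik()].
#' @return data frame with one row per pair: `sample_a`, `sample_b`,
#'   `best_hypothesis`, `log10_lr`, `posterior`, `n_markers_used`,
#'   `strong_support`.
#' @export
blind_search <- function(profiles, markers, max_degree = 6, error_rate = 0) {
  stopifnot(is.matrix(profiles))
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(profiles)))
  hyp <- relationship_hypotheses()
  hyp <- hyp$name[!is.na(hyp$degree) & hyp$degree <= max_degree]
  if (nrow(profiles) < 2L)
    return(data.frame(sample_a = character(), sample_b = character(),
                      best_hypothesis = character(), log10_lr = numeric(),
                      posterior = numeric(), n_markers_used = integer(),
                      strong_support = logical(), stringsAsFactors = FALSE))
  pairs <- combn(nrow(profiles), 2)
  out <- vector("list", ncol(pairs))
  for (c0 in seq_len(ncol(pairs))) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    res <- do.call(rbind, lapply(hyp, function(h)
      pairwise_lr(profiles[i, ], profiles[j, ], h, markers, error_rate = error_rate)))
    post <- posteriors(res[, c("hypothesis", "log10_lr")])
    res$posterior <- post$posterior[match(res$hypothesis, post$hypothesis)]
    best <- which.max(ifelse(is.finite(res$log10_lr), res$log10_lr, -Inf))
    out[[c0]] <- data.frame(
      sample_a = ids[i], sample_b = ids[j],
      best_hypothesis = res$hypothesis[best],
      log10_lr = res$log10_lr[best],
      posterior = res$posterior[best],
      n_markers_used = res$n_markers_used[best],
      strong_support = is.finite(res$log10_lr[best]) &&
        res$log10_lr[best] >= 4 && res$posterior[best] >= 0.9999,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
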