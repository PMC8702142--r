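# Independent oracles used to validate the likelihood engine. These never
# touch the engine's code path: oracle A enumerates inheritance vectors and
# founder-allele assignments explicitly (Kronecker-product transition
# matrices); oracle B enumerates only the connecting-path meiosis bits with
# hand-coded coalescence logic per relationship and textbook
# P(g1, g2 | alleles shared IBD) emissions.

# --- oracle A: full enumeration over inheritance vectors x founder alleles ---
# explicit per-state descent + founder-allele enumeration; transition matrices
# built as Kronecker products of per-meiosis 2x2 matrices.
oracle_enum_loglik <- function(ped, G, markers) {
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  nf <- which(!is.na(fa))
  m <- 2L * length(nf); ns <- 2^m
  founders <- which(is.na(fa)); nslots <- 2L * length(founders)
  typed <- rownames(G)
  bit <- function(s, b) bitwAnd(s, 2^(b - 1)) > 0
  L <- ncol(G)
  emis <- matrix(0, ns, L)
  for (s in 0:(ns - 1)) {
    sp <- integer(nrow(ped)); sm <- integer(nrow(ped)); slot <- 0L
    for (i in seq_len(nrow(ped))) {
      if (is.na(fa[i])) { sp[i] <- slot + 1L; sm[i] <- slot + 2L; slot <- slot + 2L }
      else {
        k <- match(i, nf)
        sp[i] <- if (bit(s, 2 * k - 1)) sm[fa[i]] else sp[fa[i]]
        sm[i] <- if (bit(s, 2 * k)) sm[mo[i]] else sp[mo[i]]
      }
    }
    ti <- match(typed, ped$id)
    for (j in seq_len(L)) {
      p <- markers$freq[j]
      tot <- 0
      for (a in 0:(2^nslots - 1)) {
        al <- as.integer(bitwAnd(a, 2^(seq_len(nslots) - 1)) > 0)
        ok <- TRUE
        for (q in seq_along(ti)) {
          g <- G[q, j]
          if (is.na(g)) next
          if (al[sp[ti[q]]] + al[sm[ti[q]]] != g) { ok <- FALSE; break }
        }
        if (ok) tot <- tot + prod(ifelse(al == 1, p, 1 - p))
      }
      emis[s + 1, j] <- tot
    }
  }
  v <- emis[, L]
  if (L > 1) for (j in (L - 1):1) {
    th <- haldane_theta(markers$pos_cm[j + 1] - markers$pos_cm[j])
    T2 <- matrix(c(1 - th, th, th, 1 - th), 2)
    TT <- Reduce(kronecker, rep(list(T2), m))
    v <- emis[, j] * as.vector(TT %*% v)
  }
  log(mean(v))
}

# --- oracle B: descent-path bit enumeration with IBD-conditional emissions ---
# per-relationship coalescence logic over the connecting meioses only;
# emissions are textbook P(g1, g2 | number of alleles shared IBD).
oracle_pair_ibd_setup <- function(name) {
  if (name == "parent_offspring") {
    B <- 1L; ibd <- function(bits) 1L
  } else if (name == "full_siblings") {
    B <- 4L; ibd <- function(bits) (bits[1] == bits[2]) + (bits[3] == bits[4])
  } else if (name == "half_siblings") {
    B <- 2L; ibd <- function(bits) as.integer(bits[1] == bits[2])
  } else {
    gens <- switch(name,
      first_cousins = c(1L, 1L), first_cousins_once_removed = c(1L, 2L),
      second_cousins = c(2L, 2L), second_cousins_once_removed = c(2L, 3L),
      stop("unknown relationship"))
    B <- 4L + sum(gens)
    # bits: s1p, s1m, s2p, s2m, then chain side 1 (top-down), chain side 2
    ibd <- function(bits) {
      side <- function(off, sp, sm, g) {
        ch <- bits[(off + 1):(off + g)]
        if (g > 1 && any(ch[-1] == 1L)) return(NULL)   # left the path
        gp <- ch[1]                                    # 0 = grandfather, 1 = grandmother
        idx <- if (gp == 0L) bits[sp] else bits[sm]
        c(gp, idx)
      }
      g1 <- switch(name, first_cousins = 1L, first_cousins_once_removed = 1L,
                   second_cousins = 2L, second_cousins_once_removed = 2L)
      g2 <- switch(name, first_cousins = 1L, first_cousins_once_removed = 2L,
                   second_cousins = 2L, second_cousins_once_removed = 3L)
      a <- side(4L, 1L, 2L, g1)
      b <- side(4L + g1, 3L, 4L, g2)
      if (is.null(a) || is.null(b)) return(0L)
      as.integer(all(a == b))
    }
  }
  list(B = B, ibd = ibd)
}

# P(gA, gB | k alleles IBD) for alt dosages and alt freq p
oracle_pair_emission <- function(gA, gB, p, k) {
  hwe <- function(g) c((1 - p)^2, 2 * p * (1 - p), p^2)[g + 1]
  if (k == 0L) return(hwe(gA) * hwe(gB))
  if (k == 2L) return(hwe(gA) * as.numeric(gA == gB))
  # share exactly one allele s; the spare allele of each is a fresh draw
  tot <- 0
  for (s in 0:1) {
    fs <- if (s == 1) p else 1 - p
    h <- function(g) { o <- g - s; if (o < 0 || o > 1) 0 else if (o == 1) p else 1 - p }
    tot <- tot + fs * h(gA) * h(gB)
  }
  tot
}

oracle_pair_loglik <- function(name, gA, gB, markers) {
  su <- oracle_pair_ibd_setup(name)
  B <- su$B; nv <- 2^B
  bits_of <- function(v) as.integer(bitwAnd(v, 2^(seq_len(B) - 1)) > 0)
  ibd_v <- vapply(0:(nv - 1), function(v) su$ibd(bits_of(v)), integer(1))
  L <- length(gA)
  emat <- vapply(seq_len(L), function(j) {
    e <- vapply(0:2, function(k) {
      if (is.na(gA[j]) && is.na(gB[j])) return(1)
      if (is.na(gA[j]) || is.na(gB[j])) {
        g <- if (is.na(gA[j])) gB[j] else gA[j]
        p <- markers$freq[j]
        return(c((1 - p)^2, 2 * p * (1 - p), p^2)[g + 1])
      }
      oracle_pair_emission(gA[j], gB[j], markers$freq[j], k)
    }, numeric(1))
    e[ibd_v + 1]
  }, numeric(nv))
  xor_pc <- outer(0:(nv - 1), 0:(nv - 1), function(a, b) {
    x <- bitwXor(a, b)
    n <- integer(length(x))
    for (b2 in seq_len(B)) n <- n + (bitwAnd(x, 2^(b2 - 1)) > 0)
    n
  })
  v <- emat[, L]
  if (L > 1) for (j in (L - 1):1) {
    th <- haldane_theta(markers$pos_cm[j + 1] - markers$pos_cm[j])
    TT <- th^xor_pc * (1 - th)^(B - xor_pc)
    v <- emat[, j] * as.vector(TT %*% v)
  }
  log(mean(v))
}

# single-locus likelihood ratio from unlinked IBD (kappa) coefficients
kappa_lr_single <- function(g1, g2, p, k) {
  hwe <- function(g) c((1 - p)^2, 2 * p * (1 - p), p^2)[g + 1]
  e1 <- oracle_pair_emission(g1, g2, p, 1L)
  e2 <- oracle_pair_emission(g1, g2, p, 2L)
  (k[1] * hwe(g1) * hwe(g2) + k[2] * e1 + k[3] * e2) / (hwe(g1) * hwe(g2))
}
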