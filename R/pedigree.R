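#' Construct a pedigree specification
#'
#' A pedigree is a table of individuals with sexes and parent links. Founders
#' have both parents missing; non-founders must have both parents present
#' (single known parents are modelled by adding an untyped founder spouse).
#'
#' @param id character vector of individual identifiers (unique).
#' @param father,mother identifiers of the parents, `NA` for founders.
#' @param sex `"M"` or `"F"` per individual.
#' @return A `pedigree_spec` data frame in topological order (parents precede
#'   children) with columns `id`, `father`, `mother`, `sex`.
#' @examples
#' trio <- pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
#'                  mother = c(NA, NA, "m"), sex = c("M", "F", "F"))
#' @export
pedigree <- function(id, father = NA, mother = NA, sex) {
  id <- as.character(id)
  father <- as.character(rep_len(father, length(id)))
  mother <- as.character(rep_len(mother, length(id)))
  sex <- as.character(rep_len(sex, length(id)))
  if (anyDuplicated(id)) .fk_stopf("duplicated individual id: %s",
                                   paste(unique(id[duplicated(id)]), collapse = ", "))
  if (!all(sex %in% c("M", "F"))) .fk_stopf("sex must be 'M' or 'F'")
  has_f <- !is.na(father)
  has_m <- !is.na(mother)
  if (any(has_f != has_m))
    .fk_stopf("individuals must have both parents or neither: %s",
              paste(id[has_f != has_m], collapse = ", "))
  if (any(has_f & !(father %in% id))) .fk_stopf("unknown father id")
  if (any(has_m & !(mother %in% id))) .fk_stopf("unknown mother id")
  if (any(sex[match(father[has_f], id)] != "M")) .fk_stopf("father must be male")
  if (any(sex[match(mother[has_m], id)] != "F")) .fk_stopf("mother must be female")

  # topological sort; also detects ancestor cycles
  ord <- character(0)
  placed <- setNames(rep(FALSE, length(id)), id)
  repeat {
    ready <- !placed & (is.na(father) | placed[father]) & (is.na(mother) | placed[mother])
    if (!any(ready)) break
    ord <- c(ord, id[ready])
    placed[id[ready]] <- TRUE
  }
  if (!all(placed)) .fk_stopf("pedigree contains a cycle (individual its own ancestor)")
  i <- match(ord, id)
  out <- data.frame(id = id[i], father = father[i], mother = mother[i],
                    sex = sex[i], stringsAsFactors = FALSE)
  class(out) <- c("pedigree_spec", "data.frame")
  out
}

#' @export
print.pedigree_spec <- function(x, ...) {
  cat(sprintf("pedigree_spec: %d individuals (%d founders)\n",
              nrow(x), sum(is.na(x$father))))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read a PED-style pedigree file
#'
#' Expects whitespace/tab-separated columns family, id, father, mother, sex
#' (1 = male, 2 = female; 0 = missing parent), as used by linkage-format
#' pedigree files.
#'
#' @param path file path.
#' @param family optional family id to extract; default: the first family.
#' @return a [pedigree()] object.
#' @export
read_pedigree <- function(path, family = NULL) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("family", "id", "father", "mother", "sex"))
  if (is.null(family)) family <- d$family[1]
  d <- d[d$family == family, , drop = FALSE]
  if (!nrow(d)) .fk_stopf("family '%s' not found in %s", family, path)
  pedigree(id = d$id,
           father = ifelse(d$father == "0", NA, d$father),
           mother = ifelse(d$mother == "0", NA, d$mother),
           sex = ifelse(d$sex == 1, "M", "F"))
}

#' Write a pedigree in PED format
#' @param ped a [pedigree()] object.
#' @param path output file; `family` the family label to emit.
#' @export
write_pedigree <- function(ped, path, family = "FAM1") {
  d <- data.frame(family = family, id = ped$id,
                  father = ifelse(is.na(ped$father), "0", ped$father),
                  mother = ifelse(is.na(ped$mother), "0", ped$mother),
                  sex = ifelse(ped$sex == "M", 1L, 2L))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pairwise relationship hypotheses
#'
#' Names, degrees of relatedness, and unlinked IBD (kappa) coefficients for the
#' seven tested relationships plus the unrelated alternative.
#'
#' @return data frame with columns `name`, `degree`, `k0`, `k1`, `k2`.
#' @export
relationship_hypotheses <- function() {
  data.frame(
    name = c("parent_offspring", "full_siblings", "half_siblings",
             "first_cousins", "first_cousins_once_removed",
             "second_cousins", "second_cousins_once_removed", "unrelated"),
    degree = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, NA_integer_),
    k0 = c(0, 1 / 4, 1 / 2, 3 / 4, 7 / 8, 15 / 16, 31 / 32, 1),
    k1 = c(1, 1 / 2, 1 / 2, 1 / 4, 1 / 8, 1 / 16, 1 / 32, 0),
    k2 = c(0, 1 / 4, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Unlinked IBD coefficients for a relationship
#' @param name relationship name as in [relationship_hypotheses()].
#' @return numeric `c(k0, k1, k2)`.
#' @export
kappa_coefficients <- function(name) {
  h <- relationship_hypotheses()
  i <- match(name, h$name)
  if (is.na(i)) .fk_stopf("unknown relationship '%s'", name)
  c(k0 = h$k0[i], k1 = h$k1[i], k2 = h$k2[i])
}

#' Template pedigree connecting two typed individuals
#'
#' Builds the minimal pedigree realising a named pairwise relationship between
#' typed individuals `"A"` and `"B"`; connecting relatives are untyped.
#' Intermediate path individuals are male with female founder spouses (the
#' autosomal likelihood is invariant to this choice). For X-chromosomal use,
#' the sexes of A and B can be overridden.
#'
#' @param name relationship name as in [relationship_hypotheses()].
#' @param sexA,sexB sexes of the typed pair.
#' @return a [pedigree()] with attributes `typed` (ids) and `relationship`.
#' @export
relationship_template <- function(name, sexA = "M", sexB = "F") {
  add <- function(p, id, father = NA, mother = NA, sex) {
    rbind(p, data.frame(id = id, father = father, mother = mother, sex = sex,
                        stringsAsFactors = FALSE))
  }
  p <- data.frame(id = character(), father = character(), mother = character(),
                  sex = character(), stringsAsFactors = FALSE)
  if (name == "unrelated") {
    p <- add(p, "A", sex = sexA); p <- add(p, "B", sex = sexB)
  } else if (name == "parent_offspring") {
    p <- add(p, "A", sex = "M"); p <- add(p, "spA", sex = "F")
    p <- add(p, "B", "A", "spA", sex = sexB)
    if (sexA != "M") {
      p$sex[p$id == "A"] <- "F"; p$sex[p$id == "spA"] <- "M"
      p[p$id == "B", c("father", "mother")] <- c("spA", "A")
    }
  } else if (name == "full_siblings") {
    p <- add(p, "fa", sex = "M"); p <- add(p, "mo", sex = "F")
    p <- add(p, "A", "fa", "mo", sex = sexA); p <- add(p, "B", "fa", "mo", sex = sexB)
  } else if (name == "half_siblings") {
    # shared mother: the X-informative configuration is maternal half sibs;
    # autosomally the shared-parent choice is immaterial
    p <- add(p, "mo", sex = "F"); p <- add(p, "fa1", sex = "M"); p <- add(p, "fa2", sex = "M")
    p <- add(p, "A", "fa1", "mo", sex = sexA); p <- add(p, "B", "fa2", "mo", sex = sexB)
  } else {
    # cousin-type chains: sibs s1/s2 under a founder couple, then g1/g2 further
    # meioses down each side to the typed pair
    gens <- switch(name,
      first_cousins = c(1L, 1L),
      first_cousins_once_removed = c(1L, 2L),
      second_cousins = c(2L, 2L),
      second_cousins_once_removed = c(2L, 3L),
      .fk_stopf("unknown relationship '%s'", name))
    p <- add(p, "gf", sex = "M"); p <- add(p, "gm", sex = "F")
    p <- add(p, "s1", "gf", "gm", sex = "M"); p <- add(p, "s2", "gf", "gm", sex = "M")
    mk_chain <- function(p, side, g, typed_id, typed_sex) {
      par <- paste0("s", side)
      if (g > 1L) for (k in seq_len(g - 1L)) {
        sp <- paste0("sp", side, k); ch <- paste0("c", side, k)
        p <- add(p, sp, sex = "F"); p <- add(p, ch, par, sp, sex = "M")
        par <- ch
      }
      sp <- paste0("sp", side, "T")
      p <- add(p, sp, sex = "F")
      p <- add(p, typed_id, par, sp, sex = typed_sex)
      p
    }
    p <- mk_chain(p, 1L, gens[1], "A", sexA)
    p <- mk_chain(p, 2L, gens[2], "B", sexB)
    # X mode requires typed females to have a father in the pedigree; path
    # intermediates are male so the maternal line is founder spouses -- fine.
  }
  out <- pedigree(p$id, p$father, p$mother, p$sex)
  attr(out, "typed") <- c("A", "B")
  attr(out, "relationship") <- name
  out
}
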