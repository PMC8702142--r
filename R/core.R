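#' Population labels used throughout the package
#'
#' The five continental population groups whose allele frequencies annotate
#' every panel marker.
#' @export
FK_POPULATIONS <- c("AFR", "AMR", "EAS", "EUR", "SAS")

# frequency floor/ceiling applied before any likelihood so that a private
# allele never yields a zero-probability founder assignment
.fk_clamp_freq <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

# log10-space sum: log10(sum(10^x)) without overflow
.fk_log10_sum <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(x - m)))
}

.fk_stopf <- function(...) stop(sprintf(...), call. = FALSE)
.fk_warnf <- function(...) warning(sprintf(...), call. = FALSE)

# derive a bounded child seed from a user seed and a stream label
.fk_child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629
}

# Hardy-Weinberg genotype probability for alt-allele dosage g given alt freq p
.fk_hwe_prob <- function(g, p) {
  out <- numeric(length(g))
  out[g == 0L] <- (1 - p[g == 0L])^2
  out[g == 1L] <- 2 * p[g == 1L] * (1 - p[g == 1L])
  out[g == 2L] <- p[g == 2L]^2
  out
}

# haploid probability of allele a (0/1) given alt frequency p
.fk_hap_prob <- function(a, p) ifelse(a == 1L, p, 1 - p)

.fk_header_comment <- function(extra = NULL) {
  c(sprintf("# forcekin %s", as.character(packageVersion("forcekin"))),
    if (!is.null(extra)) paste0("# ", extra))
}

# write a TSV with leading comment lines
.fk_write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(comments, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.fk_read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE, ...)
}
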