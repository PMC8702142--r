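#' Simulate likelihood-ratio distributions for a kinship scenario
#'
#' Reproduces the panel-performance simulation design: per replicate, a pair
#' of individuals is gene-dropped either from the relationship's template
#' pedigree (truth = related arm) or as two independent individuals (truth =
#' unrelated arm), the kinship markers are optionally subsampled to a panel
#' fraction, and the pairwise likelihood ratio of the scenario's hypothesis
#' against unrelated is computed with linkage accounted for. Per-replicate
#' seeds derive from the scenario seed by counter, so each arm is reproducible
#' independently.
#'
#' @param relationship hypothesis name from [relationship_hypotheses()].
#' @param panel an `fk_panel`; only its kinship-category SNPs are used.
#' @param n_reps replicates per truth arm.
#' @param panel_fraction fraction of kinship SNPs retained per replicate
#'   (1.0, 0.75, 0.25, or any value in (0, 1]).
#' @param pop population whose frequencies drive simulation and likelihoods.
#' @param seed scenario seed.
#' @return an `lr_distribution` list: `relationship`, `panel_fraction`,
#'   `log10_lr_related`, `log10_lr_unrelated`, `quantiles` (per arm),
#'   `exceedance` (fractions with log10 LR >= 0 and >= 4, per arm).
#' @export
run_scenario <- function(relationship, panel, n_reps = 500, panel_fraction = 1.0,
                         pop = "EUR", seed = 1) {
  stopifnot(n_reps >= 1)
  kin <- panel[panel$category == "kinship", , drop = FALSE]
  if (!nrow(kin)) .fk_stopf("panel has no kinship SNPs")
  tpl <- relationship_template(relationship)
  unrel <- relationship_template("unrelated")
  fcol <- paste0("freq_", pop)

  one_rep <- function(ped, rep_seed) {
    use <- if (panel_fraction < 1)
      subsample_panel(kin, panel_fraction, seed = rep_seed + 1)
    else kin
    sim <- simulate_pedigree_genotypes(ped, use, pop = pop, seed = rep_seed)
    markers <- data.frame(chrom = use$chrom, pos_cm = use$pos_cm,
                          freq = use[[fcol]])
    pairwise_lr(sim$dosage["A", ], sim$dosage["B", ], relationship,
                markers)$log10_lr
  }
  related <- vapply(seq_len(n_reps), function(r)
    one_rep(tpl, .fk_child_seed(seed, r)), numeric(1))
  unrelated <- vapply(seq_len(n_reps), function(r)
    one_rep(unrel, .fk_child_seed(seed, n_reps + r)), numeric(1))

  qs <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  structure(list(
    relationship = relationship, panel_fraction = panel_fraction,
    n_reps = n_reps,
    log10_lr_related = related, log10_lr_unrelated = unrelated,
    quantiles = rbind(related = quantile(related, qs),
                      unrelated = quantile(unrelated, qs)),
    exceedance = rbind(
      related = c(ge0 = mean(related >= 0), ge4 = mean(related >= 4)),
      unrelated = c(ge0 = mean(unrelated >= 0), ge4 = mean(unrelated >= 4)))),
    class = "lr_distribution")
}

#' @export
print.lr_distribution <- function(x, ...) {
  cat(sprintf("lr_distribution: %s, panel fraction %.2f, %d reps/arm\n",
              x$relationship, x$panel_fraction, x$n_reps))
  cat(sprintf("  related   median log10 LR %.2f, P(log10 LR >= 4) = %.3f\n",
              stats::median(x$log10_lr_related), x$exceedance["related", "ge4"]))
  cat(sprintf("  unrelated median log10 LR %.2f, P(log10 LR >= 4) = %.3f\n",
              stats::median(x$log10_lr_unrelated), x$exceedance["unrelated", "ge4"]))
  invisible(x)
}

#' Overlap between related and unrelated LR distributions
#'
#' Quantifies the distribution overlap that limits distant-kinship inference:
#' the fraction of related-arm log10 LRs lying below the unrelated arm's 99th
#' percentile, and the fraction of unrelated-arm values above the related
#' arm's 1st percentile.
#'
#' @param dist an `lr_distribution`.
#' @return list `related_below_unrelated_p99`, `unrelated_above_related_p01`.
#' @export
overlap_summary <- function(dist) {
  rel <- dist$log10_lr_related
  unr <- dist$log10_lr_unrelated
  if (!length(rel) || !length(unr)) .fk_stopf("both truth arms must be non-empty")
  list(related_below_unrelated_p99 = mean(rel <= quantile(unr, 0.99)),
       unrelated_above_related_p01 = mean(unr >= quantile(rel, 0.01)))
}

#' Export an LR distribution to TSV and a density plot
#'
#' Writes the per-replicate log10 LR samples (long format with a `truth`
#' column), a quantile summary, and a density figure.
#'
#' @param dist an `lr_distribution`.
#' @param path_prefix file prefix; writes `<prefix>_samples.tsv`,
#'   `<prefix>_summary.tsv`, `<prefix>_density.png`.
#' @return invisibly, the written paths.
#' @export
export_distributions <- function(dist, path_prefix) {
  if (!length(dist$log10_lr_related) || !length(dist$log10_lr_unrelated))
    .fk_stopf("refusing to export an empty truth arm")
  samples <- data.frame(
    truth = rep(c("related", "unrelated"),
                c(length(dist$log10_lr_related), length(dist$log10_lr_unrelated))),
    log10_lr = c(dist$log10_lr_related, dist$log10_lr_unrelated))
  hdr <- .fk_header_comment(sprintf("scenario=%s panel_fraction=%.2f",
                                    dist$relationship, dist$panel_fraction))
  p_samples <- paste0(path_prefix, "_samples.tsv")
  p_summary <- paste0(path_prefix, "_summary.tsv")
  p_plot <- paste0(path_prefix, "_density.png")
  .fk_write_tsv(samples, p_samples, comments = hdr)
  qdf <- data.frame(arm = rownames(dist$quantiles), dist$quantiles,
                    check.names = FALSE)
  .fk_write_tsv(qdf, p_summary, comments = hdr)
  gg <- ggplot2::ggplot(samples, ggplot2::aes(x = log10_lr, fill = truth)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 4, linetype = "dashed") +
    ggplot2::labs(x = "log10 likelihood ratio", y = "density",
                  title = sprintf("%s vs unrelated (panel fraction %.0f%%)",
                                  dist$relationship, 100 * dist$panel_fraction)) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(p_plot, gg, width = 7, height = 4, dpi = 120)
  invisible(c(samples = p_samples, summary = p_summary, plot = p_plot))
}
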