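#' Weighted methylation level of a set of CpG sites
#'
#' The coverage-weighted level: summed methylated reads over summed total
#' reads. Invariant under subdividing a site's reads across sites and under
#' site ordering.
#'
#' @param n_meth,n_total Read-count vectors over the sites of one unit.
#' @return A single level in `[0, 1]`, or `NA` when total coverage is zero.
#' @export
#' @examples
#' weighted_level(c(3, 7), c(10, 10))  # 0.5
weighted_level <- function(n_meth, n_total) {
  tot <- sum(n_total)
  if (tot == 0) return(NA_real_)
  sum(n_meth) / tot
}

#' Per-unit, per-sample weighted methylation
#'
#' Aggregates a long count table over an assignment of sites to units
#' (genes, exons, feature classes, linkage groups...). Units with zero total
#' coverage in a sample get `W = NA` and are excluded from downstream caste
#' means.
#'
#' @param counts Long tibble with `sample_id`, `chrom`, `pos`, `n_meth`,
#'   `n_total`.
#' @param assignment Tibble mapping sites to units: `chrom`, `pos` plus the
#'   unit column. A site assigned to several units contributes to each.
#' @param unit Name of the unit column in `assignment` (default
#'   `"gene_id"`).
#' @return Tibble with the unit column, `sample_id`, `W`, `n_cpgs`.
#' @export
weighted_methylation <- function(counts, assignment, unit = "gene_id") {
  stopifnot(unit %in% names(assignment))
  counts |>
    inner_join(dplyr::distinct(assignment[, c("chrom", "pos", unit)]),
               by = c("chrom", "pos"), relationship = "many-to-many") |>
    group_by(dplyr::across(dplyr::all_of(c(unit, "sample_id")))) |>
    summarise(W = weighted_level(.data$n_meth, .data$n_total),
              n_cpgs = n(), .groups = "drop")
}

#' Caste-level weighted methylation (mean across colonies)
#'
#' The caste value of a unit is the mean of its per-sample `W` across that
#' caste's colonies, with a 95% confidence interval of the mean. Samples with
#' undefined `W` are excluded.
#'
#' @param wm Output of [weighted_methylation()].
#' @param samples Sample metadata tibble (`sample_id`, `caste`, `colony`).
#' @param unit Unit column name (default `"gene_id"`).
#' @return Tibble with unit, `caste`, `W` (mean across colonies),
#'   `ci_lo`/`ci_hi`, `n_colonies`.
#' @export
caste_methylation <- function(wm, samples, unit = "gene_id") {
  wm |>
    inner_join(samples, by = "sample_id") |>
    filter(!is.na(.data$W)) |>
    group_by(dplyr::across(dplyr::all_of(c(unit, "caste")))) |>
    summarise(mean_W = mean(.data$W),
              se = if (n() > 1) stats::sd(.data$W) / sqrt(n()) else NA_real_,
              n_colonies = n(), .groups = "drop") |>
    mutate(ci_lo = .data$mean_W - stats::qt(0.975, pmax(.data$n_colonies - 1, 1)) * .data$se,
           ci_hi = .data$mean_W + stats::qt(0.975, pmax(.data$n_colonies - 1, 1)) * .data$se) |>
    rename(W = "mean_W")
}

#' Genes classed as methylated
#'
#' A gene counts as methylated when its weighted methylation level exceeds
#' zero in at least one sample.
#'
#' @param wm Output of [weighted_methylation()] at gene level.
#' @return Character vector of methylated gene ids.
#' @export
classify_methylated_genes <- function(wm) {
  wm |>
    filter(!is.na(.data$W), .data$W > 0) |>
    pull("gene_id") |>
    unique() |>
    sort()
}

#' Bin weighted methylation levels
#'
#' Four classes: `none` (exactly 0), `low` (>0-0.2], `medium` (0.2-0.7],
#' `high` (0.7-1]. Upper boundaries are inclusive, so `W = 0.2` is `low` and
#' `W = 0.7` is `medium`.
#'
#' @param W Numeric vector of levels in `[0, 1]` (`NA` passes through).
#' @return Ordered factor with levels `none < low < medium < high`.
#' @export
bin_methylation <- function(W) {
  stopifnot(all(W >= 0 & W <= 1, na.rm = TRUE))
  out <- cut(W, breaks = c(-Inf, 0, 0.2, 0.7, 1),
             labels = c("none", "low", "medium", "high"),
             right = TRUE, ordered_result = TRUE)
  out
}

#' Weighted methylation summarised by feature class
#'
#' Per-sample weighted methylation over each annotated feature class
#' (exon, intron, gene, ncRNA, ...) with caste means and 95% confidence
#' intervals across colonies.
#'
#' @param counts Long count tibble.
#' @param annotation Site-feature assignment from [annotate_sites()].
#' @param samples Sample metadata.
#' @return Tibble: `feature_type`, `caste`, `W`, `ci_lo`, `ci_hi`,
#'   `n_colonies`.
#' @export
feature_summary <- function(counts, annotation, samples) {
  wm <- weighted_methylation(counts, annotation, unit = "feature_type")
  caste_methylation(wm, samples, unit = "feature_type")
}

#' Weighted methylation summarised by linkage group
#'
#' @param counts Long count tibble (`chrom` is the linkage group).
#' @param samples Sample metadata.
#' @return Tibble: `chrom`, `caste`, `W`, `ci_lo`, `ci_hi`, `n_colonies`.
#' @export
linkage_summary <- function(counts, samples) {
  wm <- counts |>
    group_by(.data$chrom, .data$sample_id) |>
    summarise(W = weighted_level(.data$n_meth, .data$n_total),
              n_cpgs = n(), .groups = "drop")
  caste_methylation(wm, samples, unit = "chrom")
}

#' Genome-wide single-site methylation level, error-corrected
#'
#' The pooled methylated-read fraction over all sites and samples
#' (methylated cytosine calls divided by total cytosine calls), corrected for
#' the non-conversion background via [corrected_site_level()]. Pooling before
#' correcting avoids the upward bias that truncating per-site corrected
#' levels at zero would introduce at sparse methylation.
#'
#' @param counts Long count tibble.
#' @param epsilon Non-conversion error rate.
#' @return Single number: the corrected genome-wide level.
#' @export
genome_mean_site_level <- function(counts, epsilon = 0) {
  df <- filter(counts, .data$n_total > 0)
  corrected_site_level(sum(df$n_meth), sum(df$n_total), epsilon)
}
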