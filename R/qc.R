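#' Bisulfite conversion efficiency from a lambda spike-in
#'
#' The lambda phage genome is unmethylated, so any methylated read over a
#' lambda cytosine is a non-conversion event. Efficiency is one minus the
#' weighted methylation level of the lambda table (summed methylated reads
#' over summed total reads).
#'
#' @param lambda_counts Tibble with `n_meth`, `n_total` over lambda sites.
#' @return Conversion efficiency in `[0, 1]`.
#' @export
#' @examples
#' conversion_efficiency(data.frame(n_meth = 45, n_total = 10000))  # 0.9955
conversion_efficiency <- function(lambda_counts) {
  tot <- sum(lambda_counts$n_total)
  if (tot == 0) abort_ct("lambda table has zero total coverage")
  1 - sum(lambda_counts$n_meth) / tot
}

#' Error-corrected single-site methylation level
#'
#' Subtracts the expected non-conversion background from the raw proportion:
#' `max(0, (n_meth/n_total - epsilon) / (1 - epsilon))`.
#'
#' @param n_meth,n_total Read counts (vectorised).
#' @param epsilon Non-conversion error rate, e.g. from
#'   [conversion_efficiency()] as `1 - efficiency`.
#' @return Corrected level(s) in `[0, 1]`.
#' @export
corrected_site_level <- function(n_meth, n_total, epsilon) {
  stopifnot(epsilon >= 0, epsilon < 1, all(n_total > 0))
  pmax(0, (n_meth / n_total - epsilon) / (1 - epsilon))
}

#' Coverage-filter CpG sites across all samples
#'
#' A site is kept if and only if, in every sample, its coverage is at least
#' `min_cov` and at most that sample's `pct` coverage percentile (the
#' percentile is computed per sample with linear interpolation, so outlier
#' removal reflects library-specific artifacts). Zero-coverage rows fail the
#' minimum-coverage rule. The site universe is the intersection across
#' samples: a site absent from any sample is removed.
#'
#' @param counts Long tibble with `sample_id`, `chrom`, `pos`, `n_meth`,
#'   `n_total`.
#' @param min_cov Minimum coverage (default 10 reads).
#' @param pct Upper percentile cutoff (default 99.9).
#' @param require_all_samples Keep only sites passing in every sample
#'   (default TRUE; FALSE keeps rows passing per sample independently).
#' @return List of class `qc_filtered` with `counts` (the filtered long
#'   tibble) and `report` (per-sample tibble: conversion bookkeeping slots,
#'   `coverage_p999`, `n_sites_removed_low`, `n_sites_removed_high`,
#'   `n_sites_in`, `n_sites_kept`).
#' @export
filter_sites <- function(counts, min_cov = 10, pct = 99.9,
                         require_all_samples = TRUE) {
  stopifnot(min_cov >= 0, pct > 0, pct <= 100)
  report <- counts |>
    group_by(.data$sample_id) |>
    summarise(
      coverage_p999 = quantile(.data$n_total, pct / 100, type = 7, names = FALSE),
      n_sites_removed_low = sum(.data$n_total < min_cov),
      n_sites_removed_high = sum(.data$n_total > coverage_p999),
      n_sites_in = n(),
      .groups = "drop"
    )
  flagged <- counts |>
    left_join(select(report, "sample_id", "coverage_p999"), by = "sample_id") |>
    mutate(pass = .data$n_total >= min_cov & .data$n_total <= .data$coverage_p999)
  n_samples <- dplyr::n_distinct(counts$sample_id)
  if (require_all_samples) {
    keep_sites <- flagged |>
      group_by(.data$chrom, .data$pos) |>
      summarise(ok = sum(.data$pass) == n_samples & n() == n_samples,
                .groups = "drop") |>
      filter(.data$ok) |>
      select("chrom", "pos")
    if (nrow(keep_sites) == 0L) {
      pass_n <- flagged |> filter(.data$pass) |> dplyr::count(.data$sample_id)
      abort_ct(paste0(
        "no site passes the coverage filter in all %d samples ",
        "(min_cov = %g, percentile = %g); per-sample pass counts: %s"),
        n_samples, min_cov, pct,
        paste(sprintf("%s=%d", pass_n$sample_id, pass_n$n), collapse = ", "))
    }
    out <- flagged |>
      inner_join(keep_sites, by = c("chrom", "pos")) |>
      select(-"coverage_p999", -"pass")
  } else {
    out <- flagged |> filter(.data$pass) |> select(-"coverage_p999", -"pass")
  }
  report <- report |>
    left_join(out |> dplyr::count(.data$sample_id, name = "n_sites_kept"),
              by = "sample_id")
  structure(list(counts = out, report = report), class = "qc_filtered")
}
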