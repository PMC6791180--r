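#' Site-level differential methylation between castes
#'
#' For every CpG, fits a binomial logistic regression of methylated versus
#' unmethylated read counts on caste plus colony (the colony covariate
#' absorbs the strong shared intercolony variation), and tests the caste term
#' by likelihood ratio. P-values are Benjamini-Hochberg adjusted across all
#' tested sites; a site is called differentially methylated (DM) when
#' `q < qvalue` and the absolute difference between the caste-pooled
#' methylation proportions is at least `min_diff`.
#'
#' Degenerate sites (no variation: all reads methylated or none in every
#' sample; or separated/non-converged fits) are assigned `p = 1` with a flag
#' rather than dropped, keeping the tested-site universe stable for the BH
#' correction.
#'
#' @param counts Long count tibble (`sample_id`, `chrom`, `pos`, `n_meth`,
#'   `n_total`).
#' @param samples Sample metadata (`sample_id`, `caste`, `colony`); at least
#'   two samples per caste.
#' @param sites Optional tibble of sites to test (`chrom`, `pos`), typically
#'   the informative sites from [filter_informative()].
#' @param qvalue BH-adjusted significance threshold (default 0.05).
#' @param min_diff Minimum absolute caste methylation difference on the
#'   proportion scale (default 0.10).
#' @return Tibble with one row per tested site: `chrom`, `pos`, `meth_diff`
#'   (reproductive minus sterile pooled proportion), `p`, `q`, `is_dm`,
#'   `degenerate`.
#' @export
dm_sites <- function(counts, samples, sites = NULL, qvalue = 0.05,
                     min_diff = 0.10) {
  stopifnot(all(c("reproductive", "sterile") %in% samples$caste))
  if (min(table(samples$caste)) < 2) {
    abort_ct("need at least two samples per caste")
  }
  df <- inner_join(counts, samples, by = "sample_id")
  if (!is.null(sites)) {
    df <- inner_join(df, dplyr::distinct(sites[, c("chrom", "pos")]),
                     by = c("chrom", "pos"))
  }
  df <- filter(df, .data$n_total > 0)
  use_colony <- dplyr::n_distinct(df$colony) > 1
  res <- df |>
    group_by(.data$chrom, .data$pos) |>
    group_modify(~ dm_site_test(.x, use_colony)) |>
    ungroup()
  res$q <- p.adjust(res$p, method = "BH")
  res$is_dm <- res$q < qvalue & abs(res$meth_diff) >= min_diff
  res
}

dm_site_test <- function(d, use_colony) {
  pooled <- d |>
    group_by(.data$caste) |>
    summarise(p_hat = sum(.data$n_meth) / sum(.data$n_total), .groups = "drop")
  diff <- pooled$p_hat[pooled$caste == "reproductive"] -
    pooled$p_hat[pooled$caste == "sterile"]
  no_var <- all(d$n_meth == 0) || all(d$n_meth == d$n_total)
  if (no_var) {
    return(tibble(meth_diff = diff, p = 1, degenerate = TRUE))
  }
  d$caste <- factor(d$caste, levels = c("sterile", "reproductive"))
  f_full <- if (use_colony) cbind(n_meth, n_total - n_meth) ~ caste + colony else
    cbind(n_meth, n_total - n_meth) ~ caste
  f_red <- if (use_colony) cbind(n_meth, n_total - n_meth) ~ colony else
    cbind(n_meth, n_total - n_meth) ~ 1
  out <- tryCatch({
    full <- suppressWarnings(glm(f_full, family = binomial(), data = d))
    red <- suppressWarnings(glm(f_red, family = binomial(), data = d))
    separated <- !full$converged ||
      any(abs(coef(full)["castereproductive"]) > 15, na.rm = TRUE)
    if (separated) {
      tibble(meth_diff = diff, p = 1, degenerate = TRUE)
    } else {
      lrt <- max(red$deviance - full$deviance, 0)
      tibble(meth_diff = diff,
             p = pchisq(lrt, df = 1, lower.tail = FALSE),
             degenerate = FALSE)
    }
  }, error = function(e) tibble(meth_diff = diff, p = 1, degenerate = TRUE))
  out
}

#' Gene-level differential methylation calls
#'
#' A gene is differentially methylated when it contains at least
#' `min_dm_cpgs` DM CpGs (from [dm_sites()]) *and* its caste weighted
#' methylation levels differ by at least `min_diff` across the entire gene.
#' `hyper_in` records the caste with the larger weighted level. Only sites
#' assigned to genes count; intergenic DM CpGs are reported separately by
#' [annotate_sites()] and never contribute here.
#'
#' @param site_results Output of [dm_sites()].
#' @param site_genes Site-gene map: `chrom`, `pos`, `gene_id` (e.g. gene rows
#'   of [annotate_sites()] output).
#' @param caste_w Gene-level caste weighted methylation from
#'   [caste_methylation()]: `gene_id`, `caste`, `W`.
#' @param qvalue,min_diff Thresholds; `min_diff` applies to `|delta_W|`.
#' @param min_dm_cpgs Minimum number of DM CpGs in the gene (default 1).
#' @return Tibble: `gene_id`, `n_dm_cpgs`, `n_tested_cpgs`, `delta_w`
#'   (reproductive minus sterile), `is_dm_gene`, `hyper_in`.
#' @export
dm_genes <- function(site_results, site_genes, caste_w, qvalue = 0.05,
                     min_diff = 0.10, min_dm_cpgs = 1) {
  per_gene <- site_results |>
    inner_join(dplyr::distinct(site_genes[, c("chrom", "pos", "gene_id")]),
               by = c("chrom", "pos"), relationship = "many-to-many") |>
    filter(!is.na(.data$gene_id)) |>
    group_by(.data$gene_id) |>
    summarise(n_dm_cpgs = sum(.data$is_dm), n_tested_cpgs = n(),
              .groups = "drop")
  w_wide <- caste_w |>
    select("gene_id", "caste", "W") |>
    tidyr::pivot_wider(names_from = "caste", values_from = "W")
  per_gene |>
    left_join(w_wide, by = "gene_id") |>
    mutate(
      delta_w = .data$reproductive - .data$sterile,
      is_dm_gene = .data$n_dm_cpgs >= min_dm_cpgs &
        !is.na(.data$delta_w) & abs(.data$delta_w) >= min_diff,
      hyper_in = dplyr::case_when(
        is.na(.data$delta_w) ~ NA_character_,
        .data$delta_w > 0 ~ "reproductive",
        .data$delta_w < 0 ~ "sterile",
        TRUE ~ NA_character_
      )
    ) |>
    select("gene_id", "n_dm_cpgs", "n_tested_cpgs", "delta_w",
           "is_dm_gene", "hyper_in")
}

#' Chi-squared goodness-of-fit test for hyper/hypomethylation direction
#'
#' Tests whether genes (or exons) split evenly between the two directions:
#' Pearson chi-squared against equal expected counts,
#' `X^2 = (a-E)^2/E + (b-E)^2/E` with `E = (a+b)/2`, 1 degree of freedom.
#'
#' @param n_a,n_b Counts in the two directions.
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
#' @examples
#' direction_test(63, 48)  # X-squared = 2.027
direction_test <- function(n_a, n_b) {
  if (n_a + n_b <= 0) abort_ct("direction_test needs a positive total count")
  e <- (n_a + n_b) / 2
  stat <- (n_a - e)^2 / e + (n_b - e)^2 / e
  tibble(statistic = stat, df = 1L,
         p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Permutation null distribution of the DM-site count
#'
#' Shuffles caste labels over samples (preserving the caste balance),
#' recomputes [dm_sites()] for each permutation, and returns the null
#' distribution of the number of DM sites together with the observed count's
#' empirical quantile. With few samples, `enumerate = TRUE` replaces random
#' shuffles with the complete set of distinct balanced label assignments
#' (at most `choose(n, n/2)`).
#'
#' Note: with strong structure between replicates (as between colonies),
#' permutation tests that break that structure are unreliable; interpret the
#' null with care, or shuffle within colonies when replication allows.
#'
#' @param counts,samples,sites,qvalue,min_diff As in [dm_sites()].
#' @param n_perm Number of random permutations (ignored when enumerating).
#' @param seed Optional seed for the random shuffles.
#' @param enumerate Enumerate all distinct balanced assignments instead of
#'   sampling.
#' @return Tibble with `perm` and `n_dm` per permutation; attributes
#'   `observed` (the unpermuted DM count) and `quantile` (its empirical
#'   quantile in the null).
#' @export
permutation_null <- function(counts, samples, sites = NULL, n_perm = 10000,
                             seed = NULL, enumerate = FALSE,
                             qvalue = 0.05, min_diff = 0.10) {
  message("note: permutation nulls are unreliable when the data carry ",
          "structure (e.g. strong colony effects) that label shuffling breaks")
  observed <- sum(dm_sites(counts, samples, sites, qvalue, min_diff)$is_dm)
  n_s <- nrow(samples)
  n_repro <- sum(samples$caste == "reproductive")
  assignments <- if (enumerate) {
    combn(n_s, n_repro, simplify = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    replicate(n_perm, sample.int(n_s, n_repro), simplify = FALSE)
  }
  if (length(assignments) == 0L || n_perm == 0L && !enumerate) {
    out <- tibble(perm = integer(), n_dm = integer())
    attr(out, "observed") <- observed
    attr(out, "quantile") <- NA_real_
    return(out)
  }
  n_dm <- purrr::map_int(assignments, function(idx) {
    perm_samples <- samples
    perm_samples$caste <- "sterile"
    perm_samples$caste[idx] <- "reproductive"
    sum(dm_sites(counts, perm_samples, sites, qvalue, min_diff)$is_dm)
  })
  out <- tibble(perm = seq_along(n_dm), n_dm = n_dm)
  attr(out, "observed") <- observed
  attr(out, "quantile") <- mean(n_dm <= observed)
  out
}
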