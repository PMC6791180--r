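#' Configuration for the WGBS simulator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate a pooled-library bumblebee-style caste study: six WGBS
#' libraries (two castes by three colonies), mean coverage around 17.7 reads
#' per CpG, a genome in which roughly 2% of CpG sites are methylated (giving a
#' genome-wide weighted methylation level of a few tenths of a percent),
#' bisulfite non-conversion of 0.45%, and strong shared intercolony variation
#' on the logit scale.
#'
#' @param n_sites Total number of CpG sites to simulate.
#' @param n_genes Number of genes the sites tile (default `n_sites / 10`,
#'   i.e. ten CpGs per gene).
#' @param frac_methylated_sites Fraction of sites that are truly methylated.
#' @param mean_coverage Mean read coverage per site (negative binomial mean).
#' @param coverage_dispersion Negative-binomial size parameter for coverage.
#' @param nonconversion Bisulfite non-conversion error rate (probability an
#'   unmethylated cytosine reads as methylated).
#' @param meth_alpha,meth_beta Beta parameters of the methylated-site level
#'   distribution.
#' @param n_dm_sites Number of truly differentially methylated (DM) CpGs.
#' @param n_dm_genes Number of genes the DM CpGs are clustered into
#'   (default `ceiling(n_dm_sites / 8)`).
#' @param dm_effect Difference in methylation proportion between castes at DM
#'   sites (split symmetrically, half added to one caste and subtracted from
#'   the other).
#' @param colony_sd SD of the logit-scale colony random effect, drawn once per
#'   colony and shared by both of its caste samples and all methylated sites.
#' @param n_colonies Number of colonies (each contributes one reproductive and
#'   one sterile pooled sample).
#' @param n_lambda_sites Number of lambda spike-in cytosines for
#'   [simulate_lambda()].
#' @param seed Integer seed; identical configurations give identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 50000,
                       n_genes = NULL,
                       frac_methylated_sites = 0.02,
                       mean_coverage = 17.7,
                       coverage_dispersion = 8,
                       nonconversion = 0.0045,
                       meth_alpha = 8,
                       meth_beta = 2,
                       n_dm_sites = 0,
                       n_dm_genes = NULL,
                       dm_effect = 0,
                       colony_sd = 0.5,
                       n_colonies = 3,
                       n_lambda_sites = 1e5,
                       seed = 1) {
  if (is.null(n_genes)) n_genes <- max(1L, floor(n_sites / 10))
  if (is.null(n_dm_genes)) n_dm_genes <- if (n_dm_sites > 0) ceiling(n_dm_sites / 8) else 0L
  cfg <- list(
    n_sites = as.integer(n_sites), n_genes = as.integer(n_genes),
    frac_methylated_sites = frac_methylated_sites,
    mean_coverage = mean_coverage, coverage_dispersion = coverage_dispersion,
    nonconversion = nonconversion,
    meth_alpha = meth_alpha, meth_beta = meth_beta,
    n_dm_sites = as.integer(n_dm_sites), n_dm_genes = as.integer(n_dm_genes),
    dm_effect = dm_effect, colony_sd = colony_sd,
    n_colonies = as.integer(n_colonies),
    n_lambda_sites = as.integer(n_lambda_sites),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_sites >= 1, n_genes >= 1, n_colonies >= 1,
              frac_methylated_sites >= 0, frac_methylated_sites <= 1,
              mean_coverage > 0, coverage_dispersion > 0,
              nonconversion >= 0, nonconversion < 1,
              meth_alpha > 0, meth_beta > 0,
              n_dm_sites >= 0, dm_effect >= 0, dm_effect <= 1,
              colony_sd >= 0, n_lambda_sites >= 1)
  })
  if (cfg$dm_effect / 2 > 0.49) {
    abort_ct("dm_effect %.2f leaves no room inside [0.01, 0.99] after clipping",
             cfg$dm_effect)
  }
  if (cfg$n_dm_sites > 0 && cfg$n_dm_genes > cfg$n_genes) {
    abort_ct("n_dm_genes exceeds n_genes")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a pooled WGBS caste study with ground truth
#'
#' Generates one per-CpG count table per sample (two castes by `n_colonies`
#' colonies) plus a toy gene/exon/intron annotation and truth tables for
#' recovery tests.
#'
#' Sites tile genes laid end-to-end (CpG every 50 bp, 500 bp gaps) across four
#' linkage groups. Coverage per site and sample is negative binomial truncated
#' at one read. Unmethylated sites emit methylated reads at the non-conversion
#' rate only. Each truly methylated site draws a level from
#' `Beta(meth_alpha, meth_beta)`; a colony effect drawn once per colony from
#' `Normal(0, colony_sd^2)` shifts that level on the logit scale for both of
#' the colony's samples. Methylated sites are clustered into genes (gene-body
#' methylation). DM CpGs are clustered into `n_dm_genes` genes; within a DM
#' gene all DM sites shift by `+dm_effect/2` in one caste and `-dm_effect/2`
#' in the other (clipped to `[0.01, 0.99]`), with the hypermethylated caste
#' chosen by a fair coin per gene so direction tests have a true null. The
#' level of DM sites is redrawn until the shifted levels survive clipping, so
#' the truth table always satisfies
#' `|p_reproductive - p_sterile| >= dm_effect`.
#'
#' @param config A [sim_config()].
#' @return A list of class `wgbs_sim` with tibbles `counts` (long:
#'   `sample_id`, `chrom`, `pos`, `strand`, `n_meth`, `n_total`), `samples`
#'   (`sample_id`, `caste`, `colony`), `features` (gene/exon/intron
#'   intervals), `truth_sites` and `truth_genes`.
#' @export
simulate_wgbs <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_sites <- config$n_sites
  n_genes <- config$n_genes

  # --- site / gene layout --------------------------------------------------
  gene_of_site <- sort(rep_len(seq_len(n_genes), n_sites))
  sites_per_gene <- tabulate(gene_of_site, nbins = n_genes)
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  n_lg <- 4L
  lg_of_gene <- rep_len(seq_len(n_lg), n_genes)[order(rep_len(seq_len(n_lg), n_genes))]
  lg_of_gene <- sort(rep_len(seq_len(n_lg), n_genes))
  # per linkage group, genes laid end to end: CpG every 50 bp, 500 bp gaps
  gene_len <- sites_per_gene * 50L
  gene_start <- integer(n_genes)
  for (lg in seq_len(n_lg)) {
    idx <- which(lg_of_gene == lg)
    gene_start[idx] <- cumsum(c(1L, head(gene_len[idx] + 500L, -1L)))
  }
  site_rank <- sequence(sites_per_gene)
  pos <- gene_start[gene_of_site] + (site_rank - 1L) * 50L + 10L
  chrom <- paste0("LG", lg_of_gene[gene_of_site])

  # --- truth assignment ----------------------------------------------------
  n_meth_target <- round(config$frac_methylated_sites * n_sites)
  dm_gene_idx <- integer(0)
  dm_site <- logical(n_sites)
  if (config$n_dm_sites > 0) {
    dm_gene_idx <- sample.int(n_genes, config$n_dm_genes)
    per_gene <- diff(round(seq(0, config$n_dm_sites, length.out = config$n_dm_genes + 1)))
    for (k in seq_along(dm_gene_idx)) {
      g_sites <- which(gene_of_site == dm_gene_idx[k])
      take <- min(per_gene[k], length(g_sites))
      dm_site[g_sites[seq_len(take)]] <- TRUE
    }
  }
  meth_site <- dm_site
  n_bg <- max(0L, n_meth_target - sum(dm_site))
  if (n_bg > 0L) {
    # cluster background methylated sites gene by gene (gene-body methylation)
    pool <- sample(setdiff(seq_len(n_genes), dm_gene_idx))
    for (g in pool) {
      if (n_bg <= 0L) break
      g_sites <- which(gene_of_site == g)
      take <- min(n_bg, length(g_sites))
      meth_site[g_sites[seq_len(take)]] <- TRUE
      n_bg <- n_bg - take
    }
  }

  m <- rep(NA_real_, n_sites)
  m[meth_site & !dm_site] <- rbeta(sum(meth_site & !dm_site),
                                   config$meth_alpha, config$meth_beta)
  # DM sites: level must leave room for +/- dm_effect/2 inside [0.01, 0.99]
  if (any(dm_site)) {
    lo <- 0.01 + config$dm_effect / 2
    hi <- 0.99 - config$dm_effect / 2
    need <- which(dm_site)
    draw <- rbeta(length(need), config$meth_alpha, config$meth_beta)
    for (round in 1:1000) {
      bad <- draw < lo | draw > hi
      if (!any(bad)) break
      draw[bad] <- rbeta(sum(bad), config$meth_alpha, config$meth_beta)
      if (round == 1000) {
        abort_ct("dm_effect %.2f incompatible with the Beta(%g, %g) level support",
                 config$dm_effect, config$meth_alpha, config$meth_beta)
      }
    }
    m[need] <- draw
  }

  dm_dir_gene <- setNames(sample(c(1, -1), length(dm_gene_idx), replace = TRUE),
                          gene_id[dm_gene_idx])
  dirs <- rep(0, n_sites)
  dirs[dm_site] <- dm_dir_gene[gene_id[gene_of_site[dm_site]]]
  half <- config$dm_effect / 2
  clip <- function(x) pmin(pmax(x, 0.01), 0.99)
  p_repro <- ifelse(meth_site, clip(m + dirs * half), 0)
  p_sterile <- ifelse(meth_site, clip(m - dirs * half), 0)

  # --- sample design and counts -------------------------------------------
  colonies <- paste0("C", seq_len(config$n_colonies))
  samples <- tidyr::expand_grid(colony = colonies,
                                caste = c("reproductive", "sterile")) |>
    mutate(sample_id = paste(.data$colony, substr(.data$caste, 1, 5), sep = "_")) |>
    select("sample_id", "caste", "colony")
  b_colony <- setNames(rnorm(config$n_colonies, 0, config$colony_sd), colonies)

  counts <- purrr::pmap(samples, function(sample_id, caste, colony) {
    n <- rnbinom(n_sites, mu = config$mean_coverage, size = config$coverage_dispersion)
    while (any(n == 0L)) {
      z <- which(n == 0L)
      n[z] <- rnbinom(length(z), mu = config$mean_coverage,
                      size = config$coverage_dispersion)
    }
    p_caste <- if (caste == "reproductive") p_repro else p_sterile
    level <- ifelse(meth_site, plogis(qlogis(p_caste) + b_colony[colony]),
                    config$nonconversion)
    tibble(sample_id = sample_id, chrom = chrom, pos = pos, strand = "+",
           n_meth = rbinom(n_sites, n, level), n_total = n)
  }) |> bind_rows()

  # --- annotation: gene span + two exons and one intron per gene -----------
  gene_end <- gene_start + gene_len - 1L
  feats_gene <- tibble(chrom = paste0("LG", lg_of_gene), start = gene_start,
                       end = gene_end, strand = "+", feature_type = "gene",
                       gene_id = gene_id)
  third <- pmax(1L, gene_len %/% 3L)
  feats_children <- bind_rows(
    tibble(chrom = feats_gene$chrom, start = gene_start,
           end = gene_start + third - 1L, strand = "+",
           feature_type = "exon", gene_id = gene_id),
    tibble(chrom = feats_gene$chrom, start = gene_start + third,
           end = gene_start + 2L * third - 1L, strand = "+",
           feature_type = "intron", gene_id = gene_id),
    tibble(chrom = feats_gene$chrom, start = gene_start + 2L * third,
           end = gene_end, strand = "+", feature_type = "exon",
           gene_id = gene_id)
  )
  features <- bind_rows(feats_gene, feats_children) |>
    arrange(.data$chrom, .data$start, .data$feature_type)

  truth_sites <- tibble(
    chrom = chrom, pos = pos, gene_id = gene_id[gene_of_site],
    true_class = ifelse(meth_site, "methylated", "unmethylated"),
    p_reproductive = p_repro, p_sterile = p_sterile,
    dm_flag = dm_site
  )
  truth_genes <- truth_sites |>
    group_by(.data$gene_id) |>
    summarise(n_cpgs = n(),
              n_meth_cpgs = sum(.data$true_class == "methylated"),
              methylated = .data$n_meth_cpgs > 0,
              dm_flag = any(.data$dm_flag),
              .groups = "drop") |>
    mutate(hyper_in = dplyr::case_when(
      !.data$dm_flag ~ NA_character_,
      dm_dir_gene[.data$gene_id] > 0 ~ "reproductive",
      TRUE ~ "sterile"
    ))

  structure(list(counts = counts, samples = samples, features = features,
                 truth_sites = truth_sites, truth_genes = truth_genes,
                 config = config),
            class = "wgbs_sim")
}

#' Simulate an unmethylated lambda spike-in count table
#'
#' Every lambda cytosine is truly unmethylated; methylated reads arise only
#' through bisulfite non-conversion, so
#' `1 - weighted methylation` of this table estimates conversion efficiency.
#'
#' @param config A [sim_config()]; uses `n_lambda_sites`, `mean_coverage`,
#'   `coverage_dispersion`, `nonconversion` and `seed`.
#' @return Tibble of lambda CpG count records (`chrom`, `pos`, `strand`,
#'   `n_meth`, `n_total`).
#' @export
simulate_lambda <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- rnbinom(config$n_lambda_sites, mu = config$mean_coverage,
               size = config$coverage_dispersion)
  while (any(n == 0L)) {
    z <- which(n == 0L)
    n[z] <- rnbinom(length(z), mu = config$mean_coverage,
                    size = config$coverage_dispersion)
  }
  tibble(chrom = "lambda", pos = seq_len(config$n_lambda_sites) * 10L,
         strand = "+",
         n_meth = rbinom(config$n_lambda_sites, n, config$nonconversion),
         n_total = n)
}

#' Simulate gene and exon expression tables with known differential labels
#'
#' Stand-in for upstream count-model outputs: negative-binomial gene counts
#' for three individuals per caste per colony (18 samples by default),
#' matching exon counts (three exons per gene), and tidy differential
#' expression / differential exon usage result tables computed from the truth
#' labels rather than from a fitted model (`q = 1` for null genes, a small
#' constant for labelled ones).
#'
#' Expression can be coupled to a per-gene methylation covariate: the
#' log-scale mean increases by `meth_effect` per unit of `meth_level`, which
#' lets power analyses construct a known methylation-expression slope.
#'
#' @param n_genes Number of genes.
#' @param n_colonies Number of colonies (3 individuals per caste per colony).
#' @param n_de_genes Number of differentially expressed genes.
#' @param log2fc Absolute caste log2 fold-change given to DE genes (sign is a
#'   fair coin per gene).
#' @param n_dee_exons Number of differentially used exons (each in a distinct
#'   gene).
#' @param meth_level Optional numeric vector (length `n_genes`) of per-gene
#'   methylation levels to couple expression to.
#' @param meth_effect Log-scale slope of expression on `meth_level`.
#' @param base_log_mean,base_log_sd Log-normal parameters of per-gene baseline
#'   mean expression.
#' @param size Negative-binomial size (inverse dispersion) of counts.
#' @param seed Integer seed.
#' @return List of class `expr_sim` with `gene_counts` (long tibble:
#'   `gene_id`, `sample_id`, `caste`, `colony`, `count`, `fpkm`),
#'   `exon_counts`, `samples`, `de_results` (`gene_id`, `log2fc`, `q`,
#'   `de_flag`), `dee_results` (`gene_id`, `exon_id`, `log2fc`, `q`,
#'   `dee_flag`) and `gene_means` (configured per-gene baseline means).
#' @export
simulate_expression <- function(n_genes = 1000,
                                n_colonies = 3,
                                n_de_genes = 0,
                                log2fc = 2,
                                n_dee_exons = 0,
                                meth_level = NULL,
                                meth_effect = 0,
                                base_log_mean = 4,
                                base_log_sd = 1,
                                size = 10,
                                seed = 1) {
  stopifnot(n_de_genes <= n_genes, n_dee_exons <= n_genes)
  set.seed(seed)
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  if (is.null(meth_level)) meth_level <- rep(0, n_genes)
  stopifnot(length(meth_level) == n_genes)

  samples <- tidyr::expand_grid(colony = paste0("C", seq_len(n_colonies)),
                                caste = c("reproductive", "sterile"),
                                rep = 1:3) |>
    mutate(sample_id = paste(.data$colony, substr(.data$caste, 1, 5),
                             .data$rep, sep = "_")) |>
    select("sample_id", "caste", "colony")

  base_mu <- exp(rnorm(n_genes, base_log_mean, base_log_sd) +
                   meth_effect * meth_level)
  de_idx <- if (n_de_genes > 0) sample.int(n_genes, n_de_genes) else integer(0)
  de_sign <- setNames(rep(0, n_genes), gene_id)
  de_sign[de_idx] <- sample(c(1, -1), n_de_genes, replace = TRUE)
  gene_len <- sample(500:5000, n_genes, replace = TRUE)

  gene_counts <- purrr::pmap(samples, function(sample_id, caste, colony) {
    lfc <- ifelse(caste == "reproductive", de_sign * log2fc / 2,
                  -de_sign * log2fc / 2)
    mu <- base_mu * 2^lfc
    tibble(gene_id = gene_id, sample_id = sample_id, caste = caste,
           colony = colony,
           count = rnbinom(n_genes, mu = mu, size = size))
  }) |> bind_rows()
  lib_size <- gene_counts |> group_by(.data$sample_id) |>
    summarise(lib = sum(.data$count), .groups = "drop")
  gene_counts <- gene_counts |>
    left_join(lib_size, by = "sample_id") |>
    mutate(fpkm = .data$count / (gene_len[match(.data$gene_id, gene_id)] / 1e3) /
             (.data$lib / 1e6)) |>
    select(-"lib")

  de_results <- tibble(
    gene_id = gene_id,
    log2fc = de_sign * log2fc,
    de_flag = de_sign != 0,
    q = ifelse(de_sign != 0, 1e-3, 1)
  )

  # exons: 3 per gene; DEE exons sit in distinct genes, exon 1 shifts
  dee_genes <- if (n_dee_exons > 0) sample.int(n_genes, n_dee_exons) else integer(0)
  exon_tbl <- tidyr::expand_grid(gene_id = gene_id, exon = 1:3) |>
    mutate(exon_id = paste0(.data$gene_id, "_e", .data$exon),
           dee_flag = .data$gene_id %in% gene_id[dee_genes] & .data$exon == 1L,
           dee_sign = ifelse(.data$dee_flag,
                             sample(c(1, -1), dplyr::n(), replace = TRUE), 0))
  exon_counts <- purrr::pmap(samples, function(sample_id, caste, colony) {
    lfc <- ifelse(caste == "reproductive", exon_tbl$dee_sign * log2fc / 2,
                  -exon_tbl$dee_sign * log2fc / 2)
    mu <- (base_mu[match(exon_tbl$gene_id, gene_id)] / 3) * 2^lfc
    tibble(gene_id = exon_tbl$gene_id, exon_id = exon_tbl$exon_id,
           sample_id = sample_id, caste = caste, colony = colony,
           count = rnbinom(nrow(exon_tbl), mu = mu, size = size))
  }) |> bind_rows()
  dee_results <- exon_tbl |>
    transmute_dee(log2fc)

  structure(list(gene_counts = gene_counts, exon_counts = exon_counts,
                 samples = samples, de_results = de_results,
                 dee_results = dee_results,
                 gene_means = tibble(gene_id = gene_id, mu = base_mu,
                                     length = gene_len)),
            class = "expr_sim")
}

transmute_dee <- function(exon_tbl, log2fc) {
  tibble(gene_id = exon_tbl$gene_id, exon_id = exon_tbl$exon_id,
         log2fc = exon_tbl$dee_sign * log2fc,
         dee_flag = exon_tbl$dee_flag,
         q = ifelse(exon_tbl$dee_flag, 1e-3, 1))
}
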