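test_that("weighted level is the pooled-count ratio", {
  expect_equal(weighted_level(c(0, 0), c(10, 30)), 0)
  expect_equal(weighted_level(c(3, 7), c(10, 10)), 0.5)
  expect_true(is.na(weighted_level(integer(0), integer(0))))
  expect_true(is.na(weighted_level(0, 0)))
})

test_that("weighted level is invariant under site subdivision and ordering", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    tot <- sample(5:40, n, replace = TRUE)
    met <- rbinom(n, tot, 0.3)
    w0 <- weighted_level(met, tot)
    # split the first site's reads into two pieces
    k <- sample.int(met[1] + 1, 1) - 1
    kt <- sample(seq(max(k, 1), tot[1] - (met[1] - k)), 1)
    met2 <- c(k, met[1] - k, met[-1])
    tot2 <- c(kt, tot[1] - kt, tot[-1])
    expect_equal(weighted_level(met2, tot2), w0)
    perm <- sample.int(n)
    expect_equal(weighted_level(met[perm], tot[perm]), w0)
    # bounded by the per-site extremes
    lev <- met / tot
    expect_gte(w0, min(lev) - 1e-12)
    expect_lte(w0, max(lev) + 1e-12)
  }
})

test_that("per-unit weighted methylation aggregates over the assignment", {
  counts <- tibble::tibble(
    sample_id = "s1", chrom = "c1", pos = c(10L, 20L, 30L),
    n_meth = c(3L, 7L, 0L), n_total = c(10L, 10L, 10L))
  map <- tibble::tibble(chrom = "c1", pos = c(10L, 20L, 30L),
                        gene_id = c("gA", "gA", "gB"))
  wm <- weighted_methylation(counts, map)
  expect_equal(wm$W[wm$gene_id == "gA"], 0.5)
  expect_equal(wm$W[wm$gene_id == "gB"], 0)
  expect_equal(wm$n_cpgs, c(2L, 1L))
})

test_that("caste means sit between the colony values", {
  cfg <- sim_config(n_sites = 2000, seed = 13)
  sim <- simulate_wgbs(cfg)
  sg <- dplyr::filter(annotate_sites(dplyr::distinct(sim$counts, chrom, pos),
                                     sim$features),
                      feature_type == "gene")
  wm <- weighted_methylation(sim$counts, sg)
  cw <- caste_methylation(wm, sim$samples)
  per_sample <- wm |>
    dplyr::inner_join(sim$samples, by = "sample_id") |>
    dplyr::filter(!is.na(W))
  chk <- cw |>
    dplyr::inner_join(
      per_sample |>
        dplyr::group_by(gene_id, caste) |>
        dplyr::summarise(lo = min(W), hi = max(W), .groups = "drop"),
      by = c("gene_id", "caste"))
  expect_true(all(chk$W >= chk$lo - 1e-12 & chk$W <= chk$hi + 1e-12))
})

test_that("methylated-gene classification follows the W > 0 rule", {
  wm <- tibble::tibble(gene_id = c("g1", "g1", "g2", "g2", "g3"),
                       sample_id = c("a", "b", "a", "b", "a"),
                       W = c(0, 0, 0, 0.001, NA), n_cpgs = 1L)
  expect_equal(classify_methylated_genes(wm), "g2")
})

test_that("classification recovers truth-methylated genes on simulated data", {
  cfg <- sim_config(n_sites = 4000, seed = 17)
  sim <- simulate_wgbs(cfg)
  sg <- dplyr::filter(annotate_sites(dplyr::distinct(sim$counts, chrom, pos),
                                     sim$features),
                      feature_type == "gene")
  wm <- weighted_methylation(sim$counts, sg)
  called <- classify_methylated_genes(wm)
  truth <- sim$truth_genes$gene_id[sim$truth_genes$methylated]
  # every truth-methylated gene shows W > 0 somewhere (non-conversion reads
  # can add spurious "methylated" genes, so containment, not equality)
  expect_true(all(truth %in% called))
})

test_that("methylation bins respect the printed boundaries", {
  expect_equal(as.character(bin_methylation(c(0, 0.2, 0.700001, 1, 0.0001))),
               c("none", "low", "high", "high", "low"))
  expect_equal(as.character(bin_methylation(0.7)), "medium")
  expect_true(all(bin_methylation(rep(1, 5)) == "high"))
  # brute-force interval test on random levels
  set.seed(23)
  w <- runif(1000)
  got <- as.character(bin_methylation(w))
  want <- ifelse(w == 0, "none",
                 ifelse(w <= 0.2, "low", ifelse(w <= 0.7, "medium", "high")))
  expect_equal(got, want)
})

test_that("feature and linkage summaries aggregate weighted levels", {
  counts <- tibble::tibble(
    sample_id = "s1", chrom = "c1", pos = c(10L, 20L),
    n_meth = c(2L, 4L), n_total = c(10L, 10L))
  ann <- tibble::tibble(chrom = "c1", pos = c(10L, 20L),
                        feature_type = "exon", gene_id = "g")
  samples <- tibble::tibble(sample_id = "s1", caste = "sterile", colony = "C1")
  fs <- feature_summary(counts, ann, samples)
  expect_equal(fs$W, weighted_level(c(2, 4), c(10, 10)))

  # disjoint classes stay independent
  ann2 <- tibble::tibble(chrom = "c1", pos = c(10L, 20L),
                         feature_type = c("exon", "intron"), gene_id = "g")
  fs2 <- feature_summary(counts, ann2, samples)
  expect_equal(fs2$W[fs2$feature_type == "exon"], 0.2)
  expect_equal(fs2$W[fs2$feature_type == "intron"], 0.4)

  ls <- linkage_summary(counts, samples)
  expect_equal(ls$W, 0.3)
})

test_that("exon-enriched fixture orders feature classes in both castes", {
  # construct counts where exon CpGs carry 5x the methylation of intron CpGs
  set.seed(41)
  samples <- toy_samples()
  grid <- tidyr::expand_grid(sample_id = samples$sample_id,
                             pos = 1:200 * 10L)
  grid$chrom <- "c1"
  exon <- grid$pos <= 1000
  grid$n_total <- 20L
  grid$n_meth <- rbinom(nrow(grid), 20, ifelse(exon, 0.5, 0.1))
  ann <- tibble::tibble(chrom = "c1", pos = 1:200 * 10L,
                        feature_type = ifelse(1:200 * 10L <= 1000,
                                              "exon", "intron"),
                        gene_id = "g")
  fs <- feature_summary(grid, ann, samples)
  for (ca in c("reproductive", "sterile")) {
    expect_gt(fs$W[fs$feature_type == "exon" & fs$caste == ca],
              fs$W[fs$feature_type == "intron" & fs$caste == ca])
  }
})
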