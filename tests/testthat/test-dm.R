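test_that("identical caste count profiles are never differentially methylated", {
  counts <- toy_site_counts(meth_repro = c(5, 6, 4), meth_sterile = c(5, 6, 4))
  res <- dm_sites(counts, toy_samples())
  expect_equal(res$meth_diff, 0)
  expect_false(res$is_dm)
})

test_that("clear caste separation is detected and the LRT matches an
           independent likelihood maximisation", {
  counts <- toy_site_counts(meth_repro = c(18, 17, 19),
                            meth_sterile = c(2, 3, 1))
  res <- dm_sites(counts, toy_samples())
  expect_true(res$is_dm)
  expect_equal(res$meth_diff, (18 + 17 + 19) / 60 - (2 + 3 + 1) / 60)
  d <- dplyr::inner_join(counts, toy_samples(), by = "sample_id")
  expect_lt(abs(res$p - ml_lrt_oracle(d)), 1e-6)

  # a weaker, noisier site: oracle still agrees
  counts2 <- toy_site_counts(meth_repro = c(10, 12, 8),
                             meth_sterile = c(6, 5, 9))
  res2 <- dm_sites(counts2, toy_samples())
  d2 <- dplyr::inner_join(counts2, toy_samples(), by = "sample_id")
  expect_lt(abs(res2$p - ml_lrt_oracle(d2)), 1e-6)
})

test_that("caste-label swap flips the difference sign but not the p-value", {
  counts <- toy_site_counts(meth_repro = c(15, 14, 16),
                            meth_sterile = c(5, 7, 6))
  samples <- toy_samples()
  res <- dm_sites(counts, samples)
  swapped <- samples
  swapped$caste <- ifelse(samples$caste == "reproductive", "sterile",
                          "reproductive")
  res_sw <- dm_sites(counts, swapped)
  expect_equal(res_sw$meth_diff, -res$meth_diff)
  expect_equal(res_sw$p, res$p, tolerance = 1e-9)
  # sample order is irrelevant
  res_perm <- dm_sites(counts[sample.int(6), ], samples)
  expect_equal(res_perm$p, res$p)
})

test_that("BH q-values are monotone in p-value rank", {
  cfg <- sim_config(n_sites = 1500, n_dm_sites = 24, n_dm_genes = 3,
                    dm_effect = 0.3, seed = 19)
  sim <- simulate_wgbs(cfg)
  meth <- sim$truth_sites[sim$truth_sites$true_class == "methylated",
                          c("chrom", "pos")]
  res <- dm_sites(sim$counts, sim$samples, sites = meth)
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_equal(res$q, p.adjust(res$p, "BH"))
})

test_that("degenerate sites keep p = 1 and stay in the tested universe", {
  counts <- dplyr::bind_rows(
    toy_site_counts(c(0, 0, 0), c(0, 0, 0)),
    toy_site_counts(c(18, 17, 19), c(2, 3, 1)) |> dplyr::mutate(pos = 200L))
  res <- dm_sites(counts, toy_samples())
  expect_equal(nrow(res), 2)
  expect_true(res$degenerate[res$pos == 100])
  expect_equal(res$p[res$pos == 100], 1)
})

test_that("gene calls require both a DM CpG and a 10% weighted difference", {
  site_res <- tibble::tibble(chrom = "c1", pos = c(10L, 20L),
                             meth_diff = c(0.4, 0.02), p = c(1e-5, 0.9),
                             q = c(1e-4, 0.9), is_dm = c(TRUE, FALSE),
                             degenerate = FALSE)
  map <- tibble::tibble(chrom = "c1", pos = c(10L, 20L),
                        gene_id = c("gA", "gB"))
  cw <- tibble::tibble(gene_id = rep(c("gA", "gB"), each = 2),
                       caste = rep(c("reproductive", "sterile"), 2),
                       W = c(0.30, 0.25, 0.9, 0.4))
  res <- dm_genes(site_res, map, cw)
  # gA has a DM CpG but only 5% gene-level difference
  expect_false(res$is_dm_gene[res$gene_id == "gA"])
  # gB has a 50% difference but no DM CpG
  expect_false(res$is_dm_gene[res$gene_id == "gB"])
  expect_equal(res$hyper_in, c("reproductive", "reproductive"))

  # both conditions met
  cw2 <- cw
  cw2$W[cw2$gene_id == "gA"] <- c(0.45, 0.25)
  res2 <- dm_genes(site_res, map, cw2)
  expect_true(res2$is_dm_gene[res2$gene_id == "gA"])
})

test_that("direction test reproduces the chi-squared goodness-of-fit form", {
  expect_equal(round(direction_test(63, 48)$statistic, 3), 2.027)
  expect_equal(direction_test(50, 50)$statistic, 0)
  expect_equal(round(direction_test(33, 50)$statistic, 4), 3.4819)
  # equals stats::chisq.test against equal expected proportions
  ct <- suppressWarnings(stats::chisq.test(c(63, 48), p = c(0.5, 0.5)))
  expect_equal(direction_test(63, 48)$statistic, unname(ct$statistic))
  expect_equal(direction_test(63, 48)$p, ct$p.value)
  expect_error(direction_test(0, 0), "positive")
})

test_that("permutation null enumerates the exchangeable set and is reproducible", {
  cfg <- sim_config(n_sites = 60, n_dm_sites = 8, n_dm_genes = 1,
                    dm_effect = 0.4, seed = 29)
  sim <- simulate_wgbs(cfg)
  meth <- sim$truth_sites[sim$truth_sites$true_class == "methylated",
                          c("chrom", "pos")]
  suppressMessages({
    null0 <- permutation_null(sim$counts, sim$samples, sites = meth, n_perm = 0)
    expect_equal(nrow(null0), 0)
    expect_true(is.numeric(attr(null0, "observed")))

    en <- permutation_null(sim$counts, sim$samples, sites = meth,
                           enumerate = TRUE)
    expect_equal(nrow(en), choose(6, 3))

    r1 <- permutation_null(sim$counts, sim$samples, sites = meth,
                           n_perm = 8, seed = 5)
    r2 <- permutation_null(sim$counts, sim$samples, sites = meth,
                           n_perm = 8, seed = 5)
    expect_identical(r1$n_dm, r2$n_dm)
  })
})
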