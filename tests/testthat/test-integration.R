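test_that("binned expression contrast matches rank-sum arithmetic", {
  # identical expression in every gene: H = 0
  flat <- tibble::tibble(bin = factor(rep(c("none", "low"), each = 5)),
                         expr = 1)
  res <- expression_by_meth_bin(flat)
  expect_equal(res$kruskal$statistic, 0)

  # two clearly separated bins: H from hand-computed rank sums
  d <- tibble::tibble(bin = factor(rep(c("none", "low"), each = 3)),
                      expr = c(1, 2, 3, 10, 11, 12))
  res2 <- expression_by_meth_bin(d)
  N <- 6; R1 <- 1 + 2 + 3; R2 <- 4 + 5 + 6
  H <- 12 / (N * (N + 1)) * (R1^2 / 3 + R2^2 / 3) - 3 * (N + 1)
  expect_equal(res2$kruskal$statistic, H)
  # Dunn Z for the only pair: difference of mean ranks over its SE
  sigma <- sqrt((N * (N + 1) / 12) * (1 / 3 + 1 / 3))
  expect_equal(abs(res2$dunn$z), abs((R1 / 3 - R2 / 3) / sigma))

  # under-filled bins are dropped with a warning
  expect_warning(
    expression_by_meth_bin(tibble::tibble(
      bin = factor(c(rep("none", 4), rep("low", 4), "high")),
      expr = c(rnorm(8), 5))),
    "high")
})

test_that("suppressed low-methylation genes show lower binned expression", {
  set.seed(51)
  n <- 400
  W <- c(rep(0, n / 2), runif(n / 4, 0.01, 0.2), runif(n / 4, 0.3, 0.9))
  bins <- bin_methylation(W)
  mu <- ifelse(bins == "low", 2, 4)   # low bin suppressed by construction
  d <- tibble::tibble(bin = bins, expr = rnorm(n, mu, 0.5))
  res <- expression_by_meth_bin(d)
  expect_lt(res$summary$mean[res$summary$bin == "low"],
            res$summary$mean[res$summary$bin == "none"])
  expect_lt(res$kruskal$p, 0.01)
})

test_that("methylation-expression mixed model finds a built-in W slope", {
  set.seed(61)
  n_genes <- 500
  genes <- tibble::tibble(gene_id = seq_len(n_genes),
                          W = runif(n_genes, 0, 0.8))
  d <- tidyr::expand_grid(gene_id = genes$gene_id,
                          colony = c("C1", "C2", "C3"),
                          caste = c("reproductive", "sterile")) |>
    dplyr::left_join(genes, by = "gene_id") |>
    dplyr::mutate(colony_eff = c(C1 = -0.3, C2 = 0, C3 = 0.3)[colony],
                  expr = 1 + 2 * W + colony_eff + rnorm(dplyr::n(), 0, 0.5))
  fit <- meth_expression_model(d)
  expect_lt(fit$p[fit$term == "W"], 0.01)
  expect_gt(fit$p[fit$term == "castereproductive"], 0.05)
  expect_false(attr(fit, "fallback"))
  expect_equal(fit$estimate[fit$term == "W"], 2, tolerance = 0.15)
})

test_that("constant methylation is flagged inestimable and permuted caste
           labels stay null", {
  d0 <- tibble::tibble(expr = rnorm(60), W = 0.3,
                       caste = rep(c("reproductive", "sterile"), 30),
                       colony = rep(c("C1", "C2", "C3"), 20))
  fit0 <- meth_expression_model(d0)
  expect_true(attr(fit0, "inestimable"))

  set.seed(71)
  base <- tidyr::expand_grid(gene_id = 1:150,
                             colony = c("C1", "C2", "C3"),
                             caste = c("reproductive", "sterile"))
  base$W <- runif(nrow(base), 0, 0.5)
  base$expr <- 1 + base$W + rnorm(nrow(base), 0, 0.4)
  hits <- 0
  for (i in 1:20) {
    perm <- base
    perm$caste <- sample(perm$caste)
    fit <- meth_expression_model(perm)
    if (fit$p[fit$term == "castereproductive"] < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 2)
})

test_that("group methylation contrast reports the nested-model algebra", {
  set.seed(81)
  n <- 30
  d <- tibble::tibble(
    W = runif(2 * n, 0, 0.6),
    group = rep(c(TRUE, FALSE), n),
    caste = rep(c("reproductive", "sterile"), each = n))
  tab <- group_methylation_contrast(d)
  expect_equal(tab$comparison, c("interaction_vs_main", "group", "caste"))
  # F equals ((RSS_r - RSS_f)/d.df) / (RSS_f/df_f) computed from raw residuals
  full <- lm(W ~ group * caste, data = d)
  main <- lm(W ~ group + caste, data = d)
  no_group <- lm(W ~ caste, data = d)
  rss <- function(m) sum(resid(m)^2)
  f_inter <- ((rss(main) - rss(full)) / 1) / (rss(full) / full$df.residual)
  f_group <- ((rss(no_group) - rss(main)) / 1) / (rss(main) / main$df.residual)
  expect_equal(tab$F[1], f_inter, tolerance = 1e-10)
  expect_equal(tab$F[2], f_group, tolerance = 1e-10)
  expect_equal(tab$sum_sq[2], rss(no_group) - rss(main), tolerance = 1e-10)
})

test_that("a lower-methylation gene group is detected without a caste effect", {
  set.seed(91)
  n <- 500
  d <- tidyr::expand_grid(gene = seq_len(n),
                          caste = c("reproductive", "sterile"))
  d$group <- rep(c(rep(TRUE, 100), rep(FALSE, n - 100)), each = 2)
  d$W <- pmax(0, rnorm(nrow(d), ifelse(d$group, 0.1, 0.25), 0.08))
  tab <- group_methylation_contrast(d)
  expect_lt(tab$p[tab$comparison == "group"], 1e-6)
  expect_gt(tab$p[tab$comparison == "caste"], 0.05)
  # identical-distribution null: group term quiet
  d0 <- d; d0$group <- sample(d0$group)
  tab0 <- group_methylation_contrast(d0)
  expect_gt(tab0$p[tab0$comparison == "group"], 0.01)
})

test_that("hypergeometric overlap equals exact enumeration", {
  expect_equal(overlap_test("a", "b", c("a", "b"))$p, 1)
  p3 <- overlap_test(c("a", "b", "c"), c("a", "b", "c"),
                     c("a", "b", "c", "d", "e", "f"))$p
  expect_equal(p3, 1 / choose(6, 3))
  expect_error(overlap_test("z", "a", c("a", "b")), "subset")

  set.seed(101)
  universe <- paste0("g", 1:20)
  for (i in 1:5) {
    A <- sample(universe, sample(3:8, 1))
    B <- sample(universe, sample(3:6, 1))
    got <- overlap_test(A, B, universe)$p
    expect_equal(got, enum_hyper_p(A, B, universe), tolerance = 1e-12)
  }
})

test_that("differential methylation vs expression regression behaves", {
  d <- tibble::tibble(delta_w = seq(0.01, 0.5, length.out = 20))
  d$log2fc <- 2 * d$delta_w
  fit <- suppressWarnings(dm_de_relationship(d))  # perfect-fit diagnostic
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_error(dm_de_relationship(d[1:2, ]), "at least 3")

  # independent signals: p roughly uniform across seeds
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    dd <- tibble::tibble(delta_w = runif(50, 0, 0.4), log2fc = rnorm(50))
    if (dm_de_relationship(dd)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.01)
  expect_lte(hits / 100, 0.10)
})

test_that("sample PCA is deterministic with orthonormal loadings and
           separates colonies when colony variance dominates", {
  m <- matrix(rnorm(40), nrow = 4,
              dimnames = list(paste0("s", 1:4), NULL))
  m[2, ] <- m[1, ]   # identical samples coincide
  pca <- sample_pca(m)
  expect_equal(unlist(pca$scores[1, -1]), unlist(pca$scores[2, -1]))
  rot <- pca$fit$rotation
  expect_equal(unname(crossprod(rot)), diag(ncol(rot)), tolerance = 1e-10)

  cfg <- sim_config(n_sites = 3000, colony_sd = 0.8, seed = 37)
  sim <- simulate_wgbs(cfg)
  meth <- sim$truth_sites[sim$truth_sites$true_class == "methylated",
                          c("chrom", "pos")]
  wide <- sim$counts |>
    dplyr::inner_join(meth, by = c("chrom", "pos")) |>
    dplyr::mutate(level = n_meth / n_total,
                  site = paste(chrom, pos)) |>
    dplyr::select(sample_id, site, level) |>
    tidyr::pivot_wider(names_from = site, values_from = level)
  mat <- as.matrix(wide[, -1]); rownames(mat) <- wide$sample_id
  pca2 <- sample_pca(mat)
  sc <- dplyr::inner_join(pca2$scores, sim$samples, by = "sample_id")
  sil <- function(lab) {
    xy <- as.matrix(sc[, c("PC1", "PC2")])
    d <- as.matrix(dist(xy))
    mean(sapply(seq_len(nrow(xy)), function(i) {
      same <- lab == lab[i] & seq_along(lab) != i
      other <- lab != lab[i]
      a <- mean(d[i, same])
      b <- min(tapply(d[i, other], lab[other], mean))
      (b - a) / max(a, b)
    }))
  }
  expect_gt(sil(sc$colony), sil(sc$caste))
})
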