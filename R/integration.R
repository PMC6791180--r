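#' Expression contrasts across methylation bins
#'
#' Compares (log-scale) expression across methylation bins with a
#' Kruskal-Wallis test and pairwise Dunn rank-sum contrasts with
#' Benjamini-Hochberg adjustment. Bins with fewer than two genes are excluded
#' with a warning.
#'
#' @param data Tibble with a `bin` column (from [bin_methylation()]) and an
#'   `expr` column (typically `log(FPKM + offset)`).
#' @param offset If `expr` is absent but `fpkm` is present, `expr` is
#'   computed as `log(fpkm + offset)` (default 0.01).
#' @return List of class `meth_bin_contrast`: `summary` (per-bin n, mean,
#'   median), `kruskal` (tibble: `statistic`, `df`, `p`) and `dunn` (tibble:
#'   `bin_a`, `bin_b`, `z`, `p`, `p_adj`).
#' @export
expression_by_meth_bin <- function(data, offset = 0.01) {
  if (!"expr" %in% names(data)) {
    stopifnot("fpkm" %in% names(data))
    data$expr <- log(data$fpkm + offset)
  }
  data <- filter(data, !is.na(.data$bin), !is.na(.data$expr))
  sizes <- table(droplevels(factor(data$bin)))
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning(sprintf("bins excluded with < 2 genes: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    data <- filter(data, !(.data$bin %in% small))
  }
  data$bin <- droplevels(factor(data$bin))
  if (nlevels(data$bin) < 2) abort_ct("need at least two non-empty bins")
  if (stats::var(data$expr) == 0) {
    # all observations tied: no rank variation, H is identically zero
    kw <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
               parameter = c(df = nlevels(data$bin) - 1), p.value = 1)
  } else {
    kw <- kruskal.test(expr ~ bin, data = data)
  }
  summary_tbl <- data |>
    group_by(.data$bin) |>
    summarise(n = n(), mean = mean(.data$expr), median = stats::median(.data$expr),
              .groups = "drop")
  structure(list(
    summary = summary_tbl,
    kruskal = tibble(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p = kw$p.value),
    dunn = dunn_pairwise(data$expr, data$bin)
  ), class = "meth_bin_contrast")
}

# Dunn's pairwise rank-sum Z with tie correction, BH-adjusted; the standard
# post hoc for a Kruskal-Wallis comparison.
dunn_pairwise <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  pairs <- combn(levels(g), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    sigma <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / sigma
    tibble(bin_a = i, bin_b = j, z = z, p = 2 * pnorm(-abs(z)))
  }) |>
    mutate(p_adj = p.adjust(.data$p, method = "BH"))
}

#' @export
print.meth_bin_contrast <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.3g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p))
  print(x$dunn)
  invisible(x)
}

#' Mixed model of expression on methylation and caste
#'
#' Fits `expr ~ W * caste + (1 | colony)` (random colony intercept) with
#' lmerTest so the methylation, caste and interaction terms come with
#' Satterthwaite degrees of freedom and p-values. If the random-effect fit is
#' singular or fails, falls back to fixed colony effects
#' (`expr ~ W * caste + colony`) and flags the result.
#'
#' @param data Tibble with `expr`, `W`, `caste`, `colony` (one row per gene
#'   per caste per colony, i.e. W and expression matched within colony).
#' @return Tibble of the `W`, caste and interaction terms: `term`,
#'   `estimate`, `std_error`, `df`, `t`, `p`; attribute `fallback` is TRUE
#'   when fixed colony effects were used, and `inestimable` flags a constant
#'   `W`.
#' @export
meth_expression_model <- function(data) {
  stopifnot(all(c("expr", "W", "caste", "colony") %in% names(data)))
  data$caste <- factor(data$caste, levels = c("sterile", "reproductive"))
  if (stats::var(data$W, na.rm = TRUE) == 0) {
    out <- tibble(term = c("W", "castereproductive", "W:castereproductive"),
                  estimate = NA_real_, std_error = NA_real_, df = NA_real_,
                  t = NA_real_, p = NA_real_)
    attr(out, "inestimable") <- TRUE
    attr(out, "fallback") <- FALSE
    return(out)
  }
  fallback <- FALSE
  fit <- tryCatch({
    m <- lmerTest::lmer(expr ~ W * caste + (1 | colony), data = data)
    if (lme4::isSingular(m, tol = 1e-5)) NULL else m
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    fallback <- TRUE
    m <- lm(expr ~ W * caste + colony, data = data)
    cf <- summary(m)$coefficients
    keep <- c("W", "castereproductive", "W:castereproductive")
    out <- tibble(term = keep,
                  estimate = unname(cf[keep, 1]), std_error = unname(cf[keep, 2]),
                  df = m$df.residual, t = unname(cf[keep, 3]),
                  p = unname(cf[keep, 4]))
  } else {
    cf <- summary(fit)$coefficients
    keep <- c("W", "castereproductive", "W:castereproductive")
    out <- tibble(term = keep,
                  estimate = unname(cf[keep, "Estimate"]),
                  std_error = unname(cf[keep, "Std. Error"]),
                  df = unname(cf[keep, "df"]), t = unname(cf[keep, "t value"]),
                  p = unname(cf[keep, "Pr(>|t|)"]))
  }
  attr(out, "fallback") <- fallback
  attr(out, "inestimable") <- FALSE
  out
}

#' Weighted-methylation contrast between gene sets
#'
#' Tests whether a gene group (e.g. differentially expressed vs not) differs
#' in weighted methylation, accounting for caste, via nested linear models:
#' the interaction model `W ~ group * caste` against the main-effects model
#' (interaction row), the main-effects model against `W ~ caste` (group row)
#' and against `W ~ group` (caste row). Each row reports residual df, RSS,
#' the df and sum-of-squares difference, F and p — the classic
#' model-comparison ANOVA layout.
#'
#' @param data Tibble with `W`, logical or factor `group`, and `caste` (one
#'   row per unit per caste).
#' @return Tibble with rows `interaction_vs_main`, `group`, `caste` and
#'   columns `res_df`, `rss`, `df`, `sum_sq`, `F`, `p`.
#' @export
group_methylation_contrast <- function(data) {
  stopifnot(all(c("W", "group", "caste") %in% names(data)))
  data <- filter(data, !is.na(.data$W))
  data$group <- factor(data$group)
  data$caste <- factor(data$caste)
  full <- lm(W ~ group * caste, data = data)
  main <- lm(W ~ group + caste, data = data)
  no_group <- lm(W ~ caste, data = data)
  no_caste <- lm(W ~ group, data = data)
  cmp <- function(label, reduced, larger) {
    a <- anova(reduced, larger)
    tibble(comparison = label,
           res_df = a$Res.Df[2], rss = a$RSS[2],
           df = a$Df[2], sum_sq = a$`Sum of Sq`[2],
           F = a$F[2], p = a$`Pr(>F)`[2])
  }
  bind_rows(
    cmp("interaction_vs_main", full, main),
    cmp("group", no_group, main),
    cmp("caste", no_caste, main)
  )
}

#' Hypergeometric set-overlap test
#'
#' Upper-tail probability of observing at least the realised overlap between
#' two gene sets drawn from a common universe: `P(X >= k)` with
#' `X ~ Hypergeometric(|A|, N - |A|, |B|)`.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector containing both sets.
#' @return Tibble with `n_a`, `n_b`, `n_universe`, `overlap`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort_ct("both sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, length(set_a), length(universe) - length(set_a),
              length(set_b), lower.tail = FALSE)
  tibble(n_a = length(set_a), n_b = length(set_b),
         n_universe = length(universe), overlap = k, p = p)
}

#' Relationship between differential methylation and differential expression
#'
#' Ordinary least squares of expression log2 fold-change on the gene-level
#' caste weighted-methylation difference, for genes carrying both signals.
#'
#' @param data Tibble with `delta_w` and `log2fc`.
#' @return Tibble with `slope`, `r_squared`, `F`, `df1`, `df2`, `p`.
#' @export
dm_de_relationship <- function(data) {
  data <- filter(data, !is.na(.data$delta_w), !is.na(.data$log2fc))
  if (nrow(data) < 3) abort_ct("need at least 3 genes for a residual df")
  fit <- lm(log2fc ~ delta_w, data = data)
  s <- summary(fit)
  tibble(slope = coef(fit)[["delta_w"]],
         r_squared = s$r.squared,
         F = s$fstatistic[["value"]],
         df1 = s$fstatistic[["numdf"]], df2 = s$fstatistic[["dendf"]],
         p = pf(s$fstatistic[["value"]], s$fstatistic[["numdf"]],
                s$fstatistic[["dendf"]], lower.tail = FALSE))
}

#' PCA of samples over methylation or expression features
#'
#' Centred (optionally scaled) principal component analysis of a
#' samples-by-features matrix via SVD; deterministic, no seed involved.
#'
#' @param mat Numeric matrix, samples in rows (rownames are sample ids).
#' @param scale. Scale features to unit variance (default FALSE; constant
#'   features are dropped first when scaling).
#' @return List of class `sample_pca`: `scores` tibble (`sample_id`, `PC1`,
#'   ...), `var_explained` numeric vector, and the `prcomp` fit.
#' @export
sample_pca <- function(mat, scale. = FALSE) {
  stopifnot(is.matrix(mat))
  if (scale.) {
    keep <- apply(mat, 2, stats::sd) > 0
    mat <- mat[, keep, drop = FALSE]
  }
  fit <- prcomp(mat, center = TRUE, scale. = scale.)
  scores <- as_tibble(fit$x, rownames = "sample_id")
  structure(list(scores = scores,
                 var_explained = fit$sdev^2 / sum(fit$sdev^2),
                 fit = fit),
            class = "sample_pca")
}

#' @export
print.sample_pca <- function(x, ...) {
  cat(sprintf("PCA of %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * ifelse(length(x$var_explained) > 1, x$var_explained[2], 0)))
  print(x$scores)
  invisible(x)
}
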