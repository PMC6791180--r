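# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive (brute force / direct arithmetic) and stay
# independent of the implementation paths they check.

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Brute-force all-pairs site-feature overlap scan (oracle for annotate_sites).
brute_annotate <- function(sites, features, flank_bp = 5000) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]; p <- sites$pos[i]
    hit <- FALSE
    for (j in seq_len(nrow(features))) {
      if (features$chrom[j] == ch && features$start[j] <= p &&
          p <= features$end[j]) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, pos = p, feature_type = features$feature_type[j],
          gene_id = features$gene_id[j], stringsAsFactors = FALSE)
        hit <- TRUE
      }
    }
    if (!hit) {
      genes <- features[features$feature_type == "gene" & features$chrom == ch, ]
      nd <- NA_integer_; ng <- NA_character_
      if (nrow(genes) > 0) {
        d <- pmax(genes$start - p, p - genes$end, 0)
        if (min(d) <= flank_bp) {
          ng <- genes$gene_id[which.min(d)]; nd <- min(d)
        }
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, pos = p, feature_type = "intergenic",
        gene_id = NA_character_, nearest_gene = ng, nearest_dist = nd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, lapply(out, function(d) {
    if (is.null(d$nearest_gene)) { d$nearest_gene <- NA_character_; d$nearest_dist <- NA_integer_ }
    d
  }))
}

# Brute-force evaluation of the two coverage-filter rules (oracle for
# filter_sites with require_all_samples = TRUE).
brute_filter_keep <- function(counts, min_cov = 10, pct = 99.9) {
  samples <- unique(counts$sample_id)
  cut_hi <- sapply(samples, function(s) {
    stats::quantile(counts$n_total[counts$sample_id == s], pct / 100,
                    type = 7, names = FALSE)
  })
  sites <- unique(counts[, c("chrom", "pos")])
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    rows <- counts[counts$chrom == sites$chrom[i] & counts$pos == sites$pos[i], ]
    ok <- nrow(rows) == length(samples)
    if (ok) {
      for (j in seq_len(nrow(rows))) {
        if (rows$n_total[j] < min_cov ||
            rows$n_total[j] > cut_hi[[rows$sample_id[j]]]) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  sites[keep, ]
}

# Exact upper-tail hypergeometric P(X >= k) by enumeration over all draws of
# size |B| from the universe (oracle for overlap_test / go_enrichment).
enum_hyper_p <- function(set_a, set_b, universe) {
  draws <- utils::combn(universe, length(set_b), simplify = FALSE)
  k_obs <- length(intersect(set_a, set_b))
  mean(vapply(draws, function(d) length(intersect(d, set_a)) >= k_obs,
              logical(1)))
}

# Independent maximum-likelihood LRT for the caste term of the binomial
# logistic model, by direct numerical optimisation of both likelihoods.
ml_lrt_oracle <- function(d, use_colony = TRUE) {
  d$caste <- factor(d$caste, levels = c("sterile", "reproductive"))
  X_full <- stats::model.matrix(~ caste + colony, d)
  X_red <- stats::model.matrix(~ colony, d)
  if (!use_colony) {
    X_full <- stats::model.matrix(~ caste, d)
    X_red <- stats::model.matrix(~ 1, d)
  }
  nll <- function(beta, X) {
    p <- stats::plogis(drop(X %*% beta))
    -sum(stats::dbinom(d$n_meth, d$n_total, p, log = TRUE))
  }
  fit <- function(X) {
    stats::optim(rep(0, ncol(X)), nll, X = X, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }
  lrt <- 2 * (fit(X_red) - fit(X_full))
  stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
}

# Brute-force reciprocal-best-hit rules (oracle for reciprocal_best_hits).
brute_rbh <- function(ab, ba, max_evalue = 1e-3) {
  best <- function(h) {
    h <- h[h$evalue <= max_evalue, ]
    out <- list()
    for (q in unique(h$query_id)) {
      rows <- h[h$query_id == q, ]
      rows <- rows[rows$evalue == min(rows$evalue), ]
      rows <- rows[rows$bitscore == max(rows$bitscore), ]
      rows <- unique(rows[, c("query_id", "subject_id", "evalue")])
      if (nrow(rows) == 1) out[[q]] <- rows
    }
    do.call(rbind, out)
  }
  ba_best <- best(ba); ab_best <- best(ab)
  pairs <- list()
  if (!is.null(ab_best)) {
    for (i in seq_len(nrow(ab_best))) {
      a <- ab_best$query_id[i]; b <- ab_best$subject_id[i]
      if (!is.null(ba_best) && b %in% ba_best$query_id &&
          ba_best$subject_id[ba_best$query_id == b] == a) {
        pairs[[length(pairs) + 1]] <- data.frame(gene_a = a, gene_b = b,
                                                 stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(data.frame(gene_a = character(), gene_b = character()))
  dup_a <- pairs$gene_a[duplicated(pairs$gene_a)]
  dup_b <- pairs$gene_b[duplicated(pairs$gene_b)]
  pairs <- pairs[!(pairs$gene_a %in% dup_a) & !(pairs$gene_b %in% dup_b), ]
  pairs[order(pairs$gene_a), ]
}

# Random BLAST-style hit table between two gene panels.
random_hits <- function(queries, subjects, n, seed) {
  set.seed(seed)
  data.frame(
    query_id = sample(queries, n, replace = TRUE),
    subject_id = sample(subjects, n, replace = TRUE),
    evalue = 10^stats::runif(n, -12, 0),
    bitscore = round(stats::runif(n, 40, 300), 1),
    stringsAsFactors = FALSE
  )
}

# Six-sample toy count table for one CpG: three colonies, both castes.
toy_site_counts <- function(meth_repro, meth_sterile, n_total = 20) {
  tibble::tibble(
    sample_id = c("C1_r", "C2_r", "C3_r", "C1_s", "C2_s", "C3_s"),
    chrom = "LG1", pos = 100L, strand = "+",
    n_meth = c(meth_repro, meth_sterile),
    n_total = n_total
  )
}

toy_samples <- function() {
  tibble::tibble(
    sample_id = c("C1_r", "C2_r", "C3_r", "C1_s", "C2_s", "C3_s"),
    caste = rep(c("reproductive", "sterile"), each = 3),
    colony = rep(c("C1", "C2", "C3"), 2)
  )
}

# Run the full MSC step (per-sample fits + calls) on a simulated study.
run_msc_calls <- function(sim, eps, fdr_target = 0.05, counts = sim$counts) {
  dplyr::bind_rows(lapply(sim$samples$sample_id, function(s) {
    one <- dplyr::filter(counts, sample_id == s)
    call_status(fit_msc(one, p0 = eps), one, fdr_target = fdr_target)
  }))
}
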