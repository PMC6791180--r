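#' Fit the methylation-status-calling (MSC) binomial mixture for one sample
#'
#' Models the per-CpG methylated read counts of one library as a two-component
#' mixture: an "error" component, binomial with success probability `p0`
#' (bisulfite non-conversion; ideally the lambda-spike estimate), and a
#' "methylated" component, by default beta-binomial so that biological
#' variation in methylation level is absorbed, or plain binomial with a free
#' point probability (`component = "binom"`). Parameters are estimated by EM
#' across all sites of the sample; posterior membership in the methylated
#' component then drives binary calling with local-FDR control in
#' [call_status()].
#'
#' With genome methylation well under 1%, almost all sites belong to the
#' error component; EM is run on the aggregated unique `(n_meth, n_total)`
#' pairs, which makes fitting cheap even at millions of sites.
#'
#' @param counts Tibble (or data frame) with columns `n_meth` and `n_total`
#'   for one sample; at least ~100 sites are recommended for a stable fit.
#' @param p0 Initial (or fixed) error-component rate; default 0.0045, the
#'   scale of typical non-conversion. Pass the lambda estimate when you have
#'   one.
#' @param fix_p0 Keep `p0` fixed at its given value (default TRUE; the spike
#'   exists precisely to pin down the error rate).
#' @param component `"betabinom"` (default) or `"binom"` methylated
#'   component.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` or after `max_iter` iterations.
#' @return An object of class `msc_model`: mixture weight `pi` of the
#'   methylated component, `p0`, component-1 parameters (`p1` or
#'   `alpha1`/`beta1`), `loglik`, `n_iter`, `converged`, and the fitting
#'   metadata. Supports [tidy()] and [glance()].
#' @export
fit_msc <- function(counts, p0 = 0.0045, fix_p0 = TRUE,
                    component = c("betabinom", "binom"),
                    max_iter = 500, tol = 1e-6) {
  component <- match.arg(component)
  x_all <- counts$n_meth
  n_all <- counts$n_total
  stopifnot(all(x_all >= 0), all(n_all >= x_all))
  keep <- n_all > 0
  x_all <- x_all[keep]; n_all <- n_all[keep]
  n_sites <- length(x_all)
  if (n_sites == 0L || all(x_all == 0L)) {
    return(new_msc_model(pi = 0, p0 = p0, component = component,
                         p1 = 0.8, alpha1 = 8, beta1 = 2, loglik = 0,
                         n_iter = 0L, converged = TRUE, fix_p0 = fix_p0,
                         n_sites = n_sites, degenerate = TRUE))
  }

  agg <- dplyr::count(tibble(x = x_all, n = n_all), .data$x, .data$n,
                      name = "w")
  x <- agg$x; n <- agg$n; w <- agg$w

  pi_hat <- max(sum(w[x / n > 0.5]) / sum(w), 1 / n_sites)
  p1 <- 0.8
  a1 <- 8; b1 <- 2    # beta-binomial init, mean 0.8
  lchoose_xn <- lchoose(n, x)

  logf1 <- function() {
    if (component == "binom") {
      dbinom(x, n, p1, log = TRUE)
    } else {
      lchoose_xn + lbeta(x + a1, n - x + b1) - lbeta(a1, b1)
    }
  }
  ll_fun <- function(lf0, lf1) {
    m <- pmax(lf0 + log1p(-pi_hat), lf1 + log(pi_hat))
    sum(w * (m + log(exp(lf0 + log1p(-pi_hat) - m) +
                       exp(lf1 + log(pi_hat) - m))))
  }

  ll_old <- -Inf; ll_trace <- numeric(0); converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    lf0 <- dbinom(x, n, p0, log = TRUE)
    lf1 <- logf1()
    # E-step (log-sum-exp)
    la <- lf1 + log(pi_hat); lb <- lf0 + log1p(-pi_hat)
    m <- pmax(la, lb)
    r <- exp(la - m) / (exp(la - m) + exp(lb - m))
    # M-step
    pi_hat <- sum(w * r) / sum(w)
    pi_hat <- min(max(pi_hat, 1e-12), 1 - 1e-12)
    if (!fix_p0) {
      p0 <- sum(w * (1 - r) * x) / max(sum(w * (1 - r) * n), 1e-12)
      p0 <- min(max(p0, 1e-8), 0.5)
    }
    if (component == "binom") {
      p1 <- sum(w * r * x) / max(sum(w * r * n), 1e-12)
      p1 <- min(max(p1, 1e-8), 1 - 1e-8)
    } else {
      obj <- function(par) {
        a <- exp(par[1]); b <- exp(par[2])
        -sum(w * r * (lchoose_xn + lbeta(x + a, n - x + b) - lbeta(a, b)))
      }
      opt <- optim(c(log(a1), log(b1)), obj, method = "Nelder-Mead",
                   control = list(maxit = 200))
      a1 <- exp(opt$par[1]); b1 <- exp(opt$par[2])
    }
    lf0 <- dbinom(x, n, p0, log = TRUE)
    lf1 <- logf1()
    ll <- ll_fun(lf0, lf1)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged) {
    warning("MSC EM did not converge within max_iter; returning last state",
            call. = FALSE)
  }
  new_msc_model(pi = pi_hat, p0 = p0, component = component, p1 = p1,
                alpha1 = a1, beta1 = b1, loglik = ll_trace[length(ll_trace)],
                n_iter = iter, converged = converged, fix_p0 = fix_p0,
                n_sites = n_sites, degenerate = FALSE, loglik_trace = ll_trace)
}

new_msc_model <- function(..., loglik_trace = numeric(0)) {
  structure(c(list(...), list(loglik_trace = loglik_trace)),
            class = "msc_model")
}

#' @export
print.msc_model <- function(x, ...) {
  comp1 <- if (x$component == "binom") {
    sprintf("Binomial(p1 = %.3f)", x$p1)
  } else {
    sprintf("BetaBinomial(alpha = %.2f, beta = %.2f; mean = %.3f)",
            x$alpha1, x$beta1, x$alpha1 / (x$alpha1 + x$beta1))
  }
  cat("MSC two-component mixture\n",
      sprintf("  pi (methylated weight): %.4g\n", x$pi),
      sprintf("  error component: Binomial(p0 = %.4g)%s\n", x$p0,
              if (x$fix_p0) " [fixed]" else ""),
      sprintf("  methylated component: %s\n", comp1),
      sprintf("  loglik %.2f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"), sep = "")
  invisible(x)
}

#' @rdname fit_msc
#' @param x,object An `msc_model`.
#' @param ... Unused.
#' @method tidy msc_model
#' @export
tidy.msc_model <- function(x, ...) {
  comp1_mean <- if (x$component == "binom") x$p1 else x$alpha1 / (x$alpha1 + x$beta1)
  tibble(
    component = c("error", "methylated"),
    distribution = c("binomial", if (x$component == "binom") "binomial" else "beta-binomial"),
    weight = c(1 - x$pi, x$pi),
    mean = c(x$p0, comp1_mean),
    alpha = c(NA_real_, if (x$component == "binom") NA_real_ else x$alpha1),
    beta = c(NA_real_, if (x$component == "binom") NA_real_ else x$beta1)
  )
}

#' @rdname fit_msc
#' @method glance msc_model
#' @export
glance.msc_model <- function(x, ...) {
  tibble(pi = x$pi, p0 = x$p0, loglik = x$loglik, n_iter = x$n_iter,
         converged = x$converged, n_sites = x$n_sites,
         degenerate = isTRUE(x$degenerate))
}

#' Posterior probability that sites belong to the methylated component
#'
#' The "methylated" label always refers to the component with the larger
#' mean, so relabelling the mixture components leaves posteriors and calls
#' unchanged.
#'
#' @param model An `msc_model`.
#' @param n_meth,n_total Count vectors.
#' @return Posterior probabilities in `[0, 1]`.
#' @export
posterior_methylated <- function(model, n_meth, n_total) {
  if (isTRUE(model$degenerate) || model$pi <= 0) return(rep(0, length(n_meth)))
  lf0 <- dbinom(n_meth, n_total, model$p0, log = TRUE)
  lf1 <- if (model$component == "binom") {
    dbinom(n_meth, n_total, model$p1, log = TRUE)
  } else {
    lchoose(n_total, n_meth) +
      lbeta(n_meth + model$alpha1, n_total - n_meth + model$beta1) -
      lbeta(model$alpha1, model$beta1)
  }
  comp1_mean <- if (model$component == "binom") model$p1 else
    model$alpha1 / (model$alpha1 + model$beta1)
  la <- lf1 + log(model$pi); lb <- lf0 + log1p(-model$pi)
  m <- pmax(la, lb)
  post1 <- exp(la - m) / (exp(la - m) + exp(lb - m))
  if (comp1_mean >= model$p0) post1 else 1 - post1
}

#' Binary methylation calls under local-FDR control
#'
#' Sites are ranked by posterior membership in the methylated component; the
#' call set is the largest prefix whose estimated FDR — the mean of
#' `1 - posterior` over called sites — stays at or below `fdr_target`. The
#' complementary non-discovery rate (mean posterior over uncalled sites) is
#' reported alongside.
#'
#' @param model An `msc_model` from [fit_msc()].
#' @param counts Tibble with `n_meth`, `n_total` and any site-identifying
#'   columns (they are carried through).
#' @param fdr_target Target false discovery rate among called sites
#'   (default 0.05).
#' @return `counts` plus `posterior`, `local_fdr` (`1 - posterior`) and
#'   `status` (`"methylated"`/`"unmethylated"`), with attributes
#'   `fdr_estimate` (mean local FDR over the call set) and
#'   `non_discovery_rate`.
#' @export
call_status <- function(model, counts, fdr_target = 0.05) {
  post <- posterior_methylated(model, counts$n_meth, counts$n_total)
  sel <- fdr_call_set(post, fdr_target)
  out <- counts |>
    mutate(posterior = post, local_fdr = 1 - post,
           status = ifelse(sel$called, "methylated", "unmethylated"))
  attr(out, "fdr_estimate") <- sel$fdr_estimate
  attr(out, "non_discovery_rate") <- sel$non_discovery_rate
  out
}

# Largest call set whose estimated FDR (mean 1 - posterior over called sites)
# stays at or below the target; cumulative means over the posterior-sorted
# sites are monotone, so a prefix rule suffices.
fdr_call_set <- function(post, fdr_target) {
  ord <- order(post, decreasing = TRUE)
  cum_fdr <- cumsum(1 - post[ord]) / seq_along(ord)
  k <- max(c(0L, which(cum_fdr <= fdr_target)))
  called <- rep(FALSE, length(post))
  if (k > 0L) called[ord[seq_len(k)]] <- TRUE
  list(called = called,
       fdr_estimate = if (k > 0L) cum_fdr[k] else 0,
       non_discovery_rate =
         if (k < length(post)) mean(post[ord[-seq_len(k)]]) else 0)
}

#' Keep CpG sites called methylated in at least one sample
#'
#' In genomes with very sparse methylation most sites are unmethylated in
#' every sample; dropping them before differential testing shrinks the
#' multiple-testing burden. A site survives if any sample called it
#' methylated.
#'
#' @param calls Tibble of per-sample calls (from [call_status()] runs bound
#'   together) with `chrom`, `pos`, `sample_id`, `status`.
#' @return Tibble of informative sites (`chrom`, `pos`,
#'   `n_samples_methylated`) with attribute `n_removed`.
#' @export
filter_informative <- function(calls) {
  site_tab <- calls |>
    group_by(.data$chrom, .data$pos) |>
    summarise(n_samples_methylated = sum(.data$status == "methylated"),
              .groups = "drop")
  out <- filter(site_tab, .data$n_samples_methylated >= 1L)
  attr(out, "n_removed") <- nrow(site_tab) - nrow(out)
  out
}
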