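# Bayesian comparison of two models' accuracy distributions ("BEST"-style),
# sampled with a component-wise random-walk Metropolis-Hastings MCMC.
#
# Each group's per-fold accuracies are modelled as Gaussian with unknown mean
# and sd; means and sds carry normal priors (sd truncated positive). The
# "null" (no practical difference) is a region of practical equivalence
# (ROPE) on the difference of means, and its posterior probability is the
# reported p-value analogue. Multiple comparisons are handled by
# Benjamini-Hochberg FDR control.

#' Configuration for the BEST accuracy comparison
#'
#' @param n_iter Total MCMC iterations (default 11,000).
#' @param burn_in Initial iterations discarded (default 1,000, so 10,000
#'   posterior samples are retained).
#' @param proposal_sd Length-2 numeric: random-walk proposal sd for the mean
#'   and sd moves. `NULL` scales proposals to the pooled data
#'   (`2.4 * pooled_sd / sqrt(n)`), which keeps acceptance in a healthy range.
#' @param prior List with `mean_sd` (sd of the normal prior on each group
#'   mean, centered on the pooled mean; default 0.5) and `sd_sd` (sd of the
#'   positive-truncated normal prior on each group sd, centered on the pooled
#'   sd; default 0.5). Weakly informative on the accuracy scale.
#' @param rope Half-width of the region of practical equivalence on the
#'   difference of mean accuracies (default 0.005, i.e. 0.5% accuracy).
#' @param seed Integer seed for the chain.
#' @return A `best_config` object.
#' @export
best_config <- function(n_iter = 11000L, burn_in = 1000L, proposal_sd = NULL,
                        prior = list(mean_sd = 0.5, sd_sd = 0.5),
                        rope = 0.005, seed = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (!is.null(proposal_sd) && any(proposal_sd <= 0)) {
    stop("proposal_sd must be > 0")
  }
  if (rope < 0) stop("rope must be >= 0")
  structure(list(n_iter = n_iter, burn_in = burn_in, proposal_sd = proposal_sd,
                 prior = prior, rope = rope, seed = as.integer(seed)),
            class = "best_config")
}

# Gaussian log-likelihood from sufficient statistics (n, mean, centered SS).
loglik_group <- function(mu, sdv, n, m, ss) {
  -n * log(sdv) - (ss + n * (m - mu)^2) / (2 * sdv^2)
}

#' Compare two accuracy samples by Bayesian estimation (BEST)
#'
#' Runs a Metropolis-Hastings chain over (mean_A, sd_A, mean_B, sd_B) and
#' reports `p_null`, the posterior probability that the two mean accuracies
#' are practically equivalent (|mean_A - mean_B| <= rope). Unlike a t-test
#' this can *accept* the null with quantified probability. If both groups are
#' degenerate (zero spread), the comparison is resolved analytically.
#'
#' @param acc_a,acc_b Numeric vectors of per-fold accuracies in `[0, 1]`,
#'   each of length >= 3.
#' @param cfg A [best_config()].
#' @return A `best_result`: `samples` (retained draws, columns mu_a, sd_a,
#'   mu_b, sd_b), `p_null`, `acceptance_rate`, `config`.
#' @export
best_compare <- function(acc_a, acc_b, cfg = best_config()) {
  stopifnot(inherits(cfg, "best_config"))
  for (v in list(acc_a, acc_b)) {
    if (length(v) < 3L) stop("each accuracy sample needs length >= 3")
    if (any(v < 0 | v > 1)) stop("accuracies must lie in [0, 1]")
  }
  n_keep <- cfg$n_iter - cfg$burn_in
  na <- length(acc_a); nb <- length(acc_b)
  ma <- mean(acc_a); mb <- mean(acc_b)
  ssa <- sum((acc_a - ma)^2); ssb <- sum((acc_b - mb)^2)
  if (ssa == 0 && ssb == 0) {
    # no spread in either group: the posterior collapses onto the sample means
    p_null <- as.numeric(abs(ma - mb) <= cfg$rope)
    samples <- matrix(rep(c(ma, 0, mb, 0), each = n_keep), ncol = 4L,
                      dimnames = list(NULL, c("mu_a", "sd_a", "mu_b", "sd_b")))
    return(structure(list(samples = samples, p_null = p_null,
                          acceptance_rate = NA_real_, analytic = TRUE,
                          config = cfg),
                     class = "best_result"))
  }
  pooled <- c(acc_a, acc_b)
  pm <- mean(pooled)
  ps <- max(stats::sd(pooled), 1e-4)
  prop <- cfg$proposal_sd %||% rep(max(2.4 * ps / sqrt(na + nb), 1e-4), 2L)
  if (length(prop) == 1L) prop <- rep(prop, 2L)
  mean_sd <- cfg$prior$mean_sd %||% 0.5
  sd_sd <- cfg$prior$sd_sd %||% 0.5
  log_post <- function(th) {
    if (th[2] <= 0 || th[4] <= 0) return(-Inf)
    loglik_group(th[1], th[2], na, ma, ssa) +
      loglik_group(th[3], th[4], nb, mb, ssb) +
      stats::dnorm(th[1], pm, mean_sd, log = TRUE) +
      stats::dnorm(th[3], pm, mean_sd, log = TRUE) +
      stats::dnorm(th[2], ps, sd_sd, log = TRUE) +
      stats::dnorm(th[4], ps, sd_sd, log = TRUE)
  }
  th <- c(ma, max(stats::sd(acc_a), 1e-4), mb, max(stats::sd(acc_b), 1e-4))
  lp <- log_post(th)
  samples <- matrix(NA_real_, nrow = cfg$n_iter, ncol = 4L,
                    dimnames = list(NULL, c("mu_a", "sd_a", "mu_b", "sd_b")))
  prop4 <- prop[c(1L, 2L, 1L, 2L)]
  acc_count <- 0L
  with_seed(derive_seed(cfg$seed, 23L), {
    for (it in seq_len(cfg$n_iter)) {
      for (j in 1:4) {
        cand <- th
        cand[j] <- cand[j] + stats::rnorm(1L, 0, prop4[j])
        lp_cand <- log_post(cand)
        if (log(stats::runif(1L)) < lp_cand - lp) {
          th <- cand; lp <- lp_cand; acc_count <- acc_count + 1L
        }
      }
      samples[it, ] <- th
    }
  })
  kept <- samples[(cfg$burn_in + 1L):cfg$n_iter, , drop = FALSE]
  structure(list(samples = kept,
                 p_null = mean(abs(kept[, "mu_a"] - kept[, "mu_b"]) <= cfg$rope),
                 acceptance_rate = acc_count / (4L * cfg$n_iter),
                 analytic = FALSE, config = cfg),
            class = "best_result")
}

#' @export
print.best_result <- function(x, ...) {
  cat(sprintf("<best_result> p_null = %.4f | mean_A %.4f, mean_B %.4f | %d samples%s\n",
              x$p_null, mean(x$samples[, "mu_a"]), mean(x$samples[, "mu_b"]),
              nrow(x$samples),
              if (x$analytic) " (analytic degenerate case)" else
                sprintf(" | MH acceptance %.2f", x$acceptance_rate)))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment with accept/reject decisions
#'
#' @param p_values Numeric vector of p-values (or posterior null
#'   probabilities) in `[0, 1]`.
#' @param level FDR level for the reject flags (default 0.05).
#' @return List with `adjusted` (BH step-up adjusted values) and `reject`
#'   (logical, adjusted < level).
#' @export
fdr_adjust <- function(p_values, level = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = adj < level)
}

#' Sampler diagnostics for a BEST result
#'
#' @param result A `best_result`.
#' @return List with `acceptance_rate`, `flagged` (`TRUE` when the acceptance
#'   rate falls outside `[0.1, 0.7]`, suggesting the proposal scale needs
#'   attention), and `trace_summary` (posterior mean and sd per parameter).
#' @export
chain_diagnostics <- function(result) {
  stopifnot(inherits(result, "best_result"))
  rate <- result$acceptance_rate
  flagged <- if (is.na(rate)) FALSE else (rate < 0.1 || rate > 0.7)
  list(acceptance_rate = rate, flagged = flagged,
       trace_summary = data.frame(
         parameter = colnames(result$samples),
         mean = colMeans(result$samples),
         sd = apply(result$samples, 2L, stats::sd),
         row.names = NULL))
}
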