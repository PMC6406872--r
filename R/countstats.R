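#' Beta-binomial log-likelihood
#'
#' Counts k out of totals t with success probability drawn from a Beta
#' distribution: k ~ BetaBinomial(t, pi, theta) with shape parameters
#' a = pi (1 - theta) / theta and b = (1 - pi) (1 - theta) / theta, so that
#' pi is the mean proportion and theta in (0, 1) the overdispersion
#' (theta -> 0 recovers the plain binomial).
#'
#' @param k,t Integer vectors of counts and totals.
#' @param pi_,theta Mean proportion and overdispersion, both in (0, 1).
#' @return Summed log-likelihood.
#' @keywords internal
betabinom_loglik <- function(k, t, pi_, theta) {
  a <- pi_ * (1 - theta) / theta
  b <- (1 - pi_) * (1 - theta) / theta
  sum(lchoose(t, k) + lbeta(k + a, t - k + b) - lbeta(a, b))
}

#' Moment estimates of (pi, theta) for the beta-binomial
#' @keywords internal
betabinom_moments <- function(k, t) {
  pi_hat <- sum(k) / sum(t)
  p <- k / t
  tbar <- mean(t)
  v <- stats::var(p)
  theta_hat <- if (is.na(v) || pi_hat <= 0 || pi_hat >= 1) {
    1e-3
  } else {
    (v / (pi_hat * (1 - pi_hat)) - 1 / tbar) / (1 - 1 / tbar)
  }
  c(pi = clamp01(pi_hat), theta = clamp01(theta_hat))
}

clamp01 <- function(x, eps = 1e-8) pmin(pmax(x, eps), 1 - eps)

#' Minimum-spectra filter
#'
#' Retains a protein only if it accumulated at least `threshold`
#' protein-group-specific spectra in at least one sample; proteins below
#' that are too sparsely sampled for count statistics.
#'
#' @param counts Integer matrix, proteins x samples.
#' @param threshold Minimum per-sample spectral count, default 4.
#' @return Logical vector, retained per protein.
#' @export
min_spectra_filter <- function(counts, threshold = 4L) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0, na.rm = TRUE)) stop("negative spectral counts")
  apply(counts, 1L, function(k) max(k, na.rm = TRUE) >= threshold)
}

#' Beta-binomial likelihood-ratio test for group differences in counts
#'
#' Tests whether one protein's spectral-count proportions k_j / t_j differ
#' between groups (e.g. production batches), allowing between-replicate
#' overdispersion. Null model: one common (pi, theta) for all samples;
#' alternative: group-specific pi_g with a shared theta (or group-specific
#' theta with `theta_per_group = TRUE`). Both likelihoods are maximized by
#' bounded quasi-Newton optimization with multiple moment-based starts; the
#' statistic 2 (l1 - l0) is referred to a chi-square with G - 1 degrees of
#' freedom.
#'
#' @param k Integer vector of counts for one protein.
#' @param t Integer vector of per-sample totals (library sizes).
#' @param groups Vector of group labels, same length as `k`.
#' @param theta_per_group Allow a separate overdispersion per group under the
#'   alternative (degrees of freedom become 2 (G - 1)); default FALSE.
#' @return p-value.
#' @export
beta_binomial_test <- function(k, t, groups, theta_per_group = FALSE) {
  stopifnot(length(k) == length(t), length(k) == length(groups))
  if (any(k > t)) stop("counts exceed totals")
  groups <- factor(groups)
  G <- nlevels(groups)
  if (G < 2L) stop("need at least two groups")
  if (sum(k) == 0L) return(1)

  eps <- 1e-8
  neg0 <- function(par) -betabinom_loglik(k, t, par[1L], par[2L])
  mom <- betabinom_moments(k, t)
  starts0 <- list(mom, c(mom[1L], 1e-4), c(mom[1L], 0.01), c(mom[1L], 0.2),
                  c(mom[1L], 0.5))
  fit0 <- optimize_multistart(neg0, starts0,
                              lower = c(eps, eps), upper = c(1 - eps, 1 - eps))

  idx <- split(seq_along(k), groups)
  pig_mom <- clamp01(vapply(idx, function(j) sum(k[j]) / sum(t[j]), 0))
  if (!theta_per_group) {
    neg1 <- function(par) {
      th <- par[G + 1L]
      -sum(vapply(seq_len(G), function(g) {
        betabinom_loglik(k[idx[[g]]], t[idx[[g]]], par[g], th)
      }, 0))
    }
    starts1 <- list(
      c(pig_mom, mom[2L]),
      c(pig_mom, 1e-4),
      c(pig_mom, 0.01),
      c(pig_mom, 0.2),
      c(rep(fit0$par[1L], G), fit0$par[2L])  # includes the H0 optimum
    )
    fit1 <- optimize_multistart(neg1, starts1,
                                lower = rep(eps, G + 1L),
                                upper = rep(1 - eps, G + 1L))
    # the H1 optimum seeds one more H0 attempt: ensures the nested
    # likelihoods are compared at comparable optimization quality
    w <- vapply(idx, function(j) sum(t[j]), 0)
    pooled <- clamp01(sum(fit1$par[seq_len(G)] * w) / sum(w))
    fit0b <- optimize_multistart(neg0, list(c(pooled, fit1$par[G + 1L])),
                                 lower = c(eps, eps),
                                 upper = c(1 - eps, 1 - eps))
    if (fit0b$value < fit0$value) fit0 <- fit0b
    df <- G - 1L
  } else {
    neg1 <- function(par) {
      -sum(vapply(seq_len(G), function(g) {
        betabinom_loglik(k[idx[[g]]], t[idx[[g]]], par[g], par[G + g])
      }, 0))
    }
    starts1 <- list(
      c(pig_mom, rep(mom[2L], G)),
      c(rep(fit0$par[1L], G), rep(fit0$par[2L], G))
    )
    fit1 <- optimize_multistart(neg1, starts1,
                                lower = rep(eps, 2L * G),
                                upper = rep(1 - eps, 2L * G))
    df <- 2L * (G - 1L)
  }
  lambda <- max(2 * (fit0$value - fit1$value), 0)
  stats::pchisq(lambda, df = df, lower.tail = FALSE)
}

#' Run optim(L-BFGS-B) from several starts, keep the best
#' @keywords internal
optimize_multistart <- function(fn, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(unname(s), lower), upper)
    fit <- tryCatch(
      stats::optim(s, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("likelihood optimization failed to converge")
  best
}

#' Inverted (paired) beta-binomial test
#'
#' Paired comparison of counts between two conditions measured on the same
#' replicates. Conditioning on the pair sum s_r = k_Ar + k_Br removes the
#' pair effect: under the model k_Ar ~ BetaBinomial(s_r, pi_r, theta) with
#' logit(pi_r) = logit(pi0_r) + delta, where pi0_r = t_Ar / (t_Ar + t_Br) is
#' the share expected from the library sizes alone. The null hypothesis is
#' delta = 0 (no condition effect beyond sampling depth); theta captures
#' residual within-pair overdispersion and is profiled under both
#' hypotheses. The likelihood ratio is referred to chi-square with 1 degree
#' of freedom. Note that a pair-level abundance effect (one shared beta
#' draw per replicate pair) is already removed by the conditioning on s_r,
#' so under the null the conditional split is close to binomial and theta
#' sits near its boundary.
#'
#' @param k_a,k_b Paired count vectors for the two conditions.
#' @param t_a,t_b Per-sample totals for the two conditions.
#' @return p-value.
#' @export
inverted_beta_binomial_test <- function(k_a, k_b, t_a, t_b) {
  stopifnot(length(k_a) == length(k_b), length(k_a) == length(t_a),
            length(k_a) == length(t_b))
  if (length(k_a) < 2L) stop("need at least two pairs")
  s <- k_a + k_b
  keep <- s > 0
  if (!any(keep)) return(1)
  k <- k_a[keep]; s <- s[keep]
  eta0 <- stats::qlogis(t_a[keep] / (t_a[keep] + t_b[keep]))

  eps <- 1e-8
  ll <- function(delta, theta) {
    pi_r <- clamp01(stats::plogis(eta0 + delta))
    a <- pi_r * (1 - theta) / theta
    b <- (1 - pi_r) * (1 - theta) / theta
    sum(lchoose(s, k) + lbeta(k + a, s - k + b) - lbeta(a, b))
  }
  # H0: profile theta; golden-section can stall short of a boundary
  # optimum, so boundary and grid candidates are checked explicitly
  opt0 <- stats::optimize(function(th) -ll(0, th), c(eps, 1 - eps),
                          tol = 1e-8)
  th_cand <- c(opt0$minimum, eps, 1e-4, 1e-2, 0.1, 0.5, 0.9, 1 - 1e-4,
               1 - eps)
  l0_cand <- vapply(th_cand, function(th) ll(0, th), 0)
  l0 <- max(l0_cand)
  th0 <- th_cand[which.max(l0_cand)]

  neg1 <- function(par) -ll(par[1L], par[2L])
  p_obs <- clamp01(sum(k) / sum(s))
  delta_mom <- stats::qlogis(p_obs) - stats::qlogis(clamp01(mean(stats::plogis(eta0))))
  starts <- list(c(delta_mom, 1e-3), c(delta_mom, 0.05), c(delta_mom, 0.3),
                 c(0, th0))
  fit1 <- optimize_multistart(neg1, starts,
                              lower = c(-25, eps), upper = c(25, 1 - eps))
  lambda <- max(2 * (-l0 - fit1$value), 0)
  stats::pchisq(lambda, df = 1L, lower.tail = FALSE)
}

#' Maximum pairwise fold change of group mean count proportions
#'
#' Group means of k_j / t_j; a zero group mean is floored at the
#' half-count detection limit (half of one spectrum over the mean library
#' size) before forming ratios, so a protein absent from one batch still
#' gets a finite, count-scaled fold change.
#'
#' @param k,t Counts and totals for one protein.
#' @param groups Group labels.
#' @return Max over group pairs of the larger/smaller mean proportion ratio.
#' @export
max_pairwise_fc <- function(k, t, groups) {
  p <- k / t
  means <- tapply(p, groups, mean)
  if (all(means == 0)) return(1)
  floor_val <- 0.5 / mean(t)
  means[means == 0] <- floor_val
  max(means) / min(means)
}

#' Differential calls from spectral-count tests
#'
#' Combines Holm-corrected p-values with a fold-change requirement: a
#' protein is called batch-variable only when the corrected p-value falls
#' below `alpha` AND the maximum pairwise fold change of group mean
#' proportions exceeds `fc_threshold`.
#'
#' @param raw_p Per-protein p-values.
#' @param fold_changes Per-protein maximum pairwise fold changes.
#' @param alpha Significance level on Holm-adjusted p, default 0.05.
#' @param fc_threshold Fold-change requirement (strictly greater), default 2.
#' @return Data frame: `raw_p`, `holm_p`, `max_pairwise_fc`, `is_different`.
#' @export
call_differential <- function(raw_p, fold_changes, alpha = 0.05,
                              fc_threshold = 2) {
  stopifnot(length(raw_p) == length(fold_changes))
  holm_p <- holm_adjust(raw_p)
  data.frame(
    raw_p = raw_p,
    holm_p = holm_p,
    max_pairwise_fc = fold_changes,
    is_different = !is.na(holm_p) & holm_p < alpha & fold_changes > fc_threshold
  )
}

#' Batch-to-batch stability analysis of spectral counts
#'
#' Full count-based stability test: filter to proteins with at least
#' `min_spectra` specific spectra in some sample, recompute library-size
#' totals as column sums over the retained proteins, run the beta-binomial
#' likelihood-ratio test per protein across batches, Holm-correct, and call
#' batch-variable proteins with the combined p-value + fold-change rule.
#'
#' @param counts Integer matrix, proteins x samples (protein-specific
#'   spectra).
#' @param groups Batch labels per sample.
#' @param min_spectra Retention threshold, default 4.
#' @param alpha,fc_threshold Call thresholds, defaults 0.05 and 2.
#' @return Data frame, one row per retained protein: accession, test results
#'   and the `is_different` call; attribute `n_tested` and `n_different`.
#' @export
batch_stability <- function(counts, groups, min_spectra = 4L,
                            alpha = 0.05, fc_threshold = 2) {
  stopifnot(is.matrix(counts), length(groups) == ncol(counts))
  retained <- min_spectra_filter(counts, min_spectra)
  kept <- counts[retained, , drop = FALSE]
  totals <- colSums(kept)
  if (any(totals == 0)) stop("a sample has zero total spectra after filtering")
  raw_p <- vapply(seq_len(nrow(kept)), function(i) {
    beta_binomial_test(kept[i, ], totals, groups)
  }, numeric(1L))
  fc <- vapply(seq_len(nrow(kept)), function(i) {
    max_pairwise_fc(kept[i, ], totals, groups)
  }, numeric(1L))
  out <- call_differential(raw_p, fc, alpha = alpha, fc_threshold = fc_threshold)
  out <- cbind(
    data.frame(accession = rownames(kept) %||% paste0("P", which(retained))),
    out
  )
  attr(out, "n_tested") <- nrow(out)
  attr(out, "n_different") <- sum(out$is_different)
  out
}
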