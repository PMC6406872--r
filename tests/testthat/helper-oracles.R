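# Independent oracles used by the tests. These deliberately re-derive each
# quantity from its definition (brute force, closed form, or grid search) and
# never call the implementation they check.

# Holm step-down by definition: sort ascending, multiply p_(i) by (m - i + 1),
# running maximum, cap at 1, return in input order.
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- pmin(p[ord] * (m - seq_len(m) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Tukey-Kramer pairwise p-values from sums of squares and the studentized
# range distribution.
oracle_tukey <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n_i <- tapply(values, groups, length)
  m_i <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum((values - m_i[groups])^2) / df
  pairs <- utils::combn(levels(groups), 2L)
  p <- apply(pairs, 2L, function(pr) {
    se <- sqrt(mse / 2 * (1 / n_i[pr[1L]] + 1 / n_i[pr[2L]]))
    q <- abs(m_i[pr[1L]] - m_i[pr[2L]]) / se
    stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  })
  # TukeyHSD labels contrasts "later-earlier"
  names(p) <- apply(pairs, 2L, function(pr) paste(pr[2L], pr[1L], sep = "-"))
  p
}

# One-way ANOVA F-test p-value from sums of squares.
oracle_anova_p <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  m_i <- tapply(values, groups, mean)
  n_i <- tapply(values, groups, length)
  ss_b <- sum(n_i * (m_i - mean(values))^2)
  ss_w <- sum((values - m_i[groups])^2)
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

# Secretome retention predicate evaluated literally per protein.
oracle_retention <- function(identified, depletion_rep) {
  apply(identified, 1L, function(row) {
    all(vapply(unique(depletion_rep),
               function(r) any(row[depletion_rep == r]), logical(1L)))
  })
}

# Beta-binomial log-likelihood (mean/overdispersion parameterization),
# written independently of the package internals.
oracle_bb_ll <- function(k, t, pi_, theta) {
  a <- pi_ * (1 - theta) / theta
  b <- (1 - pi_) * (1 - theta) / theta
  sum(lchoose(t, k) + lbeta(k + a, t - k + b) - lbeta(a, b))
}

# Grouped beta-binomial LRT by profile grid search: theta on a log-spaced
# grid, pi maximized per theta with optimize().
theta_grid <- function(n = 300) {
  # log-spaced toward both boundaries: optima can sit near 0 or near 1
  sort(unique(c(10^seq(-8, -0.31, length.out = n),
                1 - 10^seq(-8, -0.31, length.out = n))))
}

oracle_bb_test <- function(k, t, groups, n_theta = 300) {
  if (sum(k) == 0) return(list(lambda = 0, p = 1))
  idx <- split(seq_along(k), groups)
  thg <- theta_grid(n_theta)
  best_pi <- function(kk, tt, th) {
    -stats::optimize(function(p) -oracle_bb_ll(kk, tt, p, th),
                     c(1e-9, 1 - 1e-9))$objective
  }
  l0 <- max(vapply(thg, function(th) best_pi(k, t, th), 0))
  l1 <- max(vapply(thg, function(th) {
    sum(vapply(idx, function(j) best_pi(k[j], t[j], th), 0))
  }, 0))
  lambda <- max(2 * (l1 - l0), 0)
  list(lambda = lambda,
       p = stats::pchisq(lambda, df = length(idx) - 1, lower.tail = FALSE))
}

# Paired beta-binomial LRT by the same grid strategy (delta profiled by
# optimize per theta).
oracle_ibb_test <- function(k_a, k_b, t_a, t_b, n_theta = 300) {
  s <- k_a + k_b
  keep <- s > 0
  if (!any(keep)) return(list(lambda = 0, p = 1))
  k <- k_a[keep]; s <- s[keep]
  eta0 <- stats::qlogis(t_a[keep] / (t_a[keep] + t_b[keep]))
  ll <- function(delta, th) {
    pi_r <- pmin(pmax(stats::plogis(eta0 + delta), 1e-8), 1 - 1e-8)
    a <- pi_r * (1 - th) / th
    b <- (1 - pi_r) * (1 - th) / th
    sum(lchoose(s, k) + lbeta(k + a, s - k + b) - lbeta(a, b))
  }
  thg <- theta_grid(n_theta)
  l0 <- max(vapply(thg, function(th) ll(0, th), 0))
  l1 <- max(vapply(thg, function(th) {
    -stats::optimize(function(d) -ll(d, th), c(-25, 25))$objective
  }, 0))
  lambda <- max(2 * (l1 - l0), 0)
  list(lambda = lambda, p = stats::pchisq(lambda, 1, lower.tail = FALSE))
}

# Fixture builders --------------------------------------------------------

write_fixture_fasta <- function(path) {
  writeLines(c(
    ">sp|P00001|ALBU_TEST test albumin-like",
    "MKWVTFISLLFLFSSAYSRGVFRRDAHKSEVAHRFKDLGEENFKALVLIAFAQYLQQCPF",
    "EDHVKLVNEVTEFAK",
    ">sp|P00002|TRFE_TEST transferrin-like",
    "MRLAVGALLVCAVLGLCLAVPDKTVRWCAVSEHEATKCQSFRDHMKSVIPSDGPSVACVK",
    ">sp|P00003|SMALL_TEST",
    "GGAGG",
    ">tr|Q00004|FRAG_TEST",
    "PEPTIDE"
  ), path)
  path
}

write_fixture_protein_groups <- function(path, n_flagged = 2L) {
  acc <- c("P00001", "P00002", "P00003", "Q00004",
           sprintf("X%05d", seq_len(4L + n_flagged)))
  n <- length(acc)
  set.seed(99)
  tab <- data.frame(
    check.names = FALSE,
    "Majority protein IDs" = acc,
    "Intensity s1" = c(0, round(runif(n - 1, 1e5, 1e9))),
    "Intensity s2" = round(runif(n, 1e5, 1e9)),
    "MS/MS count s1" = rpois(n, 5),
    "MS/MS count s2" = rpois(n, 5),
    "Reverse" = c(rep("", n - n_flagged), rep("+", ceiling(n_flagged / 2)),
                  rep("", floor(n_flagged / 2))),
    "Potential contaminant" = c(rep("", n - floor(n_flagged / 2)),
                                rep("+", floor(n_flagged / 2)))
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
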