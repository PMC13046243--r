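#' Simulate a neonatal cohort table
#'
#' Generates a synthetic cohort emulating a perinatal imaging sample:
#' gestational age (GA) is drawn from a two-component (preterm + term)
#' Gaussian mixture truncated to `ga_range`, reproducing the long left tail
#' of a cohort enriched with preterm births; postnatal age (PNA) is a
#' monotone map of a latent Gaussian negatively correlated with GA onto a
#' right-skewed distribution over `pna_range` (most infants are scanned in
#' the first postnatal week, preterm infants later); postmenstrual age (PMA)
#' is exactly `GA + PNA`; sex is a balanced 0/1 code.
#'
#' Both margins are generated through a Gaussian copula, and the latent
#' correlation is calibrated by deterministic Gauss-Hermite quadrature so
#' that the population Pearson correlation of the *transformed* pair equals
#' `ga_pna_corr` (the monotone maps would otherwise attenuate it).
#'
#' @param n Number of subjects (>= 3).
#' @param seed Integer seed; identical arguments give identical tables.
#' @param ga_range GA truncation range in weeks (default `c(23, 42.3)`).
#' @param pna_range PNA range in weeks (default `c(0, 7)`).
#' @param ga_pna_corr Target Pearson correlation between GA and PNA, in
#'   (-1, 0\] (default -0.43).
#' @param preterm_frac Mixture weight of the preterm component (default 0.27).
#' @param thickness If `TRUE`, adds a `thickness_mm` column growing mildly
#'   with PMA around 1.5 mm; default `FALSE` leaves it `NA`.
#' @return A tibble with columns `subject_id`, `ga_weeks`, `pna_weeks`,
#'   `pma_weeks`, `sex`, `thickness_mm`.
#' @export
simulate_cohort <- function(n, seed, ga_range = c(23, 42.3), pna_range = c(0, 7),
                            ga_pna_corr = -0.43, preterm_frac = 0.27,
                            thickness = FALSE) {
  if (!is_scalar_number(n) || n < 3) stop_parameter("`n` must be at least 3")
  n <- as.integer(n)
  if (!is_scalar_number(ga_pna_corr) || ga_pna_corr > 0 || ga_pna_corr <= -1) {
    stop_parameter("`ga_pna_corr` must lie in (-1, 0]")
  }
  if (diff(ga_range) <= 0 || diff(pna_range) < 0 || pna_range[1] < 0) {
    stop_parameter("invalid `ga_range`/`pna_range`")
  }
  if (preterm_frac < 0 || preterm_frac > 1) stop_parameter("`preterm_frac` must lie in [0, 1]")

  qga <- ga_quantile_fun(ga_range, preterm_frac)
  qpna <- function(p) pna_range[1] + diff(pna_range) * stats::qbeta(p, 1, 5)
  r_latent <- calibrate_latent_corr(ga_pna_corr, qga, qpna)

  withr::with_seed(seed, {
    u <- stats::rnorm(n)
    v <- r_latent * u + sqrt(1 - r_latent^2) * stats::rnorm(n)
    ga <- qga(stats::pnorm(u))
    pna <- qpna(stats::pnorm(v))
    sex <- sample(rep_len(c(0L, 1L), n))
    pma <- ga + pna
    th <- if (thickness) {
      pmax(0.8, 1.5 + 0.04 * (pma - 40) + stats::rnorm(n, sd = 0.08))
    } else NA_real_
  })
  tibble::tibble(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    ga_weeks = ga, pna_weeks = pna, pma_weeks = pma,
    sex = sex, thickness_mm = th)
}

# Quantile function of the truncated preterm+term GA mixture, via a fine
# monotone CDF grid.
ga_quantile_fun <- function(ga_range, preterm_frac,
                            term_mean = 39.6, term_sd = 1.3,
                            preterm_mean = 32, preterm_sd = 4) {
  lo <- ga_range[1]; hi <- ga_range[2]
  ptr <- function(x, m, s) {
    (stats::pnorm(x, m, s) - stats::pnorm(lo, m, s)) /
      (stats::pnorm(hi, m, s) - stats::pnorm(lo, m, s))
  }
  cdf <- function(x) preterm_frac * ptr(x, preterm_mean, preterm_sd) +
    (1 - preterm_frac) * ptr(x, term_mean, term_sd)
  xs <- seq(lo, hi, length.out = 4096L)
  ps <- cdf(xs)
  function(p) stats::approx(ps, xs, xout = pmin(pmax(p, ps[1]), ps[length(ps)]),
                            ties = "ordered")$y
}

# Population Pearson correlation of (qga(pnorm U), qpna(pnorm V)) for latent
# correlation r, by tensor Gauss-Hermite quadrature; solved for the target
# with uniroot. Deterministic: no sampling involved.
calibrate_latent_corr <- function(target, qga, qpna, n_nodes = 48L) {
  if (target == 0) return(0)
  gh <- gauss_hermite(n_nodes)
  z <- gh$nodes * sqrt(2)
  w <- gh$weights / sqrt(pi)
  gx <- qga(stats::pnorm(z))
  m1 <- sum(w * gx); s1 <- sqrt(sum(w * (gx - m1)^2))
  achieved <- function(r) {
    # V | U=u ~ N(r u, 1 - r^2); E[qpna(pnorm V) | u] on the same grid
    ey <- vapply(z, function(u) {
      vv <- r * u + sqrt(1 - r^2) * z
      sum(w * qpna(stats::pnorm(vv)))
    }, numeric(1))
    m2 <- sum(w * ey)
    gy <- qpna(stats::pnorm(z))
    my <- sum(w * gy); s2 <- sqrt(sum(w * (gy - my)^2))
    sum(w * (gx - m1) * (ey - m2)) / (s1 * s2)
  }
  lohi <- c(-0.999, 0)
  if (achieved(lohi[1]) > target) {
    stop_parameter("requested GA-PNA correlation is infeasible for these margins")
  }
  stats::uniroot(function(r) achieved(r) - target, lohi, tol = 1e-6)$root
}

# Golub-Welsch nodes/weights for Gauss-Hermite quadrature.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}
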