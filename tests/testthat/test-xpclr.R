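test_that("drift-scale estimator vanishes when populations agree", {
  # exact frequencies via very large counts: numerator terms go slightly
  # negative (sampling-variance correction), floored at zero
  n <- 1e6L
  p <- c(0.2, 0.4, 0.6, 0.8)
  cr <- toy_counts(1:4 * 10, round(p * n), n)
  co <- toy_counts(1:4 * 10, round(p * n), n)
  expect_warning(model <- estimate_omega(cr, co), "usable sites")
  expect_equal(model$omega, 0)
})

test_that("drift-scale estimator equals the hand-evaluated moment formula", {
  m1 <- c(3L, 10L, 7L, 12L, 5L, 9L, 14L, 2L, 8L, 11L)
  m2 <- c(5L, 12L, 3L, 15L, 2L, 10L, 18L, 1L, 6L, 13L)
  n1 <- 20L; n2 <- 24L
  cr <- toy_counts(1:10 * 100, m1, n1)
  co <- toy_counts(1:10 * 100, m2, n2)
  p1 <- m1 / n1; p2 <- m2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p1) * n1 / (n1 - 1)
  expected <- max(sum(num) / sum(den), 0)
  expect_warning(
    model <- estimate_omega(cr, co, truncation_correction = FALSE),
    "usable sites")
  expect_equal(model$omega, expected, tolerance = 1e-12)
  expect_identical(model$n_sites, 10L)
  # the truncation-aware default solves the clamped moment equation, which
  # approaches the plain ratio when the drift kernel stays inside (0, 1)
  small <- toy_counts(1:10 * 100, round(0.5 * 400 + (m2 - m1)), 400L)
  base <- toy_counts(1:10 * 100, rep(200L, 10), 400L)
  expect_warning(corr <- estimate_omega(base, small), "usable")
  expect_warning(raw <- estimate_omega(base, small,
                                       truncation_correction = FALSE),
                 "usable")
  expect_equal(corr$omega, raw$omega, tolerance = 0.02)
})

test_that("sites fixed in the reference are excluded; empty input errors", {
  cr <- toy_counts(1:3 * 10, c(0L, 20L, 5L), 20L)
  co <- toy_counts(1:3 * 10, c(3L, 8L, 9L), 20L)
  expect_warning(model <- estimate_omega(cr, co), "usable")
  expect_identical(model$n_sites, 1L)
  all_fixed <- toy_counts(1:2 * 10, c(0L, 20L), 20L)
  expect_error(estimate_omega(all_fixed, co[1:2, ]), "no usable")
})

test_that("neutral likelihood reduces to the binomial pmf as omega -> 0", {
  ll <- neutral_site_loglik(3, 10, 0.3, model = 1e-12)
  expect_equal(exp(ll), dbinom(3, 10, 0.3), tolerance = 1e-4)
  expect_equal(exp(ll), 0.2668279, tolerance = 1e-4)
  ll0 <- neutral_site_loglik(3, 10, 0.3, model = 0)
  expect_equal(exp(ll0), dbinom(3, 10, 0.3), tolerance = 1e-12)
})

test_that("site likelihoods normalize over outcomes at shipped quadrature", {
  quad <- gauss_legendre_quad(64)
  for (p1 in c(0.02, 0.3, 0.5, 0.97)) {
    for (omega in c(1e-12, 1e-4, 0.05, 0.3, 1)) {
      tot <- sum(exp(neutral_site_loglik(0:20, 20, p1, omega, quad)))
      expect_equal(tot, 1, tolerance = 1e-6)
    }
    for (kappa in c(0.25, 0.5, 0.9)) {
      tot <- sum(exp(sweep_site_loglik(0:20, 20, p1, 0.05, kappa, quad)))
      expect_equal(tot, 1, tolerance = 1e-6)
    }
  }
})

test_that("neutral likelihood matches a Monte-Carlo oracle", {
  # independent simulation of the generative model: clamped Gaussian drift
  # then binomial sampling
  set.seed(99)
  omega <- 0.05; p1 <- 0.5; n2 <- 20L
  x <- pmin(pmax(rnorm(1e6, p1, sqrt(omega * p1 * (1 - p1))), 0), 1)
  draws <- rbinom(1e6, n2, x)
  pmf_mc <- tabulate(draws + 1L, nbins = n2 + 1L) / 1e6
  pmf <- exp(neutral_site_loglik(0:n2, n2, p1, omega))
  se <- sqrt(pmf_mc * (1 - pmf_mc) / 1e6)
  expect_true(all(abs(pmf - pmf_mc) <= 3 * se + 1e-8))
})

test_that("sweep likelihood limits: kappa 0 is neutral, kappa 1 fixes", {
  quad <- gauss_legendre_quad(64)
  for (m2 in 0:12) {
    expect_equal(sweep_site_loglik(m2, 12, 0.35, 0.08, kappa = 0, quad),
                 neutral_site_loglik(m2, 12, 0.35, 0.08, quad),
                 tolerance = 1e-9)
  }
  # kappa = 1: every lineage captured; intermediate counts impossible
  ll_mid <- sweep_site_loglik(5, 12, 0.35, 0.08, kappa = 1, quad)
  expect_equal(ll_mid, -745)
  p_ends <- exp(sweep_site_loglik(c(0, 12), 12, 0.35, 0.08, 1, quad))
  expect_equal(sum(p_ends), 1, tolerance = 1e-6)
  expect_error(sweep_site_loglik(5, 12, 0.35, 0.08, kappa = 1.2), "kappa")
})

test_that("likelihoods are invariant to allele-label flips", {
  quad <- gauss_legendre_quad(64)
  for (kappa in c(0, 0.4, 0.9)) {
    a <- sweep_site_loglik(4, 14, 0.3, 0.07, kappa, quad)
    b <- sweep_site_loglik(10, 14, 0.7, 0.07, kappa, quad)
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("correlation weights count linked window SNPs", {
  set.seed(6)
  independent <- matrix(rbinom(50 * 4, 1, 0.5), nrow = 50)
  expect_equal(snp_weights(independent), rep(1, 4))

  x <- rbinom(50, 1, 0.5)
  triple <- cbind(x, x, x)
  expect_equal(snp_weights(triple), rep(1 / 3, 3))

  # 6-SNP toy against brute-force pairwise enumeration
  hap <- matrix(rbinom(40 * 6, 1, 0.5), nrow = 40)
  hap[, 2] <- hap[, 1]; hap[, 5] <- 1 - hap[, 4]
  w <- snp_weights(hap, r2_cutoff = 0.7)
  r2m <- cor(hap)^2
  expected <- vapply(1:6, function(k) {
    cnt <- 0L
    for (j in 1:6) if (r2m[k, j] >= 0.7) cnt <- cnt + 1L
    1 / cnt
  }, numeric(1))
  expect_equal(w, expected, tolerance = 1e-12)
})

test_that("scan scores are nonnegative with near-zero median under neutrality", {
  sim <- simulate_neutral_pair(sim_config(n_ref = 40, n_obj = 40,
                                          chrom_length = 5e5, n_snps = 2000,
                                          omega = 0.05, map_rate = 10,
                                          seed = 23))
  cr <- toy_counts(sim$positions, colSums(sim$hap_ref), 40L)
  co <- toy_counts(sim$positions, colSums(sim$hap_obj), 40L)
  model <- estimate_omega(cr, co)
  scan <- xpclr_scan(cr, co, sim$hap_obj, sim$map,
                     scan_params(grid_bp = 10000), model, seed = 3)
  expect_true(all(scan$score >= 0, na.rm = TRUE))
  expect_lt(median(scan$score, na.rm = TRUE), 2)
})

test_that("scan scores are invariant to allele-label flips", {
  sim <- simulate_neutral_pair(sim_config(n_ref = 20, n_obj = 20,
                                          chrom_length = 2e5, n_snps = 400,
                                          omega = 0.05, map_rate = 10,
                                          seed = 31))
  cr <- toy_counts(sim$positions, colSums(sim$hap_ref), 20L)
  co <- toy_counts(sim$positions, colSums(sim$hap_obj), 20L)
  model <- suppressWarnings(estimate_omega(cr, co))
  params <- scan_params(grid_bp = 20000)
  a <- xpclr_scan(cr, co, sim$hap_obj, sim$map, params, model, seed = 5)
  cr_f <- toy_counts(sim$positions, 20L - colSums(sim$hap_ref), 20L)
  co_f <- toy_counts(sim$positions, 20L - colSums(sim$hap_obj), 20L)
  b <- xpclr_scan(cr_f, co_f, 1 - sim$hap_obj, sim$map, params, model,
                  seed = 5)
  expect_equal(a$score, b$score, tolerance = 1e-7)
})

test_that("a window whose kappa is forced to zero scores exactly zero", {
  # one SNP 500 bp from the grid point, sigma grid so small that
  # kappa = exp(-d/sigma) underflows to 0: the sweep model collapses onto
  # neutrality and the score is exactly zero
  cr <- toy_counts(500, 5L, 20L)
  co <- toy_counts(500, 9L, 20L)
  map <- tibble::tibble(chrom = "A01", pos_bp = c(0, 1e5),
                        morgans = c(0, 1e-3))  # 1 cM/Mb
  model <- structure(list(omega = 0.05, n_sites = 1L), class = "drift_model")
  hap <- matrix(rbinom(20, 1, 0.4), nrow = 20, ncol = 1)
  scan <- xpclr_scan(cr, co, hap, map,
                     scan_params(window_morgans = 0.005, grid_bp = 2000,
                                 sigma_grid = 1e-9),
                     model, seed = 1)
  first <- scan[scan$pos == 0, ]
  expect_identical(first$n_snps, 1L)
  expect_identical(first$score, 0)
})
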