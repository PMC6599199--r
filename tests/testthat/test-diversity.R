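test_that("per-site diversity follows the unbiased pairwise formula", {
  # one site, m = 2 of n = 4: pi = 2*2*2/(4*3) = 2/3, spread over the window
  counts <- toy_counts(pos = 50, m = 2, n = 4)
  tr <- windowed_pi(counts, window = 100000, step = 25000,
                    chrom_lengths = c(A01 = 100000))
  expect_equal(tr$value[1], (2 * 2 * 2 / 12) / 100000, tolerance = 1e-12)

  # summed site pi divided by the full window length in bp
  counts2 <- toy_counts(pos = c(10, 20, 30), m = c(2, 2, 5),
                        n = c(4, 4, 10))
  s <- 2 * 2 * 2 / 12 * 2 + 2 * 5 * 5 / 90
  tr2 <- windowed_pi(counts2, 100000, 25000, c(A01 = 100000))
  expect_equal(tr2$value[1], s / 1e5, tolerance = 1e-12)

  # sites with n < 2 are skipped
  counts3 <- toy_counts(pos = c(10, 20), m = c(1, 1), n = c(1, 4))
  tr3 <- windowed_pi(counts3, 100000, 25000, c(A01 = 100000))
  expect_identical(tr3$n_sites[1], 1L)
})

test_that("windowed diversity matches a brute-force oracle on 1,000 sites", {
  set.seed(31)
  n_sites <- 1000
  pos <- sort(sample.int(500000, n_sites)) - 1L
  n <- sample(c(20L, 40L), n_sites, replace = TRUE)
  m <- rbinom(n_sites, n, runif(n_sites, 0.05, 0.95))
  counts <- toy_counts(pos, m, n)
  tr <- windowed_pi(counts, 100000, 25000, c(A01 = 500000))
  oracle <- oracle_windowed_pi(counts, 100000, 25000, 500000)
  expect_equal(tr$start, oracle$start)
  expect_equal(tr$value, oracle$value, tolerance = 1e-10)
  expect_identical(tr$n_sites, oracle$n_sites)
})

test_that("windowed diversity is calibrated to 2p(1-p)", {
  set.seed(7)
  n_sites <- 10000
  p <- runif(n_sites, 0.1, 0.9)
  n <- 40L
  counts <- toy_counts(seq_len(n_sites) * 10, rbinom(n_sites, n, p), n)
  site_pi <- 2 * counts$m * (counts$n - counts$m) /
    (counts$n * (counts$n - 1))
  expect_equal(mean(site_pi), mean(2 * p * (1 - p)), tolerance = 0.05)
})

test_that("Weir-Cockerham FST is 1 on fixed differences and ~0 when identical", {
  gt_fix <- cbind(matrix("0|0", 10, 6), matrix("1|1", 10, 6))
  v <- toy_variants("A01", seq(10, 100, by = 10), gt_fix)
  groups <- tibble::tibble(sample = sprintf("s%02d", 1:12),
                           group = rep(c("p1", "p2"), each = 6))
  tr <- windowed_fst(v, groups, chrom_lengths = c(A01 = 1e5))
  expect_equal(tr$value[1], 1, tolerance = 1e-12)

  set.seed(12)
  n_sites <- 10000
  p <- runif(n_sites, 0.1, 0.9)
  mk_gt <- function() {
    a1 <- matrix(rbinom(n_sites * 12, 1, p), nrow = n_sites)
    a2 <- matrix(rbinom(n_sites * 12, 1, p), nrow = n_sites)
    matrix(paste0(a1, "|", a2), nrow = n_sites)
  }
  v2 <- toy_variants("A01", seq_len(n_sites) * 10, cbind(mk_gt(), mk_gt()))
  groups2 <- tibble::tibble(sample = sprintf("s%02d", 1:24),
                            group = rep(c("p1", "p2"), times = c(12, 12)))
  g <- global_fst(v2, groups2)
  expect_lt(abs(g), 0.01)
})

test_that("site components match an independently coded WC-1984 calculator", {
  set.seed(55)
  n_sites <- 50
  mk <- function(n_ind, p) {
    a1 <- matrix(rbinom(n_sites * n_ind, 1, p), nrow = n_sites)
    a2 <- matrix(rbinom(n_sites * n_ind, 1, p), nrow = n_sites)
    list(gt = matrix(paste0(a1, "|", a2), nrow = n_sites), dose = a1 + a2)
  }
  p <- runif(n_sites, 0.1, 0.9)
  q <- pmin(pmax(p + rnorm(n_sites, 0, 0.2), 0.02), 0.98)
  pop1 <- mk(8, p); pop2 <- mk(10, q)
  v <- toy_variants("A01", seq_len(n_sites) * 10, cbind(pop1$gt, pop2$gt))
  groups <- tibble::tibble(sample = sprintf("s%02d", 1:18),
                           group = rep(c("p1", "p2"), times = c(8, 10)))
  gc <- genotype_counts(v, groups)
  g1 <- gc[gc$group == "p1", ]; g2 <- gc[gc$group == "p2", ]
  comp <- wc_components(g1$n_ind, g1$p_hat, g1$n_het / g1$n_ind,
                        g2$n_ind, g2$p_hat, g2$n_het / g2$n_ind)
  for (i in seq_len(n_sites)) {
    o <- oracle_wc_site(pop1$dose[i, ], pop2$dose[i, ])
    expect_equal(comp$a[i], o[["a"]], tolerance = 1e-10)
    expect_equal(comp$b[i], o[["b"]], tolerance = 1e-10)
    expect_equal(comp$c[i], o[["c"]], tolerance = 1e-10)
  }
})

test_that("r2 behaves on duplicated, independent, and label-flipped sites", {
  hap <- cbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 1, 0, 1))
  curve <- ld_decay(hap, positions = c(0, 500, 900), max_dist = 10000,
                    min_maf = 0, max_het = 1, bin = 10000)
  # pairs: (1,2) duplicated r2=1; (1,3) and (2,3) D=0 r2=0
  expect_equal(curve$mean_r2[1], (1 + 0 + 0) / 3, tolerance = 1e-12)
  expect_identical(curve$n_pairs[1], 3L)

  flipped <- ld_decay(cbind(1 - hap[, 1], hap[, 2:3]),
                      positions = c(0, 500, 900), max_dist = 10000,
                      min_maf = 0, max_het = 1, bin = 10000)
  expect_equal(curve$mean_r2, flipped$mean_r2, tolerance = 1e-12)
})

test_that("LD decays under the Markov copy-with-decay generator", {
  sim <- simulate_neutral_pair(sim_config(n_ref = 100, n_obj = 4,
                                          chrom_length = 200000,
                                          n_snps = 2000, omega = 0,
                                          ld_rho = 0.9, seed = 17))
  curve <- ld_decay(sim$hap_ref, sim$positions, max_dist = 50000,
                    bin = 1000)
  r2 <- curve$mean_r2[1:10]
  expect_true(all(diff(r2) <= 0))
  expect_gt(r2[1], r2[10])
})

test_that("diversity-ratio track applies the pseudocount rule", {
  a <- toy_track(c(1, 2, 4) * 1e-5)
  b <- toy_track(c(1, 2, 4) * 1e-5)
  expect_equal(pi_ratio_track(a, b)$value, rep(1, 3))

  zero_obj <- toy_track(c(0, 2e-5, 4e-5))
  ratio <- pi_ratio_track(a, zero_obj)
  eps <- 1e-5 / 2  # half the smallest nonzero windowed value
  expect_equal(ratio$value[1], (1e-5 + eps) / eps)
  expect_true(all(is.finite(ratio$value)))
  # hand-computed remaining windows
  expect_equal(ratio$value[2], (2e-5 + eps) / (2e-5 + eps))
  expect_equal(ratio$value[3], (4e-5 + eps) / (4e-5 + eps))

  # windows with no sites anywhere are flagged missing
  a2 <- toy_track(c(1e-5, 0), n_sites = c(1L, 0L))
  b2 <- toy_track(c(1e-5, 0), n_sites = c(1L, 0L))
  expect_true(is.na(pi_ratio_track(a2, b2)$value[2]))

  mismatched <- toy_track(c(1, 2) * 1e-5)
  expect_error(pi_ratio_track(a, mismatched), "grid")
})
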