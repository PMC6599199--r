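#' Configuration for the two-population genotype simulator
#'
#' Describes a neutral pair of populations related by genome-wide drift: for
#' each SNP an ancestral frequency `p` is drawn from a neutral-like spectrum,
#' the reference population keeps `p1 = p`, and the object population drifts
#' to `p2 ~ Normal(p1, omega * p1 * (1 - p1))` truncated to `[0, 1]` with the
#' excess mass collapsed onto the boundaries. Haplotypes are then sampled as
#' independent Bernoulli draws per chromosome.
#'
#' @param n_ref,n_obj Number of haploid chromosomes sampled in the reference
#'   and object populations. Must be even (chromosomes pair into diploids)
#'   and at least 4.
#' @param chrom_length Chromosome length in bp.
#' @param n_snps Number of segregating sites to place.
#' @param omega Genome-wide drift variance scale (dimensionless, >= 0).
#' @param sfs_range Support of the ancestral frequency spectrum; density is
#'   proportional to `1/x` on this interval, a neutral-like spectrum with no
#'   fixed sites.
#' @param map_rate Recombination rate in cM per Mb for the linear genetic map.
#' @param ld_rho Optional per-kb "copy-with-decay" correlation in (0, 1).
#'   When set, each haplotype copies its previous allele with probability
#'   `ld_rho^(gap_kb)` instead of drawing fresh, inducing LD that decays with
#'   distance. `NULL` (the default) gives linkage-equilibrium data.
#' @param chrom Chromosome name used in downstream tables.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_ref = 60, n_obj = 60, chrom_length = 2e6,
                       n_snps = 10000, omega = 0.1,
                       sfs_range = c(0.02, 0.98), map_rate = 1,
                       ld_rho = NULL, chrom = "A01", seed = 1) {
  check_scalar(n_ref, "n_ref", min = 4, integerish = TRUE)
  check_scalar(n_obj, "n_obj", min = 4, integerish = TRUE)
  if (n_ref %% 2 != 0 || n_obj %% 2 != 0) {
    abort("invalid configuration: fields `n_ref`, `n_obj` must be even",
          class = "polysweep_config_error")
  }
  check_scalar(chrom_length, "chrom_length", min = 1)
  check_scalar(n_snps, "n_snps", min = 1, integerish = TRUE)
  if (n_snps > chrom_length) {
    abort("invalid configuration: field `n_snps` exceeds `chrom_length`",
          class = "polysweep_config_error")
  }
  check_scalar(omega, "omega", min = 0)
  if (length(sfs_range) != 2 || sfs_range[1] <= 0 || sfs_range[2] >= 1 ||
      sfs_range[1] >= sfs_range[2]) {
    abort("invalid configuration: field `sfs_range` must be inside (0, 1)",
          class = "polysweep_config_error")
  }
  check_scalar(map_rate, "map_rate", min = 1e-9)
  if (!is.null(ld_rho)) check_scalar(ld_rho, "ld_rho", min = 1e-9, max = 1 - 1e-9)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(n_ref = as.integer(n_ref), n_obj = as.integer(n_obj),
                 chrom_length = as.integer(chrom_length),
                 n_snps = as.integer(n_snps), omega = omega,
                 sfs_range = sfs_range, map_rate = map_rate,
                 ld_rho = ld_rho, chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

# Inverse-CDF draw from density proportional to 1/x on [a, b].
r_log_uniform <- function(n, a, b) a * (b / a)^runif(n)

#' Simulate a neutral two-population SNP panel
#'
#' Draws ancestral frequencies, drifts the object population, samples phased
#' haplotypes, and builds a linear bp-to-Morgan map. See [sim_config()] for
#' the model.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `pop_sim` with elements `hap_ref`, `hap_obj`
#'   (0/1 matrices, one row per haploid chromosome, one column per SNP),
#'   `positions` (0-based bp, strictly increasing), `map` (tibble with
#'   `chrom`, `pos_bp`, `morgans`), true frequencies `p1`, `p2`, and `cfg`.
#' @export
simulate_neutral_pair <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  set.seed(cfg$seed)
  positions <- sort(sample.int(cfg$chrom_length, cfg$n_snps)) - 1L
  p1 <- r_log_uniform(cfg$n_snps, cfg$sfs_range[1], cfg$sfs_range[2])
  if (cfg$omega == 0) {
    p2 <- p1
  } else {
    p2 <- rnorm(cfg$n_snps, p1, sqrt(cfg$omega * p1 * (1 - p1)))
    p2 <- pmin(pmax(p2, 0), 1)
  }
  hap_ref <- sample_haplotypes(cfg$n_ref, p1, positions, cfg$ld_rho)
  hap_obj <- sample_haplotypes(cfg$n_obj, p2, positions, cfg$ld_rho)
  map <- linear_map(cfg$chrom, positions, cfg$map_rate, cfg$chrom_length)
  structure(list(hap_ref = hap_ref, hap_obj = hap_obj,
                 positions = positions, map = map,
                 p1 = p1, p2 = p2, cfg = cfg),
            class = "pop_sim")
}

# Bernoulli haplotypes, optionally with Markov copy-with-decay LD.
sample_haplotypes <- function(n_hap, freqs, positions, ld_rho = NULL) {
  n_snps <- length(freqs)
  fresh <- matrix(rbinom(n_hap * n_snps, 1L, rep(freqs, each = n_hap)),
                  nrow = n_hap, ncol = n_snps)
  if (is.null(ld_rho) || n_snps < 2L) return(fresh)
  copy_p <- ld_rho^(diff(positions) / 1000)
  hap <- fresh
  for (s in 2:n_snps) {
    keep <- runif(n_hap) < copy_p[s - 1L]
    hap[keep, s] <- hap[keep, s - 1L]
  }
  hap
}

# Linear genetic map: morgans = bp / 1e6 * map_rate(cM/Mb) / 100. Anchored at
# 0 and chromosome end so every SNP position interpolates strictly inside.
linear_map <- function(chrom, positions, map_rate, chrom_length) {
  pos <- sort(unique(c(0L, positions, as.integer(chrom_length))))
  tibble(chrom = chrom, pos_bp = pos,
         morgans = pos / 1e6 * map_rate / 100)
}

#' Interpolate genetic-map positions
#'
#' @param map Tibble with `chrom`, `pos_bp`, `morgans`.
#' @param chrom Chromosome name.
#' @param pos Positions in bp (0-based).
#' @return Morgans at `pos`; errors if any position falls outside the map.
#' @export
map_morgans <- function(map, chrom, pos) {
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) < 2L) abort(sprintf("genetic map has no entries for chromosome %s", chrom))
  out <- approx(m$pos_bp, m$morgans, xout = pos, rule = 1)$y
  if (anyNA(out)) {
    abort(sprintf("genetic map for %s does not cover all positions", chrom))
  }
  out
}

#' Specification of an implanted selective sweep
#'
#' A hitchhiking event in one population: a linked neutral SNP at genetic
#' distance `d` Morgans from the selected site is captured by the sweeping
#' haplotype with probability `kappa = exp(-d / sigma)`; captured lineages
#' ride to the frequency of the allele they sit on.
#'
#' @param position Selected site in bp (0-based).
#' @param sigma Sweep scale in Morgans (> 0); larger values give wider
#'   footprints.
#' @param direction Which population carries the sweep (`"obj"` or `"ref"`).
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(position, sigma, direction = "obj") {
  check_scalar(position, "position", min = 0)
  check_scalar(sigma, "sigma", min = 1e-12)
  direction <- match.arg(direction, c("obj", "ref"))
  structure(list(position = as.integer(position), sigma = sigma,
                 direction = direction), class = "sweep_spec")
}

#' Implant a selective sweep into a simulated population
#'
#' For each SNP at genetic distance `d` from `spec$position`, with
#' `kappa = exp(-d / spec$sigma)`, the pre-sweep frequency `y` becomes
#' `kappa + (1 - kappa) * y` with probability `y` (the neutral allele was on
#' the sweeping background) and `(1 - kappa) * y` otherwise; haplotypes are
#' resampled as Bernoulli draws at the new frequency. At `d = 0` the
#' frequency is forced to 0 or 1.
#'
#' @param sim A `pop_sim` from [simulate_neutral_pair()].
#' @param spec A [sweep_spec()].
#' @param seed Integer seed for the resampling.
#' @return The modified `pop_sim`; post-sweep truth is recorded in
#'   `p2` (or `p1`) and `sweep`.
#' @export
implant_sweep <- function(sim, spec, seed = 1) {
  stopifnot(inherits(sim, "pop_sim"), inherits(spec, "sweep_spec"))
  if (spec$position < 0 || spec$position >= sim$cfg$chrom_length) {
    abort("sweep position outside chromosome bounds")
  }
  set.seed(seed)
  d <- abs(map_morgans(sim$map, sim$cfg$chrom, sim$positions) -
             map_morgans(sim$map, sim$cfg$chrom, spec$position))
  kappa <- exp(-d / spec$sigma)
  y <- if (spec$direction == "obj") sim$p2 else sim$p1
  on_sweep <- runif(length(y)) < y
  x <- ifelse(on_sweep, kappa + (1 - kappa) * y, (1 - kappa) * y)
  n_hap <- if (spec$direction == "obj") sim$cfg$n_obj else sim$cfg$n_ref
  hap <- sample_haplotypes(n_hap, x, sim$positions, ld_rho = NULL)
  if (spec$direction == "obj") {
    sim$hap_obj <- hap
    sim$p2 <- x
  } else {
    sim$hap_ref <- hap
    sim$p1 <- x
  }
  sim$sweep <- spec
  sim
}
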