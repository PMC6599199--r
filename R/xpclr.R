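#' Estimate the genome-wide drift scale
#'
#' Method-of-moments estimator of the drift variance scale `omega` of the
#' cross-population model `p2 ~ Normal(p1, omega * p1 * (1 - p1))`. Each
#' usable site contributes an unbiased numerator
#' `(p1.hat - p2.hat)^2 - p1.hat*q1.hat/(n1-1) - p2.hat*q2.hat/(n2-1)`
#' (the squared frequency difference minus both binomial sampling variances)
#' and denominator `p1.hat*q1.hat*n1/(n1-1)`; the estimate is the ratio of
#' their sums, which keeps sites near the frequency boundary from blowing up
#' a per-site ratio. Negative site numerators are retained (they keep the
#' estimator unbiased); the final estimate is floored at zero. Sites fixed
#' in the reference sample are excluded.
#'
#' Because the drift Gaussian is truncated to `[0, 1]` with its tail mass
#' collapsed onto the boundaries, the realized cross-population variance at
#' a site is not `omega * p1 * q1` but the second moment of the clamped
#' Gaussian, which is smaller near the frequency boundary. By default the
#' estimator accounts for this: it solves (by one-dimensional
#' root-finding) for the `omega` whose model-implied clamped variances sum
#' to the observed bias-corrected numerator sum. With
#' `truncation_correction = FALSE` the plain ratio of sums is returned;
#' the two agree when boundary truncation is negligible.
#'
#' @param counts_ref,counts_obj Allele-count tibbles (`chrom`, `pos`, `m`,
#'   `n`) for the reference and object populations at the same sites.
#' @param truncation_correction Solve the clamped-variance moment equation
#'   (default) instead of the plain ratio of sums.
#' @return An object of class `drift_model`: list with `omega`, `n_sites`.
#' @export
estimate_omega <- function(counts_ref, counts_obj,
                           truncation_correction = TRUE) {
  stopifnot(nrow(counts_ref) == nrow(counts_obj))
  p1 <- counts_ref$m / counts_ref$n
  p2 <- counts_obj$m / counts_obj$n
  n1 <- counts_ref$n
  n2 <- counts_obj$n
  ok <- !is.na(p1) & !is.na(p2) & p1 > 0 & p1 < 1 & n1 >= 2 & n2 >= 2
  if (!any(ok)) abort("estimate_omega: no usable polymorphic sites")
  if (sum(ok) < 1000) {
    warn(sprintf("estimate_omega: only %d usable sites; estimate may be noisy",
                 sum(ok)))
  }
  p1 <- p1[ok]; p2 <- p2[ok]; n1 <- n1[ok]; n2 <- n2[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p1) * n1 / (n1 - 1)
  omega <- if (truncation_correction) {
    target <- sum(num)
    f <- function(om) sum(clamped_drift_var(p1, om)) - target
    if (target <= 0 || f(1e-10) >= 0) 0 else
      stats::uniroot(f, c(1e-10, 10), tol = 1e-10)$root
  } else {
    max(sum(num) / sum(den), 0)
  }
  structure(list(omega = omega, n_sites = length(p1)),
            class = "drift_model")
}

# Second moment about p1 of the clamped drift draw: X ~ N(p1, omega*p1*q1)
# truncated to [0, 1] with tail mass moved onto the boundaries.
clamped_drift_var <- function(p1, omega) {
  s <- sqrt(omega * p1 * (1 - p1))
  a <- -p1 / s
  b <- (1 - p1) / s
  p1^2 * pnorm(a) + (1 - p1)^2 * pnorm(b, lower.tail = FALSE) +
    s^2 * (pnorm(b) - pnorm(a) - (b * dnorm(b) - a * dnorm(a)))
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("<drift_model> omega = %.4g (from %d sites)\n",
              x$omega, x$n_sites))
  invisible(x)
}

#' Gauss-Legendre quadrature rule on (0, 1)
#'
#' @param n Number of nodes.
#' @return List with `nodes`, `weights` on the unit interval.
#' @export
gauss_legendre_quad <- function(n = 64) {
  g <- pracma::gaussLegendre(n, 0, 1)
  list(nodes = g$x, weights = g$w)
}

# Per-site quadrature of the drift kernel: 64 Gauss-Legendre nodes over the
# Gaussian's effective support (p1 +/- 8 sd, clipped to (0, 1)), plus the
# truncated tail masses at the boundaries. A fixed rule over all of (0, 1)
# cannot resolve a narrow kernel (small omega), so the rule is rescaled to
# where the density lives; mass outside +/- 8 sd is below 1e-15.
# Returns, for a vector of sites: node matrix Y (site x n), weighted density
# matrix PHI (dnorm * quad weight), and boundary masses P0, P1.
drift_kernel <- function(p1, omega, quad) {
  if (omega < 0) abort("omega must be >= 0")
  sd <- sqrt(omega * p1 * (1 - p1))
  a <- pmax(0, p1 - 8 * sd)
  b <- pmin(1, p1 + 8 * sd)
  Y <- outer(b - a, quad$nodes) + a          # site x n nodes
  W <- outer(b - a, quad$weights)
  PHI <- dnorm(Y, p1, sd) * W
  P0 <- pnorm(0, p1, sd)
  P1 <- pnorm(1, p1, sd, lower.tail = FALSE)
  list(Y = Y, PHI = PHI, P0 = P0, P1 = P1, sd = sd)
}

.log_floor <- -745  # log of the smallest positive double

#' Neutral site log-likelihood
#'
#' Marginal log-probability of observing `m2` alternate alleles among `n2`
#' chromosomes in the object population given the reference frequency
#' `p1` under pure drift: the object frequency `x` follows a Gaussian with
#' mean `p1` and variance `omega * p1 * (1 - p1)` truncated to `[0, 1]`
#' with the tail masses collapsed onto the boundaries (contributing only
#' when `m2 = 0` or `m2 = n2`); the binomial sampling layer is integrated
#' by fixed Gauss-Legendre quadrature. At `omega = 0` this reduces to the
#' binomial pmf at `p1`.
#'
#' @param m2,n2 Alternate-allele count and chromosomes sampled (vectors
#'   recycle against `p1`).
#' @param p1 Reference-population frequency in (0, 1) (clamp fixed sites
#'   upstream).
#' @param model A `drift_model` (or a bare omega value).
#' @param quad Quadrature rule from [gauss_legendre_quad()].
#' @return Log-likelihood vector, floored at `-745`.
#' @export
neutral_site_loglik <- function(m2, n2, p1, model, quad = gauss_legendre_quad()) {
  sweep_site_loglik(m2, n2, p1, model, kappa = 0, quad = quad)
}

#' Hitchhiking site log-likelihood
#'
#' As [neutral_site_loglik()], but the neutral object frequency `y` is
#' passed through the sweep transform first: with probability `y` the
#' neutral allele sat on the sweeping haplotype and rises to
#' `x = kappa + (1 - kappa) * y`; otherwise it falls to
#' `x = (1 - kappa) * y`. `kappa` in `[0, 1]` is the capture probability
#' of the site (`exp(-d / sigma)` at genetic distance `d`). `kappa = 0`
#' recovers the neutral likelihood exactly; `kappa = 1` forbids
#' intermediate counts.
#'
#' @inheritParams neutral_site_loglik
#' @param kappa Capture probability, recycled against sites.
#' @return Log-likelihood vector, floored at `-745`.
#' @export
sweep_site_loglik <- function(m2, n2, p1, model, kappa,
                              quad = gauss_legendre_quad()) {
  omega <- if (inherits(model, "drift_model")) model$omega else model
  if (any(kappa < 0 | kappa > 1)) abort("kappa must lie in [0, 1]")
  k <- max(length(m2), length(p1), length(kappa))
  m2 <- rep_len(m2, k); n2 <- rep_len(n2, k)
  p1 <- rep_len(p1, k); kappa <- rep_len(kappa, k)
  if (omega == 0) {
    x1 <- kappa + (1 - kappa) * p1
    x2 <- (1 - kappa) * p1
    p <- p1 * dbinom(m2, n2, x1) + (1 - p1) * dbinom(m2, n2, x2)
    return(pmax(log(p), .log_floor))
  }
  kern <- drift_kernel(p1, omega, quad)
  sweep_ll_kernel(kern, m2, n2, kappa)
}

# Binomial pmf over a node matrix, in log space with a precomputed
# log-binomial-coefficient; arguments recycle down rows. Success
# probabilities are clamped away from 0 and 1 (relative error < 1e-12)
# so boundary nodes cannot produce 0 * log(0).
binom_pmf_nodes <- function(m2, n2, lC, X) {
  B <- exp(lC + m2 * log(pmax(X, 1e-300)) +
             (n2 - m2) * log1p(-pmin(X, 1 - 1e-16)))
  dim(B) <- dim(X)
  # nodes pinned exactly at a boundary (kappa = 1) are degenerate draws
  ii <- which(X >= 1 | X <= 0)
  if (length(ii) > 0) {
    rows <- (ii - 1L) %% nrow(X) + 1L
    B[ii] <- ifelse(X[ii] >= 1, as.numeric(m2[rows] == n2[rows]),
                    as.numeric(m2[rows] == 0))
  }
  B
}

# Sweep log-likelihood from a precomputed drift kernel (rows = sites).
# kappa recycles down the rows of the node matrices (column-major).
sweep_ll_kernel <- function(kern, m2, n2, kappa) {
  lC <- lchoose(n2, m2)
  B1 <- binom_pmf_nodes(m2, n2, lC, kappa + (1 - kappa) * kern$Y)
  B2 <- binom_pmf_nodes(m2, n2, lC, (1 - kappa) * kern$Y)
  interior <- rowSums(kern$PHI * (kern$Y * B1 + (1 - kern$Y) * B2))
  p <- interior + kern$P0 * (m2 == 0) + kern$P1 * (m2 == n2)
  pmax(log(p), .log_floor)
}

subset_kernel <- function(kern, idx) {
  list(Y = kern$Y[idx, , drop = FALSE], PHI = kern$PHI[idx, , drop = FALSE],
       P0 = kern$P0[idx], P1 = kern$P1[idx])
}

#' Correlation down-weighting of window SNPs
#'
#' Each SNP `k` in a scan window is weighted `1 / m_k`, where `m_k` counts
#' the window SNPs (itself included) whose `r^2` with SNP `k` is at least
#' `r2_cutoff`, so clusters of redundant, tightly linked SNPs contribute
#' like a single observation.
#'
#' @param haplotypes Matrix (haplotypes or dosages in rows, window SNPs in
#'   columns).
#' @param r2_cutoff Correlation threshold.
#' @return Numeric vector of weights in (0, 1].
#' @export
snp_weights <- function(haplotypes, r2_cutoff = 0.7) {
  k <- ncol(haplotypes)
  if (k == 1L) return(1)
  r2 <- suppressWarnings(cor(haplotypes))^2
  r2[is.na(r2)] <- 0       # monomorphic-in-sample pairs carry no information
  diag(r2) <- 1
  unname(1 / rowSums(r2 >= r2_cutoff))
}

#' Scan parameters for the composite-likelihood sweep scan
#'
#' @param window_morgans Scan window size in Morgans (SNPs within half this
#'   distance of a grid point enter its window).
#' @param max_snps Maximum SNPs per window; larger windows are uniformly
#'   downsampled (deterministically, given the scan seed).
#' @param grid_bp Spacing of scan grid points in bp.
#' @param r2_cutoff Threshold for the correlation down-weighting.
#' @param sigma_grid Sweep scales (Morgans) maximized over; the neutral
#'   model (`kappa == 0` everywhere) is always included, so scores are
#'   nonnegative. Default: 12 log-spaced values spanning footprints from
#'   roughly kb to Mb scale at 1 cM/Mb.
#' @param n_quad Number of Gauss-Legendre quadrature nodes.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(window_morgans = 0.005, max_snps = 100,
                        grid_bp = 2000, r2_cutoff = 0.7,
                        sigma_grid = 10^seq(-5, -1, length.out = 12),
                        n_quad = 64) {
  check_scalar(window_morgans, "window_morgans", min = 1e-12)
  check_scalar(max_snps, "max_snps", min = 1, integerish = TRUE)
  check_scalar(grid_bp, "grid_bp", min = 1, integerish = TRUE)
  check_scalar(r2_cutoff, "r2_cutoff", min = 0, max = 1)
  stopifnot(all(sigma_grid > 0))
  check_scalar(n_quad, "n_quad", min = 2, integerish = TRUE)
  structure(list(window_morgans = window_morgans,
                 max_snps = as.integer(max_snps),
                 grid_bp = as.integer(grid_bp), r2_cutoff = r2_cutoff,
                 sigma_grid = sigma_grid, n_quad = as.integer(n_quad)),
            class = "scan_params")
}

#' Cross-population composite-likelihood sweep scan
#'
#' At each grid point (every `grid_bp` bp), SNPs within
#' `window_morgans / 2` Morgans are collected (downsampled to `max_snps`),
#' down-weighted for mutual correlation, and scored with
#' `S = 2 * [ max_sigma sum_k w_k * sweep_loglik_k(kappa_k = exp(-d_k / sigma))
#'           - sum_k w_k * neutral_loglik_k ]`,
#' where `d_k` is the genetic distance from SNP `k` to the grid point.
#' Because the neutral model is in the maximization, `S >= 0` everywhere;
#' empty windows are missing. Reference frequencies fixed in the sample are
#' clamped to `[1/(2 n1), 1 - 1/(2 n1)]` (the drift variance degenerates at
#' the boundary).
#'
#' @param counts_ref,counts_obj Allele counts at the same sites for the
#'   reference and object populations.
#' @param hap_obj Object-population haplotype (or dosage) matrix, columns
#'   aligned with the count rows, used for the correlation weights.
#' @param map Genetic map tibble (`chrom`, `pos_bp`, `morgans`) covering
#'   every SNP position.
#' @param params A [scan_params()].
#' @param model A `drift_model` from [estimate_omega()].
#' @param seed Integer seed for window downsampling.
#' @return An `xpclr_scan` tibble: `chrom`, `pos` (grid point, bp),
#'   `score`, `n_snps`, and `best_sigma` (the maximizing sweep scale, `NA`
#'   when the neutral model wins).
#' @export
xpclr_scan <- function(counts_ref, counts_obj, hap_obj, map,
                       params = scan_params(), model, seed = 1) {
  stopifnot(inherits(params, "scan_params"), inherits(model, "drift_model"))
  stopifnot(nrow(counts_ref) == nrow(counts_obj),
            ncol(hap_obj) == nrow(counts_ref))
  quad <- gauss_legendre_quad(params$n_quad)
  set.seed(seed)
  chroms <- unique(counts_ref$chrom)
  out <- purrr::map(chroms, function(ch) {
    idx <- which(counts_ref$chrom == ch)
    idx <- idx[order(counts_ref$pos[idx])]
    cr <- counts_ref[idx, ]
    co <- counts_obj[idx, ]
    usable <- cr$n >= 2 & co$n >= 2
    cr <- cr[usable, ]; co <- co[usable, ]
    hap <- hap_obj[, idx[usable], drop = FALSE]
    if (nrow(cr) == 0L) return(NULL)
    p1 <- pmin(pmax(cr$m / cr$n, 1 / (2 * cr$n)), 1 - 1 / (2 * cr$n))
    snp_mor <- map_morgans(map, ch, cr$pos)
    grid <- seq(0L, max(cr$pos), by = params$grid_bp)
    grid_mor <- map_morgans(map, ch, grid)
    neutral_ll <- neutral_site_loglik(co$m, co$n, p1, model, quad)
    kern <- if (model$omega > 0) drift_kernel(p1, model$omega, quad)
    half <- params$window_morgans / 2
    lo <- findInterval(grid_mor - half, snp_mor) + 1L
    hi <- findInterval(grid_mor + half, snp_mor)
    score <- rep(NA_real_, length(grid))
    n_snps <- integer(length(grid))
    best_sigma <- rep(NA_real_, length(grid))
    for (g in seq_along(grid)) {
      if (hi[g] < lo[g]) next
      win <- lo[g]:hi[g]
      if (length(win) > params$max_snps) {
        win <- sort(sample(win, params$max_snps))
      }
      w <- snp_weights(hap[, win, drop = FALSE], params$r2_cutoff)
      d <- abs(snp_mor[win] - grid_mor[g])
      ll_neutral <- sum(w * neutral_ll[win])
      ll_sigma <- vapply(params$sigma_grid, function(sig) {
        kappa <- exp(-d / sig)
        active <- kappa > 1e-12
        ll <- neutral_ll[win]
        if (any(active)) {
          ai <- win[active]
          ll[active] <- if (is.null(kern)) {
            sweep_site_loglik(co$m[ai], co$n[ai], p1[ai], model,
                              kappa[active], quad)
          } else {
            sweep_ll_kernel(subset_kernel(kern, ai), co$m[ai], co$n[ai],
                            kappa[active])
          }
        }
        sum(w * ll)
      }, numeric(1))
      best <- which.max(c(ll_sigma, ll_neutral))
      score[g] <- 2 * (max(ll_sigma, ll_neutral) - ll_neutral)
      n_snps[g] <- length(win)
      best_sigma[g] <- if (best > length(params$sigma_grid)) NA_real_ else
        params$sigma_grid[best]
    }
    tibble(chrom = ch, pos = grid, score = score, n_snps = n_snps,
           best_sigma = best_sigma)
  }) |> bind_rows()
  structure(out, params = params, omega = model$omega,
            class = c("xpclr_scan", class(out)))
}
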