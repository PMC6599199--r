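#' Windowed nucleotide diversity
#'
#' Per-site diversity is the unbiased pairwise estimator
#' `pi_i = 2 m (n - m) / (n (n - 1))` from `m` alternate alleles among `n`
#' sampled chromosomes; the window value is the sum of site diversities
#' divided by the full window length in bp, so bp without observed
#' polymorphism contribute zero to the numerator but stay in the
#' denominator. This is the convention of the standard windowed estimators
#' and puts transcriptome-derived values on the 1e-5 scale.
#'
#' @param counts Allele counts for one population (tibble with `chrom`,
#'   `pos`, `m`, `n`; see [allele_counts()]). Sites with `n < 2` are
#'   skipped.
#' @param window,step Window size and step in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths; by
#'   default windows run to the last observed site.
#' @return A window track: tibble `chrom`, `start`, `end`, `value`,
#'   `n_sites`, with attributes `window` and `step`.
#' @export
windowed_pi <- function(counts, window = 100000, step = 25000,
                        chrom_lengths = NULL) {
  if ("group" %in% names(counts) && length(unique(counts$group)) > 1) {
    abort("windowed_pi expects counts for a single population; filter `group` first")
  }
  counts <- counts |>
    filter(.data$n >= 2) |>
    mutate(site_pi = 2 * .data$m * (.data$n - .data$m) /
             (.data$n * (.data$n - 1)))
  track_by_chrom(counts, value_col = "site_pi", window = window, step = step,
                 chrom_lengths = chrom_lengths, normalize = "window_bp")
}

# Shared windowing core: sums value_col per window; normalize = "window_bp"
# divides by window size, "mean" divides by n_sites (NA when empty).
track_by_chrom <- function(df, value_col, window, step, chrom_lengths = NULL,
                           normalize = c("window_bp", "mean")) {
  normalize <- match.arg(normalize)
  chroms <- sort(unique(df$chrom))
  out <- purrr::map(chroms, function(ch) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    len <- chrom_lengths[[ch]] %||% (max(d$pos) + 1L)
    win <- sliding_windows(len, window, step)
    ws <- window_sums(d$pos, d[[value_col]], win$start, win$end)
    val <- switch(normalize,
                  window_bp = ws$sum / window,
                  mean = ifelse(ws$n_sites > 0, ws$sum / ws$n_sites, NA_real_))
    tibble(chrom = ch, start = win$start, end = win$end,
           value = val, n_sites = ws$n_sites)
  }) |> bind_rows()
  structure(out, window = window, step = step,
            class = c("window_track", class(out)))
}

#' Per-site Weir-Cockerham variance components
#'
#' Computes the 1984 analysis-of-variance components `a` (among
#' populations), `b` (among individuals within populations), and `c`
#' (within individuals) for two populations from diploid genotype counts,
#' including observed heterozygosity.
#'
#' @param n1,n2 Diploid sample sizes (non-missing) per population.
#' @param p1,p2 Alternate-allele frequencies per population.
#' @param h1,h2 Observed heterozygote proportions per population.
#' @return Tibble with columns `a`, `b`, `c` (one row per site).
#' @export
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tibble(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham F_ST between two populations
#'
#' Site components are combined per window as the "weighted" estimator
#' `sum(a) / sum(a + b + c)`; windows whose denominator is zero (no
#' polymorphism) are flagged missing.
#'
#' @param variants A variant table.
#' @param sample_groups Tibble `sample`/`group` naming exactly two groups.
#' @param window,step Window size and step in bp.
#' @param chrom_lengths Optional named chromosome lengths.
#' @return A window track of F_ST values (`value` is `NA` where undefined),
#'   with `n_sites` counting sites that contributed components.
#' @export
windowed_fst <- function(variants, sample_groups, window = 100000,
                         step = 25000, chrom_lengths = NULL) {
  gc <- genotype_counts(variants, sample_groups)
  grps <- unique(gc$group)
  if (length(grps) != 2) abort("windowed_fst requires exactly two groups")
  g1 <- gc[gc$group == grps[1], ]
  g2 <- gc[gc$group == grps[2], ]
  stopifnot(identical(g1$pos, g2$pos), identical(g1$chrom, g2$chrom))
  ok <- g1$n_ind >= 1 & g2$n_ind >= 1 & (g1$n_ind + g2$n_ind) >= 2
  comp <- wc_components(g1$n_ind[ok], g1$p_hat[ok], g1$n_het[ok] / g1$n_ind[ok],
                        g2$n_ind[ok], g2$p_hat[ok], g2$n_het[ok] / g2$n_ind[ok])
  df <- tibble(chrom = g1$chrom[ok], pos = g1$pos[ok],
               a = comp$a, abc = comp$a + comp$b + comp$c)
  chroms <- sort(unique(df$chrom))
  out <- purrr::map(chroms, function(ch) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    len <- chrom_lengths[[ch]] %||% (max(d$pos) + 1L)
    win <- sliding_windows(len, window, step)
    num <- window_sums(d$pos, d$a, win$start, win$end)
    den <- window_sums(d$pos, d$abc, win$start, win$end)
    tibble(chrom = ch, start = win$start, end = win$end,
           value = ifelse(den$n_sites > 0 & den$sum != 0,
                          num$sum / den$sum, NA_real_),
           n_sites = num$n_sites)
  }) |> bind_rows()
  structure(out, window = window, step = step,
            class = c("window_track", class(out)))
}

#' Genome-wide Weir-Cockerham F_ST
#'
#' The weighted estimator pooled over all sites, as a single number.
#'
#' @inheritParams windowed_fst
#' @return A length-1 double.
#' @export
global_fst <- function(variants, sample_groups) {
  tr <- windowed_fst(variants, sample_groups,
                     window = .Machine$integer.max %/% 2L,
                     step = .Machine$integer.max %/% 2L)
  tr$value[1]
}

#' Linkage-disequilibrium decay curve
#'
#' Pairwise `r^2` between sites within `max_dist` bp, averaged in distance
#' bins. For phased haplotypes `r^2` is the squared allelic correlation
#' `D^2 / (pA qA pB qB)`, computed as the squared Pearson correlation of the
#' 0/1 haplotype columns; for unphased genotypes pass a dosage matrix
#' (0/1/2) and the squared genotype-dosage correlation is used instead.
#' Site filters (minor allele frequency, heterozygosity, missingness)
#' apply to this computation only.
#'
#' @param haplotypes Matrix with one row per haploid chromosome (phased) or
#'   one row per individual with 0/1/2 dosages (`phased = FALSE`); one
#'   column per site. `NA` allowed.
#' @param positions 0-based bp positions, one per column.
#' @param max_dist Maximum pair distance in bp (default 3 Mb).
#' @param min_maf Minimum minor allele frequency per site.
#' @param max_het Maximum heterozygote proportion per site (phased input is
#'   paired into diploids row 1+2, 3+4, ... for this filter).
#' @param max_miss Maximum missing fraction per site.
#' @param bin Distance bin width in bp.
#' @param phased Whether rows are haplotypes (`TRUE`) or dosages.
#' @return An `ld_curve` tibble: `bin_start`, `bin_end`, `mean_r2`,
#'   `n_pairs`.
#' @export
ld_decay <- function(haplotypes, positions, max_dist = 3e6, min_maf = 0.05,
                     max_het = 0.88, max_miss = 0.25, bin = 10000,
                     phased = TRUE) {
  stopifnot(ncol(haplotypes) == length(positions))
  if (phased) {
    dose <- haplotypes
    n_ind <- nrow(haplotypes) %/% 2
    geno <- haplotypes[2 * seq_len(n_ind) - 1, , drop = FALSE] +
      haplotypes[2 * seq_len(n_ind), , drop = FALSE]
    p <- colMeans(haplotypes, na.rm = TRUE)
  } else {
    dose <- haplotypes
    geno <- haplotypes
    p <- colMeans(haplotypes, na.rm = TRUE) / 2
  }
  het <- colMeans(geno == 1, na.rm = TRUE)
  miss <- colMeans(is.na(dose))
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= min_maf & het <= max_het & miss <= max_miss &
    maf > 0
  dose <- dose[, keep, drop = FALSE]
  positions <- positions[keep]
  edges <- seq(0, ceiling(max_dist / bin) * bin, by = bin)
  curve <- tibble(bin_start = edges[-length(edges)], bin_end = edges[-1],
                  sum_r2 = 0, n_pairs = 0L)
  if (ncol(dose) >= 2) {
    r2 <- suppressWarnings(cor(dose, use = "pairwise.complete.obs"))^2
    ij <- which(upper.tri(r2), arr.ind = TRUE)
    d <- abs(positions[ij[, 2]] - positions[ij[, 1]])
    v <- r2[ij]
    ok <- d > 0 & d <= max_dist & !is.na(v)
    b <- findInterval(d[ok], edges, left.open = TRUE)
    agg_sum <- tapply(v[ok], b, sum)
    agg_n <- tapply(v[ok], b, length)
    idx <- as.integer(names(agg_sum))
    curve$sum_r2[idx] <- as.numeric(agg_sum)
    curve$n_pairs[idx] <- as.integer(agg_n)
  }
  out <- curve |>
    mutate(mean_r2 = ifelse(.data$n_pairs > 0,
                            .data$sum_r2 / .data$n_pairs, NA_real_)) |>
    select("bin_start", "bin_end", "mean_r2", "n_pairs")
  structure(out, class = c("ld_curve", class(out)))
}

#' Ratio of nucleotide-diversity tracks
#'
#' `value = (pi_ref + eps) / (pi_obj + eps)` per window, where the
#' pseudocount `eps` defaults to half the smallest nonzero windowed
#' diversity across both tracks: ratios stay finite and their ranking is
#' preserved. Elevated values flag diversity loss in the object (derived)
#' population. Windows with no sites in either population are flagged
#' missing.
#'
#' @param pi_ref,pi_obj Window tracks from [windowed_pi()] on the same
#'   window grid (reference population in the numerator).
#' @param eps Pseudocount; `NULL` for the default above.
#' @return A window track of ratios; `n_sites` is the summed site count.
#' @export
pi_ratio_track <- function(pi_ref, pi_obj, eps = NULL) {
  if (!identical(pi_ref$chrom, pi_obj$chrom) ||
      !identical(pi_ref$start, pi_obj$start) ||
      !identical(pi_ref$end, pi_obj$end)) {
    abort("pi_ratio_track: window grids differ between tracks")
  }
  if (is.null(eps)) {
    nz <- c(pi_ref$value[pi_ref$value > 0], pi_obj$value[pi_obj$value > 0])
    eps <- if (length(nz) > 0) min(nz, na.rm = TRUE) / 2 else 1e-12
  }
  empty <- pi_ref$n_sites == 0 & pi_obj$n_sites == 0
  out <- tibble(chrom = pi_ref$chrom, start = pi_ref$start,
                end = pi_ref$end,
                value = ifelse(empty, NA_real_,
                               (pi_ref$value + eps) / (pi_obj$value + eps)),
                n_sites = pi_ref$n_sites + pi_obj$n_sites)
  structure(out, window = attr(pi_ref, "window"), step = attr(pi_ref, "step"),
            eps = eps, class = c("window_track", class(out)))
}
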