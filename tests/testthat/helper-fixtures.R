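# Small in-code fixtures shared across test files.

# A variant table built directly from explicit per-site metadata and a
# genotype string matrix (sites x samples).
toy_variants <- function(chrom, pos, gt, dp = 30, mq = 50,
                         func_class = "synonymous",
                         ref = "A", alt = "G") {
  n <- length(pos)
  gt <- matrix(gt, nrow = n)
  colnames(gt) <- sprintf("s%02d", seq_len(ncol(gt)))
  dplyr::bind_cols(
    tibble::tibble(chrom = rep_len(chrom, n), pos = as.integer(pos),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   dp = rep_len(dp, n), mq = rep_len(mq, n),
                   func_class = rep_len(func_class, n)),
    tibble::as_tibble(gt))
}

# Allele-count tibble for one population from explicit m / n vectors.
toy_counts <- function(pos, m, n, chrom = "A01") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
                 m = as.integer(m), n = as.integer(n), p_hat = m / n)
}

# A window track from bare values on a fixed 20 kb / 10 kb grid.
toy_track <- function(values, chrom = "A01", window = 20000, step = 10000,
                      n_sites = 1L) {
  starts <- (seq_along(values) - 1L) * as.integer(step)
  structure(
    tibble::tibble(chrom = chrom, start = starts,
                   end = starts + as.integer(window),
                   value = values, n_sites = rep_len(n_sites, length(values))),
    window = window, step = step,
    class = c("window_track", class(tibble::tibble())))
}

toy_regions <- function(chrom, start, end, score = 1) {
  structure(
    tibble::tibble(chrom = chrom, start = as.integer(start),
                   end = as.integer(end),
                   region_score = rep_len(score, length(start)),
                   source = "toy"),
    class = c("region_set", class(tibble::tibble())))
}
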