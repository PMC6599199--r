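check_scalar <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max ||
      (integerish && x != round(x))) {
    abort(sprintf("invalid configuration: field `%s` must be a %snumber in [%s, %s]",
                  name, if (integerish) "whole " else "", format(min), format(max)),
          class = "polysweep_config_error")
  }
  invisible(x)
}

#' Build a sliding-window grid over one chromosome
#'
#' Windows are 0-based half-open `[start, start + window)`, placed every
#' `step` bp from 0; every window whose start lies inside the chromosome is
#' kept, so the final windows may extend past `chrom_length`.
#'
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp.
#' @param step Step between window starts in bp.
#' @return A tibble with columns `start`, `end`.
#' @export
sliding_windows <- function(chrom_length, window, step) {
  check_scalar(chrom_length, "chrom_length", min = 1)
  check_scalar(window, "window", min = 1)
  check_scalar(step, "step", min = 1)
  starts <- seq(0L, max(0L, as.integer(chrom_length) - 1L), by = as.integer(step))
  tibble(start = starts, end = starts + as.integer(window))
}

# Sum `values` at sorted integer `pos` over half-open windows, via cumulative
# sums: O(n + w) rather than per-window scans.
window_sums <- function(pos, values, starts, ends) {
  stopifnot(!is.unsorted(pos))
  cs <- c(0, cumsum(values))
  lo <- findInterval(starts - 1L, pos) + 1L   # first site with pos >= start
  hi <- findInterval(ends - 1L, pos)          # last site with pos < end
  n_sites <- pmax(hi - lo + 1L, 0L)
  sums <- ifelse(n_sites > 0L, cs[hi + 1L] - cs[lo], 0)
  list(sum = sums, n_sites = n_sites)
}

# Merge sorted half-open intervals that overlap or abut (end == next start).
merge_intervals <- function(df) {
  if (nrow(df) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  region_score = double()))
  }
  df <- dplyr::arrange(df, .data$chrom, .data$start)
  out <- df |>
    group_by(.data$chrom) |>
    mutate(new_region = cumsum(.data$start > dplyr::lag(cummax(as.double(.data$end)),
                                                        default = -Inf))) |>
    group_by(.data$chrom, .data$new_region) |>
    summarise(start = min(.data$start), end = max(.data$end),
              region_score = max(.data$value), .groups = "drop") |>
    select("chrom", "start", "end", "region_score") |>
    arrange(.data$chrom, .data$start)
  out
}

# Empirical quantile with "higher" interpolation: smallest order statistic at
# or above the n*p position. Ties at the returned threshold are meant to be
# included by callers (selection uses >=).
quantile_higher <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[min(n, max(1L, as.integer(ceiling(n * p))))]
}

# Deterministic child seeds below 2^31, derived from a user seed and a tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}
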