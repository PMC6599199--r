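#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a drift model
#' @param x A `drift_model`.
#' @param ... Ignored.
#' @return One-row tibble with `term`, `estimate`.
#' @method tidy drift_model
#' @export
tidy.drift_model <- function(x, ...) {
  tibble(term = "omega", estimate = x$omega)
}

#' Summarize a drift model
#' @param x A `drift_model`.
#' @param ... Ignored.
#' @return One-row tibble with `omega`, `n_sites`.
#' @method glance drift_model
#' @export
glance.drift_model <- function(x, ...) {
  tibble(omega = x$omega, n_sites = x$n_sites)
}

#' Tidy a sweep scan
#' @param x An `xpclr_scan`.
#' @param ... Ignored.
#' @return The scan as a plain tibble.
#' @method tidy xpclr_scan
#' @export
tidy.xpclr_scan <- function(x, ...) {
  as_tibble(x)
}

#' Summarize a sweep scan
#' @param x An `xpclr_scan`.
#' @param ... Ignored.
#' @return One-row tibble: grid points, scored points, peak position and
#'   score, drift scale used.
#' @method glance xpclr_scan
#' @export
glance.xpclr_scan <- function(x, ...) {
  scored <- x[!is.na(x$score), ]
  has_peak <- nrow(scored) > 0
  peak <- if (has_peak) scored[which.max(scored$score), ] else NULL
  tibble(n_grid = nrow(x), n_scored = nrow(scored),
         peak_chrom = if (has_peak) peak$chrom else NA_character_,
         peak_pos = if (has_peak) peak$pos else NA_integer_,
         peak_score = if (has_peak) peak$score else NA_real_,
         omega = attr(x, "omega"))
}

#' Tidy a DEG table
#' @param x A `deg_table`.
#' @param ... Ignored.
#' @return The table as a plain tibble.
#' @method tidy deg_table
#' @export
tidy.deg_table <- function(x, ...) {
  as_tibble(x)
}

#' Summarize a DEG table
#' @param x A `deg_table`.
#' @param ... Ignored.
#' @return One-row tibble with the comparison and up/down/ns counts.
#' @method glance deg_table
#' @export
glance.deg_table <- function(x, ...) {
  tibble(ref_cluster = attr(x, "ref_cluster"),
         other_cluster = attr(x, "other_cluster"),
         n_up = sum(x$call == "up"), n_down = sum(x$call == "down"),
         n_deg = sum(x$call != "ns"), n_genes = nrow(x))
}
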