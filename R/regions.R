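#' Windowed mean of a sweep-score track
#'
#' Averages grid-point scores in sliding windows (default 20 kb windows,
#' 10 kb step); windows containing no scored grid points are missing.
#'
#' @param scan An [xpclr_scan()] result (tibble with `chrom`, `pos`,
#'   `score`).
#' @param window,step Window size and step in bp.
#' @param chrom_lengths Optional named chromosome lengths.
#' @return A window track of mean scores.
#' @export
mean_score_track <- function(scan, window = 20000, step = 10000,
                             chrom_lengths = NULL) {
  df <- scan |>
    filter(!is.na(.data$score)) |>
    select(chrom = "chrom", pos = "pos", score = "score")
  track_by_chrom(df, value_col = "score", window = window, step = step,
                 chrom_lengths = chrom_lengths, normalize = "mean")
}

# Select windows at or above the (1 - q) empirical quantile (ties included)
# and merge overlapping or abutting survivors into regions.
select_and_merge <- function(track, q) {
  vals <- track$value[!is.na(track$value)]
  if (length(vals) == 0L) {
    return(merge_intervals(tibble(chrom = character(), start = integer(),
                                  end = integer(), value = double())))
  }
  thr <- quantile_higher(vals, 1 - q)
  sel <- track |> filter(!is.na(.data$value), .data$value >= thr)
  merge_intervals(sel)
}

#' Call candidate sweep regions from a mean-score track
#'
#' Two-stage percentile rule: windows in the top `window_q` fraction of
#' scores (ties at the threshold included) are selected and
#' overlapping/abutting survivors merged into regions, each scored by its
#' highest constituent window; regions whose score falls in the top
#' `region_q` fraction of region scores are returned. Quantiles are
#' empirical with "higher" interpolation and computed genome-wide (all
#' chromosomes pooled). Windows separated by an unselected or missing
#' window do not merge.
#'
#' @param track A window track of mean sweep scores.
#' @param window_q Fraction of windows selected (default top 20%).
#' @param region_q Fraction of merged regions kept by region score
#'   (default top 5%).
#' @return A `region_set` tibble: `chrom`, `start`, `end`, `region_score`,
#'   `source`.
#' @export
call_score_regions <- function(track, window_q = 0.20, region_q = 0.05) {
  regions <- select_and_merge(track, window_q)
  if (nrow(regions) > 0L) {
    thr <- quantile_higher(regions$region_score, 1 - region_q)
    regions <- regions |> filter(.data$region_score >= thr)
  }
  as_region_set(regions, source = "score")
}

#' Call regions from a diversity-ratio track
#'
#' Single-stage variant of [call_score_regions()]: windows in the top
#' `ratio_q` fraction of the ratio are selected and merged; there is no
#' region-score stage.
#'
#' @param track A window track of diversity ratios ([pi_ratio_track()]).
#' @param ratio_q Fraction of windows selected (default top 50%).
#' @return A `region_set` tibble.
#' @export
call_ratio_regions <- function(track, ratio_q = 0.50) {
  as_region_set(select_and_merge(track, ratio_q), source = "ratio")
}

as_region_set <- function(df, source) {
  out <- df |>
    mutate(source = source) |>
    arrange(.data$chrom, .data$start)
  structure(out, class = c("region_set", class(out)))
}

#' Intersect two region sets
#'
#' Base-pair-level intersection of half-open intervals; the result carries
#' the score of the region in `a` that produced each piece.
#'
#' @param a,b `region_set` tibbles (sorted, non-overlapping within a set).
#' @return A `region_set` of the intersections (empty when disjoint).
#' @seealso [overlap_fraction()] for the share of `a` recovered by `b`.
#' @export
intersect_regions <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(as_region_set(tibble(chrom = character(), start = integer(),
                                end = integer(), region_score = double()),
                         source = "intersection"))
  }
  pieces <- inner_join(
    a |> select("chrom", a_start = "start", a_end = "end",
                region_score = "region_score"),
    b |> select("chrom", b_start = "start", b_end = "end"),
    by = "chrom", relationship = "many-to-many") |>
    mutate(start = pmax(.data$a_start, .data$b_start),
           end = pmin(.data$a_end, .data$b_end)) |>
    filter(.data$end > .data$start) |>
    select("chrom", "start", "end", "region_score")
  as_region_set(pieces, source = "intersection")
}

#' Fraction of regions in `a` recovered by `b`
#'
#' Share of regions in `a` that overlap (by at least 1 bp) at least one
#' region in `b`.
#'
#' @param a,b `region_set` tibbles.
#' @return A single number in `[0, 1]` (`NaN` when `a` is empty).
#' @export
overlap_fraction <- function(a, b) {
  if (nrow(a) == 0L) return(NaN)
  if (nrow(b) == 0L) return(0)
  hits <- inner_join(
    a |> mutate(.region = row_number()) |>
      select(".region", "chrom", a_start = "start", a_end = "end"),
    b |> select("chrom", b_start = "start", b_end = "end"),
    by = "chrom", relationship = "many-to-many") |>
    filter(pmax(.data$a_start, .data$b_start) <
             pmin(.data$a_end, .data$b_end))
  dplyr::n_distinct(hits$.region) / nrow(a)
}

#' Genes overlapping candidate regions
#'
#' A gene is reported for a region iff its interval overlaps the region by
#' at least 1 bp (half-open arithmetic: a gene starting exactly at a
#' region's end does not overlap).
#'
#' @param regions A `region_set`.
#' @param annotation Gene annotation tibble with `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open, same coordinate system).
#' @return List with `by_region` (tibble: region coordinates plus
#'   `gene_id`, one row per region-gene pair) and `genes` (deduplicated
#'   genome-wide gene_id vector).
#' @export
genes_in_regions <- function(regions, annotation) {
  if (nrow(regions) == 0L) {
    return(list(by_region = tibble(chrom = character(), start = integer(),
                                   end = integer(), gene_id = character()),
                genes = character()))
  }
  hits <- inner_join(
    regions |> select("chrom", "start", "end"),
    annotation |> select("chrom", "gene_id", g_start = "start",
                         g_end = "end"),
    by = "chrom", relationship = "many-to-many") |>
    filter(pmax(.data$start, .data$g_start) <
             pmin(.data$end, .data$g_end)) |>
    select("chrom", "start", "end", "gene_id") |>
    arrange(.data$chrom, .data$start, .data$gene_id)
  list(by_region = hits, genes = sort(unique(hits$gene_id)))
}
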