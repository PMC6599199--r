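# Independent brute-force oracles. These deliberately use plain loops and a
# different code path from the package implementations they check.

# Windowed diversity: loop over windows, loop over sites.
oracle_windowed_pi <- function(counts, window, step, chrom_length) {
  starts <- seq(0L, chrom_length - 1L, by = step)
  val <- numeric(length(starts))
  ns <- integer(length(starts))
  for (i in seq_along(starts)) {
    s <- 0
    k <- 0L
    for (j in seq_len(nrow(counts))) {
      if (counts$pos[j] >= starts[i] && counts$pos[j] < starts[i] + window &&
          counts$n[j] >= 2) {
        m <- counts$m[j]; n <- counts$n[j]
        s <- s + 2 * m * (n - m) / (n * (n - 1))
        k <- k + 1L
      }
    }
    val[i] <- s / window
    ns[i] <- k
  }
  list(start = starts, value = val, n_sites = ns)
}

# Weir-Cockerham (1984) per-site components from diploid dosage vectors,
# scalar arithmetic.
oracle_wc_site <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n_i <- c(length(g1), length(g2))
  p_i <- c(sum(g1) / (2 * n_i[1]), sum(g2) / (2 * n_i[2]))
  h_i <- c(sum(g1 == 1) / n_i[1], sum(g2 == 1) / n_i[2])
  r <- 2
  nbar <- sum(n_i) / r
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c(a = a, b = b, c = hbar / 2)
}

# Percentile selection + scan-merge of selected windows, loop based.
oracle_select_merge <- function(track, q) {
  v <- track$value[!is.na(track$value)]
  k <- max(1L, as.integer(ceiling(length(v) * (1 - q))))
  thr <- sort(v)[k]
  sel <- track[!is.na(track$value) & track$value >= thr, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start), , drop = FALSE]
  out <- NULL
  cur <- NULL
  for (i in seq_len(nrow(sel))) {
    row <- sel[i, ]
    if (is.null(cur) || row$chrom != cur$chrom || row$start > cur$end) {
      out <- rbind(out, cur)
      cur <- data.frame(chrom = row$chrom, start = row$start, end = row$end,
                        region_score = row$value)
    } else {
      cur$end <- max(cur$end, row$end)
      cur$region_score <- max(cur$region_score, row$value)
    }
  }
  out <- rbind(out, cur)
  out[order(out$chrom, out$start), , drop = FALSE]
}

oracle_two_stage_regions <- function(track, window_q, region_q) {
  regions <- oracle_select_merge(track, window_q)
  k <- max(1L, as.integer(ceiling(nrow(regions) * (1 - region_q))))
  thr <- sort(regions$region_score)[k]
  regions[regions$region_score >= thr, , drop = FALSE]
}

# Pairwise interval intersection by double loop.
oracle_intersect <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j]) {
        s <- max(a$start[i], b$start[j])
        e <- min(a$end[i], b$end[j])
        if (e > s) out <- rbind(out, data.frame(chrom = a$chrom[i],
                                                start = s, end = e))
      }
    }
  }
  out
}

# Venn partition by set algebra on per-table DEG id sets.
oracle_venn <- function(id_sets) {
  union_ids <- sort(unique(unlist(id_sets)))
  pattern <- vapply(union_ids, function(g) {
    paste(sort(names(id_sets)[vapply(id_sets, function(s) g %in% s, TRUE)]),
          collapse = ",")
  }, "")
  table(pattern)
}

# Local clustering by exhaustive triple enumeration on an edge list.
oracle_clustering <- function(nodes, edges) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$from[i], edges$to[i]] <- TRUE
    adj[edges$to[i], edges$from[i]] <- TRUE
  }
  vapply(nodes, function(v) {
    nb <- nodes[adj[v, ]]
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0L
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (adj[nb[i], nb[j]]) tri <- tri + 1L
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# Mean of grid-point scores per window, loop based.
oracle_mean_track <- function(pos, score, window, step, chrom_length) {
  starts <- seq(0L, chrom_length - 1L, by = step)
  vapply(starts, function(s) {
    inside <- pos >= s & pos < s + window & !is.na(score)
    if (!any(inside)) NA_real_ else mean(score[inside])
  }, numeric(1))
}
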