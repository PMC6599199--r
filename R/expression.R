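#' Call differentially expressed genes between two clusters
#'
#' All accessions of a cluster are treated as replicates. The fold change is
#' `log2((mean FPKM_other + delta) / (mean FPKM_ref + delta))` on raw means
#' with pseudocount `delta`; the p-value comes from a Welch (unequal
#' variance) two-sample t-test on `log2(FPKM + delta)`. A gene is called
#' `up`/`down` iff `|log2_ratio| > lfc` (strictly) and `p < alpha`
#' (strictly); otherwise `ns`. Optionally Benjamini-Hochberg-adjusted
#' p-values replace raw ones (off by default; the thresholding convention
#' here is a raw per-gene p-value).
#'
#' @param expr Expression input: either an `expr_sim` from
#'   [simulate_expression()], or a list/object with `fpkm` (genes x
#'   accessions matrix) and `samples` (tibble `accession`, `cluster`).
#' @param ref_cluster,other_cluster Cluster labels to compare (`other` over
#'   `ref`).
#' @param lfc Strict absolute log2 fold-change threshold.
#' @param alpha Strict p-value threshold.
#' @param delta Pseudocount added to FPKM.
#' @param adjust Apply Benjamini-Hochberg correction to the p-values.
#' @return A `deg_table` tibble: `gene_id`, `log2_ratio`, `p_value`,
#'   `call` in `{"up", "down", "ns"}`, with attributes recording the
#'   comparison.
#' @export
call_degs <- function(expr, ref_cluster, other_cluster, lfc = 1.0,
                      alpha = 0.05, delta = 1, adjust = FALSE) {
  fpkm <- expr$fpkm
  samples <- expr$samples
  for (cl in c(ref_cluster, other_cluster)) {
    if (!cl %in% samples$cluster) {
      abort(sprintf("cluster `%s` not present in samples", cl))
    }
  }
  acc_ref <- samples$accession[samples$cluster == ref_cluster]
  acc_oth <- samples$accession[samples$cluster == other_cluster]
  if (length(acc_ref) < 2 || length(acc_oth) < 2) {
    abort("each cluster needs at least two accessions")
  }
  x_ref <- fpkm[, acc_ref, drop = FALSE]
  x_oth <- fpkm[, acc_oth, drop = FALSE]
  log2_ratio <- unname(log2((rowMeans(x_oth) + delta) /
                              (rowMeans(x_ref) + delta)))
  p_value <- welch_p(log2(x_oth + delta), log2(x_ref + delta))
  if (adjust) p_value <- stats::p.adjust(p_value, method = "BH")
  call <- ifelse(abs(log2_ratio) > lfc & p_value < alpha,
                 ifelse(log2_ratio > 0, "up", "down"), "ns")
  out <- tibble(gene_id = rownames(fpkm), log2_ratio = log2_ratio,
                p_value = p_value, call = call)
  structure(out, ref_cluster = ref_cluster, other_cluster = other_cluster,
            lfc = lfc, alpha = alpha,
            class = c("deg_table", class(out)))
}

# Row-wise Welch t-test p-values; genes with zero variance in both groups
# get p = 1 when the means agree and p = 0 when they differ.
welch_p <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t_stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t_stat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(mx[degenerate] == my[degenerate], 1, 0)
  unname(p)
}

#' Venn partition and unique counts across DEG tables
#'
#' Partitions the union of differentially expressed genes by the exact set
#' of comparisons in which each gene is called; a gene is "unique" to a
#' cluster iff it is called in exactly that one comparison. Partition
#' counts sum to the size of the union.
#'
#' @param deg_tables Named list of `deg_table`s sharing one gene universe
#'   (one table per non-reference cluster).
#' @return List with `genes` (tibble `gene_id`, `clusters`
#'   comma-separated, `n_clusters`), `partition` (tibble `clusters`,
#'   `n_genes`), and `unique_counts` (tibble `cluster`, `n_unique`).
#' @export
unique_degs <- function(deg_tables) {
  stopifnot(is.list(deg_tables), length(deg_tables) >= 1,
            !is.null(names(deg_tables)))
  universe <- deg_tables[[1]]$gene_id
  for (t in deg_tables) {
    if (!identical(sort(t$gene_id), sort(universe))) {
      abort("unique_degs: DEG tables do not share a gene universe")
    }
  }
  calls <- purrr::imap(deg_tables, function(t, nm) {
    t |> filter(.data$call != "ns") |>
      mutate(cluster = nm) |> select("gene_id", "cluster")
  }) |> bind_rows()
  genes <- calls |>
    group_by(.data$gene_id) |>
    summarise(clusters = paste(sort(.data$cluster), collapse = ","),
              n_clusters = n(), .groups = "drop")
  partition <- genes |>
    dplyr::count(.data$clusters, name = "n_genes") |>
    arrange(dplyr::desc(.data$n_genes))
  unique_counts <- tibble(cluster = names(deg_tables)) |>
    left_join(genes |> filter(.data$n_clusters == 1) |>
                dplyr::count(.data$clusters, name = "n_unique"),
              by = c(cluster = "clusters")) |>
    mutate(n_unique = dplyr::coalesce(.data$n_unique, 0L))
  list(genes = genes, partition = partition, unique_counts = unique_counts)
}

#' Sub-genome asymmetry test for differential expression
#'
#' Tests whether differentially expressed genes split between the A and C
#' sub-genomes in proportion to the tested genes on each: a Pearson
#' chi-square goodness-of-fit test (1 df, no continuity correction) of the
#' observed (DEG_A, DEG_C) counts against expected proportions equal to
#' the per-sub-genome shares of tested genes.
#'
#' @param deg_table A `deg_table`.
#' @param gene_info Tibble with `gene_id`, `subgenome` ("A"/"C").
#' @return A one-row tibble: `deg_a`, `deg_c`, `ratio_a_c`, `expected_a`,
#'   `expected_c`, `statistic`, `p_value`.
#' @export
subgenome_deg_test <- function(deg_table, gene_info) {
  d <- deg_table |>
    inner_join(gene_info |> select("gene_id", "subgenome"), by = "gene_id") |>
    filter(.data$subgenome %in% c("A", "C"))
  tested <- table(factor(d$subgenome, levels = c("A", "C")))
  if (any(tested == 0)) {
    abort("subgenome_deg_test: both sub-genomes need at least one tested gene")
  }
  deg <- table(factor(d$subgenome[d$call != "ns"], levels = c("A", "C")))
  total <- sum(deg)
  expected <- as.numeric(tested) / sum(tested) * total
  if (any(expected == 0)) abort("subgenome_deg_test: zero expected count")
  stat <- sum((as.numeric(deg) - expected)^2 / expected)
  tibble(deg_a = as.integer(deg[["A"]]), deg_c = as.integer(deg[["C"]]),
         ratio_a_c = deg[["A"]] / deg[["C"]],
         expected_a = expected[1], expected_c = expected[2],
         statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Pooled expression fold change per metabolic-network node
#'
#' For each reaction node, over the called DEGs whose ortholog ID belongs
#' to the node, the fold change is `log2` of the ratio of summed FPKM in
#' the object cluster's accessions over the summed FPKM in the reference
#' cluster's. Nodes with no DEG-mapped genes are grey ("no data"); a zero
#' denominator with a nonzero numerator is flagged infinite and colored
#' red.
#'
#' @param expr Expression input (see [call_degs()]).
#' @param network Network list with `nodes` (tibble `node_id`) and
#'   `members` (tibble `node_id`, `ortholog_id`).
#' @param annotation Gene annotation tibble with `gene_id`, `ortholog_id`.
#' @param deg_table `deg_table` for the comparison.
#' @param ref_cluster,other_cluster Cluster labels (as in the DEG call).
#' @return Tibble: `node_id`, `n_genes`, `fold_change`, `color`
#'   (`red`/`blue`/`white`/`grey`), `flag`.
#' @export
node_fold_change <- function(expr, network, annotation, deg_table,
                             ref_cluster, other_cluster) {
  fpkm <- expr$fpkm
  samples <- expr$samples
  acc_ref <- samples$accession[samples$cluster == ref_cluster]
  acc_oth <- samples$accession[samples$cluster == other_cluster]
  deg_genes <- deg_table$gene_id[deg_table$call != "ns"]
  node_genes <- network$members |>
    inner_join(annotation |>
                 filter(!is.na(.data$ortholog_id)) |>
                 select("gene_id", "ortholog_id"),
               by = "ortholog_id", relationship = "many-to-many") |>
    filter(.data$gene_id %in% deg_genes, .data$gene_id %in% rownames(fpkm))
  per_node <- network$nodes |>
    left_join(node_genes |>
                group_by(.data$node_id) |>
                summarise(genes = list(unique(.data$gene_id)),
                          .groups = "drop"),
              by = "node_id")
  rows <- purrr::pmap(per_node, function(node_id, genes) {
    if (is.null(genes) || length(genes) == 0L) {
      return(tibble(node_id = node_id, n_genes = 0L,
                    fold_change = NA_real_, color = "grey", flag = "no data"))
    }
    num <- sum(fpkm[genes, acc_oth, drop = FALSE])
    den <- sum(fpkm[genes, acc_ref, drop = FALSE])
    fc <- log2(num / den)
    flag <- if (den == 0 && num > 0) "infinite" else ""
    color <- if (is.nan(fc)) "grey" else if (fc > 0) "red" else
      if (fc < 0) "blue" else "white"
    tibble(node_id = node_id, n_genes = length(genes), fold_change = fc,
           color = color, flag = flag)
  })
  bind_rows(rows)
}

#' Local clustering coefficient of network nodes
#'
#' `2 T / (k (k - 1))` for a node of degree `k >= 2` with `T` triangles
#' through it; nodes of degree below 2 get 0.
#'
#' @param network Network list with `nodes` and `edges` (`from`, `to`), or
#'   an `igraph` object.
#' @return Tibble: `node_id`, `degree`, `clustering`.
#' @export
local_clustering <- function(network) {
  g <- if (inherits(network, "igraph")) network else
    igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                  vertices = network$nodes)
  cc <- unname(igraph::transitivity(g, type = "local", isolates = "zero"))
  deg <- unname(igraph::degree(g))
  cc[deg < 2] <- 0
  tibble(node_id = igraph::V(g)$name, degree = as.integer(deg),
         clustering = cc)
}
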