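#' Configuration for the FPKM expression simulator
#'
#' Generates log-normal FPKM matrices over a set of genetic clusters with a
#' known differentially expressed gene set. Gene baselines are drawn once as
#' `mu_g ~ Normal(baseline_log2, baseline_sd)` on the log2 scale; within a
#' cluster, `log2(FPKM) ~ Normal(mu_g + s * effect_log2 * 1{DE}, noise_sd^2)`
#' with a random sign `s` per differentially expressed (gene, cluster) pair.
#' The first cluster is the reference and carries no DE genes.
#'
#' @param clusters Tibble or data frame with columns `name` and
#'   `n_accessions`; the first row is the reference cluster.
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes differentially expressed in each
#'   non-reference cluster.
#' @param effect_log2 True absolute log2 fold-change of DE genes.
#' @param noise_sd Standard deviation of log2 FPKM within a cluster.
#' @param subgenome_split Fraction of genes labelled with the A sub-genome.
#' @param baseline_log2,baseline_sd Mean and SD of the per-gene baseline
#'   log2 FPKM.
#' @param seed Integer seed.
#' @return A list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(clusters = tibble(name = c("WEAm", "S", "R"),
                                              n_accessions = c(20, 20, 20)),
                            n_genes = 2000, de_fraction = 0.1,
                            effect_log2 = 2, noise_sd = 0.5,
                            subgenome_split = 0.55,
                            baseline_log2 = 4, baseline_sd = 2, seed = 1) {
  clusters <- as_tibble(clusters)
  stopifnot(all(c("name", "n_accessions") %in% names(clusters)),
            nrow(clusters) >= 1)
  check_scalar(n_genes, "n_genes", min = 1, integerish = TRUE)
  check_scalar(de_fraction, "de_fraction", min = 0, max = 1)
  check_scalar(effect_log2, "effect_log2", min = 0)
  check_scalar(noise_sd, "noise_sd", min = 1e-12)
  check_scalar(subgenome_split, "subgenome_split", min = 0, max = 1)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(clusters = clusters, n_genes = as.integer(n_genes),
                 de_fraction = de_fraction, effect_log2 = effect_log2,
                 noise_sd = noise_sd, subgenome_split = subgenome_split,
                 baseline_log2 = baseline_log2, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate an FPKM expression matrix with known DE truth
#'
#' @param cfg An [expr_sim_config()].
#' @return A list of class `expr_sim` with `fpkm` (genes x accessions matrix,
#'   strictly positive), `samples` (tibble: `accession`, `cluster`), `genes`
#'   (tibble: `gene_id`, `subgenome`), and `truth` (tibble per gene and
#'   non-reference cluster: `gene_id`, `cluster`, `is_de`, `direction`).
#' @export
simulate_expression <- function(cfg) {
  if (!inherits(cfg, "expr_sim_config")) cfg <- do.call(expr_sim_config, cfg)
  set.seed(cfg$seed)
  gene_id <- sprintf("gene%05d", seq_len(cfg$n_genes))
  subgenome <- ifelse(runif(cfg$n_genes) < cfg$subgenome_split, "A", "C")
  mu <- rnorm(cfg$n_genes, cfg$baseline_log2, cfg$baseline_sd)

  ref_name <- cfg$clusters$name[1]
  samples <- cfg$clusters |>
    purrr::pmap(function(name, n_accessions) {
      tibble(accession = sprintf("%s_%02d", name, seq_len(n_accessions)),
             cluster = name)
    }) |>
    bind_rows()

  truth <- tidyr::expand_grid(gene_id = gene_id,
                              cluster = setdiff(cfg$clusters$name, ref_name)) |>
    mutate(is_de = FALSE, direction = 0L)
  fpkm <- matrix(0, nrow = cfg$n_genes, ncol = nrow(samples),
                 dimnames = list(gene_id, samples$accession))
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  for (cl in cfg$clusters$name) {
    shift <- rep(0, cfg$n_genes)
    if (cl != ref_name && n_de > 0) {
      idx <- sample.int(cfg$n_genes, n_de)
      sgn <- sample(c(-1L, 1L), n_de, replace = TRUE)
      shift[idx] <- sgn * cfg$effect_log2
      sel <- truth$cluster == cl & truth$gene_id %in% gene_id[idx]
      truth$is_de[sel] <- TRUE
      truth$direction[truth$cluster == cl][idx] <- sgn
    }
    acc <- samples$accession[samples$cluster == cl]
    log2_expr <- matrix(rnorm(cfg$n_genes * length(acc), mu + shift, cfg$noise_sd),
                        nrow = cfg$n_genes)
    fpkm[, acc] <- 2^log2_expr
  }
  structure(list(fpkm = fpkm, samples = samples,
                 genes = tibble(gene_id = gene_id, subgenome = subgenome),
                 truth = truth, cfg = cfg),
            class = "expr_sim")
}

#' Simulate a gene annotation, ortholog map, and metabolic network
#'
#' Places non-overlapping gene intervals on A- and C-sub-genome chromosomes,
#' maps genes to toy ortholog identifiers, assigns orthologs to reaction
#' nodes, and draws an undirected node graph.
#'
#' @param n_genes Number of genes.
#' @param chrom_lengths Named vector of chromosome lengths in bp; names
#'   beginning with "A"/"C" set the sub-genome. Default: two chromosomes.
#' @param subgenome_split Fraction of genes placed on A chromosomes.
#' @param n_nodes Number of reaction nodes in the network.
#' @param mean_genes_per_node Mean number of ortholog members per node
#'   (Poisson); 0 gives empty nodes, flagged "no data" downstream.
#' @param edge_prob Probability of an edge between two nodes.
#' @param ortholog_fraction Fraction of genes carrying an ortholog ID.
#' @param seed Integer seed.
#' @return A list of class `annot_sim` with `genes` (tibble: `gene_id`,
#'   `chrom`, `start`, `end`, `subgenome`, `ortholog_id` with `NA` for
#'   unmapped genes) and `network` (list: `nodes` tibble, `members` tibble
#'   of `node_id`/`ortholog_id`, `edges` tibble of `from`/`to`).
#' @export
simulate_annotation_network <- function(n_genes = 2000,
                                        chrom_lengths = c(A01 = 2e6, C01 = 2e6),
                                        subgenome_split = 0.55,
                                        n_nodes = 50, mean_genes_per_node = 3,
                                        edge_prob = 0.08,
                                        ortholog_fraction = 0.6, seed = 1) {
  check_scalar(n_genes, "n_genes", min = 1, integerish = TRUE)
  check_scalar(mean_genes_per_node, "mean_genes_per_node", min = 0)
  set.seed(seed)
  chroms <- names(chrom_lengths)
  subg <- substr(chroms, 1, 1)
  is_a <- subg == "A"
  n_a <- round(n_genes * subgenome_split)
  gene_chrom <- c(
    if (n_a > 0) sample(chroms[is_a], n_a, replace = TRUE,
                        prob = chrom_lengths[is_a] / sum(chrom_lengths[is_a])),
    if (n_genes - n_a > 0) sample(chroms[!is_a], n_genes - n_a, replace = TRUE,
                                  prob = chrom_lengths[!is_a] / sum(chrom_lengths[!is_a]))
  )
  genes <- purrr::map(sort(unique(gene_chrom)), function(ch) {
    k <- sum(gene_chrom == ch)
    iv <- place_intervals(k, chrom_lengths[[ch]])
    tibble(chrom = ch, start = iv$start, end = iv$end)
  }) |>
    bind_rows() |>
    arrange(.data$chrom, .data$start) |>
    mutate(gene_id = sprintf("gene%05d", row_number()),
           subgenome = substr(.data$chrom, 1, 1),
           ortholog_id = ifelse(runif(n()) < ortholog_fraction,
                                sprintf("AT%05d", sample.int(n_genes, n())),
                                NA_character_)) |>
    select("gene_id", "chrom", "start", "end", "subgenome", "ortholog_id")

  node_id <- sprintf("rxn%03d", seq_len(n_nodes))
  pool <- genes$ortholog_id[!is.na(genes$ortholog_id)]
  sizes <- stats::rpois(n_nodes, mean_genes_per_node)
  members <- purrr::map2(node_id, sizes, function(id, k) {
    if (k == 0 || length(pool) == 0) return(NULL)
    tibble(node_id = id,
           ortholog_id = sample(pool, min(k, length(pool))))
  }) |> bind_rows()
  if (nrow(members) == 0L) {
    members <- tibble(node_id = character(), ortholog_id = character())
  }
  pairs <- utils::combn(node_id, 2)
  keep <- runif(ncol(pairs)) < edge_prob
  edges <- tibble(from = pairs[1, keep], to = pairs[2, keep])
  structure(list(genes = genes,
                 network = list(nodes = tibble(node_id = node_id),
                                members = members, edges = edges)),
            class = "annot_sim")
}

# Non-overlapping half-open intervals: divide the chromosome into n slots and
# place a gene inside each slot.
place_intervals <- function(n, chrom_length) {
  slot <- floor(chrom_length / n)
  width <- max(1L, min(2000L, floor(slot / 2)))
  start <- as.integer((seq_len(n) - 1L) * slot +
                        floor(runif(n) * max(1, slot - width)))
  list(start = start, end = start + width)
}
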