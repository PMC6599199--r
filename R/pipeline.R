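#' Pipeline configuration
#'
#' Bundles every stage parameter with its default: the filter thresholds
#' (depth > 10, MQ > 30, MAF >= 0.05, call rate > 0.5), the diversity grid
#' (100 kb windows, 25 kb step), the sweep-track grid (20 kb windows, 10 kb
#' step), the scan parameters (0.005 Morgan windows, 100 SNPs, 2 kb grid,
#' r2 cutoff 0.7), the region percentiles (top 20% windows, top 5% regions,
#' top 50% ratio windows) and the DEG thresholds (|log2 ratio| > 1,
#' p < 0.05). Simulation settings live under `sim`, `sweep` and `expr`.
#'
#' @param out_dir Output directory for stage files and the manifest.
#' @param seed Global seed; stage seeds derive from it deterministically.
#' @param sim,sweep,expr Argument lists for [sim_config()],
#'   [sweep_spec()] (or `NULL` for no implanted sweep), and
#'   [expr_sim_config()].
#' @param ... Overrides for any default listed above (see
#'   [pipeline_defaults()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            sim = list(), sweep = list(position = 1e6, sigma = 0.02),
                            expr = list(), ...) {
  cfg <- utils::modifyList(pipeline_defaults(), list(...))
  cfg$out_dir <- out_dir
  cfg$seed <- as.integer(seed)
  cfg$sim <- sim
  cfg$sweep <- sweep
  cfg$expr <- expr
  structure(cfg, class = "pipeline_config")
}

#' Default stage parameters of [pipeline_config()]
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(min_depth = 10, min_mq = 30, min_call_rate = 0.5, min_maf = 0.05,
       classes = NULL,
       div_window = 100000, div_step = 25000,
       track_window = 20000, track_step = 10000,
       scan = list(window_morgans = 0.005, max_snps = 100, grid_bp = 2000,
                   r2_cutoff = 0.7),
       window_q = 0.20, region_q = 0.05, ratio_q = 0.50,
       lfc = 1.0, alpha = 0.05,
       ld_max_dist = 3e6, ld_bin = 10000)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

write_stage <- function(df, path) {
  readr::write_tsv(as_tibble(df), path)
  path
}

#' Run the full sweep-and-expression pipeline
#'
#' Simulates (or loads) the inputs, applies the SNP filter cascade, computes
#' diversity, F_ST and LD-decay statistics, runs the composite-likelihood
#' sweep scan with the diversity-ratio track, intersects their candidate
#' regions, calls differentially expressed genes per non-reference cluster,
#' and overlays them on the metabolic network. Every stage output is a TSV
#' under `config$out_dir`; the manifest lists file, producing stage, and
#' checksum. Reruns with the same config and seed reproduce identical
#' checksums.
#'
#' @param config A [pipeline_config()].
#' @return A list with `manifest` (tibble: `file`, `stage`, `md5`) and the
#'   in-memory stage results (`variants`, `tracks`, `scan`, `regions`,
#'   `degs`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  stage_file <- function(df, name, stage) {
    path <- file.path(config$out_dir, name)
    write_stage(df, path)
    files[[length(files) + 1]] <<- tibble(file = name, stage = stage)
    path
  }

  # -- simulate ---------------------------------------------------------
  sim_args <- utils::modifyList(list(seed = derive_seed(config$seed, "sim")),
                                config$sim)
  sim <- simulate_neutral_pair(do.call(sim_config, sim_args))
  if (!is.null(config$sweep)) {
    sim <- implant_sweep(sim, do.call(sweep_spec, config$sweep),
                         seed = derive_seed(config$seed, "sweep"))
  }
  variants <- sim_to_variants(sim, seed = derive_seed(config$seed, "meta"))
  groups <- sim_sample_groups(variants)
  stage_file(variants |> select(dplyr::all_of(.variant_meta_cols)),
             "sites.tsv", "simulate")
  stage_file(sim$map, "genetic_map.tsv", "simulate")
  vcf_path <- file.path(config$out_dir, "variants.vcf")
  write_vcf(variants, vcf_path)
  files[[length(files) + 1]] <- tibble(file = "variants.vcf",
                                       stage = "simulate")

  # -- filter -----------------------------------------------------------
  filtered <- filter_variants(variants, min_depth = config$min_depth,
                              min_mq = config$min_mq,
                              min_call_rate = config$min_call_rate,
                              min_maf = config$min_maf,
                              classes = config$classes)
  stage_file(attr(filtered, "filter_report"), "filter_report.tsv", "filter")
  counts <- allele_counts(filtered, groups)
  counts_ref <- counts |> filter(.data$group == "ref")
  counts_obj <- counts |> filter(.data$group == "obj")

  # -- diversity --------------------------------------------------------
  chrom_lengths <- setNames(sim$cfg$chrom_length, sim$cfg$chrom)
  pi_ref <- windowed_pi(counts_ref, config$div_window, config$div_step,
                        chrom_lengths)
  pi_obj <- windowed_pi(counts_obj, config$div_window, config$div_step,
                        chrom_lengths)
  fst <- windowed_fst(filtered, groups, config$div_window, config$div_step,
                      chrom_lengths)
  stage_file(pi_ref, "pi_ref.tsv", "diversity")
  stage_file(pi_obj, "pi_obj.tsv", "diversity")
  stage_file(fst, "fst.tsv", "diversity")
  keep_idx <- match(paste(filtered$chrom, filtered$pos),
                    paste(variants$chrom, variants$pos))
  hap_obj <- sim$hap_obj[, keep_idx, drop = FALSE]
  ld <- ld_decay(hap_obj, filtered$pos, max_dist = config$ld_max_dist,
                 bin = config$ld_bin)
  stage_file(ld, "ld_decay.tsv", "diversity")

  # -- scan -------------------------------------------------------------
  model <- estimate_omega(counts_ref, counts_obj)
  scan <- xpclr_scan(counts_ref, counts_obj, hap_obj, sim$map,
                     do.call(scan_params, config$scan), model,
                     seed = derive_seed(config$seed, "scan"))
  stage_file(scan, "xpclr_scores.tsv", "scan")
  score_track <- mean_score_track(scan, config$track_window,
                                  config$track_step, chrom_lengths)
  pi_ref20 <- windowed_pi(counts_ref, config$track_window, config$track_step,
                          chrom_lengths)
  pi_obj20 <- windowed_pi(counts_obj, config$track_window, config$track_step,
                          chrom_lengths)
  ratio <- pi_ratio_track(pi_ref20, pi_obj20)
  stage_file(score_track, "score_track.tsv", "scan")
  stage_file(ratio, "pi_ratio_track.tsv", "scan")

  # -- regions ----------------------------------------------------------
  score_regions <- call_score_regions(score_track, config$window_q,
                                      config$region_q)
  ratio_regions <- call_ratio_regions(ratio, config$ratio_q)
  sweeps <- intersect_regions(score_regions, ratio_regions)
  ov <- overlap_fraction(score_regions, ratio_regions)
  stage_file(score_regions, "score_regions.tsv", "regions")
  stage_file(ratio_regions, "ratio_regions.tsv", "regions")
  stage_file(sweeps, "sweep_regions.tsv", "regions")

  # -- expression -------------------------------------------------------
  expr_args <- utils::modifyList(list(seed = derive_seed(config$seed, "expr")),
                                 config$expr)
  expr <- simulate_expression(do.call(expr_sim_config, expr_args))
  annot <- simulate_annotation_network(
    n_genes = expr$cfg$n_genes,
    subgenome_split = expr$cfg$subgenome_split,
    seed = derive_seed(config$seed, "annot"))
  ref_cl <- expr$cfg$clusters$name[1]
  other_cls <- setdiff(expr$cfg$clusters$name, ref_cl)
  degs <- purrr::map(other_cls, function(cl) {
    call_degs(expr, ref_cl, cl, lfc = config$lfc, alpha = config$alpha)
  }) |> setNames(other_cls)
  for (cl in other_cls) {
    stage_file(degs[[cl]], sprintf("degs_%s.tsv", cl), "expression")
  }
  venn <- unique_degs(degs)
  stage_file(venn$partition, "deg_partition.tsv", "expression")
  sg_tests <- purrr::map(degs, subgenome_deg_test,
                         gene_info = expr$genes) |>
    bind_rows(.id = "cluster")
  stage_file(sg_tests, "subgenome_tests.tsv", "expression")
  node_stats <- node_fold_change(expr, annot$network, annot$genes,
                                 degs[[other_cls[1]]], ref_cl, other_cls[1])
  node_stats <- node_stats |>
    left_join(local_clustering(annot$network), by = "node_id")
  stage_file(node_stats, "node_stats.tsv", "network")

  manifest <- bind_rows(files) |>
    mutate(md5 = unname(tools::md5sum(file.path(config$out_dir, .data$file))))
  write_stage(manifest, file.path(config$out_dir, "manifest.tsv"))
  list(manifest = manifest, sim = sim, variants = filtered, model = model,
       tracks = list(pi_ref = pi_ref, pi_obj = pi_obj, fst = fst, ld = ld,
                     score = score_track, ratio = ratio),
       scan = scan,
       regions = list(score = score_regions, ratio = ratio_regions,
                      sweeps = sweeps, overlap_fraction = ov),
       expr = expr, degs = degs, venn = venn, subgenome_tests = sg_tests,
       node_stats = node_stats)
}
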