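#' Convert a simulated population pair to a variant table
#'
#' Pairs consecutive haplotypes into diploid genotypes (emitted phased) and
#' attaches per-site depth, mapping quality, and functional-class metadata so
#' the filter cascade can be exercised on synthetic data.
#'
#' @param sim A `pop_sim` from [simulate_neutral_pair()].
#' @param mean_depth Mean of the per-site sequencing depth (Poisson).
#' @param mq_range Range of per-site mapping qualities (uniform).
#' @param class_probs Named probabilities for the functional classes
#'   `synonymous`, `noncoding`, `other`.
#' @param missing_rate Per-genotype missing probability.
#' @param seed Integer seed for the metadata and missingness draws.
#' @return A variant table: a tibble with per-site metadata columns `chrom`,
#'   `pos` (0-based), `ref`, `alt`, `dp`, `mq`, `func_class`, followed by one
#'   genotype column per sample (`"0|1"`, `"./."` style strings). Reference
#'   samples are named `ref_NN`, object samples `obj_NN`.
#' @export
sim_to_variants <- function(sim, mean_depth = 30, mq_range = c(20, 60),
                            class_probs = c(synonymous = 0.35,
                                            noncoding = 0.45, other = 0.2),
                            missing_rate = 0, seed = 1) {
  stopifnot(inherits(sim, "pop_sim"))
  set.seed(seed)
  n_snps <- length(sim$positions)
  haps <- cbind(t(sim$hap_ref), t(sim$hap_obj))  # site x haplotype
  n_dip <- ncol(haps) / 2
  a1 <- haps[, 2 * seq_len(n_dip) - 1, drop = FALSE]
  a2 <- haps[, 2 * seq_len(n_dip), drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), nrow = n_snps)
  if (missing_rate > 0) gt[runif(length(gt)) < missing_rate] <- ".|."
  samples <- c(sprintf("ref_%02d", seq_len(sim$cfg$n_ref / 2)),
               sprintf("obj_%02d", seq_len(sim$cfg$n_obj / 2)))
  colnames(gt) <- samples
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  out <- tibble(chrom = sim$cfg$chrom, pos = sim$positions,
                ref = ref, alt = unname(alt),
                dp = stats::rpois(n_snps, mean_depth),
                mq = round(runif(n_snps, mq_range[1], mq_range[2]), 1),
                func_class = sample(names(class_probs), n_snps,
                                    replace = TRUE, prob = class_probs))
  dplyr::bind_cols(out, as_tibble(gt))
}

#' Sample-to-population table for a simulated pair
#'
#' @param variants A variant table from [sim_to_variants()].
#' @return Tibble with `sample`, `group` (`"ref"`/`"obj"`).
#' @export
sim_sample_groups <- function(variants) {
  s <- variant_samples(variants)
  tibble(sample = s, group = ifelse(startsWith(s, "ref"), "ref", "obj"))
}

#' Write a variant table as VCF 4.2
#'
#' Site metadata goes to the INFO fields `DP`, `MQ`, and `FC` (functional
#' class); genotypes are written as-is (phased `|` preserved). Internal
#' 0-based positions become 1-based VCF coordinates.
#'
#' @param variants A variant table.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  samples <- variant_samples(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=polysweep",
    '##INFO=<ID=DP,Number=1,Type=Float,Description="Mapping depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##INFO=<ID=FC,Number=1,Type=String,Description="Functional class">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  info <- sprintf("DP=%s;MQ=%s;FC=%s", format(variants$dp, trim = TRUE),
                  format(variants$mq, trim = TRUE), variants$func_class)
  body <- cbind(variants$chrom, variants$pos + 1L, ".", variants$ref,
                variants$alt, ".", "PASS", info, "GT",
                as.matrix(variants[samples]))
  lines <- c(header, apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Multi-allelic and non-SNP records are dropped (with a message giving the
#' count); `DP`, `MQ`, `FC` are taken from INFO; coordinates are converted
#' to 0-based. Genotype strings keep only the GT field.
#'
#' @param path Path to a VCF 4.x file.
#' @return A variant table (see [sim_to_variants()] for the layout).
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE, convertNA = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  gt <- vcf@gt
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0) {
    message(sprintf("read_vcf: dropped %d multi-allelic or non-SNP record(s)",
                    n_drop))
  }
  keep <- which(is_snp)
  info <- fix$INFO[keep]
  grab <- function(key, as_num = TRUE) {
    m <- regexpr(paste0("(^|;)", key, "=[^;]*"), info)
    v <- rep(NA_character_, length(info))
    hit <- m > 0
    v[hit] <- sub(paste0("^;?", key, "="), "", regmatches(info, m))
    if (as_num) suppressWarnings(as.numeric(v)) else v
  }
  out <- tibble(chrom = fix$CHROM[keep],
                pos = as.integer(fix$POS[keep]) - 1L,
                ref = fix$REF[keep], alt = fix$ALT[keep],
                dp = grab("DP"), mq = grab("MQ"),
                func_class = grab("FC", as_num = FALSE))
  sample_gt <- gt[keep, -1, drop = FALSE]
  sample_gt[] <- sub(":.*$", "", sample_gt)
  out <- dplyr::bind_cols(out, as_tibble(sample_gt))
  arrange(out, .data$chrom, .data$pos)
}

#' Apply the SNP filter cascade
#'
#' Retains sites with depth strictly greater than `min_depth`, mapping
#' quality strictly greater than `min_mq`, genotype call rate strictly
#' greater than `min_call_rate`, minor allele frequency (pooled across all
#' samples, missing genotypes excluded) at least `min_maf`, and functional
#' class in `classes`. Set `classes = NULL` to skip the class filter, which
#' together with `min_call_rate = 0.5` mirrors the permissive diversity
#' panel; `min_call_rate = 0.9` with the synonymous/noncoding class filter
#' mirrors the stricter structure panel.
#'
#' @param variants A variant table.
#' @param min_depth,min_mq Strict lower bounds on `dp` and `mq`.
#' @param min_call_rate Strict lower bound on the fraction of non-missing
#'   genotypes.
#' @param min_maf Inclusive lower bound on minor allele frequency.
#' @param classes Functional classes to keep, or `NULL` for all.
#' @return The filtered variant table, with a `filter_report` attribute
#'   (tibble: rule, sites removed).
#' @export
filter_variants <- function(variants, min_depth = 10, min_mq = 30,
                            min_call_rate = 0.5, min_maf = 0.05,
                            classes = c("synonymous", "noncoding")) {
  al <- gt_alleles(variants)
  n_called <- rowSums(!is.na(al$a1)) + rowSums(!is.na(al$a2))
  m <- rowSums(al$a1, na.rm = TRUE) + rowSums(al$a2, na.rm = TRUE)
  p <- ifelse(n_called > 0, m / n_called, NA_real_)
  maf <- pmin(p, 1 - p)
  call_rate <- n_called / (2 * length(variant_samples(variants)))

  pass_depth <- variants$dp > min_depth
  pass_mq <- variants$mq > min_mq
  pass_call <- call_rate > min_call_rate
  pass_maf <- !is.na(maf) & maf >= min_maf
  pass_class <- if (is.null(classes)) rep(TRUE, nrow(variants)) else
    variants$func_class %in% classes
  keep <- pass_depth & pass_mq & pass_call & pass_maf & pass_class
  report <- tibble(
    rule = c(sprintf("depth > %s", min_depth), sprintf("mq > %s", min_mq),
             sprintf("call rate > %s", min_call_rate),
             sprintf("MAF >= %s", min_maf),
             if (is.null(classes)) "class filter skipped" else
               sprintf("class in {%s}", paste(classes, collapse = ", "))),
    removed = c(sum(!pass_depth), sum(!pass_mq), sum(!pass_call),
                sum(!pass_maf), sum(!pass_class)))
  out <- variants[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Partition a variant table by sub-genome
#'
#' Chromosome names beginning with "A" go to the A sub-genome, "C" to the C
#' sub-genome, anything else to "unassigned". The partition is disjoint and
#' conserves the site count.
#'
#' @param variants A variant table.
#' @return Named list of variant tables: `A`, `C`, `unassigned`.
#' @export
partition_subgenome <- function(variants) {
  first <- substr(variants$chrom, 1, 1)
  list(A = variants[first == "A", , drop = FALSE],
       C = variants[first == "C", , drop = FALSE],
       unassigned = variants[!first %in% c("A", "C"), , drop = FALSE])
}

# Parse genotype strings once into two allele matrices (site x sample),
# NA for missing. Assumes biallelic "a/b" or "a|b" with single-digit alleles.
gt_alleles <- function(variants) {
  samples <- variant_samples(variants)
  gt <- as.matrix(variants[samples])
  a1 <- match(substr(gt, 1, 1), c("0", "1")) - 1L
  a2 <- match(substr(gt, 3, 3), c("0", "1")) - 1L
  dim(a1) <- dim(gt); dim(a2) <- dim(gt)
  colnames(a1) <- colnames(a2) <- samples
  list(a1 = a1, a2 = a2)
}

#' Per-site, per-population genotype and allele counts
#'
#' @param variants A variant table.
#' @param sample_groups Tibble with `sample`, `group`; groups must be
#'   disjoint subsets of the table's samples.
#' @return A tibble with one row per site and group: `chrom`, `pos`,
#'   `group`, `m` (alt-allele count), `n` (non-missing chromosomes),
#'   `p_hat = m/n` (`NA` when `n = 0`), `n_ind` (non-missing diploid
#'   genotypes), and `n_het` (heterozygous genotypes).
#' @export
genotype_counts <- function(variants, sample_groups) {
  stopifnot(all(c("sample", "group") %in% names(sample_groups)))
  if (anyDuplicated(sample_groups$sample)) {
    abort("sample_groups assigns a sample to more than one group")
  }
  missing_s <- setdiff(sample_groups$sample, variant_samples(variants))
  if (length(missing_s) > 0) {
    abort(sprintf("samples not in variant table: %s",
                  paste(missing_s, collapse = ", ")))
  }
  al <- gt_alleles(variants)
  purrr::map(split(sample_groups$sample, sample_groups$group), function(s) {
    a1 <- al$a1[, s, drop = FALSE]
    a2 <- al$a2[, s, drop = FALSE]
    ok <- !is.na(a1) & !is.na(a2)
    n_ind <- rowSums(ok)
    m <- rowSums(a1 * ok, na.rm = TRUE) + rowSums(a2 * ok, na.rm = TRUE)
    n <- 2L * n_ind
    tibble(chrom = variants$chrom, pos = variants$pos,
           m = as.integer(m), n = as.integer(n),
           p_hat = ifelse(n > 0, m / n, NA_real_),
           n_ind = as.integer(n_ind),
           n_het = as.integer(rowSums((a1 != a2) & ok, na.rm = TRUE)))
  }) |>
    bind_rows(.id = "group") |>
    select("chrom", "pos", "group", "m", "n", "p_hat", "n_ind", "n_het") |>
    arrange(.data$group, .data$chrom, .data$pos)
}

#' Per-site allele counts by population
#'
#' Convenience wrapper around [genotype_counts()] returning only the
#' allele-count columns used by the diversity and scan statistics.
#'
#' @inheritParams genotype_counts
#' @return Tibble: `chrom`, `pos`, `group`, `m`, `n`, `p_hat`.
#' @export
allele_counts <- function(variants, sample_groups) {
  genotype_counts(variants, sample_groups) |>
    select("chrom", "pos", "group", "m", "n", "p_hat")
}
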