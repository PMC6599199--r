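two_cluster_expr <- function(fpkm_ref, fpkm_oth) {
  n_ref <- ncol(fpkm_ref); n_oth <- ncol(fpkm_oth)
  fpkm <- cbind(fpkm_ref, fpkm_oth)
  rownames(fpkm) <- sprintf("g%03d", seq_len(nrow(fpkm)))
  colnames(fpkm) <- c(sprintf("ref_%02d", seq_len(n_ref)),
                      sprintf("oth_%02d", seq_len(n_oth)))
  list(fpkm = fpkm,
       samples = tibble::tibble(accession = colnames(fpkm),
                                cluster = rep(c("ref", "oth"),
                                              c(n_ref, n_oth))))
}

test_that("identical groups are not called; the fold threshold is strict", {
  x <- matrix(rep(c(2, 8, 32), 8), nrow = 3)
  expr <- two_cluster_expr(x, x)
  degs <- call_degs(expr, "ref", "oth")
  expect_true(all(degs$log2_ratio == 0))
  expect_true(all(degs$call == "ns"))

  # mean+delta ratio exactly 2 -> log2 ratio exactly 1 -> ns despite p ~ 0
  expr2 <- two_cluster_expr(matrix(1, 1, 6), matrix(3, 1, 6))
  degs2 <- call_degs(expr2, "ref", "oth")
  expect_equal(degs2$log2_ratio, 1)
  expect_identical(degs2$call, "ns")

  # just past the threshold is called
  expr3 <- two_cluster_expr(matrix(1, 1, 6), matrix(3.2, 1, 6))
  expect_identical(call_degs(expr3, "ref", "oth")$call, "up")

  expect_error(call_degs(expr2, "ref", "absent"), "absent")
})

test_that("DEG calls are antisymmetric under swapping the clusters", {
  set.seed(8)
  base <- matrix(2^rnorm(200 * 10, 4, 1), nrow = 200)
  shifted <- base * rep(sample(c(1, 4, 0.25), 200, replace = TRUE,
                               prob = c(0.7, 0.15, 0.15)), 10)
  expr <- two_cluster_expr(base, shifted)
  fwd <- call_degs(expr, "ref", "oth")
  rev <- call_degs(expr, "oth", "ref")
  expect_identical(fwd$call == "ns", rev$call == "ns")
  expect_identical(fwd$call == "up", rev$call == "down")
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-10)
})

test_that("Venn partition and unique counts match brute-force set algebra", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:150)
  mk_table <- function(de_ids) {
    structure(tibble::tibble(
      gene_id = genes, log2_ratio = ifelse(genes %in% de_ids, 2, 0),
      p_value = ifelse(genes %in% de_ids, 1e-4, 0.8),
      call = ifelse(genes %in% de_ids, "up", "ns")),
      class = c("deg_table", class(tibble::tibble())))
  }
  sets <- list(S = sample(genes, 40), R = sample(genes, 35),
               SK = sample(genes, 50))
  tables <- lapply(sets, mk_table)
  got <- unique_degs(tables)
  oracle <- oracle_venn(sets)
  for (pat in names(oracle)) {
    expect_identical(got$partition$n_genes[got$partition$clusters == pat],
                     as.integer(oracle[[pat]]))
  }
  expect_identical(sum(got$partition$n_genes),
                   length(unique(unlist(sets))))
  for (cl in names(sets)) {
    expected_unique <- length(setdiff(sets[[cl]],
                                      unlist(sets[names(sets) != cl])))
    expect_identical(
      got$unique_counts$n_unique[got$unique_counts$cluster == cl],
      expected_unique)
  }

  one <- unique_degs(tables["S"])
  expect_identical(one$unique_counts$n_unique, length(sets$S))
  same <- unique_degs(list(a = tables$S, b = tables$S))
  expect_identical(sum(same$unique_counts$n_unique), 0L)

  bad <- tables$S[-1, ]
  expect_error(unique_degs(list(a = tables$S, b = bad)), "universe")
})

test_that("sub-genome asymmetry test is a 1-df Pearson chi-square", {
  mk <- function(n_a, n_c, deg_a, deg_c) {
    genes <- tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(n_a + n_c)),
      subgenome = rep(c("A", "C"), c(n_a, n_c)))
    call <- rep("ns", n_a + n_c)
    call[seq_len(deg_a)] <- "up"
    call[n_a + seq_len(deg_c)] <- "down"
    degs <- structure(tibble::tibble(gene_id = genes$gene_id,
                                     log2_ratio = 0, p_value = 1,
                                     call = call),
                      class = c("deg_table", class(tibble::tibble())))
    subgenome_deg_test(degs, genes)
  }
  even <- mk(500, 500, 100, 100)
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  skewed <- mk(500, 500, 120, 80)
  expect_equal(skewed$statistic, 8)       # (20^2/100) * 2
  # chi-square(1) survival equals the two-sided normal tail of sqrt(x)
  expect_equal(skewed$p_value, 2 * pnorm(-sqrt(8)), tolerance = 1e-10)
  expect_equal(skewed$p_value, 0.004678, tolerance = 1e-4)
  expect_equal(skewed$ratio_a_c, 1.5)

  # p decreases as the imbalance grows at fixed totals
  ps <- vapply(seq(100, 180, by = 20),
               function(a) mk(500, 500, a, 200 - a)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("node fold change pools FPKM sums over DEG-mapped members", {
  expr <- two_cluster_expr(matrix(c(1, 1), 2, 4), matrix(c(4, 4), 2, 4))
  # both genes 4x up: sums 8 vs 2 per accession set scale -> log2 = 2
  annotation <- tibble::tibble(gene_id = c("g001", "g002"),
                               ortholog_id = c("AT1", "AT2"))
  network <- list(nodes = tibble::tibble(node_id = c("n1", "n2", "n3")),
                  members = tibble::tibble(node_id = c("n1", "n1", "n2"),
                                           ortholog_id = c("AT1", "AT2", "AT9")),
                  edges = tibble::tibble(from = "n1", to = "n2"))
  degs <- call_degs(expr, "ref", "oth")
  expect_true(all(degs$call == "up"))
  nf <- node_fold_change(expr, network, annotation, degs, "ref", "oth")
  expect_equal(nf$fold_change[nf$node_id == "n1"], 2)
  expect_identical(nf$color[nf$node_id == "n1"], "red")
  expect_identical(nf$color[nf$node_id == "n2"], "grey")  # no mapped DEG
  expect_identical(nf$color[nf$node_id == "n3"], "grey")

  # equal sums -> 0; sign rule follows the un-logged ratio
  expr_eq <- two_cluster_expr(matrix(2, 2, 4), matrix(2, 2, 4))
  degs_eq <- structure(tibble::tibble(gene_id = c("g001", "g002"),
                                      log2_ratio = 0, p_value = 0,
                                      call = "up"),
                       class = c("deg_table", class(tibble::tibble())))
  nf_eq <- node_fold_change(expr_eq, network, annotation, degs_eq,
                            "ref", "oth")
  expect_equal(nf_eq$fold_change[nf_eq$node_id == "n1"], 0)
  expect_identical(nf_eq$color[nf_eq$node_id == "n1"], "white")
})

test_that("local clustering matches exhaustive triangle enumeration", {
  # triangle plus a pendant: triangle vertices 1, star-like center gets the
  # triangle share of its pairs
  nodes <- c("a", "b", "c", "d")
  edges <- tibble::tibble(from = c("a", "b", "c", "a"),
                          to = c("b", "c", "a", "d"))
  got <- local_clustering(list(nodes = tibble::tibble(node_id = nodes),
                               edges = edges))
  expect_equal(got$clustering[got$node_id == "b"], 1)
  expect_equal(got$clustering[got$node_id == "d"], 0)  # degree 1

  star <- list(nodes = tibble::tibble(node_id = c("hub", "x", "y", "z")),
               edges = tibble::tibble(from = "hub", to = c("x", "y", "z")))
  got_star <- local_clustering(star)
  expect_equal(got_star$clustering[got_star$node_id == "hub"], 0)

  set.seed(44)
  nodes12 <- sprintf("v%02d", 1:12)
  pairs <- t(combn(nodes12, 2))
  keep <- runif(nrow(pairs)) < 0.3
  edges12 <- tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2])
  got12 <- local_clustering(list(nodes = tibble::tibble(node_id = nodes12),
                                 edges = edges12))
  oracle <- oracle_clustering(nodes12, edges12)
  expect_equal(got12$clustering[match(nodes12, got12$node_id)],
               unname(oracle), tolerance = 1e-12)
})
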