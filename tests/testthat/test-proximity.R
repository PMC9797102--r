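.mk_genes <- function(...) {
  g <- tibble::tibble(...)
  g$id <- paste0("gene", seq_len(nrow(g)))
  g
}

test_that("gap arithmetic: overlap is zero, otherwise boundary distance", {
  genes <- .mk_genes(chrom = "c1", start = 300, end = 400)
  tes <- tibble::tibble(chrom = "c1", start = 100, end = 200, id = "te1",
                        superfamily = "Gypsy", status = "intact")
  expect_equal(nearest_gene_distance(genes, tes)$distance_bp, 100)
  tes$start <- 100; tes$end <- 350
  expect_equal(nearest_gene_distance(genes, tes)$distance_bp, 0)
  # TE downstream of the gene
  tes$start <- 450; tes$end <- 500
  expect_equal(nearest_gene_distance(genes, tes)$distance_bp, 50)
  # adjacency in half-open coordinates is distance zero
  tes$start <- 400; tes$end <- 450
  expect_equal(nearest_gene_distance(genes, tes)$distance_bp, 0)
})

test_that("TEs on gene-less chromosomes are flagged missing", {
  genes <- .mk_genes(chrom = "c1", start = 10, end = 20)
  tes <- tibble::tibble(chrom = c("c1", "c2"), start = c(0, 0),
                        end = c(5, 5), id = c("t1", "t2"),
                        superfamily = "Copia", status = "intact")
  out <- nearest_gene_distance(genes, tes)
  expect_equal(out$distance_bp, c(5, NA))
  expect_equal(out$flags, c("", "no_gene_on_chrom"))
})

test_that("interval bounds are validated against declared chromosomes", {
  chroms <- tibble::tibble(name = "c1", length = 1000)
  genes <- .mk_genes(chrom = "c1", start = 10, end = 20)
  tes <- tibble::tibble(chrom = "c1", start = 990, end = 1100, id = "bad",
                        superfamily = "Gypsy", status = "intact")
  expect_error(nearest_gene_distance(genes, tes, chroms),
               class = "wgdclock_validation_error")
  expect_error(
    nearest_gene_distance(.mk_genes(chrom = "cX", start = 1, end = 5),
                          tes, chroms),
    class = "wgdclock_validation_error")
})

test_that("distances equal the all-pairs brute-force scan on random models", {
  set.seed(19)
  for (rep in 1:10) {
    n_g <- sample(5:40, 1); n_t <- sample(5:60, 1)
    genes <- tibble::tibble(
      chrom = sample(c("c1", "c2"), n_g, replace = TRUE),
      start = sample.int(9000, n_g))
    genes$end <- genes$start + sample.int(500, n_g)
    genes$id <- paste0("g", seq_len(n_g))
    tes <- tibble::tibble(
      chrom = sample(c("c1", "c2"), n_t, replace = TRUE),
      start = sample.int(9000, n_t))
    tes$end <- tes$start + sample.int(300, n_t)
    tes$id <- paste0("t", seq_len(n_t))
    tes$superfamily <- "Gypsy"; tes$status <- "intact"
    got <- nearest_gene_distance(genes, tes)$distance_bp
    expect_identical(got, oracle_nearest(genes, tes))
  }
})

test_that("distances are invariant under chromosome coordinate reversal", {
  set.seed(20)
  L <- 10000
  genes <- tibble::tibble(chrom = "c1", start = sample.int(9000, 15))
  genes$end <- genes$start + sample.int(400, 15)
  genes$id <- paste0("g", 1:15)
  tes <- tibble::tibble(chrom = "c1", start = sample.int(9000, 25))
  tes$end <- tes$start + sample.int(200, 25)
  tes$id <- paste0("t", 1:25); tes$superfamily <- "Copia"
  tes$status <- "fragmentary"
  fwd <- nearest_gene_distance(genes, tes)$distance_bp
  flip <- function(d) {
    tibble::tibble(chrom = d$chrom, start = L - d$end, end = L - d$start,
                   id = d$id)
  }
  g2 <- flip(genes); t2 <- flip(tes)
  t2$superfamily <- tes$superfamily; t2$status <- tes$status
  rev_ <- nearest_gene_distance(g2, t2)$distance_bp
  expect_identical(fwd, rev_)
})

test_that("maximal separation gives an overwhelming chi-square signal", {
  dist <- tibble::tibble(
    distance_bp = c(rep(0, 50), rep(10000, 50)),
    status = rep(c("intact", "fragmentary"), each = 50),
    superfamily = "Gypsy", id = paste0("t", 1:100))
  out <- proximity_test(dist)
  all_row <- dplyr::filter(out$tests, superfamily == "all")
  expect_lt(all_row$chisq_p, 1e-6)
  expect_equal(all_row$closer_group, "intact")
})

test_that("equal layouts are flagged at close to the nominal rate", {
  set.seed(47)
  reps <- 300
  hits <- 0
  for (i in seq_len(reps)) {
    d <- tibble::tibble(
      distance_bp = rexp(400, rate = 1 / 2000),
      status = rep(c("intact", "fragmentary"), each = 200),
      superfamily = "Gypsy")
    p <- proximity_test(d)$tests
    if (p$chisq_p[p$superfamily == "all"] < 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.02)
  expect_lt(hits / reps, 0.09)
})

test_that("planted intact-near-gene layouts are detected in direction", {
  cfg <- simulation_config(seed = 50)
  ann <- simulate_annotations(cfg)
  d <- nearest_gene_distance(ann$genes, ann$tes, ann$chromosomes)
  res <- proximity_test(d, bin_edge_bp = 1000)
  row <- dplyr::filter(res$tests, superfamily == "all")
  expect_lt(row$chisq_p, 0.001)
  expect_lt(row$ranksum_p, 0.001)
  expect_equal(row$closer_group, "intact")
  expect_error(
    proximity_test(dplyr::filter(d, status == "intact")),
    class = "wgdclock_empty_group")
})
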