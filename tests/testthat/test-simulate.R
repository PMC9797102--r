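test_that("generators are fully deterministic given a seed", {
  g1 <- simulate_gene_pairs(10, 60, seed = 123)
  g2 <- simulate_gene_pairs(10, 60, seed = 123)
  expect_identical(g1, g2)
  l1 <- simulate_ltr_pairs(tibble::tibble(age_ma = 1, n_elements = 5,
                                          ltr_length = 200,
                                          superfamily = "Gypsy"), seed = 4)
  l2 <- simulate_ltr_pairs(tibble::tibble(age_ma = 1, n_elements = 5,
                                          ltr_length = 200,
                                          superfamily = "Gypsy"), seed = 4)
  expect_identical(l1, l2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- simulation_config(seed = 77, n_genes = 10L, codon_length = 60L,
                           n_blocks = 20L)
  cfg$ltr_cohorts$n_elements <- 25L
  cfg$ltr_cohorts$ltr_length <- 200L
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("simulated gene pairs carry no stops and hit their target Ks", {
  pairs <- simulate_gene_pairs(300, 300, target_ks = 0.33, omega = 0.2,
                               seed = 202)
  for (s in c(pairs$seq_a[1:5], pairs$seq_b[1:5])) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- vapply(cods, oracle_translate, character(1))
    expect_false(any(aa == "*"))
  }
  res <- kaks(pairs)
  expect_lt(abs(mean(res$ks) - 0.33) / 0.33, 0.05)
  expect_warning(simulate_gene_pairs(1, 30, target_ks = 3.5, seed = 1),
                 class = "wgdclock_config_warning")
})

test_that("ks mixture draws are positive and labelled by true component", {
  x <- simulate_ks_mixture(500, seed = 66)
  expect_true(all(x > 0))
  comp <- attr(x, "component")
  expect_equal(length(comp), 500)
  # component labels track the draw locations
  expect_lt(max(abs(x[comp == 1] - 0.329)), 0.3)
  expect_gt(min(x[comp == 3]), 1)
})

test_that("synteny truth bookkeeping matches the emitted anchors", {
  cfg <- simulation_config(seed = 88, n_blocks = 50L)
  syn <- simulate_synteny(cfg)
  expect_setequal(unique(syn$anchors$block_id), syn$truth$block_id)
  counted <- dplyr::count(syn$anchors, block_id)
  m <- dplyr::inner_join(counted, syn$truth, by = "block_id")
  expect_equal(m$n, m$n_pairs)
  # some blocks are deliberately below the 10-pair threshold
  expect_true(any(m$n_pairs < 10))
})

test_that("all blocks below threshold give an empty distribution", {
  cfg <- simulation_config(seed = 89, n_blocks = 15L,
                           pairs_per_block = 4L, small_block_fraction = 0)
  syn <- simulate_synteny(cfg)
  med <- block_median_ks(syn$anchors, min_pairs = 10)
  expect_equal(nrow(med), 0)
})

test_that("LTR pairs at age zero are identical; aged cohorts diverge", {
  z <- simulate_ltr_pairs(tibble::tibble(age_ma = 0, n_elements = 5,
                                         ltr_length = 300,
                                         superfamily = "Gypsy"), seed = 9)
  expect_identical(z$seq5, z$seq3)
  a <- simulate_ltr_pairs(tibble::tibble(age_ma = 2, n_elements = 5,
                                         ltr_length = 300,
                                         superfamily = "Gypsy"), seed = 9)
  expect_true(all(a$seq5 != a$seq3))
})

test_that("annotation layout plants the proximity signal it promises", {
  cfg <- simulation_config(seed = 90)
  cfg$te_layout$near_gene_fraction <- 1
  ann <- simulate_annotations(cfg)
  d <- nearest_gene_distance(ann$genes, ann$tes, ann$chromosomes)
  med_intact <- median(d$distance_bp[d$status == "intact"], na.rm = TRUE)
  expect_lte(med_intact, 500)
  # planted GO categories exceed the 20-member test gate
  counts <- dplyr::count(ann$gene2go, go_id)
  expect_true(all(counts$n[counts$go_id %in% cfg$go$accelerated] > 20))
  short <- simulation_config(seed = 91)
  short$te_layout$chromosomes <- tibble::tibble(name = "c1", length = 1e4)
  expect_error(simulate_annotations(short),
               class = "wgdclock_config_error")
})

test_that("equal intact/fragmentary layouts stay null-calibrated", {
  set.seed(52)
  reps <- 60
  hits <- 0
  for (i in seq_len(reps)) {
    cfg <- simulation_config(seed = 5200 + i)
    cfg$te_layout$near_gene_fraction <- 0
    cfg$te_layout$near_gene_fraction_fragmentary <- 0
    cfg$te_layout$n_intact <- 150L
    cfg$te_layout$n_fragmentary <- 150L
    ann <- simulate_annotations(cfg)
    d <- nearest_gene_distance(ann$genes, ann$tes, ann$chromosomes)
    p <- proximity_test(d)$tests
    if (p$chisq_p[p$superfamily == "all"] < 0.05) hits <- hits + 1
  }
  expect_lt(hits / reps, 0.15)
})

test_that("every generated file round-trips through its reader", {
  d <- withr::local_tempdir()
  cfg <- simulation_config(seed = 95, n_genes = 10L, codon_length = 60L,
                           n_blocks = 15L)
  cfg$ltr_cohorts$n_elements <- 25L
  cfg$ltr_cohorts$ltr_length <- 200L
  simulate_dataset(cfg, d)
  pairs <- read_paired_fasta(file.path(d, "genes.fasta"))
  expect_equal(nrow(pairs), 10)
  expect_equal(nchar(pairs$seq_a[1]), 180)
  anchors <- read_anchors(file.path(d, "anchors.tsv"))
  expect_true(all(c("block_id", "gene_a", "gene_b", "ks") %in% names(anchors)))
  ltr <- read_ltr_fasta(file.path(d, "ltr_pairs.fasta"))
  expect_equal(nrow(ltr), 25)
  expect_equal(unique(ltr$superfamily), "Gypsy")
  genes <- read_gene_gff(file.path(d, "genes.gff3"))
  expect_equal(nrow(genes), cfg$n_genes)
  tes <- read_te_bed(file.path(d, "tes.bed"))
  expect_equal(nrow(tes), 600)
  g2g <- read_gene2go(file.path(d, "gene2go.tsv"))
  expect_true(all(g2g$gene %in% genes$id))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(unlist(truth$accelerated_go), cfg$go$accelerated)
})
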