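test_that("site counting classifies the nine single-base mutants correctly", {
  expect_equal(count_sites("ATG"), c(n = 3, s = 0))
  expect_equal(count_sites("TTT"), c(n = 8 / 3, s = 1 / 3))
  # fourfold-degenerate third position: glycine GGN
  expect_equal(count_sites("GGA")[["s"]], 1)
  # fractions always partition the 9 mutants
  for (cod in oracle_all_codons()) {
    if (oracle_translate(cod) == "*") next
    cs <- count_sites(cod)
    expect_equal(sum(cs), 3)
    expect_equal(unname(cs), unname(oracle_sites(cod)), tolerance = 1e-14)
  }
})

test_that("rejected codons signal instead of returning numbers", {
  expect_error(count_sites("TAA"), class = "wgdclock_rejected_codon")
  expect_error(count_sites("ANT"), class = "wgdclock_rejected_codon")
  expect_error(count_differences("TTT", "TAA"),
               class = "wgdclock_rejected_codon")
})

test_that("difference counting averages over minimal pathways", {
  expect_equal(as.numeric(count_differences("TTT", "TTT")), c(0, 0))
  expect_equal(as.numeric(count_differences("TTT", "TTC")), c(0, 1))
  # two 2-step pathways: TTT>GTT>GTA = (1n,1s); TTT>TTA>GTA = (2n,0s)
  expect_equal(as.numeric(count_differences("TTT", "GTA")), c(1.5, 0.5))
  # n + s equals the Hamming distance; symmetric in its arguments
  set.seed(11)
  cods <- oracle_all_codons()
  cods <- cods[vapply(cods, oracle_translate, character(1)) != "*"]
  for (i in 1:200) {
    a <- sample(cods, 1); b <- sample(cods, 1)
    d_ab <- count_differences(a, b)
    d_ba <- count_differences(b, a)
    expect_equal(as.numeric(d_ab), as.numeric(d_ba), tolerance = 1e-14)
    hamming <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(sum(d_ab), hamming, tolerance = 1e-14)
    expect_equal(as.numeric(d_ab), as.numeric(oracle_diffs(a, b)),
                 tolerance = 1e-14)
  }
})

test_that("Jukes-Cantor correction behaves at its boundaries", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.3), -0.75 * log(0.6))
  expect_true(jukes_cantor(0.3) >= 0.3)
  expect_warning(out <- jukes_cantor(0.75), class = "wgdclock_saturation")
  expect_true(is.na(out))
})

test_that("kaks_pair handles identical, gapped and degenerate alignments", {
  a <- strrep("ATGGCTAAA", 20)
  res <- kaks_pair(a, a)
  expect_equal(res$ka, 0)
  expect_equal(res$ks, 0)
  expect_true(is.na(res$omega))
  expect_match(res$flags, "omega_undefined")
  expect_equal(res$n_sites + res$s_sites, 3 * res$codons_used)

  # gapped and N codons are skipped pairwise
  b <- paste0("---", substr(a, 4, nchar(a)))
  res_g <- kaks_pair(a, b)
  expect_equal(res_g$codons_used, 59)
  cN <- paste0("NNN", substr(a, 4, nchar(a)))
  expect_equal(kaks_pair(a, cN)$codons_used, 59)

  expect_error(kaks_pair("---", "---"), class = "wgdclock_empty_alignment")
  expect_error(kaks_pair("ATG", "ATGGCT"), class = "wgdclock_invalid_alignment")
  expect_error(kaks_pair("ATGC", "ATGC"), class = "wgdclock_invalid_alignment")
  expect_error(kaks_pair("TAAATG", "ATGATG"),
               class = "wgdclock_invalid_alignment")
})

test_that("kaks_pair is symmetric and matches the brute-force oracle", {
  set.seed(42)
  for (i in 1:40) {
    pr <- random_codon_pair(60, diff_rate = runif(1, 0.01, 0.2))
    got <- kaks_pair(pr$a, pr$b)
    rev <- kaks_pair(pr$b, pr$a)
    expect_equal(got$ka, rev$ka, tolerance = 1e-14)
    expect_equal(got$ks, rev$ks, tolerance = 1e-14)
    exp_ <- oracle_kaks(pr$a, pr$b)
    expect_equal(got$n_sites, exp_$n_sites, tolerance = 1e-12)
    expect_equal(got$s_sites, exp_$s_sites, tolerance = 1e-12)
    expect_equal(got$n_diff, exp_$n_diff, tolerance = 1e-12)
    expect_equal(got$s_diff, exp_$s_diff, tolerance = 1e-12)
    expect_equal(got$ka, exp_$ka, tolerance = 1e-12)
    expect_equal(got$ks, exp_$ks, tolerance = 1e-12)
  }
})

test_that("adding a nonsynonymous difference never decreases pn", {
  base <- strrep("ATGGCTAAAGGG", 25)
  res0 <- kaks_pair(base, base)
  # substitute first codon ATG -> CTG (Met->Leu, nonsynonymous)
  mut <- paste0("CTG", substr(base, 4, nchar(base)))
  res1 <- kaks_pair(base, mut)
  expect_gt(res1$pn, res0$pn)
  # and a further nonsynonymous change on top
  mut2 <- paste0("CTGCTT", substr(base, 7, nchar(base)))
  res2 <- kaks_pair(base, mut2)
  expect_gt(res2$pn, res1$pn)
})

test_that("a synonymous-only process yields ka near 0 and ks > 0", {
  # ka is not exactly zero in every pair: when the two lineages take
  # synonymous paths into different codon boxes of a split amino acid
  # (e.g. Arg CGA->AGA vs CGA->CGC), NG86's pathway averaging assigns a
  # fractional nonsynonymous difference to the resulting codon pair
  pairs <- simulate_gene_pairs(20, 150, target_ks = 0.3, omega = 0,
                               seed = 7)
  res <- kaks(pairs)
  expect_true(all(res$ks > 0))
  expect_gte(mean(res$ka == 0), 0.5)
  expect_lt(mean(res$ka), 0.01)
  expect_lt(mean(res$ka) / mean(res$ks), 0.05)
})

test_that("estimated omega recovers the simulated dN/dS at low divergence", {
  pairs <- simulate_gene_pairs(200, 300, target_ks = 0.4, omega = 0.3,
                               seed = 99)
  res <- kaks(pairs)
  expect_lt(abs(median(res$omega) - 0.3) / 0.3, 0.15)
})
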