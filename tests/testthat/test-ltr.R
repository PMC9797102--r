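.ltr_tbl <- function(s5, s3, id = "e1", sf = "Gypsy") {
  tibble::tibble(element_id = id, superfamily = sf, seq5 = s5, seq3 = s3)
}

test_that("LTR divergence evaluates the JC69 closed form", {
  s <- strrep("ACGT", 250)
  expect_equal(ltr_divergence(.ltr_tbl(s, s))$k, 0)
  # plant exactly 1.41% mismatches over 1000 columns
  s3 <- s
  flip <- c("A" = "G", "C" = "T", "G" = "A", "T" = "C")
  pos <- seq(10, 985, by = 75)  # 14 distinct positions
  ch <- strsplit(s3, "")[[1]]
  ch[pos] <- flip[ch[pos]]
  s3 <- paste(ch, collapse = "")
  res <- ltr_divergence(.ltr_tbl(s, s3))
  expect_equal(res$p, 0.014)
  expect_equal(res$k, -0.75 * log(1 - 4 * 0.014 / 3), tolerance = 1e-12)
  expect_equal(-0.75 * log(1 - 4 * 0.0141 / 3), 0.01424, tolerance = 1e-3)
})

test_that("gapped and ambiguous columns are excluded; short pairs flagged", {
  s5 <- paste0(strrep("-", 30), strrep("A", 40))
  s3 <- paste0(strrep("N", 30), strrep("A", 40))
  res <- ltr_divergence(.ltr_tbl(s5, s3), min_columns = 50)
  expect_equal(res$comparable_columns, 40)
  expect_equal(res$flags, "insufficient_data")
  expect_true(is.na(res$k))
  # saturation
  a <- strrep("A", 100); tt <- strrep("T", 100)
  res2 <- ltr_divergence(.ltr_tbl(a, tt))
  expect_equal(res2$flags, "saturated")
  expect_error(ltr_divergence(.ltr_tbl("ACGT", "ACG")),
               class = "wgdclock_invalid_alignment")
})

test_that("K2P reduces to JC at low transversion-free divergence", {
  set.seed(8)
  bases <- c("A", "C", "G", "T")
  transit <- c("A" = "G", "G" = "A", "C" = "T", "T" = "C")
  s5 <- sample(bases, 2000, replace = TRUE)
  s3 <- s5
  pos <- sample(2000, 30)
  s3[pos] <- transit[s3[pos]]
  tbl <- .ltr_tbl(paste(s5, collapse = ""), paste(s3, collapse = ""))
  k_jc <- ltr_divergence(tbl, model = "JC69")$k
  k_k2p <- ltr_divergence(tbl, model = "K2P")$k
  expect_lt(abs(k_k2p - k_jc) / k_jc, 0.05)
})

test_that("distances agree with an independent implementation", {
  skip_if_not_installed("ape")
  pairs <- simulate_ltr_pairs(
    tibble::tibble(age_ma = 2, n_elements = 5, ltr_length = 800,
                   superfamily = "Copia"), mu = 7.06e-9, seed = 3)
  ours <- ltr_divergence(pairs, model = "K2P")
  for (i in seq_len(nrow(pairs))) {
    m <- rbind(strsplit(pairs$seq5[i], "")[[1]],
               strsplit(pairs$seq3[i], "")[[1]])
    ref <- ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "K80")
    expect_equal(ours$k[i], as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("insertion time inverts the molecular clock", {
  expect_equal(insertion_time(0.01412, 7.06e-9), 1.0, tolerance = 1e-2)
  expect_equal(insertion_time(0.0186, 6.20e-9), 1.5, tolerance = 1e-2)
  expect_equal(insertion_time(0, 5e-9), 0)
  # linear in k, inverse in mu
  set.seed(14)
  k <- runif(10, 0, 0.1); mu <- runif(10, 1e-9, 1e-8)
  expect_equal(insertion_time(3 * k, mu), 3 * insertion_time(k, mu))
  expect_equal(insertion_time(k, 2 * mu), insertion_time(k, mu) / 2)
  expect_error(insertion_time(0.1, 0), class = "wgdclock_domain_error")
  expect_error(insertion_time(-0.1, 1e-9), class = "wgdclock_domain_error")
})

test_that("simulated cohorts are dated accurately and profiles find modes", {
  pairs <- simulate_ltr_pairs(
    tibble::tibble(age_ma = 1.0, n_elements = 500, ltr_length = 1000,
                   superfamily = "Gypsy"), mu = 7.06e-9, seed = 101)
  prof <- insertion_time_profile(pairs, mu = 7.06e-9)
  expect_lt(abs(prof$summary$mean_ma[prof$summary$superfamily == "all"] - 1.0),
            0.05)
  mode_bin <- prof$summary$mode_ma[prof$summary$superfamily == "all"]
  expect_lt(abs(mode_bin - 1.0), 0.1 + 1e-9)  # mode bin contains 1.0 Ma
})

test_that("identical pairs collapse to the zero bin; mixed cohorts are bimodal", {
  same <- tibble::tibble(
    element_id = paste0("e", 1:25), superfamily = "Gypsy",
    seq5 = strrep("ACGT", 50), seq3 = strrep("ACGT", 50))
  prof <- insertion_time_profile(same, mu = 7.06e-9)
  h <- dplyr::filter(prof$histogram, superfamily == "all")
  expect_equal(sum(h$count > 0), 1)
  expect_equal(h$bin_mid[h$count > 0], 0.05)

  two <- simulate_ltr_pairs(
    tibble::tibble(age_ma = c(0.5, 2.0), n_elements = c(250, 250),
                   ltr_length = 1000, superfamily = c("Gypsy", "Copia")),
    mu = 7.06e-9, seed = 55)
  prof2 <- insertion_time_profile(two, mu = 7.06e-9, bin_width_ma = 0.25)
  h2 <- dplyr::filter(prof2$histogram, superfamily == "all")
  peaks <- which(diff(sign(diff(h2$count))) == -2) + 1
  expect_gte(length(peaks), 2)
})

test_that("profiles require at least 20 datable pairs", {
  few <- tibble::tibble(element_id = paste0("e", 1:5),
                        superfamily = "Gypsy",
                        seq5 = strrep("ACGT", 50),
                        seq3 = strrep("ACGT", 50))
  expect_error(insertion_time_profile(few, mu = 7e-9),
               class = "wgdclock_insufficient_data")
})
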