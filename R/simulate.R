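# Seeded synthetic-data generator emulating every pipeline input:
# codon-aligned gene pairs diverging under a chosen dN/dS, syntenic
# blocks clustered around WGD Ks peaks, LTR pairs diverged under a
# Jukes-Cantor clock, and annotated gene/TE layouts.

#' Default simulation configuration
#'
#' Bundles the study-scale defaults used throughout the synthetic
#' pipeline: three WGD cohorts at Ks 0.329 / 0.502 / 2.019, an LTR
#' cohort of 500 elements inserted 1 Ma ago at mu = 7.06e-9 per site
#' per year, and a two-chromosome annotation layout in which intact
#' TEs preferentially insert within 500 bp of genes.
#'
#' @param seed Master seed (default 20221214).
#' @param ... Overrides for any config element.
#' @return A named list of class `sim_config`.
#' @export
simulation_config <- function(seed = 20221214L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = 200L,
    codon_length = 300L,
    omega = 0.2,
    wgd_events = tibble::tibble(
      name = c("HRT", "HAT", "ECH"),
      target_ks = c(0.329, 0.502, 2.019),
      sd = c(0.04, 0.06, 0.25),
      weight = c(0.35, 0.35, 0.30)
    ),
    n_blocks = 2000L,
    pairs_per_block = 12L,
    small_block_fraction = 0.1,
    pair_ks_sd = 0.05,
    ltr_cohorts = tibble::tibble(
      age_ma = 1.0, n_elements = 500L, ltr_length = 1000L,
      superfamily = "Gypsy"
    ),
    mu = 7.06e-9,
    te_layout = list(
      n_intact = 300L, n_fragmentary = 300L,
      near_gene_fraction = 0.8, near_gene_fraction_fragmentary = 0,
      near_gene_bp = 500L, te_length = 500L, gene_length = 2000L,
      chromosomes = tibble::tibble(name = c("chr1", "chr2"),
                                   length = c(2e6, 2e6))
    ),
    go = list(n_categories = 40L, genes_per_category = 30L,
              accelerated = c("GO:ACC1", "GO:ACC2"), enrichment = 3,
              mean_subs = 20, p_neutral = 0.4)
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

# sample non-stop codon indices uniformly
.sample_codons <- function(n) {
  ok <- which(!.ng_is_stop(seq_len(64)))
  sample(ok, n, replace = TRUE)
}

# Evolve a codon-index vector along one branch: `m` expected proposed
# mutations per nucleotide site; proposals creating stops are rejected,
# nonsynonymous proposals accepted with probability omega.
.evolve_codons <- function(idx, m, omega) {
  L <- length(idx)
  n_prop <- stats::rpois(1, 3 * L * m)
  if (n_prop == 0) return(idx)
  digs <- .ng_digits(seq_len(64))
  pos <- sample.int(3L * L, n_prop, replace = TRUE)
  shift <- sample.int(3L, n_prop, replace = TRUE)   # 1..3 -> other base
  acc <- stats::runif(n_prop)
  for (t in seq_len(n_prop)) {
    p <- pos[t]
    cj <- (p - 1L) %/% 3L + 1L
    wp <- (p - 1L) %% 3L + 1L
    d <- digs[idx[cj], ]
    d[wp] <- (d[wp] + shift[t]) %% 4L
    new_idx <- d[1] * 16L + d[2] * 4L + d[3] + 1L
    if (.ng_aa64[new_idx] == "*") next
    syn <- .ng_aa64[new_idx] == .ng_aa64[idx[cj]]
    if (syn || acc[t] < omega) idx[cj] <- new_idx
  }
  idx
}

.codon_to_string <- function(idx) {
  paste(.ng_codon_strings()[idx], collapse = "")
}

#' Simulate codon-aligned gene pairs with known divergence and dN/dS
#'
#' Each pair descends from a random stop-free ancestral CDS; both
#' copies accumulate Poisson-distributed single-base mutation proposals
#' such that the expected pairwise synonymous divergence matches
#' `target_ks`, with nonsynonymous proposals accepted with probability
#' `omega` and stop-creating proposals rejected. Deterministic given
#' the seed.
#'
#' @param n_pairs Number of pairs.
#' @param codon_length Codons per gene.
#' @param target_ks Expected pairwise synonymous divergence (scalar or
#'   per-pair vector). Values at or above 3 trigger a saturation
#'   warning.
#' @param omega dN/dS of the substitution process (scalar or
#'   per-pair).
#' @param seed Integer seed.
#' @param prefix Gene-id prefix.
#' @return A tibble with `id_a`, `id_b`, `seq_a`, `seq_b`,
#'   `true_omega`, `target_ks`.
#' @export
simulate_gene_pairs <- function(n_pairs, codon_length = 300L,
                                target_ks = 0.33, omega = 0.2,
                                seed = 20221214L, prefix = "g") {
  set.seed(seed)
  target_ks <- rep_len(target_ks, n_pairs)
  omega <- rep_len(omega, n_pairs)
  if (any(target_ks >= 3)) {
    rlang::warn("target_ks >= 3 is beyond practical saturation for NG86",
                class = "wgdclock_config_warning")
  }
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    anc <- .sample_codons(codon_length)
    a <- .evolve_codons(anc, target_ks[i] / 2, omega[i])
    b <- .evolve_codons(anc, target_ks[i] / 2, omega[i])
    out[[i]] <- tibble::tibble(
      id_a = paste0(prefix, i, "_a"), id_b = paste0(prefix, i, "_b"),
      seq_a = .codon_to_string(a), seq_b = .codon_to_string(b),
      true_omega = omega[i], target_ks = target_ks[i])
  }
  purrr::list_rbind(out)
}

#' Simulate block-median Ks values from a Gaussian-mixture of WGD peaks
#'
#' @param n Number of block medians.
#' @param means,sds,weights Mixture parameters (equal lengths; weights
#'   are normalised). Defaults are the three-cohort configuration of
#'   [simulation_config()].
#' @param seed Integer seed.
#' @return Numeric vector of positive Ks values; attribute `component`
#'   records each value's true cohort.
#' @export
simulate_ks_mixture <- function(n, means = c(0.329, 0.502, 2.019),
                                sds = c(0.04, 0.06, 0.25),
                                weights = c(0.35, 0.35, 0.30),
                                seed = 20221214L) {
  stopifnot(length(means) == length(sds), length(means) == length(weights))
  set.seed(seed)
  comp <- sample.int(length(means), n, replace = TRUE,
                     prob = weights / sum(weights))
  x <- stats::rnorm(n, means[comp], sds[comp])
  while (any(x <= 0)) {
    bad <- which(x <= 0)
    x[bad] <- stats::rnorm(length(bad), means[comp[bad]], sds[comp[bad]])
  }
  attr(x, "component") <- comp
  x
}

#' Simulate a collinearity anchor table clustered around WGD cohorts
#'
#' Every block is assigned to one WGD cohort; its pairs' Ks values
#' scatter around a block-level mean drawn from the cohort. A fraction
#' of blocks is emitted with fewer than 10 pairs to exercise the
#' block-size filter downstream.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `anchors` (tibble `block_id`, `gene_a`, `gene_b`,
#'   `ks`) and `truth` (tibble `block_id`, `event`, `block_mean_ks`,
#'   `n_pairs`).
#' @export
simulate_synteny <- function(cfg = simulation_config()) {
  set.seed(cfg$seed + 1L)
  ev <- cfg$wgd_events
  nb <- cfg$n_blocks
  comp <- sample.int(nrow(ev), nb, replace = TRUE,
                     prob = ev$weight / sum(ev$weight))
  block_mean <- stats::rnorm(nb, ev$target_ks[comp], ev$sd[comp])
  while (any(block_mean <= 0)) {
    bad <- which(block_mean <= 0)
    block_mean[bad] <- stats::rnorm(length(bad), ev$target_ks[comp[bad]],
                                    ev$sd[comp[bad]])
  }
  n_pairs <- rep(cfg$pairs_per_block, nb)
  small <- stats::runif(nb) < cfg$small_block_fraction
  n_pairs[small] <- sample(3:9, sum(small), replace = TRUE)
  anchors <- purrr::map(seq_len(nb), function(b) {
    ks <- stats::rnorm(n_pairs[b], block_mean[b], cfg$pair_ks_sd)
    ks <- pmax(ks, 1e-4)
    tibble::tibble(
      block_id = sprintf("blk%04d", b),
      gene_a = sprintf("blk%04d_g%02d_a", b, seq_len(n_pairs[b])),
      gene_b = sprintf("blk%04d_g%02d_b", b, seq_len(n_pairs[b])),
      ks = ks)
  }) |> purrr::list_rbind()
  truth <- tibble::tibble(block_id = sprintf("blk%04d", seq_len(nb)),
                          event = ev$name[comp],
                          block_mean_ks = block_mean, n_pairs = n_pairs)
  list(anchors = anchors, truth = truth)
}

# exact Jukes-Cantor chain: per-column substitution probability after
# per-branch distance d, uniform choice among the three other bases
.jc_mutate <- function(chars, d) {
  p_change <- 0.75 * (1 - exp(-4 / 3 * d))
  n <- length(chars)
  hit <- stats::runif(n) < p_change
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(chars[hit], bases)
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    chars[hit] <- bases[(cur - 1L + shift) %% 4L + 1L]
  }
  chars
}

#' Simulate aligned 5'/3' LTR pairs under a Jukes-Cantor clock
#'
#' Both LTR copies start identical and diverge independently for
#' `age_ma` at rate `mu`, so their pairwise divergence has expectation
#' `2 * mu * age_ma * 1e6` (before multiple-hit loss, which the
#' Jukes-Cantor estimator recovers).
#'
#' @param cohorts Tibble with `age_ma`, `n_elements`, `ltr_length`,
#'   `superfamily` (one row per cohort), e.g.
#'   `simulation_config()$ltr_cohorts`.
#' @param mu Substitution rate per site per year.
#' @param seed Integer seed.
#' @return A tibble with `element_id`, `superfamily`, `seq5`, `seq3`,
#'   `true_age_ma`.
#' @export
simulate_ltr_pairs <- function(cohorts, mu = 7.06e-9, seed = 20221214L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- vector("list", nrow(cohorts))
  for (ci in seq_len(nrow(cohorts))) {
    co <- cohorts[ci, ]
    d <- mu * co$age_ma * 1e6
    recs <- vector("list", co$n_elements)
    for (i in seq_len(co$n_elements)) {
      anc <- sample(bases, co$ltr_length, replace = TRUE)
      s5 <- .jc_mutate(anc, d)
      s3 <- .jc_mutate(anc, d)
      recs[[i]] <- tibble::tibble(
        element_id = sprintf("c%dltr%04d", ci, i),
        superfamily = co$superfamily,
        seq5 = paste(s5, collapse = ""),
        seq3 = paste(s3, collapse = ""),
        true_age_ma = co$age_ma)
    }
    out[[ci]] <- purrr::list_rbind(recs)
  }
  purrr::list_rbind(out)
}

#' Simulate gene and TE annotations with a plantable proximity signal
#'
#' Genes are placed without overlap on each chromosome (jittered grid).
#' Intact TEs land within `near_gene_bp` of a random gene with
#' probability `near_gene_fraction`, otherwise uniformly; fragmentary
#' TEs use `near_gene_fraction_fragmentary` (0 by default, i.e.
#' uniform). GO labels are assigned so that planted accelerated
#' categories have more than 20 members.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `chromosomes`, `genes`, `tes` (interval tibbles,
#'   0-based half-open) and `gene2go`.
#' @export
simulate_annotations <- function(cfg = simulation_config()) {
  set.seed(cfg$seed + 2L)
  lay <- cfg$te_layout
  chroms <- lay$chromosomes
  per_chrom <- ceiling(cfg$n_genes / nrow(chroms))
  genes <- purrr::map(seq_len(nrow(chroms)), function(ci) {
    slot <- floor(chroms$length[ci] / per_chrom)
    if (slot <= lay$gene_length) {
      rlang::abort("chromosome too short for requested gene layout",
                   class = "wgdclock_config_error")
    }
    jitter <- floor(stats::runif(per_chrom, 0, slot - lay$gene_length))
    start <- (seq_len(per_chrom) - 1L) * slot + jitter
    tibble::tibble(chrom = chroms$name[ci], start = start,
                   end = start + lay$gene_length,
                   strand = sample(c("+", "-"), per_chrom, replace = TRUE),
                   id = sprintf("%s_gene%03d", chroms$name[ci],
                                seq_len(per_chrom)))
  }) |> purrr::list_rbind()
  genes <- genes[seq_len(min(nrow(genes), cfg$n_genes)), ]

  place_tes <- function(n, status, near_frac) {
    near <- stats::runif(n) < near_frac
    sf <- sample(c("Gypsy", "Copia"), n, replace = TRUE)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (near[i]) {
        g <- genes[sample.int(nrow(genes), 1), ]
        gap <- floor(stats::runif(1, 0, lay$near_gene_bp + 1))
        left <- stats::runif(1) < 0.5
        start <- if (left) g$start - gap - lay$te_length else g$end + gap
        chrom <- g$chrom
      } else {
        ci <- sample.int(nrow(chroms), 1)
        chrom <- chroms$name[ci]
        start <- floor(stats::runif(1, 0, chroms$length[ci] - lay$te_length))
      }
      clen <- chroms$length[match(chrom, chroms$name)]
      start <- max(0, min(start, clen - lay$te_length))
      rows[[i]] <- tibble::tibble(chrom = chrom, start = start,
                                  end = start + lay$te_length,
                                  id = paste0(status, i),
                                  superfamily = sf[i], status = status)
    }
    purrr::list_rbind(rows)
  }
  tes <- dplyr::bind_rows(
    place_tes(lay$n_intact, "intact", lay$near_gene_fraction),
    place_tes(lay$n_fragmentary, "fragmentary",
              lay$near_gene_fraction_fragmentary))

  go <- cfg$go
  cats <- c(go$accelerated,
            sprintf("GO:%07d", seq_len(go$n_categories - length(go$accelerated))))
  gene2go <- purrr::map(cats, function(cat) {
    members <- sample(genes$id, min(go$genes_per_category, nrow(genes)))
    tibble::tibble(gene = members, go_id = cat)
  }) |> purrr::list_rbind()
  list(chromosomes = chroms, genes = genes, tes = tes, gene2go = gene2go)
}

#' Simulate per-ortholog substitution counts for GO acceleration tests
#'
#' Direct count-level simulation for calibrating the binomial
#' acceleration test: each gene belongs to one GO category, carries a
#' Poisson number of substitutions, and each substitution is
#' nonsynonymous with the neutral probability `p_neutral`, multiplied
#' (on the rate scale) by `enrichment` in accelerated categories.
#'
#' @param n_categories Number of GO categories.
#' @param orthologs_per_category Genes per category.
#' @param mean_subs Mean substitutions per gene.
#' @param p_neutral Null nonsynonymous fraction.
#' @param accelerated Indices (or names) of categories with planted
#'   enrichment.
#' @param enrichment Nonsynonymous rate multiplier in accelerated
#'   categories.
#' @param seed Integer seed.
#' @return A list: `counts` (tibble `gene`, `n_diff`, `s_diff`),
#'   `gene2go`, `truth` (tibble `go_id`, `accelerated`).
#' @export
simulate_ortholog_counts <- function(n_categories = 100,
                                     orthologs_per_category = 50,
                                     mean_subs = 20, p_neutral = 0.4,
                                     accelerated = integer(0),
                                     enrichment = 3,
                                     seed = 20221214L) {
  set.seed(seed)
  cats <- sprintf("GO:%07d", seq_len(n_categories))
  acc <- if (is.character(accelerated)) cats %in% accelerated
         else seq_len(n_categories) %in% accelerated
  p_acc <- enrichment * p_neutral /
    (enrichment * p_neutral + (1 - p_neutral))
  n_genes <- n_categories * orthologs_per_category
  cat_of <- rep(seq_len(n_categories), each = orthologs_per_category)
  p <- ifelse(acc[cat_of], p_acc, p_neutral)
  total <- stats::rpois(n_genes, mean_subs)
  n_diff <- stats::rbinom(n_genes, total, p)
  counts <- tibble::tibble(gene = sprintf("gene%06d", seq_len(n_genes)),
                           n_diff = n_diff, s_diff = total - n_diff)
  list(counts = counts,
       gene2go = tibble::tibble(gene = counts$gene, go_id = cats[cat_of]),
       truth = tibble::tibble(go_id = cats, accelerated = acc))
}

#' Write a complete synthetic input set to a directory
#'
#' Emits every pipeline input with full determinism: `genes.fasta`
#' (paired codon alignments), `anchors.tsv`, `ltr_pairs.fasta`,
#' `genes.gff3`, `tes.bed`, `gene2go.tsv`, `truth.json` and
#' `config.yaml` (the config echo).
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
simulate_dataset <- function(cfg = simulation_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- simulate_gene_pairs(cfg$n_genes, cfg$codon_length,
                               target_ks = 0.33, omega = cfg$omega,
                               seed = cfg$seed)
  fa <- character(2 * nrow(pairs))
  fa[c(TRUE, FALSE)] <- paste0(">", pairs$id_a, "\n", pairs$seq_a)
  fa[c(FALSE, TRUE)] <- paste0(">", pairs$id_b, "\n", pairs$seq_b)
  writeLines(fa, file.path(dir, "genes.fasta"))

  syn <- simulate_synteny(cfg)
  readr::write_tsv(syn$anchors, file.path(dir, "anchors.tsv"),
                   progress = FALSE)

  ltr <- simulate_ltr_pairs(cfg$ltr_cohorts, cfg$mu, seed = cfg$seed + 3L)
  fa <- character(2 * nrow(ltr))
  fa[c(TRUE, FALSE)] <- paste0(">", ltr$element_id, ":5ltr superfamily=",
                               ltr$superfamily, "\n", ltr$seq5)
  fa[c(FALSE, TRUE)] <- paste0(">", ltr$element_id, ":3ltr superfamily=",
                               ltr$superfamily, "\n", ltr$seq3)
  writeLines(fa, file.path(dir, "ltr_pairs.fasta"))

  ann <- simulate_annotations(cfg)
  gff <- c("##gff-version 3",
           sprintf("%s\twgdclock\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   ann$genes$chrom, ann$genes$start + 1L, ann$genes$end,
                   ann$genes$strand, ann$genes$id))
  writeLines(gff, file.path(dir, "genes.gff3"))
  readr::write_tsv(ann$tes, file.path(dir, "tes.bed"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(ann$gene2go, file.path(dir, "gene2go.tsv"),
                   progress = FALSE)

  truth <- list(
    gene_pairs = list(target_ks = 0.33, omega = cfg$omega),
    blocks = syn$truth,
    ltr = dplyr::distinct(ltr[, c("superfamily", "true_age_ma")]),
    chromosomes = ann$chromosomes,
    accelerated_go = cfg$go$accelerated
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  cfg_plain <- unclass(cfg)
  cfg_plain <- purrr::map(cfg_plain, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  })
  cfg_plain$te_layout$chromosomes <- as.list(cfg$te_layout$chromosomes)
  yaml::write_yaml(cfg_plain, file.path(dir, "config.yaml"))
  invisible(dir)
}
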