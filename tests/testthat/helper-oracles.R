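# Independent brute-force oracles, written naively and kept separate
# from the implementation paths they check.

.oracle_env <- new.env(parent = emptyenv())

oracle_bases <- c("A", "C", "G", "T")

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

oracle_all_codons <- function() {
  g <- expand.grid(b1 = oracle_bases, b2 = oracle_bases, b3 = oracle_bases,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

# fractional synonymous/nonsynonymous sites of one codon, by direct
# enumeration of its nine single-base mutants
oracle_sites <- function(codon) {
  key <- paste0("S", codon)
  if (!is.null(.oracle_env[[key]])) return(.oracle_env[[key]])
  aa0 <- oracle_translate(codon)
  stopifnot(aa0 != "*")
  s <- 0
  for (pos in 1:3) {
    for (b in oracle_bases) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      aa1 <- oracle_translate(mut)
      if (aa1 != "*" && aa1 == aa0) s <- s + 1 / 3
    }
  }
  out <- c(n = 3 - s, s = s)
  .oracle_env[[key]] <- out
  out
}

# all orderings of a set, by naive recursion
oracle_orderings <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_orderings(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# pathway-averaged differences between two codons, enumerating every
# ordering of the differing positions step by step
oracle_diffs <- function(ca, cb) {
  key <- paste0("D", ca, cb)
  if (!is.null(.oracle_env[[key]])) return(.oracle_env[[key]])
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0) {
    out <- c(n = 0, s = 0)
    .oracle_env[[key]] <- out
    return(out)
  }
  res <- list()
  for (ord in oracle_orderings(pos)) {
    cur <- ca
    nn <- 0; ss <- 0; through_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      aa1 <- oracle_translate(cur)
      aa2 <- oracle_translate(nxt)
      if (aa2 == "*") through_stop <- TRUE
      if (aa1 == aa2) ss <- ss + 1 else nn <- nn + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- list(n = nn, s = ss, stop = through_stop)
  }
  ok <- !vapply(res, `[[`, logical(1), "stop")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  out <- c(n = mean(vapply(res[ok], `[[`, numeric(1), "n")),
           s = mean(vapply(res[ok], `[[`, numeric(1), "s")))
  .oracle_env[[key]] <- out
  out
}

# full NG86 estimate for one aligned pair, codon by codon
oracle_kaks <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  n_sites <- s_sites <- n_diff <- s_diff <- 0
  used <- 0
  for (i in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    if (oracle_translate(ca[i]) == "*" || oracle_translate(cb[i]) == "*") next
    sa <- oracle_sites(ca[i]); sb <- oracle_sites(cb[i])
    n_sites <- n_sites + (sa[["n"]] + sb[["n"]]) / 2
    s_sites <- s_sites + (sa[["s"]] + sb[["s"]]) / 2
    d <- oracle_diffs(ca[i], cb[i])
    n_diff <- n_diff + d[["n"]]
    s_diff <- s_diff + d[["s"]]
    used <- used + 1
  }
  pn <- n_diff / n_sites
  ps <- s_diff / s_sites
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(n_sites = n_sites, s_sites = s_sites, n_diff = n_diff,
       s_diff = s_diff, pn = pn, ps = ps, ka = jc(pn), ks = jc(ps),
       codons_used = used)
}

# exact upper binomial tail by direct pmf summation
oracle_binom_tail <- function(a, n, p) {
  if (a <= 0) return(1)
  if (a > n) return(0)
  x <- a:n
  sum(exp(lchoose(n, x) + x * log(p) + (n - x) * log(1 - p)))
}

# all-pairs nearest-gene distance on 0-based half-open intervals
oracle_nearest <- function(genes, tes) {
  vapply(seq_len(nrow(tes)), function(i) {
    g <- genes[genes$chrom == tes$chrom[i], ]
    if (nrow(g) == 0) return(NA_real_)
    min(pmax(0, pmax(g$start - tes$end[i], tes$start[i] - g$end)))
  }, numeric(1))
}

# random stop-free codon-aligned pair with point differences
random_codon_pair <- function(n_codons, diff_rate = 0.05) {
  cods <- oracle_all_codons()
  ok <- cods[vapply(cods, oracle_translate, character(1)) != "*"]
  a <- sample(ok, n_codons, replace = TRUE)
  b <- a
  flip <- which(runif(n_codons) < 3 * diff_rate)
  for (i in flip) {
    repeat {
      mut <- b[i]
      p <- sample(1:3, 1)
      substr(mut, p, p) <- sample(setdiff(oracle_bases,
                                          substr(mut, p, p)), 1)
      if (oracle_translate(mut) != "*") { b[i] <- mut; break }
    }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
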