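#' Synonymous and nonsynonymous site fractions of a codon
#'
#' Classifies each of the nine single-base mutants of a codon as
#' synonymous or nonsynonymous under the standard genetic code and
#' returns the fractional site counts used by the Nei-Gojobori (1986)
#' method. Mutations that create a stop codon count as nonsynonymous.
#'
#' @param codon A single 3-letter codon made of A/C/G/T.
#' @return A named numeric vector with elements `n` (nonsynonymous site
#'   fraction) and `s` (synonymous site fraction); `n + s == 3`.
#' @examples
#' count_sites("ATG") # Met: all 9 mutants change the amino acid
#' count_sites("TTT")
#' @export
count_sites <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L, nchar(codon) == 3L)
  idx <- .ng_codon_index(toupper(codon))
  if (is.na(idx)) {
    rlang::abort(paste0("ambiguous codon '", codon, "'"), class = "wgdclock_rejected_codon")
  }
  if (.ng_is_stop(idx)) {
    rlang::abort(paste0("stop codon '", codon, "'"), class = "wgdclock_rejected_codon")
  }
  st <- .ng_site_table()
  c(n = unname(st[idx, "n"]), s = unname(st[idx, "s"]))
}

#' Pathway-averaged substitution differences between two codons
#'
#' Enumerates every minimal mutational pathway between two codons (1, 2
#' or 6 orderings of the differing positions), classifies each step as
#' synonymous or nonsynonymous, drops pathways passing through a stop
#' codon, and averages over the remaining pathways with equal weights.
#' If every pathway transits a stop, stop-transit pathways are retained
#' and the result is flagged.
#'
#' @param codon_a,codon_b 3-letter codons (A/C/G/T, non-stop).
#' @return A named numeric vector with elements `n` and `s`
#'   (`n + s` equals the Hamming distance of the codons) and an
#'   attribute `stop_transit` (logical).
#' @examples
#' count_differences("TTT", "GTA")
#' @export
count_differences <- function(codon_a, codon_b) {
  i <- .ng_codon_index(toupper(codon_a))
  j <- .ng_codon_index(toupper(codon_b))
  if (is.na(i) || is.na(j) || .ng_is_stop(i) || .ng_is_stop(j)) {
    rlang::abort("codons must be unambiguous and non-stop",
                 class = "wgdclock_rejected_codon")
  }
  dt <- .ng_diff_tables()
  out <- c(n = dt$n[i, j], s = dt$s[i, j])
  attr(out, "stop_transit") <- dt$stop_transit[i, j]
  out
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p Proportion of observed differences per site, `0 <= p < 0.75`.
#' @return The corrected distance `-(3/4) * log(1 - (4/3) * p)`. Values
#'   with `p >= 0.75` (substitution saturation) return `NA` with a
#'   warning condition class `wgdclock_saturation`.
#' @export
jukes_cantor <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0, na.rm = TRUE))
  out <- ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_)
  if (any(p >= 0.75, na.rm = TRUE)) {
    rlang::warn("p >= 0.75: Jukes-Cantor correction saturated, returning NA",
                class = "wgdclock_saturation")
  }
  out
}

# Split an aligned sequence into codon triplets (uppercase).
.split_codons <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Validate a codon alignment; returns invisible(TRUE) or aborts.
.validate_alignment <- function(seq_a, seq_b, id = "") {
  lab <- if (nzchar(id)) paste0(" [", id, "]") else ""
  if (nchar(seq_a) != nchar(seq_b)) {
    rlang::abort(paste0("aligned sequences differ in length", lab),
                 class = "wgdclock_invalid_alignment")
  }
  if (nchar(seq_a) %% 3L != 0L) {
    rlang::abort(paste0("alignment length not divisible by 3", lab),
                 class = "wgdclock_invalid_alignment")
  }
  for (s in c(seq_a, seq_b)) {
    if (grepl("[^ACGTN-]", toupper(s))) {
      rlang::abort(paste0("alphabet must be A/C/G/T/N/-", lab),
                   class = "wgdclock_invalid_alignment")
    }
    ungapped <- gsub("-", "", toupper(s))
    if (nchar(ungapped) %% 3L == 0L && nchar(ungapped) >= 3L) {
      cod <- .split_codons(ungapped)
      internal <- cod[-length(cod)]
      idx <- .ng_codon_index(internal)
      if (any(!is.na(idx) & .ng_is_stop(idx))) {
        rlang::abort(paste0("internal stop codon in ungapped sequence", lab),
                     class = "wgdclock_invalid_alignment")
      }
    }
  }
  invisible(TRUE)
}

#' Nei-Gojobori Ka/Ks for one codon-aligned pair
#'
#' Implements the NG86 counting method: fractional synonymous /
#' nonsynonymous site counts averaged over the two sequences,
#' pathway-averaged difference counts, and Jukes-Cantor correction of
#' the difference proportions. Codon pairs containing a gap, an `N`, an
#' ambiguous base or a stop codon are skipped pairwise.
#'
#' @param seq_a,seq_b Aligned coding sequences (equal length, multiple
#'   of 3, alphabet A/C/G/T/N/-, no internal stops when ungapped).
#' @param id_a,id_b Optional identifiers carried into the result.
#' @return A one-row tibble with columns `id_a`, `id_b`, `ka`, `ks`,
#'   `omega`, `n_sites`, `s_sites`, `n_diff`, `s_diff`, `pn`, `ps`,
#'   `codons_used`, `flags` (`;`-separated: `ka_saturated`,
#'   `ks_saturated`, `omega_undefined`, `stop_transit`).
#' @examples
#' a <- strrep("ATGGCT", 5)
#' kaks_pair(a, a)
#' @export
kaks_pair <- function(seq_a, seq_b, id_a = "a", id_b = "b") {
  .validate_alignment(seq_a, seq_b, paste(id_a, id_b))
  ca <- .split_codons(seq_a)
  cb <- .split_codons(seq_b)
  ia <- .ng_codon_index(ca)
  ib <- .ng_codon_index(cb)
  usable <- !is.na(ia) & !is.na(ib) & !.ng_is_stop(pmax(ia, 1L)) &
    !.ng_is_stop(pmax(ib, 1L))
  usable[is.na(usable)] <- FALSE
  if (!any(usable)) {
    rlang::abort("no scorable codon pairs in alignment",
                 class = "wgdclock_empty_alignment")
  }
  ia <- ia[usable]; ib <- ib[usable]
  st <- .ng_site_table()
  dt <- .ng_diff_tables()
  # sites averaged over the two sequences
  n_sites <- (sum(st[ia, "n"]) + sum(st[ib, "n"])) / 2
  s_sites <- (sum(st[ia, "s"]) + sum(st[ib, "s"])) / 2
  lin <- cbind(ia, ib)
  n_diff <- sum(dt$n[lin])
  s_diff <- sum(dt$s[lin])
  stop_transit <- any(dt$stop_transit[lin])
  pn <- n_diff / n_sites
  ps <- s_diff / s_sites
  flags <- character(0)
  ka <- if (pn < 0.75) -0.75 * log(1 - (4 / 3) * pn) else NA_real_
  ks <- if (ps < 0.75) -0.75 * log(1 - (4 / 3) * ps) else NA_real_
  if (is.na(ka)) flags <- c(flags, "ka_saturated")
  if (is.na(ks)) flags <- c(flags, "ks_saturated")
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  if (is.na(omega)) flags <- c(flags, "omega_undefined")
  if (stop_transit) flags <- c(flags, "stop_transit")
  tibble::tibble(
    id_a = id_a, id_b = id_b,
    ka = ka, ks = ks, omega = omega,
    n_sites = n_sites, s_sites = s_sites,
    n_diff = n_diff, s_diff = s_diff,
    pn = pn, ps = ps,
    codons_used = length(ia),
    flags = paste(flags, collapse = ";")
  )
}

#' Nei-Gojobori Ka/Ks for a table of aligned pairs
#'
#' Tidy, vectorised wrapper around [kaks_pair()].
#'
#' @param pairs A data frame with columns `id_a`, `id_b`, `seq_a`,
#'   `seq_b` (codon-aligned sequences), e.g. from [read_paired_fasta()]
#'   or [simulate_gene_pairs()].
#' @return A tibble with one row per pair; see [kaks_pair()] for
#'   columns.
#' @export
kaks <- function(pairs) {
  stopifnot(all(c("id_a", "id_b", "seq_a", "seq_b") %in% names(pairs)))
  purrr::pmap(
    pairs[c("seq_a", "seq_b", "id_a", "id_b")],
    function(seq_a, seq_b, id_a, id_b) kaks_pair(seq_a, seq_b, id_a, id_b)
  ) |>
    purrr::list_rbind()
}
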