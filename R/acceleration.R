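#' Genome-wide expected nonsynonymous fraction
#'
#' The null of the per-GO-category acceleration test: the pooled
#' fraction of nonsynonymous changes among all substitutions observed
#' in one lineage, `p = sum(n_diff) / sum(n_diff + s_diff)` over all
#' orthologs.
#'
#' @param counts A data frame with columns `n_diff` and `s_diff`
#'   (pathway-averaged substitution counts per ortholog, e.g. from
#'   [kaks()] of lineage-vs-outgroup alignments).
#' @return The expected nonsynonymous fraction (scalar in \[0, 1\]).
#' @export
genome_wide_expectation <- function(counts) {
  stopifnot(all(c("n_diff", "s_diff") %in% names(counts)))
  tot <- sum(counts$n_diff, na.rm = TRUE) + sum(counts$s_diff, na.rm = TRUE)
  if (tot == 0) {
    rlang::abort("no substitutions observed: null fraction undefined",
                 class = "wgdclock_undefined_null")
  }
  sum(counts$n_diff, na.rm = TRUE) / tot
}

#' Per-GO-category binomial test for excess nonsynonymous change
#'
#' For each GO category with more than `min_orthologs - 1` member
#' orthologs, sums the members' nonsynonymous (`a_obs`) and synonymous
#' (`s_obs`) substitution counts and computes the one-sided exact
#' binomial tail `P[X >= a_obs]` for
#' `X ~ Binomial(a_obs + s_obs, p_expect)`. Pathway-averaged counts are
#' fractional; totals are rounded to the nearest integer for the exact
#' test. A gene contributes to every category it is annotated to.
#'
#' @param counts Per-ortholog counts: data frame with columns `gene`
#'   (or `id_a`, taken as the gene id), `n_diff`, `s_diff`.
#' @param gene2go Data frame with columns `gene`, `go_id`.
#' @param p_expect Null nonsynonymous fraction; default computed from
#'   `counts` via [genome_wide_expectation()].
#' @param min_orthologs Minimum category size actually tested
#'   (default 21, i.e. "more than 20 orthologs"); smaller categories
#'   are reported with `tested = FALSE`.
#' @param alternative `"greater"` (excess nonsynonymous, the default)
#'   or `"two.sided"`.
#' @param bh Add a Benjamini-Hochberg FDR column over tested
#'   categories (default TRUE; the raw p-values remain the primary
#'   output).
#' @return A tibble with one row per GO category: `go_id`,
#'   `n_orthologs`, `a_obs`, `s_obs`, `p_expect`, `tested`, `p_value`,
#'   `bh_fdr`, `flags` (`untestable` when a tested category has zero
#'   substitutions).
#' @export
category_test <- function(counts, gene2go, p_expect = NULL,
                          min_orthologs = 21,
                          alternative = c("greater", "two.sided"),
                          bh = TRUE) {
  alternative <- match.arg(alternative)
  if (!"gene" %in% names(counts) && "id_a" %in% names(counts)) {
    counts$gene <- counts$id_a
  }
  stopifnot(all(c("gene", "n_diff", "s_diff") %in% names(counts)),
            all(c("gene", "go_id") %in% names(gene2go)))
  if (is.null(p_expect)) p_expect <- genome_wide_expectation(counts)
  stopifnot(p_expect >= 0, p_expect <= 1)
  joined <- dplyr::inner_join(gene2go, counts, by = "gene",
                              relationship = "many-to-many")
  per_cat <- joined |>
    dplyr::group_by(.data$go_id) |>
    dplyr::summarise(n_orthologs = dplyr::n_distinct(.data$gene),
                     a_obs = sum(.data$n_diff, na.rm = TRUE),
                     s_obs = sum(.data$s_diff, na.rm = TRUE),
                     .groups = "drop")
  # categories present in the GO universe but with no scored member
  empty <- setdiff(unique(gene2go$go_id), per_cat$go_id)
  if (length(empty) > 0) {
    per_cat <- dplyr::bind_rows(
      per_cat,
      tibble::tibble(go_id = empty, n_orthologs = 0L, a_obs = 0, s_obs = 0))
  }
  per_cat$p_expect <- p_expect
  per_cat$tested <- per_cat$n_orthologs >= min_orthologs
  a_r <- round(per_cat$a_obs)
  n_r <- round(per_cat$a_obs + per_cat$s_obs)
  upper <- stats::pbinom(a_r - 1, n_r, p_expect, lower.tail = FALSE)
  if (alternative == "greater") {
    pv <- upper
  } else {
    lower <- stats::pbinom(a_r, n_r, p_expect)
    pv <- pmin(1, 2 * pmin(upper, lower))
  }
  per_cat$p_value <- ifelse(per_cat$tested & n_r > 0, pv, NA_real_)
  per_cat$flags <- ifelse(per_cat$tested & n_r == 0, "untestable", "")
  per_cat$bh_fdr <- NA_real_
  if (bh) {
    idx <- which(per_cat$tested & !is.na(per_cat$p_value))
    per_cat$bh_fdr[idx] <- stats::p.adjust(per_cat$p_value[idx], "BH")
  }
  dplyr::arrange(per_cat, .data$p_value)
}

#' Contrast per-category acceleration between two lineages
#'
#' Labels each GO category as accelerated in the focal lineage, in the
#' other lineage, in both, or in neither: a category is accelerated in
#' a lineage when its one-sided binomial p-value is below `alpha`
#' there and not in the contrast lineage (`"both"` when below in
#' both).
#'
#' @param results_focal,results_other Tibbles from [category_test()]
#'   for the two lineages, computed on the same GO universe.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `go_id`, per-lineage `p_value_focal`,
#'   `p_value_other`, member counts, and `accelerated_in` in
#'   `{"focal", "other", "both", "neither"}`; sorted by the smaller of
#'   the two p-values.
#' @export
two_lineage_contrast <- function(results_focal, results_other,
                                 alpha = 0.05) {
  uf <- sort(unique(results_focal$go_id))
  uo <- sort(unique(results_other$go_id))
  if (!identical(uf, uo)) {
    extra_f <- setdiff(uf, uo)
    extra_o <- setdiff(uo, uf)
    rlang::abort(
      paste0("GO universes differ; only in focal: ",
             paste(utils::head(extra_f, 5), collapse = ","),
             "; only in other: ",
             paste(utils::head(extra_o, 5), collapse = ",")),
      class = "wgdclock_universe_mismatch")
  }
  merged <- dplyr::inner_join(
    dplyr::select(results_focal, "go_id", n_focal = "n_orthologs",
                  p_value_focal = "p_value"),
    dplyr::select(results_other, "go_id", n_other = "n_orthologs",
                  p_value_other = "p_value"),
    by = "go_id")
  sig_f <- !is.na(merged$p_value_focal) & merged$p_value_focal < alpha
  sig_o <- !is.na(merged$p_value_other) & merged$p_value_other < alpha
  merged$accelerated_in <- dplyr::case_when(
    sig_f & sig_o ~ "both",
    sig_f ~ "focal",
    sig_o ~ "other",
    TRUE ~ "neither")
  merged$min_p <- pmin(merged$p_value_focal, merged$p_value_other,
                       na.rm = TRUE)
  merged$min_p[is.na(merged$p_value_focal) & is.na(merged$p_value_other)] <- NA
  dplyr::arrange(merged, .data$min_p)
}
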