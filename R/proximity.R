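# TE-to-gene proximity: distances and intact-vs-fragmentary tests.

.validate_intervals <- function(x, chromosomes, what) {
  bad_chrom <- setdiff(unique(x$chrom), chromosomes$name)
  if (length(bad_chrom) > 0) {
    rlang::abort(paste0(what, " on undeclared chromosome: ",
                        paste(bad_chrom, collapse = ", ")),
                 class = "wgdclock_validation_error")
  }
  len <- chromosomes$length[match(x$chrom, chromosomes$name)]
  bad <- which(!(x$start >= 0 & x$start < x$end & x$end <= len))
  if (length(bad) > 0) {
    rlang::abort(paste0(what, " interval out of bounds: ",
                        x$id[bad[1]], " (", x$chrom[bad[1]], ":",
                        x$start[bad[1]], "-", x$end[bad[1]], ")"),
                 class = "wgdclock_validation_error")
  }
  invisible(TRUE)
}

.to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Distance from each TE to its nearest gene
#'
#' Computes, for every transposable-element interval, the gap in bp to
#' the nearest gene on the same chromosome (0 when the TE overlaps or
#' abuts a gene). Coordinates are 0-based half-open; strand is
#' ignored. TEs on chromosomes without any gene get `NA` with flag
#' `no_gene_on_chrom`.
#'
#' @param genes Gene intervals: data frame with `chrom`, `start`,
#'   `end` (and optionally `id`), e.g. from [read_gene_gff()].
#' @param tes TE intervals: data frame with `chrom`, `start`, `end`,
#'   `id`, `superfamily`, `status`, e.g. from [read_te_bed()].
#' @param chromosomes Optional data frame with `name`, `length` used
#'   to validate interval bounds.
#' @return `tes` with added columns `distance_bp` and `flags`.
#' @export
nearest_gene_distance <- function(genes, tes, chromosomes = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(genes)),
            all(c("chrom", "start", "end") %in% names(tes)))
  if (!"id" %in% names(genes)) genes$id <- paste0("g", seq_len(nrow(genes)))
  if (!"id" %in% names(tes)) tes$id <- paste0("te", seq_len(nrow(tes)))
  if (!is.null(chromosomes)) {
    .validate_intervals(genes, chromosomes, "gene")
    .validate_intervals(tes, chromosomes, "TE")
  }
  gr_genes <- .to_granges(genes)
  gr_tes <- .to_granges(tes)
  hits <- GenomicRanges::distanceToNearest(gr_tes, gr_genes,
                                           ignore.strand = TRUE)
  d <- rep(NA_real_, nrow(tes))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out <- tibble::as_tibble(tes)
  out$distance_bp <- d
  out$flags <- ifelse(is.na(d), "no_gene_on_chrom", "")
  out
}

#' Test whether intact TEs lie closer to genes than fragmentary TEs
#'
#' Primary test: chi-square (no continuity correction) on the 2x2
#' table of status (intact / fragmentary) against distance class
#' (within vs beyond `bin_edge_bp` of the nearest gene). Secondary:
#' Wilcoxon rank-sum on the raw distance distributions. Both are run
#' pooled and per superfamily; direction is reported by group medians.
#'
#' @param distances Output of [nearest_gene_distance()] (needs
#'   `distance_bp`, `status`, `superfamily`).
#' @param bin_edge_bp Distance threshold for the chi-square binning
#'   (default 1000).
#' @param min_group Minimum TEs per compared group (default 20).
#' @return A list of class `te_proximity`: `summary` (per status x
#'   superfamily cell: `n`, `median_bp`, `mean_bp`) and `tests`
#'   (per comparison: `superfamily` with `"all"` pooled, `n_intact`,
#'   `n_fragmentary`, `chisq_p`, `ranksum_p`, `closer_group`).
#' @export
proximity_test <- function(distances, bin_edge_bp = 1000, min_group = 20) {
  stopifnot(all(c("distance_bp", "status") %in% names(distances)))
  d <- dplyr::filter(distances, !is.na(.data$distance_bp))
  if (!"superfamily" %in% names(d)) d$superfamily <- "other"
  for (st in c("intact", "fragmentary")) {
    if (sum(d$status == st) == 0) {
      rlang::abort(paste0("empty group: ", st),
                   class = "wgdclock_empty_group")
    }
  }
  summ <- d |>
    dplyr::group_by(.data$status, .data$superfamily) |>
    dplyr::summarise(n = dplyr::n(),
                     median_bp = stats::median(.data$distance_bp),
                     mean_bp = mean(.data$distance_bp), .groups = "drop")
  one_test <- function(dd, sf) {
    di <- dd$distance_bp[dd$status == "intact"]
    df_ <- dd$distance_bp[dd$status == "fragmentary"]
    if (length(di) < min_group || length(df_) < min_group) {
      return(tibble::tibble(superfamily = sf, n_intact = length(di),
                            n_fragmentary = length(df_),
                            chisq_p = NA_real_, ranksum_p = NA_real_,
                            closer_group = NA_character_))
    }
    tab <- rbind(intact = c(sum(di <= bin_edge_bp), sum(di > bin_edge_bp)),
                 fragmentary = c(sum(df_ <= bin_edge_bp), sum(df_ > bin_edge_bp)))
    chisq_p <- if (any(colSums(tab) == 0)) 1 else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    rs <- suppressWarnings(stats::wilcox.test(di, df_))
    closer <- if (stats::median(di) < stats::median(df_)) "intact"
              else if (stats::median(di) > stats::median(df_)) "fragmentary"
              else "tie"
    tibble::tibble(superfamily = sf, n_intact = length(di),
                   n_fragmentary = length(df_), chisq_p = chisq_p,
                   ranksum_p = rs$p.value, closer_group = closer)
  }
  tests <- dplyr::bind_rows(
    one_test(d, "all"),
    purrr::map(split(d, d$superfamily), one_test, sf = NA_character_) |>
      purrr::imap(~ dplyr::mutate(.x, superfamily = .y)) |>
      purrr::list_rbind()
  )
  structure(list(summary = summ, tests = tests,
                 bin_edge_bp = bin_edge_bp),
            class = "te_proximity")
}

#' @export
print.te_proximity <- function(x, ...) {
  cat("TE proximity to genes (chi-square bin edge",
      x$bin_edge_bp, "bp)\n")
  print(x$tests)
  invisible(x)
}

#' Plot TE-to-gene distance distributions by status
#'
#' @param object A `te_proximity` result (plots its summary) or the
#'   distance tibble from [nearest_gene_distance()].
#' @param distances Distance tibble (required when `object` is a
#'   `te_proximity`).
#' @param ... Unused.
#' @return A ggplot of log10 distance by status and superfamily.
#' @export
plot_te_distance <- function(object, distances = NULL, ...) {
  d <- if (is.data.frame(object)) object else distances
  if (is.null(d)) rlang::abort("supply the per-TE distance table")
  d <- dplyr::filter(d, !is.na(.data$distance_bp))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$status,
                                  y = .data$distance_bp + 1,
                                  fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ superfamily) +
    ggplot2::labs(x = NULL, y = "distance to nearest gene + 1 (bp)") +
    ggplot2::guides(fill = "none")
}
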