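#' Attach Ka/Ks estimates to collinearity anchors
#'
#' Joins a Ka/Ks table (from [kaks()]) onto an anchor table by the
#' `(gene_a, gene_b)` pair, matching either orientation.
#'
#' @param anchors Anchor tibble from [read_anchors()] (columns
#'   `block_id`, `gene_a`, `gene_b`).
#' @param kaks_tbl Ka/Ks tibble with columns `id_a`, `id_b`, `ks`.
#' @return `anchors` with a `ks` column (NA where no estimate exists).
#' @export
attach_ks <- function(anchors, kaks_tbl) {
  key <- dplyr::bind_rows(
    dplyr::select(kaks_tbl, gene_a = "id_a", gene_b = "id_b", "ks"),
    dplyr::select(kaks_tbl, gene_a = "id_b", gene_b = "id_a", "ks")
  )
  key <- dplyr::distinct(key, .data$gene_a, .data$gene_b, .keep_all = TRUE)
  anchors$ks <- NULL
  dplyr::left_join(anchors, key, by = c("gene_a", "gene_b"))
}

#' Block-median Ks distribution from anchored pairs
#'
#' Computes the median Ks of every syntenic block from its usable
#' anchor pairs and keeps blocks with at least `min_pairs` usable
#' pairs. A pair is usable when its Ks is non-missing (saturated
#' estimates arrive as NA), positive, and at most `ks_max`. The
#' usability filter is applied before the block-size threshold, so the
#' threshold counts usable pairs only.
#'
#' @param anchors Anchor tibble with a `ks` column (see [attach_ks()]).
#' @param min_pairs Minimum usable pairs for a block to be retained
#'   (default 10, the conventional "at least 10 collinear genes" block
#'   filter).
#' @param ks_max Ks ceiling for inclusion (default 5).
#' @param label Comparison name carried into the output.
#' @return A tibble with columns `block_id`, `n_pairs`, `median_ks`,
#'   `label`, containing only retained blocks; attribute `rejected`
#'   lists blocks that failed the size filter.
#' @export
block_median_ks <- function(anchors, min_pairs = 10, ks_max = 5,
                            label = "ks") {
  stopifnot("ks" %in% names(anchors))
  usable <- dplyr::filter(anchors, !is.na(.data$ks), .data$ks > 0,
                          .data$ks <= ks_max)
  med <- usable |>
    dplyr::group_by(.data$block_id) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     median_ks = stats::median(.data$ks), .groups = "drop")
  keep <- dplyr::filter(med, .data$n_pairs >= min_pairs)
  keep$label <- label
  attr(keep, "rejected") <- dplyr::filter(med, .data$n_pairs < min_pairs)$block_id
  attr(keep, "min_pairs") <- min_pairs
  keep
}
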