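#' Read codon-aligned sequence pairs from a paired FASTA file
#'
#' The file must contain an even number of records; consecutive records
#' (1st/2nd, 3rd/4th, ...) form one aligned pair.
#'
#' @param path Path to a FASTA file of aligned CDS.
#' @return A tibble with columns `id_a`, `id_b`, `seq_a`, `seq_b`.
#' @export
read_paired_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) %% 2L != 0L) {
    rlang::abort("paired FASTA must contain an even number of records")
  }
  odd <- seq(1L, length(x), 2L)
  tibble::tibble(
    id_a = names(x)[odd],
    id_b = names(x)[odd + 1L],
    seq_a = unname(as.character(x[odd])),
    seq_b = unname(as.character(x[odd + 1L]))
  )
}

#' Read aligned 5'/3' LTR pairs from FASTA
#'
#' Records are matched by element id: `<id>:5ltr` and `<id>:3ltr`
#' suffixes name the two aligned LTR copies of one element. A record
#' description may carry `superfamily=<name>` after whitespace.
#'
#' @param path Path to an LTR FASTA file.
#' @return A tibble with columns `element_id`, `superfamily`, `seq5`,
#'   `seq3`.
#' @export
read_ltr_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  full <- names(x)
  id_part <- sub("\\s.*$", "", full)
  sf <- ifelse(grepl("superfamily=", full),
               sub(".*superfamily=(\\S+).*", "\\1", full), "other")
  end <- sub(".*:(5ltr|3ltr)$", "\\1", id_part)
  elem <- sub(":(5ltr|3ltr)$", "", id_part)
  if (!all(end %in% c("5ltr", "3ltr"))) {
    rlang::abort("every record name must end in ':5ltr' or ':3ltr'")
  }
  d5 <- tibble::tibble(element_id = elem[end == "5ltr"],
                       superfamily = sf[end == "5ltr"],
                       seq5 = unname(as.character(x[end == "5ltr"])))
  d3 <- tibble::tibble(element_id = elem[end == "3ltr"],
                       seq3 = unname(as.character(x[end == "3ltr"])))
  out <- dplyr::inner_join(d5, d3, by = "element_id")
  if (nrow(out) * 2L != length(x)) {
    rlang::abort("unmatched 5'/3' LTR records in file")
  }
  out
}

#' Read a collinearity anchor table
#'
#' Accepts either a minimal TSV with header columns `block_id`,
#' `gene_a`, `gene_b` (optional `ks`), or an MCScanX-style
#' `.collinearity` text in which `## Alignment n` headers open blocks
#' and subsequent non-comment lines carry two gene ids.
#'
#' Duplicate `(gene_a, gene_b)` rows within a block are collapsed;
#' within-block row order is preserved.
#'
#' @param path Path to the anchor table.
#' @return A tibble with columns `block_id`, `gene_a`, `gene_b` and,
#'   when present in the input, `ks`.
#' @export
read_anchors <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(block_id = character(), gene_a = character(),
                          gene_b = character()))
  }
  if (any(grepl("^## Alignment", lines))) {
    return(.read_mcscanx(lines))
  }
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!all(c("block_id", "gene_a", "gene_b") %in% hdr)) {
    rlang::abort("anchor TSV must have columns block_id, gene_a, gene_b")
  }
  body <- lines[-1]
  body <- body[!startsWith(body, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(hdr))
  if (length(bad) > 0L) {
    rlang::abort(paste0("malformed anchor row at line ", bad[1] + 1L))
  }
  m <- do.call(rbind, fields)
  colnames(m) <- hdr
  out <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  if ("ks" %in% names(out)) {
    out$ks <- suppressWarnings(as.numeric(out$ks))
  }
  dplyr::distinct(out, .data$block_id, .data$gene_a, .data$gene_b,
                  .keep_all = TRUE)
}

.read_mcscanx <- function(lines) {
  block <- NA_character_
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^## Alignment", ln)) {
      block <- sub("^## Alignment\\s+(\\S+).*", "\\1", ln)
      block <- sub(":$", "", block)
    } else if (startsWith(ln, "#")) {
      next
    } else {
      if (is.na(block)) {
        rlang::abort(paste0("anchor line before any '## Alignment' header at line ", i))
      }
      f <- strsplit(trimws(ln), "[\t ]+")[[1]]
      f <- f[nzchar(f)]
      if (length(f) < 2L) {
        rlang::abort(paste0("malformed collinearity row at line ", i))
      }
      # MCScanX rows look like "  0-  0:  geneA  geneB  e-value";
      # drop the block-pair index tokens before taking the gene ids
      genes <- f[!grepl("^[0-9]+-$|:$", f)]
      out[[length(out) + 1L]] <- tibble::tibble(
        block_id = block, gene_a = genes[1], gene_b = genes[2]
      )
    }
  }
  dplyr::distinct(purrr::list_rbind(out), .data$block_id, .data$gene_a,
                  .data$gene_b, .keep_all = TRUE)
}

#' Read gene intervals from a GFF3 file
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type to keep (default `"gene"`).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based,
#'   half-open), `strand`, `id`.
#' @export
read_gene_gff <- function(path, feature = "gene") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == feature, logical(1))
  f <- f[keep]
  id <- vapply(f, function(x) {
    m <- regmatches(x[9], regexpr("ID=[^;]+", x[9]))
    if (length(m)) sub("^ID=", "", m) else x[9]
  }, character(1))
  tibble::tibble(
    chrom = vapply(f, `[[`, character(1), 1),
    start = as.integer(vapply(f, `[[`, character(1), 4)) - 1L,
    end = as.integer(vapply(f, `[[`, character(1), 5)),
    strand = vapply(f, `[[`, character(1), 7),
    id = id
  )
}

#' Read transposable-element intervals from a BED-like TSV
#'
#' Expected columns (no header): chrom, start, end, id, superfamily,
#' status. Coordinates are 0-based half-open as in BED.
#'
#' @param path Path to the TE table.
#' @return A tibble with columns `chrom`, `start`, `end`, `id`,
#'   `superfamily`, `status`.
#' @export
read_te_bed <- function(path) {
  out <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "id", "superfamily", "status"),
    col_types = "ciiccc", comment = "#", progress = FALSE
  )
  bad <- setdiff(unique(out$status), c("intact", "fragmentary"))
  if (length(bad) > 0L) {
    rlang::abort(paste0("unknown TE status: ", paste(bad, collapse = ", ")))
  }
  out
}

#' Read a gene-to-GO mapping table
#'
#' @param path TSV with two columns (gene id, GO id), one annotation
#'   per line, optional header `gene`/`go_id`.
#' @return A tibble with columns `gene`, `go_id`.
#' @export
read_gene2go <- function(path) {
  out <- readr::read_tsv(path, col_names = c("gene", "go_id"),
                         col_types = "cc", comment = "#", progress = FALSE)
  if (nrow(out) > 0 && out$gene[1] == "gene" && out$go_id[1] == "go_id") {
    out <- out[-1, ]
  }
  out
}

#' Write a tibble as TSV with a commented metadata block
#'
#' The universal inter-stage format of the pipeline: a block of
#' `#key=value` lines followed by a header line and tab-separated rows.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param meta Named list of metadata values written as `#key=value`.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(paste0("#", k, "=", format(meta[[k]], scientific = FALSE)), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_stage_tsv()]
#'
#' @param path Input path.
#' @return A tibble; the metadata block is attached as attribute
#'   `meta` (named character vector).
#' @export
read_stage_tsv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[cumsum(!is_meta) == 0 & is_meta]
  meta <- NULL
  if (length(meta_lines) > 0) {
    kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
    meta <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                                   character(1)),
                            vapply(kv, `[[`, character(1), 1))
  }
  out <- readr::read_tsv(I(paste(lines[!startsWith(lines, "#")], collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE)
  attr(out, "meta") <- meta
  out
}
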