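#' Divergence between the two LTRs of a retrotransposon
#'
#' The 5' and 3' LTRs of a retroelement are identical at insertion, so
#' their present-day divergence is a clock. Divergence is computed over
#' comparable columns (both bases in A/C/G/T) as the mismatch
#' proportion, corrected for multiple hits under Jukes-Cantor (default)
#' or Kimura two-parameter.
#'
#' @param pairs A data frame with columns `element_id`, `seq5`, `seq3`
#'   (aligned, equal length) and optionally `superfamily`, e.g. from
#'   [read_ltr_fasta()] or [simulate_ltr_pairs()].
#' @param model `"JC69"` or `"K2P"`.
#' @param min_columns Minimum comparable aligned columns per pair
#'   (default 50); pairs below it are flagged `insufficient_data` with
#'   `k = NA`.
#' @return The input tibble with added columns `comparable_columns`,
#'   `p` (mismatch proportion), `k` (corrected divergence), `flags`.
#' @export
ltr_divergence <- function(pairs, model = c("JC69", "K2P"),
                           min_columns = 50) {
  model <- match.arg(model)
  stopifnot(all(c("element_id", "seq5", "seq3") %in% names(pairs)))
  res <- purrr::map2(pairs$seq5, pairs$seq3, function(s5, s3) {
    if (nchar(s5) != nchar(s3)) {
      rlang::abort("aligned LTR sequences differ in length",
                   class = "wgdclock_invalid_alignment")
    }
    a <- strsplit(toupper(s5), "", fixed = TRUE)[[1]]
    b <- strsplit(toupper(s3), "", fixed = TRUE)[[1]]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    nc <- sum(ok)
    if (nc < min_columns) {
      return(list(nc = nc, p = NA_real_, k = NA_real_,
                  flags = "insufficient_data"))
    }
    a <- a[ok]; b <- b[ok]
    mism <- a != b
    p <- mean(mism)
    if (model == "JC69") {
      if (p >= 0.75) {
        return(list(nc = nc, p = p, k = NA_real_, flags = "saturated"))
      }
      k <- -0.75 * log(1 - (4 / 3) * p)
    } else {
      purine <- c("A", "G")
      transition <- mism & ((a %in% purine) == (b %in% purine))
      P <- mean(transition)
      Q <- p - P
      arg1 <- 1 - 2 * P - Q
      arg2 <- 1 - 2 * Q
      if (arg1 <= 0 || arg2 <= 0) {
        return(list(nc = nc, p = p, k = NA_real_, flags = "saturated"))
      }
      k <- -0.5 * log(arg1) - 0.25 * log(arg2)
    }
    list(nc = nc, p = p, k = k, flags = "")
  })
  out <- pairs
  out$comparable_columns <- vapply(res, `[[`, numeric(1), "nc")
  out$p <- vapply(res, `[[`, numeric(1), "p")
  out$k <- vapply(res, `[[`, numeric(1), "k")
  out$flags <- vapply(res, `[[`, character(1), "flags")
  out$model <- model
  tibble::as_tibble(out)
}

#' Insertion age from LTR divergence
#'
#' `T = K / (2 mu)`: both LTR copies accumulate substitutions, so the
#' pairwise divergence grows at twice the per-copy rate.
#'
#' @param k Corrected LTR divergence (substitutions per site).
#' @param mu Substitution rate per site per year.
#' @return Insertion age in Ma.
#' @examples
#' insertion_time(0.01412, 7.06e-9) # about 1 Ma
#' @export
insertion_time <- function(k, mu) {
  if (any(mu <= 0)) {
    rlang::abort("mu must be positive", class = "wgdclock_domain_error")
  }
  if (any(k < 0, na.rm = TRUE)) {
    rlang::abort("k must be nonnegative", class = "wgdclock_domain_error")
  }
  k / (2 * mu * 1e6)
}

#' Insertion-time profile of an LTR cohort
#'
#' Dates every element ([ltr_divergence()] + [insertion_time()]) and
#' bins the ages into a histogram, overall and per superfamily.
#'
#' @param pairs As in [ltr_divergence()]; needs at least 20 datable
#'   pairs.
#' @param mu Substitution rate per site per year.
#' @param bin_width_ma Histogram bin width in Ma (default 0.1).
#' @param model Distance model, see [ltr_divergence()].
#' @return A list of class `ltr_profile`: `ages` (per-element tibble
#'   with `t_ma`), `histogram` (tibble: `superfamily`, `bin_mid`,
#'   `count`; superfamily `"all"` pools everything), and `summary`
#'   (per-superfamily `mode_ma`, `mean_ma`, `median_ma`, `n`).
#' @export
insertion_time_profile <- function(pairs, mu, bin_width_ma = 0.1,
                                   model = "JC69") {
  div <- ltr_divergence(pairs, model = model)
  div$t_ma <- insertion_time(ifelse(is.na(div$k), NA_real_, div$k), mu)
  dated <- dplyr::filter(div, !is.na(.data$t_ma))
  if (nrow(dated) < 20) {
    rlang::abort("need at least 20 datable LTR pairs",
                 class = "wgdclock_insufficient_data")
  }
  if (!"superfamily" %in% names(dated)) dated$superfamily <- "other"
  breaks <- seq(0, max(dated$t_ma) + bin_width_ma, by = bin_width_ma)
  hist_of <- function(t, sf) {
    ct <- table(cut(t, breaks, right = FALSE, include.lowest = TRUE))
    tibble::tibble(superfamily = sf,
                   bin_mid = utils::head(breaks, -1) + bin_width_ma / 2,
                   count = as.integer(ct))
  }
  hists <- dplyr::bind_rows(
    hist_of(dated$t_ma, "all"),
    purrr::map(split(dated$t_ma, dated$superfamily),
               ~ hist_of(.x, NA_character_)) |>
      purrr::imap(~ dplyr::mutate(.x, superfamily = .y)) |>
      purrr::list_rbind()
  )
  summ <- hists |>
    dplyr::group_by(.data$superfamily) |>
    dplyr::summarise(mode_ma = .data$bin_mid[which.max(.data$count)],
                     .groups = "drop") |>
    dplyr::left_join(
      dplyr::bind_rows(
        dated |> dplyr::group_by(.data$superfamily) |>
          dplyr::summarise(mean_ma = mean(.data$t_ma),
                           median_ma = stats::median(.data$t_ma),
                           n = dplyr::n(), .groups = "drop"),
        tibble::tibble(superfamily = "all", mean_ma = mean(dated$t_ma),
                       median_ma = stats::median(dated$t_ma),
                       n = nrow(dated))
      ),
      by = "superfamily"
    )
  structure(list(ages = tibble::as_tibble(div), histogram = hists,
                 summary = summ, mu = mu, model = model,
                 bin_width_ma = bin_width_ma),
            class = "ltr_profile")
}

#' @export
print.ltr_profile <- function(x, ...) {
  cat("LTR insertion-time profile (mu =", format(x$mu), "per site/yr,",
      x$model, ")\n")
  print(x$summary)
  invisible(x)
}

#' Plot an LTR insertion-time profile
#'
#' @param object An `ltr_profile` from [insertion_time_profile()].
#' @param ... Unused.
#' @return A ggplot of per-superfamily insertion-age histograms.
#' @export
autoplot.ltr_profile <- function(object, ...) {
  df <- dplyr::filter(object$histogram, .data$superfamily != "all")
  if (nrow(df) == 0) df <- object$histogram
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$count,
                                   fill = .data$superfamily)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "insertion age (Ma)", y = "elements",
                  fill = "superfamily")
}
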