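# Gaussian mixture fitting of block-median Ks distributions by EM.

# One EM run at fixed k from a given initialisation. Returns NULL on
# degeneracy (starved component or collapsing variance).
.em_from_init <- function(x, mu, sd_, w, max_iter = 2000, tol = 1e-8,
                          check_monotone = TRUE) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  pruned <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      log(w[j]) + stats::dnorm(x, mu[j], sd_[j], log = TRUE)
    }, numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    if (check_monotone && ll < ll_old - 1e-6 * (abs(ll_old) + 1)) {
      rlang::abort("EM log-likelihood decreased", class = "wgdclock_em_error")
    }
    resp <- exp(logd - lse)           # n x k posterior responsibilities
    nk <- colSums(resp)
    if (any(nk < 2) || any(!is.finite(nk))) {
      return(NULL)                    # degenerate: component starved
    }
    mu <- colSums(resp * x) / nk
    sd_ <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    if (any(sd_ < 1e-6)) {
      return(NULL)                    # degenerate: collapsing variance
    }
    w <- nk / n
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  o <- order(mu)
  list(mean = mu[o], sd = sd_[o], weight = w[o], loglik = ll_old,
       iterations = it, resp = resp[, o, drop = FALSE])
}

# Multi-start EM: kmeans, quantile-spread, and random initialisations;
# the run with the best log-likelihood wins. Returns NULL only when
# every start degenerates.
.em_gaussian <- function(x, k, max_iter = 2000, tol = 1e-8,
                         check_monotone = TRUE, n_init = 10) {
  n <- length(x)
  if (k == 1L) {
    mu <- mean(x); sd_ <- stats::sd(x) * sqrt((n - 1) / n)
    if (sd_ <= 0) sd_ <- 1e-6
    ll <- sum(stats::dnorm(x, mu, sd_, log = TRUE))
    return(list(mean = mu, sd = sd_, weight = 1, loglik = ll,
                iterations = 0L))
  }
  sx <- stats::sd(x)
  inits <- list()
  km <- tryCatch(suppressWarnings(stats::kmeans(x, centers = k, nstart = 5)),
                 error = function(e) NULL)
  if (!is.null(km)) {
    sd0 <- vapply(seq_len(k), function(j) {
      xs <- x[km$cluster == j]
      s <- if (length(xs) > 1) stats::sd(xs) else 0
      max(s, sx / (4 * k), 1e-4)
    }, numeric(1))
    inits[[1]] <- list(
      mu = as.numeric(km$centers), sd = sd0,
      w = as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n)
  }
  inits[[length(inits) + 1L]] <- list(
    mu = as.numeric(stats::quantile(x, (seq_len(k) - 0.5) / k)),
    sd = rep(max(sx / k, 1e-4), k), w = rep(1 / k, k))
  while (length(inits) < n_init) {
    inits[[length(inits) + 1L]] <- list(
      mu = sort(sample(x, k)), sd = rep(max(sx / (2 * k), 1e-4), k),
      w = rep(1 / k, k))
  }
  # coarse short runs for every start, full-tolerance polish of the best
  best <- NULL
  for (ini in inits) {
    fit <- .em_from_init(x, ini$mu, ini$sd, ini$w,
                         max_iter = min(max_iter, 150L),
                         tol = max(tol, 1e-5),
                         check_monotone = check_monotone)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (is.null(best)) return(NULL)
  polished <- .em_from_init(x, best$mean, best$sd, best$weight,
                            max_iter = max_iter, tol = tol,
                            check_monotone = check_monotone)
  if (is.null(polished)) best else polished
}

.ks_values <- function(dist) {
  if (is.data.frame(dist)) {
    stopifnot("median_ks" %in% names(dist))
    dist$median_ks
  } else {
    as.numeric(dist)
  }
}

#' Fit a Gaussian mixture to a Ks distribution
#'
#' Fits a finite Gaussian mixture to block-median Ks values by
#' expectation-maximisation, either at a fixed number of components or
#' selecting it in 1..`k_max` by lowest BIC. Initialisation is by
#' k-means from the given seed; EM runs to a relative log-likelihood
#' change below `tol` or `max_iter` iterations. A component whose
#' variance collapses is pruned and the model refit at k-1 (flagged).
#'
#' @param dist Numeric vector of Ks values, or a tibble with a
#'   `median_ks` column (e.g. from [block_median_ks()]).
#' @param k Number of components, or `"auto"` for BIC selection.
#' @param window Ks window (exclusive lower, inclusive upper bound)
#'   retained before fitting; default `c(0, 3)`.
#' @param log_scale Fit in log(Ks) space instead of raw Ks.
#' @param seed Integer seed controlling the k-means initialisation.
#' @param k_max Largest k tried in auto mode.
#' @param max_iter,tol EM stopping rule.
#' @param label Comparison name carried into the result.
#' @return An object of class `ks_peaks`: list with `components`
#'   (tibble: `component`, `mean`, `sd`, `weight`), `loglik`, `bic`,
#'   `k`, `n_values`, `values`, `flags`, `label`. Means are sorted
#'   ascending. Use [tidy()][generics::tidy] / [glance()]
#'   [generics::glance] / [ggplot2::autoplot()] on it.
#' @export
fit_ks_peaks <- function(dist, k = "auto", window = c(0, 3),
                         log_scale = FALSE, seed = 20221214L,
                         k_max = 5, max_iter = 2000, tol = 1e-8,
                         label = "ks") {
  x <- .ks_values(dist)
  x <- x[is.finite(x) & x > window[1] & x <= window[2]]
  if (log_scale) x <- log(x)
  ks_try <- if (identical(k, "auto")) seq_len(k_max) else as.integer(k)
  if (length(x) < 10 * min(ks_try)) {
    rlang::abort(
      paste0("insufficient data: ", length(x), " values for k >= ",
             min(ks_try), " (need >= ", 10 * min(ks_try), ")"),
      class = "wgdclock_insufficient_data")
  }
  fits <- list()
  for (kk in ks_try) {
    if (length(x) < 10 * kk) next
    flags <- character(0)
    set.seed(seed)
    fit <- .em_gaussian(x, kk, max_iter = max_iter, tol = tol)
    while (is.null(fit) && kk > 1) {
      kk <- kk - 1L
      flags <- c(flags, "component_pruned")
      set.seed(seed)
      fit <- .em_gaussian(x, kk, max_iter = max_iter, tol = tol)
    }
    if (is.null(fit)) next
    npar <- 3 * kk - 1
    fit$bic <- -2 * fit$loglik + npar * log(length(x))
    fit$k <- kk
    fit$flags <- flags
    fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0) {
    rlang::abort("no mixture fit succeeded", class = "wgdclock_em_error")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  structure(
    list(
      components = tibble::tibble(
        component = seq_len(best$k),
        mean = best$mean, sd = best$sd, weight = best$weight
      ),
      loglik = best$loglik, bic = best$bic, k = best$k,
      n_values = length(x), values = x, log_scale = log_scale,
      seed = seed, flags = best$flags, label = label
    ),
    class = "ks_peaks"
  )
}

#' @export
print.ks_peaks <- function(x, ...) {
  cat("Gaussian mixture fit (", x$k, " component",
      if (x$k > 1) "s", ") on ", x$n_values, " Ks values [",
      x$label, "]\n", sep = "")
  print(x$components)
  cat("log-likelihood:", format(x$loglik), " BIC:", format(x$bic), "\n")
  invisible(x)
}

# Best assignment of fitted means to reference means: minimal total
# |difference| over all permutations (k <= 6 keeps this exact and cheap).
.match_components <- function(fitted_means, ref_means) {
  k <- length(ref_means)
  if (length(fitted_means) != k) return(NULL)
  perms <- .ng_perms(k)
  costs <- apply(perms, 1, function(p) sum(abs(fitted_means[p] - ref_means)))
  perms[which.min(costs), ]
}

#' Bootstrap standard errors of mixture peak positions
#'
#' Resamples the Ks values with replacement, refits the k-component
#' mixture on each replicate, matches replicate components to the
#' full-sample components by nearest mean (exact minimal-cost
#' assignment over permutations), and reports the standard deviation of
#' the matched means across replicates.
#'
#' @param dist As in [fit_ks_peaks()].
#' @param k Number of components (fixed).
#' @param reps Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @param ... Passed to [fit_ks_peaks()].
#' @return The `ks_peaks` fit on the full sample with an added
#'   `se_mean` column in `components` and fields `boot_reps`,
#'   `boot_failures`.
#' @export
bootstrap_peak_se <- function(dist, k, reps = 200, seed = 20221214L, ...) {
  fit <- fit_ks_peaks(dist, k = k, seed = seed, ...)
  x <- fit$values
  ref <- fit$components$mean
  set.seed(seed + 1L)
  boot_means <- matrix(NA_real_, reps, k)
  failures <- character(0)
  for (r in seq_len(reps)) {
    xb <- sample(x, length(x), replace = TRUE)
    bf <- tryCatch(
      .em_gaussian(xb, k, check_monotone = FALSE),
      error = function(e) NULL
    )
    if (is.null(bf)) {
      failures <- c(failures, paste0("rep ", r, ": degenerate fit"))
      next
    }
    p <- .match_components(bf$mean, ref)
    boot_means[r, ] <- bf$mean[p]
  }
  if (length(failures) > 0.1 * reps) {
    rlang::abort(
      paste0("bootstrap failure rate above 10%:\n",
             paste(utils::head(failures, 5), collapse = "\n")),
      class = "wgdclock_bootstrap_error")
  }
  fit$components$se_mean <- apply(boot_means, 2, stats::sd, na.rm = TRUE)
  fit$boot_reps <- reps
  fit$boot_failures <- length(failures)
  fit
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a `ks_peaks` fit into its component table
#'
#' @param x A `ks_peaks` object.
#' @param ... Unused.
#' @return Tibble with one row per mixture component: `component`,
#'   `mean`, `sd`, `weight` (and `se_mean` after
#'   [bootstrap_peak_se()]), plus the fit `label`.
#' @export
tidy.ks_peaks <- function(x, ...) {
  out <- x$components
  out$label <- x$label
  out
}

#' One-row model summary of a `ks_peaks` fit
#'
#' @param x A `ks_peaks` object.
#' @param ... Unused.
#' @return Tibble with `k`, `loglik`, `bic`, `n_values`, `flags`.
#' @export
glance.ks_peaks <- function(x, ...) {
  tibble::tibble(k = x$k, loglik = x$loglik, bic = x$bic,
                 n_values = x$n_values,
                 flags = paste(x$flags, collapse = ";"))
}

#' Histogram of a Ks distribution with the fitted mixture density
#'
#' @param object A `ks_peaks` object.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ks_peaks <- function(object, bins = 60, ...) {
  x <- object$values
  grid <- seq(min(x), max(x), length.out = 512)
  dens <- purrr::pmap(object$components[c("mean", "sd", "weight")],
                      function(mean, sd, weight) weight * stats::dnorm(grid, mean, sd))
  df_d <- tibble::tibble(x = grid, density = Reduce(`+`, dens))
  ggplot2::ggplot(tibble::tibble(ks = x), ggplot2::aes(x = .data$ks)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = df_d,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$components$mean,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = if (object$log_scale) "log Ks" else "Ks",
                  y = "density", title = object$label)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
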