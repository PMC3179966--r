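# Constrained four-Gaussian mixture calibration of depth thresholds.
#
# The 5-kub depth distribution over single-copy calibration regions is
# modelled as a mixture of four Gaussians representing copy numbers 1-4.
# Component n is tied to the first: mean avg*n and standard deviation
# sd*sqrt(n) (Poisson-like depth variance scaling with the mean; a switch
# reverts to the linear sd*n scaling). Only (avg, sd, f1..f4) are free, with
# the fractions summing to one.

component_sd <- function(sd, n, sqrt_scaling = TRUE) {
  if (sqrt_scaling) sd * sqrt(n) else sd * n
}

#' Constrained mixture density
#'
#' `sum_{n=1..4} f_n * Normal(x; avg * n, sd * sqrt(n))`.
#'
#' @param x Depth values.
#' @param avg,sd Mean and standard deviation of the first (single-copy)
#'   Gaussian.
#' @param f Four mixture fractions summing to 1.
#' @param sqrt_scaling If `FALSE`, component n has standard deviation
#'   `sd * n` instead of `sd * sqrt(n)`.
#' @return Density values.
#' @export
dmixture <- function(x, avg, sd, f, sqrt_scaling = TRUE) {
  stopifnot(length(f) == 4, abs(sum(f) - 1) < 1e-8, all(f >= -1e-12),
            avg > 0, sd > 0)
  out <- 0
  for (n in 1:4) {
    out <- out + f[n] * dnorm(x, mean = avg * n,
                              sd = component_sd(sd, n, sqrt_scaling))
  }
  out
}

mixture_negloglik <- function(par, x, sqrt_scaling = TRUE) {
  avg <- exp(par[1]); s <- exp(par[2])
  z <- c(par[3:5], 0)
  f <- exp(z - max(z)); f <- f / sum(f)
  d <- dmixture(x, avg, s, f, sqrt_scaling)
  -sum(log(pmax(d, 1e-300)))
}

#' Fit the constrained four-Gaussian mixture
#'
#' Unbinned maximum likelihood over `(avg, sd, f1..f4)` with `f4 = 1 - f1 -
#' f2 - f3`, by direct minimisation of the negative log-likelihood
#' (Nelder-Mead then BFGS polish) over log means/SDs and softmax fractions.
#' Multi-start from the sample mode (histogram peak) and the median;
#' deterministic given the data.
#'
#' @param depths Numeric vector of 5-kub depths from calibration (single
#'   copy) regions; at least 50 observations.
#' @param init Optional list overriding the initial `avg`, `sd`, `f`.
#' @param sqrt_scaling See [dmixture()].
#' @return Object of class `wssd_mixture` with elements `avg`, `sd`, `f`,
#'   `loglik`, `n_obs`, `converged`, `sqrt_scaling`.
#' @export
fit_mixture <- function(depths, init = NULL, sqrt_scaling = TRUE) {
  x <- as.numeric(depths)
  stopifnot(all(is.finite(x)), all(x >= 0))
  if (length(x) < 50) stop("need at least 50 depth observations", call. = FALSE)
  if (stats::sd(x) < .Machine$double.eps * max(1, mean(x))) {
    stop("degenerate sample: all depths identical (sd -> 0)", call. = FALSE)
  }
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mode0 <- h$mids[which.max(h$counts)]
  mad0 <- max(stats::mad(x), 1e-3 * max(mode0, 1))
  f0 <- c(0.85, 0.10, 0.04, 0.01)
  if (!is.null(init)) {
    if (!is.null(init$avg)) mode0 <- init$avg
    if (!is.null(init$sd)) mad0 <- init$sd
    if (!is.null(init$f)) f0 <- init$f
  }
  starts <- list(
    c(log(mode0), log(mad0), log(f0[1:3] / f0[4])),
    c(log(max(median(x), 1e-6)), log(mad0), log(f0[1:3] / f0[4]))
  )
  best <- NULL
  for (p0 in starts) {
    fit <- optim(p0, mixture_negloglik, x = x, sqrt_scaling = sqrt_scaling,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
    fit <- tryCatch(
      optim(fit$par, mixture_negloglik, x = x, sqrt_scaling = sqrt_scaling,
            method = "BFGS", control = list(maxit = 200)),
      error = function(e) fit
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value)) {
    stop("mixture fit failed to produce a finite likelihood", call. = FALSE)
  }
  z <- c(best$par[3:5], 0)
  f <- exp(z - max(z)); f <- f / sum(f)
  structure(
    list(avg = exp(best$par[1]), sd = exp(best$par[2]), f = unname(f),
         loglik = -best$value, n_obs = length(x),
         converged = best$convergence == 0, sqrt_scaling = sqrt_scaling),
    class = "wssd_mixture"
  )
}

#' @export
print.wssd_mixture <- function(x, ...) {
  cat(sprintf(
    "<wssd_mixture> avg = %.2f, sd = %.2f (n = %d, logLik = %.1f)\n",
    x$avg, x$sd, x$n_obs, x$loglik
  ))
  cat(sprintf("  fractions f1..f4: %s\n",
              paste(sprintf("%.3f", x$f), collapse = ", ")))
  th <- mixture_thresholds(x)
  cat(sprintf("  borderline > %.2f, positive >= %.2f\n",
              th$borderline_cut, th$positive_cut))
  invisible(x)
}

#' @export
tidy.wssd_mixture <- function(x, ...) {
  tibble::tibble(
    term = c("avg", "sd", paste0("f", 1:4)),
    estimate = c(x$avg, x$sd, x$f)
  )
}

#' @export
glance.wssd_mixture <- function(x, ...) {
  th <- mixture_thresholds(x)
  tibble::tibble(
    logLik = x$loglik, n_obs = x$n_obs, converged = x$converged,
    borderline_cut = th$borderline_cut, positive_cut = th$positive_cut
  )
}

#' Classification thresholds from a fitted mixture
#'
#' Borderline cut `avg + 2 sd`, positive cut `avg + 3 sd`.
#'
#' @param model A `wssd_mixture`, or a list with `avg` and `sd`.
#' @return List with `borderline_cut` and `positive_cut`.
#' @export
mixture_thresholds <- function(model) {
  stopifnot(model$sd > 0)
  list(borderline_cut = model$avg + 2 * model$sd,
       positive_cut = model$avg + 3 * model$sd)
}

#' Implied sequencing coverage
#'
#' Converts a mean window depth into fold sequence coverage:
#' `read_len * avg_depth / window_size`, reported to one decimal. With the
#' defaults of this pipeline, 735 x 79.2 / 5000 = 11.6.
#'
#' @param read_len Mean clipped read length (bp).
#' @param avg_depth Mean 5-kub window depth in single-copy regions.
#' @param window_size Unmasked bases per aggregated window (default 5000).
#' @return Fold coverage, rounded to one decimal.
#' @export
implied_sequencing_coverage <- function(read_len, avg_depth,
                                        window_size = 5000) {
  stopifnot(read_len > 0, avg_depth > 0, window_size > 0)
  round(read_len * avg_depth / window_size, 1)
}

pmixture <- function(q, avg, sd, f, sqrt_scaling = TRUE) {
  out <- 0
  for (n in 1:4) {
    out <- out + f[n] * stats::pnorm(q, mean = avg * n,
                                     sd = component_sd(sd, n, sqrt_scaling))
  }
  out
}

#' Normalised residuals (pulls) of a mixture fit
#'
#' Bins the data and reports, per bin, `(N_data - N_fit) / sigma_data` with
#' `sigma_data = sqrt(N_data)` — the display-parity check that fit
#' fluctuations are statistical (pulls within about +/-3).
#'
#' @param model A fitted `wssd_mixture`.
#' @param depths The depth sample the model was fitted to.
#' @param bins Number of histogram bins (default 40).
#' @return Tibble with `mid`, `n_data`, `n_fit`, `pull`.
#' @export
mixture_pulls <- function(model, depths, bins = 40) {
  x <- as.numeric(depths)
  br <- seq(min(x), max(x), length.out = bins + 1)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  cdf <- pmixture(br, model$avg, model$sd, model$f, model$sqrt_scaling)
  n_fit <- length(x) * diff(cdf)
  tibble::tibble(
    mid = h$mids, n_data = h$counts, n_fit = n_fit,
    pull = ifelse(h$counts > 0, (h$counts - n_fit) / sqrt(h$counts), NA_real_)
  )
}

#' Depths of windows inside calibration regions
#'
#' Selects the sliding 5-kub windows whose spans lie entirely within the
#' supplied single-copy calibration regions.
#'
#' @param w5 Window tibble from [sliding_windows()].
#' @param regions Interval tibble (`chrom`, `start`, `end`) of known
#'   single-copy loci.
#' @return Numeric vector of depths.
#' @export
calibration_depths <- function(w5, regions) {
  assert_intervals(regions, "calibration regions")
  if (nrow(w5) == 0) return(numeric(0))
  u <- interval_union(regions)
  inside <- overlap_bp_per_row(w5[, c("chrom", "start", "end")], u) ==
    (w5$end - w5$start)
  w5$depth[inside]
}

#' Sample depths from a constrained mixture
#'
#' Sampling counterpart of [dmixture()]: components chosen by the fractions,
#' values from `Normal(avg * n, sd * sqrt(n))`. Negative draws are truncated
#' at 0, with a warning if more than 0.1% are truncated.
#'
#' @param avg,sd,f Mixture parameters (see [dmixture()]).
#' @param n Number of draws.
#' @param seed Optional RNG seed for reproducibility.
#' @param sqrt_scaling See [dmixture()].
#' @return Numeric vector of `n` depths.
#' @export
simulate_mixture_sample <- function(avg, sd, f, n, seed = NULL,
                                    sqrt_scaling = TRUE) {
  stopifnot(length(f) == 4, abs(sum(f) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(4, n, replace = TRUE, prob = f)
  x <- rnorm(n, mean = avg * comp, sd = component_sd(sd, comp, sqrt_scaling))
  neg <- x < 0
  if (mean(neg) > 0.001) {
    warning(sprintf("%.2f%% of draws truncated at 0", 100 * mean(neg)))
  }
  pmax(x, 0)
}

#' Plot a mixture fit over the depth histogram
#'
#' @param object A fitted `wssd_mixture`.
#' @param depths The depth sample.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wssd_mixture <- function(object, depths, bins = 60, ...) {
  x <- as.numeric(depths)
  grid <- seq(min(x), max(x), length.out = 400)
  comp <- purrr::map_dfr(1:4, function(n) {
    tibble::tibble(
      x = grid, component = paste0("G", n),
      density = object$f[n] *
        dnorm(grid, object$avg * n,
              component_sd(object$sd, n, object$sqrt_scaling))
    )
  })
  total <- tibble::tibble(x = grid, density = dmixture(
    grid, object$avg, object$sd, object$f, object$sqrt_scaling))
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(x = x),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey60"
    ) +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(.data$x, .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = total, ggplot2::aes(.data$x, .data$density),
                       linewidth = 0.9) +
    ggplot2::labs(x = "5-kub window depth", y = "density",
                  colour = "component") +
    ggplot2::theme_minimal()
}
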