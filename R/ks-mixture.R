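# Log-normal mixture modelling of Ks distributions. A WGD leaves a peak in
# the paralog Ks distribution; fitting a Gaussian mixture to log(Ks) by EM
# and selecting the component count by BIC turns the distribution into a set
# of peaks (component medians in Ks space) that can be dated against a
# calibration WGD of known age.

#' Fit a log-normal mixture to a Ks sample
#'
#' Fits Gaussian mixtures to `log(Ks)` by expectation-maximization for each
#' candidate component count, with quantile-based initialization plus random
#' restarts, and selects the component count by minimum BIC (ties broken
#' toward fewer components). Equivalent to a log-normal mixture on the Ks
#' scale; each component's Ks-space median `exp(meanlog)` is reported as a
#' peak by [extract_peaks()].
#'
#' @param ks Numeric vector of Ks values (non-finite values dropped).
#' @param k Candidate component counts (default `1:5`).
#' @param filter_range Ks values outside `[lo, hi]` are discarded before
#'   fitting (default `c(0.005, 3)`: excludes zero-inflation near 0 and
#'   saturated estimates).
#' @param n_restarts Random restarts per component count, in addition to
#'   the quantile-based start.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param min_n Minimum sample size after filtering.
#' @param seed Optional integer seed for the random restarts (fit is
#'   deterministic given `seed`).
#' @return An object of class `ks_mixture`: list with `K`, `components`
#'   (data frame `weight`, `meanlog`, `sdlog`), `loglik`, `bic`, `fits`
#'   (per-K summaries), `converged`, `loglik_trace`, `n`, `ks` (the
#'   filtered sample), `filter_range`, `seed`.
#' @examples
#' ks <- exp(log(0.2) + rnorm(500, sd = 0.25))
#' fit <- ks_mixture(ks, k = 1:3, seed = 1)
#' extract_peaks(fit)
#' @export
ks_mixture <- function(ks, k = 1:5, filter_range = c(0.005, 3),
                       n_restarts = 10, max_iter = 500, tol = 1e-8,
                       min_n = 50, seed = NULL) {
  ks <- ks[is.finite(ks)]
  ks <- ks[ks >= filter_range[1] & ks <= filter_range[2]]
  n <- length(ks)
  if (n < min_n) {
    stop("only ", n, " Ks values after filtering; need at least ", min_n,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- log(ks)
  fits <- lapply(sort(unique(as.integer(k))), function(K) {
    best <- NULL
    for (rs in 0:n_restarts) {
      init <- .em_init(x, K, random = rs > 0)
      f <- .em_lognormal(x, init, max_iter = max_iter, tol = tol)
      if (is.null(best) || (f$converged && !best$converged) ||
          (f$converged == best$converged && f$loglik > best$loglik)) {
        best <- f
      }
    }
    best$K <- K
    best$bic <- -2 * best$loglik + (3 * K - 1) * log(n)
    best
  })
  bics <- vapply(fits, function(f) if (f$converged) f$bic else Inf,
                 numeric(1))
  if (all(!is.finite(bics))) {
    warning("no candidate fit converged; returning best unconverged fit")
    bics <- vapply(fits, `[[`, numeric(1), "bic")
  }
  # ties toward smaller K: which.min takes the first (fits sorted by K)
  best <- fits[[which.min(round(bics, 9))]]
  structure(list(
    K = best$K,
    components = data.frame(weight = best$weight, meanlog = best$meanlog,
                            sdlog = best$sdlog),
    loglik = best$loglik, bic = best$bic,
    fits = data.frame(K = vapply(fits, `[[`, integer(1), "K"),
                      loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                      bic = vapply(fits, `[[`, numeric(1), "bic"),
                      converged = vapply(fits, `[[`, logical(1), "converged")),
    converged = best$converged,
    loglik_trace = best$trace,
    n = n, ks = ks, filter_range = filter_range, seed = seed,
    call = match.call()
  ), class = "ks_mixture")
}

.em_init <- function(x, K, random = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) s <- 0.1
  if (random) {
    mu <- sample(x, K)
  } else {
    mu <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  }
  list(weight = rep(1 / K, K), meanlog = mu,
       sdlog = rep(max(s / sqrt(K), 1e-3), K))
}

.em_lognormal <- function(x, init, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  K <- length(init$meanlog)
  w <- init$weight; mu <- init$meanlog; sg <- init$sdlog
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(j)
      w[j] * stats::dnorm(x, mu[j], sg[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    sg[sg < 1e-4] <- 1e-4
  }
  ord <- order(mu)
  list(weight = w[ord] / sum(w), meanlog = mu[ord], sdlog = sg[ord],
       loglik = ll, converged = converged, trace = trace)
}

#' @export
print.ks_mixture <- function(x, digits = 4, ...) {
  cat(sprintf("Log-normal Ks mixture: K = %d components, n = %d (BIC %.1f%s)\n",
              x$K, x$n, x$bic,
              if (x$converged) "" else ", NOT converged"))
  comp <- x$components
  comp$peak_ks <- exp(comp$meanlog)
  print(format(comp, digits = digits), ...)
  invisible(x)
}

#' @export
summary.ks_mixture <- function(object, ...) {
  out <- list(K = object$K, n = object$n, bic = object$bic,
              loglik = object$loglik, converged = object$converged,
              peaks = extract_peaks(object), fits = object$fits,
              filter_range = object$filter_range)
  class(out) <- "summary.ks_mixture"
  out
}

#' @export
print.summary.ks_mixture <- function(x, ...) {
  cat(sprintf("Log-normal Ks mixture on %d values in [%.3g, %.3g]\n",
              x$n, x$filter_range[1], x$filter_range[2]))
  cat("Model selection (BIC):\n")
  print(x$fits, row.names = FALSE)
  cat(sprintf("Selected K = %d; peaks (Ks-space component medians):\n", x$K))
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ks_mixture <- function(object, ...) {
  as.matrix(object$components)
}

#' @export
logLik.ks_mixture <- function(object, ...) {
  structure(object$loglik, df = 3 * object$K - 1, nobs = object$n,
            class = "logLik")
}

#' Mixture density evaluated on the Ks scale
#'
#' @param object A `ks_mixture` fit.
#' @param newdata Ks values at which to evaluate the fitted density
#'   (default: the fitted sample).
#' @param ... Unused.
#' @return Numeric vector of mixture density values (log-normal mixture on
#'   the Ks scale).
#' @export
predict.ks_mixture <- function(object, newdata = object$ks, ...) {
  comp <- object$components
  rowSums(vapply(seq_len(nrow(comp)), function(j)
    comp$weight[j] * stats::dlnorm(newdata, comp$meanlog[j], comp$sdlog[j]),
    numeric(length(newdata))))
}

#' Draw Ks values from a fitted (or specified) mixture
#'
#' @param object A `ks_mixture` fit.
#' @param nsim Number of values to draw.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Numeric vector of simulated Ks values.
#' @export
simulate.ks_mixture <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- object$components
  j <- sample.int(nrow(comp), nsim, replace = TRUE, prob = comp$weight)
  stats::rlnorm(nsim, comp$meanlog[j], comp$sdlog[j])
}

#' @export
plot.ks_mixture <- function(x, breaks = 50, main = "Ks distribution", ...) {
  graphics::hist(x$ks, breaks = breaks, freq = FALSE, main = main,
                 xlab = "Ks", border = "grey70", col = "grey90", ...)
  xs <- seq(x$filter_range[1], x$filter_range[2], length.out = 512)
  graphics::lines(xs, predict(x, xs), lwd = 2)
  comp <- x$components
  for (j in seq_len(nrow(comp))) {
    graphics::lines(xs, comp$weight[j] *
                      stats::dlnorm(xs, comp$meanlog[j], comp$sdlog[j]),
                    lty = 2)
  }
  graphics::abline(v = exp(comp$meanlog), col = "firebrick", lty = 3)
  invisible(x)
}

#' Extract Ks-space peaks from a mixture fit
#'
#' Peaks are the per-component Ks-space medians `exp(meanlog)` (the central
#' tendency of a log-normal component), sorted ascending.
#'
#' @param fit A converged `ks_mixture`.
#' @return Data frame `peak` (Ks), `weight`, sorted by peak.
#' @export
extract_peaks <- function(fit) {
  stopifnot(inherits(fit, "ks_mixture"))
  if (!fit$converged) stop("mixture fit did not converge", call. = FALSE)
  comp <- fit$components
  out <- data.frame(peak = exp(comp$meanlog), weight = comp$weight)
  out[order(out$peak), , drop = FALSE]
}

#' Date a WGD by linear Ks calibration
#'
#' Converts a Ks peak to an age using a calibration WGD of known age and
#' Ks, assuming a constant synonymous rate:
#' `age = calib_age * peak_ks / calib_peak_ks`. The default calibration is
#' the Brassicaceae alpha-WGD (Ks 0.85, ~35 Mya).
#'
#' @param peak_ks Ks peak of the WGD to date (>= 0).
#' @param calib_peak_ks Ks of the calibration WGD (> 0).
#' @param calib_age_my Age of the calibration WGD in My (> 0).
#' @return List of class `wgd_age`: `age_my`, `peak_ks`, `calib_peak_ks`,
#'   `calib_age_my`, `syn_rate_per_year` (implied rate
#'   `calib_peak_ks / (2 * calib_age)` per site per year).
#' @examples
#' estimate_wgd_age(0.18)  # ~7.4 My under the alpha calibration
#' @export
estimate_wgd_age <- function(peak_ks, calib_peak_ks = 0.85,
                             calib_age_my = 35) {
  if (peak_ks < 0) stop("peak_ks must be >= 0", call. = FALSE)
  if (calib_peak_ks <= 0 || calib_age_my <= 0) {
    stop("calibration peak and age must be > 0", call. = FALSE)
  }
  structure(list(
    age_my = calib_age_my * peak_ks / calib_peak_ks,
    peak_ks = peak_ks, calib_peak_ks = calib_peak_ks,
    calib_age_my = calib_age_my,
    syn_rate_per_year = calib_peak_ks / (2 * calib_age_my * 1e6)
  ), class = "wgd_age")
}

#' @export
print.wgd_age <- function(x, ...) {
  cat(sprintf("WGD age: %.2f My (Ks peak %.3g; calibration Ks %.3g at %.3g My;\n",
              x$age_my, x$peak_ks, x$calib_peak_ks, x$calib_age_my))
  cat(sprintf("  implied synonymous rate %.3g /site/year)\n",
              x$syn_rate_per_year))
  invisible(x)
}

#' Is a WGD shared between two species?
#'
#' A WGD predates the split of two species carrying it exactly when the
#' ortholog-divergence Ks peak is younger (smaller) than the paralog WGD
#' Ks peak.
#'
#' @param wgd_peak_ks Paralog Ks peak of the WGD.
#' @param ortholog_divergence_peak_ks Ks peak of the cross-species ortholog
#'   divergence.
#' @param tolerance Dead band around equality within which the verdict is
#'   `"ambiguous"`.
#' @return `"shared"`, `"lineage_specific"` or `"ambiguous"`.
#' @examples
#' test_shared_wgd(0.18, 0.08)  # "shared"
#' @export
test_shared_wgd <- function(wgd_peak_ks, ortholog_divergence_peak_ks,
                            tolerance = 0.02) {
  stopifnot(wgd_peak_ks >= 0, ortholog_divergence_peak_ks >= 0,
            tolerance >= 0)
  if (ortholog_divergence_peak_ks < wgd_peak_ks - tolerance) "shared"
  else if (ortholog_divergence_peak_ks > wgd_peak_ks + tolerance)
    "lineage_specific"
  else "ambiguous"
}
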