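#' Cumulative jump-distance model for a 2D Brownian mixture
#'
#' Probability that a molecule drawn from the mixture moves less than `r`
#' in one lag `dt`:
#' `P(r) = sum_i f_i * (1 - exp(-r^2 / (4 * D_i * dt)))`.
#' A component with `D = 0` contributes a step at `r = 0`.
#'
#' @param r Jump distance(s), um (>= 0).
#' @param components Data.frame with columns `D` (um^2/s) and `fraction`.
#' @param dt Lag time in seconds.
#' @return Model CDF value(s) in `[0, 1]`.
#' @examples
#' jd_cdf_model(sqrt(4 * 1 * 0.0135 * log(2)),
#'              data.frame(D = 1, fraction = 1), 0.0135)  # 0.5
#' @export
jd_cdf_model <- function(r, components, dt) {
  stopifnot(all(r >= 0), dt > 0,
            all(c("D", "fraction") %in% names(components)))
  out <- numeric(length(r))
  for (i in seq_len(nrow(components))) {
    D <- components$D[i]
    term <- if (D > 0) 1 - exp(-r^2 / (4 * D * dt)) else as.numeric(r > 0)
    out <- out + components$fraction[i] * term
  }
  out
}

#' Fit a jump-distance distribution with a Brownian mixture
#'
#' Least-squares fit of the 2D Brownian mixture to the pooled jump
#' distances. The default target, `"hist"`, fits the model's per-bin
#' probabilities (differences of [jd_cdf_model()] across bin edges) to
#' the jump-distance histogram, using `n_bins` equal-width bins up to
#' the 99.9th percentile plus a catch-all tail bin; histogram counts are
#' nearly independent, which makes the RSS-based [bic()] reliable for
#' choosing the number of components. `target = "cdf"` fits the
#' empirical cumulative distribution at every jump (Hazen plotting
#' positions) instead.
#'
#' Fractions are constrained to the simplex and diffusion coefficients
#' positive via an internal log/normalized-weight parameterization, with
#' multi-start initialization from quantile-based D guesses. Components
#' are returned sorted by D ascending. The apparent D of slow components
#' includes the localization-noise floor `sigma_loc^2 / dt`; no
#' correction is applied.
#'
#' @param jumps A [jump_dataset()] (>= 100 jumps).
#' @param n_components Number of mixture components (1-3).
#' @param bound_max,diff_min Classification thresholds in um^2/s:
#'   components with `D <= bound_max` count as bound, `D >= diff_min` as
#'   diffusing (defaults 0.1 and 0.6).
#' @param target `"hist"` (default) or `"cdf"`.
#' @param n_bins Number of histogram bins for `target = "hist"`.
#' @return An object of class `jd_fit` with elements `components` (D,
#'   fraction), `dt`, `rss`, `bic`, `n_jumps`, `bound_fraction`,
#'   `diffusing_fraction`.
#' @export
fit_jd <- function(jumps, n_components = 2L, bound_max = 0.1,
                   diff_min = 0.6, target = c("hist", "cdf"),
                   n_bins = 100L) {
  stopifnot(inherits(jumps, "jump_dataset"))
  target <- match.arg(target)
  K <- as.integer(n_components)
  if (K < 1L || K > 3L) stop("n_components must be 1..3")
  r <- sort(jumps$jumps)
  n <- length(r)
  if (n < 100L) stop("need >= 100 jumps to fit")
  dt <- jumps$dt

  if (target == "hist") {
    edges <- seq(0, stats::quantile(r, 0.999, names = FALSE),
                 length.out = n_bins + 1L)
    edges[n_bins + 1L] <- max(r) * (1 + 1e-9) + 1e-12
    obs <- graphics::hist(r, breaks = edges, plot = FALSE)$counts / n
    e2 <- edges^2
    resid_fn <- function(D, f) {
      cs <- as.vector((1 - exp(-outer(e2, 4 * D * dt, "/"))) %*% f)
      diff(cs) - obs
    }
    n_points <- n_bins
  } else {
    u <- (seq_len(n) - 0.5) / n
    r2 <- r^2
    resid_fn <- function(D, f) {
      as.vector((1 - exp(-outer(r2, 4 * D * dt, "/"))) %*% f) - u
    }
    n_points <- n
  }
  obj <- function(theta) {
    D <- exp(theta[seq_len(K)])
    f <- softnorm_weights(theta, K)
    sum(resid_fn(D, f)^2)
  }

  qs <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
  base_D <- pmax(qs^2 / (4 * dt * -log(1 - c(0.25, 0.5, 0.75))), 1e-8)
  starts <- jd_starts(base_D, K)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, method = "BFGS",
                   control = list(maxit = 600, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("jump-distance fit failed to converge from all starts (K=", K, ")")
  }
  D <- exp(best$par[seq_len(K)])
  f <- softnorm_weights(best$par, K)
  ord <- order(D)
  comps <- data.frame(D = D[ord], fraction = f[ord])
  out <- structure(list(
    components = comps, dt = dt, rss = best$value,
    bic = bic(n = n_points, p = 2L * K - 1L, rss = max(best$value, 1e-300)),
    n_jumps = n, n_components = K, target = target), class = "jd_fit")
  cf <- classify_fractions(out, bound_max = bound_max, diff_min = diff_min)
  out$bound_fraction <- cf[["bound_fraction"]]
  out$diffusing_fraction <- cf[["diffusing_fraction"]]
  out
}

jd_starts <- function(base_D, K) {
  if (K == 1L) {
    lapply(base_D, log)
  } else if (K == 2L) {
    list(c(log(base_D[2] / 20), log(base_D[3] * 2), 0),
         c(log(base_D[1] / 50), log(base_D[2]), 0),
         c(log(base_D[2] / 2), log(base_D[2] * 2), 0))
  } else {
    list(c(log(base_D[2] / 50), log(base_D[2] / 5), log(base_D[3] * 2), 0, 0),
         c(log(base_D[1] / 20), log(base_D[2]), log(base_D[3]), 0, 0))
  }
}

#' Classify fitted diffusion components as bound or diffusing
#'
#' Sums component fractions with `D <= bound_max` into the bound fraction
#' and `D >= diff_min` into the diffusing fraction; components between
#' the thresholds are intermediate and counted in neither.
#'
#' @param fit A `jd_fit`.
#' @param bound_max Upper D threshold for bound molecules (um^2/s).
#' @param diff_min Lower D threshold for diffusing molecules (um^2/s).
#' @return Named numeric vector `c(bound_fraction, diffusing_fraction)`.
#' @export
classify_fractions <- function(fit, bound_max = 0.1, diff_min = 0.6) {
  stopifnot(bound_max > 0, diff_min > bound_max)
  comps <- fit$components
  c(bound_fraction = sum(comps$fraction[comps$D <= bound_max]),
    diffusing_fraction = sum(comps$fraction[comps$D >= diff_min]))
}

#' Select the number of diffusion components by BIC
#'
#' Fits mixtures with 1 to `max_components` components and returns the
#' fit with the lowest BIC (the minimum number of diffusion coefficients
#' needed to describe the motion).
#'
#' @param jumps A [jump_dataset()].
#' @param max_components Maximum components to try (<= 3).
#' @param ... Passed to [fit_jd()].
#' @return The selected `jd_fit`, with the per-model BIC table attached
#'   as element `bic_table`.
#' @export
select_jd_model <- function(jumps, max_components = 3L, ...) {
  fits <- list()
  for (K in seq_len(max_components)) {
    fits[[K]] <- tryCatch(fit_jd(jumps, n_components = K, ...),
                          error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no jump-distance model converged")
  bics <- vapply(fits[ok], function(f) f$bic, numeric(1))
  sel <- fits[ok][[which.min(bics)]]
  sel$bic_table <- data.frame(n_components = which(ok), bic = bics)
  sel
}

#' @export
print.jd_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Jump-distance mixture fit: %d component(s), %d jumps at dt = %g s\n",
              x$n_components, x$n_jumps, x$dt))
  comps <- x$components
  for (i in seq_len(nrow(comps))) {
    cat(sprintf("  D%d = %s um^2/s  (fraction %s)\n", i,
                signif(comps$D[i], digits), signif(comps$fraction[i], digits)))
  }
  cat(sprintf("  bound %.1f%%, diffusing %.1f%%;  RSS %.4g, BIC %.4g\n",
              100 * x$bound_fraction, 100 * x$diffusing_fraction,
              x$rss, x$bic))
  invisible(x)
}

#' @export
summary.jd_fit <- function(object, ...) {
  out <- object
  class(out) <- c("summary.jd_fit", class(object))
  out
}

#' @export
print.summary.jd_fit <- function(x, ...) {
  print.jd_fit(x, ...)
  if (!is.null(x$bic_table)) {
    cat("BIC by model:\n")
    print(x$bic_table, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.jd_fit <- function(object, ...) {
  comps <- object$components
  stats::setNames(c(comps$D, comps$fraction),
                  c(paste0("D", seq_len(nrow(comps))),
                    paste0("f", seq_len(nrow(comps)))))
}

#' @export
predict.jd_fit <- function(object, r, ...) {
  jd_cdf_model(r, object$components, object$dt)
}

#' @export
plot.jd_fit <- function(x, jumps = NULL, ...) {
  rmax <- if (!is.null(jumps)) max(jumps$jumps) else {
    3 * sqrt(4 * max(x$components$D) * x$dt)
  }
  rr <- seq(0, rmax, length.out = 300)
  graphics::plot(rr, predict(x, rr), type = "l", xlab = "jump distance (um)",
                 ylab = "cumulative fraction of jumps", ylim = c(0, 1), ...)
  if (!is.null(jumps)) {
    r <- sort(jumps$jumps)
    graphics::lines(r, (seq_along(r) - 0.5) / length(r), col = "grey50",
                    lty = 2)
  }
  invisible(x)
}
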