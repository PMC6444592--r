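# Independent oracles used across the suite.

# Exhaustive frame-pair assignment: enumerate all one-to-one matchings of
# previous ends to current localizations restricted to pairs within the
# radius; prefer more links, then smaller summed distance. Returns, per
# previous end, the matched current index or NA.
oracle_assignment <- function(prev_xy, cur_xy, radius) {
  n1 <- nrow(prev_xy); n2 <- nrow(cur_xy)
  d <- sqrt(outer(prev_xy[, 1], cur_xy[, 1], "-")^2 +
              outer(prev_xy[, 2], cur_xy[, 2], "-")^2)
  best <- list(links = -1L, cost = Inf, assn = rep(NA_integer_, n1))
  recurse <- function(i, used, assn, links, cost) {
    if (i > n1) {
      if (links > best$links ||
          (links == best$links && cost < best$cost - 1e-12)) {
        best <<- list(links = links, cost = cost, assn = assn)
      }
      return(invisible())
    }
    recurse(i + 1L, used, assn, links, cost)  # leave i unmatched
    for (j in seq_len(n2)) {
      if (!used[j] && d[i, j] <= radius) {
        used[j] <- TRUE; assn[i] <- j
        recurse(i + 1L, used, assn, links + 1L, cost + d[i, j])
        used[j] <- FALSE; assn[i] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, n2), rep(NA_integer_, n1), 0L, 0)
  best$assn
}

# analytic CDF of an exponential mixture of dwell times
mixture_cdf <- function(fractions, taus) {
  function(q) {
    out <- 0
    for (i in seq_along(taus)) out <- out + fractions[i] * stats::pexp(q, 1 / taus[i])
    out
  }
}

# render a noiseless Gaussian spot on a given background field
spot_image <- function(nrow_px, ncol_px, x, y, amplitude, sigma,
                       background = 0) {
  xs <- 0:(ncol_px - 1); ys <- 0:(nrow_px - 1)
  background + amplitude * outer(exp(-(ys - y)^2 / (2 * sigma^2)),
                                 exp(-(xs - x)^2 / (2 * sigma^2)))
}

two_exp_components <- function() {
  data.frame(fraction = c(0.88, 0.12), tau = c(2.4, 28.8))
}
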