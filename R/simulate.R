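#' Simulate two-state single-molecule trajectories
#'
#' Generates ground-truth molecule paths under the generative model the
#' downstream analysis assumes: each molecule is assigned to the bound or
#' the diffusing population, moves by 2D Brownian increments with per-axis
#' variance `2 * D * dt` at sub-step resolution, and disappears when it
#' photobleaches, when a bound molecule's dwell time (drawn from the
#' configured exponential mixture) elapses, or when the movie ends.
#' Re-binding is not simulated: an unbinding event censors the molecule,
#' matching a residence-time analysis that treats binding events
#' independently.
#'
#' Reported per-frame positions are the instantaneous mid-exposure true
#' position plus additive Gaussian localization noise of standard
#' deviation `localization_sigma`, so consecutive reports are separated
#' by exactly one frame interval and jump variance follows the 2D
#' Brownian law. Ground truth is kept separately at sub-step resolution
#' for movie rendering (where motion blur is modelled) and for recall
#' benchmarking.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `trajectory_set`: a list with elements
#'   `tracks` (data.frame `molecule_id`, `frame`, `x_px`, `y_px`, `state`,
#'   `dwell_s`), `truth` (data.frame of sub-step true positions with
#'   `molecule_id`, `frame`, `sub`, `x_px`, `y_px`), `molecules`
#'   (per-molecule data.frame with `state`, `dwell_s`, `bleach_s`,
#'   `last_frame`) and `config`.
#' @examples
#' ts <- simulate_trajectories(sim_config(n_molecules = 5, n_frames = 10))
#' head(ts$tracks)
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  px_um <- config$pixel_size / 1000
  sigma_loc_px <- config$localization_sigma / config$pixel_size
  n_sub <- 10L                       # sub-steps per exposure
  dt_sub <- config$exposure / n_sub
  dark <- config$frame_interval - config$exposure

  mols <- vector("list", config$n_molecules)
  subs <- vector("list", config$n_molecules)
  frames_out <- vector("list", config$n_molecules)

  for (m in seq_len(config$n_molecules)) {
    bound <- stats::runif(1) < config$fraction_bound
    D <- if (bound) config$d_bound else config$d_free
    dwell <- if (bound) {
      comp <- sample.int(nrow(config$dwell_components), 1L,
                         prob = config$dwell_components$fraction)
      stats::rexp(1, rate = 1 / config$dwell_components$tau[comp])
    } else Inf
    bleach <- if (config$bleach_rate > 0) {
      stats::rexp(1, rate = config$bleach_rate)
    } else Inf
    life_s <- min(dwell, bleach, config$n_frames * config$frame_interval)
    # visible in frame f iff its exposure window completes before death:
    # (f-1)*frame_interval + exposure <= life_s
    n_vis <- max(0L, min(config$n_frames, as.integer(
      floor((life_s - config$exposure) / config$frame_interval) + 1L)))
    step_sd <- sqrt(2 * D * dt_sub) / px_um
    dark_sd <- if (dark > 0) sqrt(2 * D * dark) / px_um else 0

    x0 <- stats::runif(1, 3, config$field_size[1] - 4)
    y0 <- stats::runif(1, 3, config$field_size[2] - 4)
    if (n_vis < 1L) {
      mols[[m]] <- data.frame(molecule_id = m,
                              state = if (bound) "bound" else "diffusing",
                              dwell_s = ifelse(is.finite(dwell), dwell, NA_real_),
                              bleach_s = ifelse(is.finite(bleach), bleach, NA_real_),
                              last_frame = 0L)
      next
    }
    # sub-step positions: n_sub per exposure, plus one dark-gap step/frame
    xs <- numeric(n_vis * n_sub); ys <- numeric(n_vis * n_sub)
    x <- x0; y <- y0
    k <- 0L
    for (f in seq_len(n_vis)) {
      for (s in seq_len(n_sub)) {
        k <- k + 1L
        xs[k] <- x; ys[k] <- y
        x <- x + stats::rnorm(1, 0, step_sd)
        y <- y + stats::rnorm(1, 0, step_sd)
      }
      if (dark_sd > 0) {
        x <- x + stats::rnorm(1, 0, dark_sd)
        y <- y + stats::rnorm(1, 0, dark_sd)
      }
    }
    fr <- rep(seq_len(n_vis), each = n_sub)
    subs[[m]] <- data.frame(molecule_id = m, frame = fr,
                            sub = rep(seq_len(n_sub), n_vis),
                            x_px = xs, y_px = ys)
    # report the instantaneous mid-exposure position: consecutive reports
    # are exactly frame_interval apart, so jump variance is 2*D*dt per
    # axis as the JD model assumes (exposure-averaged centroids would
    # shrink apparent jumps; the blur itself is modelled in render_movie)
    mid <- (seq_len(n_vis) - 1L) * n_sub + (n_sub %/% 2L)
    cx <- xs[mid] + stats::rnorm(n_vis, 0, sigma_loc_px)
    cy <- ys[mid] + stats::rnorm(n_vis, 0, sigma_loc_px)
    frames_out[[m]] <- data.frame(
      molecule_id = m, frame = seq_len(n_vis),
      x_px = as.numeric(cx), y_px = as.numeric(cy),
      state = if (bound) "bound" else "diffusing",
      dwell_s = ifelse(is.finite(dwell), dwell, NA_real_))
    mols[[m]] <- data.frame(molecule_id = m,
                            state = if (bound) "bound" else "diffusing",
                            dwell_s = ifelse(is.finite(dwell), dwell, NA_real_),
                            bleach_s = ifelse(is.finite(bleach), bleach, NA_real_),
                            last_frame = n_vis)
  }
  out <- list(tracks = do.call(rbind, frames_out),
              truth = do.call(rbind, subs),
              molecules = do.call(rbind, mols),
              config = config)
  class(out) <- "trajectory_set"
  out
}

#' @export
print.trajectory_set <- function(x, ...) {
  nb <- sum(x$molecules$state == "bound")
  cat(sprintf("trajectory_set: %d molecules (%d bound, %d diffusing), %d localizations\n",
              nrow(x$molecules), nb, nrow(x$molecules) - nb,
              if (is.null(x$tracks)) 0L else nrow(x$tracks)))
  invisible(x)
}

#' Draw residence times from an exponential mixture
#'
#' Samples i.i.d. dwell times from `sum_i f_i * Exponential(tau_i)`, the
#' model fitted by [fit_exponential_mixture()].
#'
#' @param components Data.frame/matrix with columns `fraction` and `tau`
#'   (seconds); fractions must sum to 1.
#' @param n Number of samples (>= 1).
#' @param seed Optional integer seed.
#' @param frame_interval Acquisition grid in seconds attached to the
#'   dataset for survival-curve construction (default 0.5 s, the slow
#'   imaging mode).
#' @return A `dwell_dataset` object (see [dwell_dataset()]).
#' @examples
#' d <- simulate_dwell_times(data.frame(fraction = c(0.88, 0.12),
#'                                      tau = c(2.4, 28.8)), 1000, seed = 1)
#' mean(d$dwells)
#' @export
simulate_dwell_times <- function(components, n, seed = NULL,
                                 frame_interval = 0.5) {
  components <- as_dwell_components(components)
  if (nrow(components) < 1L) stop("empty dwell component list")
  if (abs(sum(components$fraction) - 1) > 1e-9) {
    stop("dwell component fractions must sum to 1")
  }
  if (any(components$tau <= 0)) stop("all tau must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(nrow(components), n, replace = TRUE,
                     prob = components$fraction)
  dwells <- stats::rexp(n, rate = 1 / components$tau[comp])
  dwell_dataset(dwells, frame_interval = frame_interval)
}

#' Construct a dwell-time dataset
#'
#' @param dwells Positive dwell durations in seconds.
#' @param frame_interval Acquisition frame interval in seconds.
#' @param censored Logical vector flagging right-censored dwells
#'   (trajectories still present in the movie's last frame).
#' @return An object of class `dwell_dataset`.
#' @export
dwell_dataset <- function(dwells, frame_interval = 0.5,
                          censored = rep(FALSE, length(dwells))) {
  stopifnot(is.numeric(dwells), all(dwells > 0), frame_interval > 0,
            length(censored) == length(dwells))
  structure(list(dwells = as.numeric(dwells),
                 frame_interval = frame_interval,
                 censored = as.logical(censored)),
            class = "dwell_dataset")
}

#' @export
print.dwell_dataset <- function(x, ...) {
  cat(sprintf("dwell_dataset: %d dwells (%d censored), frame interval %g s, mean %.3g s\n",
              length(x$dwells), sum(x$censored), x$frame_interval,
              mean(x$dwells)))
  invisible(x)
}

#' Simulate jump distances from a 2D Brownian mixture
#'
#' Draws displacement magnitudes over one lag directly from the mixture
#' model fitted by [fit_jd()]: a molecule with diffusion coefficient D
#' has per-axis Gaussian increments of variance `2 * D * dt` (plus
#' `2 * sigma_loc^2` of localization error, which enters twice per jump).
#'
#' @param n Number of jumps.
#' @param components Data.frame with columns `D` (um^2/s) and `fraction`.
#' @param dt Lag time in seconds.
#' @param sigma_loc Localization noise standard deviation in um (applied
#'   independently to both endpoints of each jump); default 0.
#' @param seed Optional integer seed.
#' @return A `jump_dataset` (see [jump_dataset()]); jumps in um.
#' @examples
#' j <- simulate_jumps(1000, data.frame(D = c(0.02, 1.5),
#'                                      fraction = c(0.374, 0.626)),
#'                     dt = 0.0135, seed = 1)
#' @export
simulate_jumps <- function(n, components, dt, sigma_loc = 0, seed = NULL) {
  stopifnot(is.data.frame(components), all(c("D", "fraction") %in%
                                             names(components)))
  if (abs(sum(components$fraction) - 1) > 1e-9) {
    stop("component fractions must sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(nrow(components), n, replace = TRUE,
                     prob = components$fraction)
  sd_ax <- sqrt(2 * components$D[comp] * dt + 2 * sigma_loc^2)
  jumps <- sqrt(stats::rnorm(n, 0, sd_ax)^2 + stats::rnorm(n, 0, sd_ax)^2)
  jump_dataset(jumps, dt)
}

#' Construct a jump-distance dataset
#'
#' @param jumps Non-negative displacement magnitudes in um.
#' @param dt Lag time in seconds.
#' @return An object of class `jump_dataset`.
#' @export
jump_dataset <- function(jumps, dt) {
  stopifnot(is.numeric(jumps), all(jumps >= 0), dt > 0)
  structure(list(jumps = as.numeric(jumps), dt = dt),
            class = "jump_dataset")
}

#' @export
print.jump_dataset <- function(x, ...) {
  cat(sprintf("jump_dataset: %d jumps at dt = %g s, mean %.4g um\n",
              length(x$jumps), x$dt, mean(x$jumps)))
  invisible(x)
}
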