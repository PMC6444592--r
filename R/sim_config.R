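#' Simulation configuration for synthetic single-particle tracking data
#'
#' Bundles and validates all parameters of the generative model used by
#' [simulate_trajectories()] and [render_movie()]: two-state (bound vs
#' diffusing) 2D Brownian motion, an exponential mixture of bound dwell
#' times, Gaussian localization noise, photon emission and photobleaching.
#'
#' Coordinates are 0-based pixel indices with the origin at the top-left
#' corner; `x` indexes columns and `y` rows. Physical units enter through
#' `pixel_size`. The default pixel size of 156 nm makes the conventional
#' 6-pixel linking radius equal to 936 nm.
#'
#' @param pixel_size Pixel pitch in nm.
#' @param frame_interval Time between frame starts, in seconds.
#' @param exposure Camera integration time per frame, in seconds; must not
#'   exceed `frame_interval`. Defaults to `frame_interval` (no dead time).
#' @param n_frames Number of movie frames (>= 2).
#' @param field_size Integer vector `c(width, height)` in pixels.
#' @param d_bound Apparent diffusion coefficient of chromatin-bound
#'   molecules, um^2/s. Bound molecules are not strictly immobile: slow
#'   residual motion of the chromatin fiber gives them a small apparent D.
#' @param d_free Diffusion coefficient of freely diffusing molecules,
#'   um^2/s; must exceed `d_bound` when both populations are present.
#' @param fraction_bound Proportion of molecules in the bound state at
#'   activation, in `[0, 1]`.
#' @param dwell_components Two-column matrix or data.frame with columns
#'   `fraction` and `tau` (seconds) describing the exponential mixture of
#'   bound dwell times. Fractions must sum to 1.
#' @param localization_sigma Standard deviation of additive Gaussian
#'   localization noise, in nm, applied to reported (not ground-truth)
#'   positions.
#' @param photons_per_molecule Expected photons emitted per molecule per
#'   full exposure.
#' @param background_level Mean background, in camera counts per pixel.
#' @param psf_sigma Standard deviation of the isotropic Gaussian PSF, nm.
#' @param bleach_rate Photobleaching rate in 1/s; emitter lifetimes are
#'   exponential with this rate. 0 disables bleaching.
#' @param n_molecules Number of molecules to simulate.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_molecules = 10, n_frames = 20)
#' cfg$frame_interval
#' @export
sim_config <- function(pixel_size = 156,
                       frame_interval = 0.0135,
                       exposure = frame_interval,
                       n_frames = 100L,
                       field_size = c(64L, 64L),
                       d_bound = 0.02,
                       d_free = 1.5,
                       fraction_bound = 0.374,
                       dwell_components = default_dwell_components(),
                       localization_sigma = 30,
                       photons_per_molecule = 2000,
                       background_level = 100,
                       psf_sigma = 170,
                       bleach_rate = 0.01,
                       n_molecules = 100L,
                       seed = 1L) {
  dwell_components <- as_dwell_components(dwell_components)
  cfg <- list(
    pixel_size = pixel_size, frame_interval = frame_interval,
    exposure = exposure, n_frames = as.integer(n_frames),
    field_size = as.integer(field_size),
    d_bound = d_bound, d_free = d_free, fraction_bound = fraction_bound,
    dwell_components = dwell_components,
    localization_sigma = localization_sigma,
    photons_per_molecule = photons_per_molecule,
    background_level = background_level, psf_sigma = psf_sigma,
    bleach_rate = bleach_rate, n_molecules = as.integer(n_molecules),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Single-particle tracking simulation configuration\n")
  cat(sprintf("  field: %d x %d px @ %g nm/px, %d frames\n",
              x$field_size[1], x$field_size[2], x$pixel_size, x$n_frames))
  cat(sprintf("  timing: frame interval %g s, exposure %g s\n",
              x$frame_interval, x$exposure))
  cat(sprintf("  motion: D_bound %g, D_free %g um^2/s, bound fraction %g\n",
              x$d_bound, x$d_free, x$fraction_bound))
  cat("  dwell mixture:",
      paste(sprintf("%.0f%% x %g s", 100 * x$dwell_components$fraction,
                    x$dwell_components$tau), collapse = ", "), "\n")
  cat(sprintf("  optics: PSF sigma %g nm, %g photons/frame, bg %g, sigma_loc %g nm\n",
              x$psf_sigma, x$photons_per_molecule, x$background_level,
              x$localization_sigma))
  invisible(x)
}

default_dwell_components <- function() {
  data.frame(fraction = c(0.88, 0.12), tau = c(2.4, 28.8))
}

as_dwell_components <- function(x) {
  if (is.matrix(x)) x <- as.data.frame(x)
  if (!is.data.frame(x)) {
    stop("dwell_components must be a data.frame/matrix with columns ",
         "'fraction' and 'tau'")
  }
  if (is.null(names(x)) || !all(c("fraction", "tau") %in% names(x))) {
    names(x) <- c("fraction", "tau")[seq_along(x)]
  }
  x[c("fraction", "tau")]
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid simulation config: ", msg,
                                 call. = FALSE)
  num_ok <- function(v) is.numeric(v) && all(is.finite(v))
  for (fld in c("pixel_size", "frame_interval", "exposure", "d_bound",
                "d_free", "fraction_bound", "localization_sigma",
                "photons_per_molecule", "background_level", "psf_sigma",
                "bleach_rate")) {
    if (!num_ok(cfg[[fld]])) stop_cfg(paste0(fld, " must be finite numeric"))
  }
  if (cfg$pixel_size <= 0 || cfg$psf_sigma <= 0) {
    stop_cfg("pixel_size and psf_sigma must be positive")
  }
  if (cfg$frame_interval <= 0) stop_cfg("frame_interval must be positive")
  if (cfg$exposure <= 0 || cfg$exposure > cfg$frame_interval + 1e-12) {
    stop_cfg("exposure must be in (0, frame_interval]")
  }
  if (cfg$n_frames < 2L) stop_cfg("n_frames must be >= 2")
  if (length(cfg$field_size) != 2L || any(cfg$field_size < 8L)) {
    stop_cfg("field_size must be two integers >= 8")
  }
  if (cfg$fraction_bound < 0 || cfg$fraction_bound > 1) {
    stop_cfg("fraction_bound must lie in [0, 1]")
  }
  if (cfg$d_bound < 0 || cfg$d_free < 0 || cfg$bleach_rate < 0 ||
      cfg$localization_sigma < 0) {
    stop_cfg("rates, diffusion coefficients and noise sigmas must be >= 0")
  }
  both <- cfg$fraction_bound > 0 && cfg$fraction_bound < 1
  if (both && cfg$d_bound >= cfg$d_free) {
    stop_cfg("d_bound must be < d_free when both populations are present")
  }
  dc <- cfg$dwell_components
  if (nrow(dc) < 1L) stop_cfg("dwell_components must have >= 1 row")
  if (!num_ok(dc$fraction) || !num_ok(dc$tau)) {
    stop_cfg("dwell_components must be finite numeric")
  }
  if (abs(sum(dc$fraction) - 1) > 1e-9) {
    stop_cfg("dwell component fractions must sum to 1")
  }
  if (any(dc$fraction < 0) || any(dc$tau <= 0)) {
    stop_cfg("dwell fractions must be >= 0 and all tau > 0")
  }
  if (cfg$n_molecules < 1L) stop_cfg("n_molecules must be >= 1")
  invisible(cfg)
}

#' Read or write a simulation configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` invisibly returns `path`.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$dwell_components)) {
    x$dwell_components <- as_dwell_components(as.data.frame(x$dwell_components))
  }
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @param config A `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}
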