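#' Render a synthetic fluorescence movie from simulated trajectories
#'
#' Integrates each emitter's photons over the exposure window by summing
#' isotropic Gaussian PSF renderings at the ten sub-step positions of the
#' ground-truth path, adds a constant background, applies Poisson shot
#' noise, and quantizes to the 16-bit camera range. Long exposures
#' therefore blur diffusing molecules over roughly `sqrt(4 * D * exposure)`,
#' suppressing their peak intensity and SNR, while bound molecules remain
#' compact — the motion-blurring contrast the slow acquisition mode
#' exploits.
#'
#' @param trajectories A `trajectory_set` from [simulate_trajectories()].
#' @param config Optional [sim_config()]; defaults to the one stored in
#'   `trajectories`.
#' @return An `image_stack`: an integer array `height x width x n_frames`
#'   in camera counts, with the config attached as attribute `config`.
#' @examples
#' ts <- simulate_trajectories(sim_config(n_molecules = 3, n_frames = 4,
#'                                        field_size = c(32, 32)))
#' mov <- render_movie(ts)
#' dim(mov)
#' @export
render_movie <- function(trajectories, config = trajectories$config) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(config, "sim_config"))
  w <- config$field_size[1]; h <- config$field_size[2]
  sigma_px <- config$psf_sigma / config$pixel_size
  half <- ceiling(4 * sigma_px) + 1L
  if (2L * half + 1L > min(w, h)) {
    stop("field too small for PSF support (need >= ", 2L * half + 1L,
         " px per side)")
  }
  tr <- trajectories$truth
  if (is.null(tr) || nrow(tr) == 0L) stop("trajectory set has no visible emitters")
  n_sub <- max(tr$sub)
  photons_sub <- config$photons_per_molecule / n_sub
  off <- seq(-half, half)
  stack <- array(0, dim = c(h, w, config$n_frames))
  set.seed(config$seed + 76543L)
  for (f in seq_len(config$n_frames)) {
    img <- matrix(config$background_level, h, w)
    pts <- tr[tr$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(pts))) {
      # 0-based (x=col, y=row) physical coords -> 1-based matrix indices
      cx <- pts$x_px[i]; cy <- pts$y_px[i]
      c0 <- round(cx) + 1L; r0 <- round(cy) + 1L
      cols <- c0 + off; rows <- r0 + off
      keep_c <- cols >= 1L & cols <= w; keep_r <- rows >= 1L & rows <= h
      if (!any(keep_c) || !any(keep_r)) next
      gx <- exp(-((cols[keep_c] - 1L - cx)^2) / (2 * sigma_px^2))
      gy <- exp(-((rows[keep_r] - 1L - cy)^2) / (2 * sigma_px^2))
      patch <- outer(gy, gx) / (2 * pi * sigma_px^2) * photons_sub
      img[rows[keep_r], cols[keep_c]] <-
        img[rows[keep_r], cols[keep_c]] + patch
    }
    noisy <- stats::rpois(length(img), lambda = img)
    stack[, , f] <- matrix(pmin(noisy, 65535L), h, w)
  }
  structure(as.integer(round(stack)) |> array(dim = dim(stack)),
            config = config, class = "image_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("image_stack: %d x %d px, %d frames, counts in [%d, %d]\n",
              d[2], d[1], d[3], min(x), max(x)))
  invisible(x)
}

#' Write or read a movie as a 16-bit multi-page TIFF
#'
#' @param stack An `image_stack` (or plain `h x w x n` integer array) in
#'   counts on the 16-bit range.
#' @param path File path.
#' @return `read_movie_tiff()` returns an `image_stack` in integer counts;
#'   `write_movie_tiff()` invisibly returns `path`.
#' @export
write_movie_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3L)
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(f) stack[, , f] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  stack <- array(0L, dim = c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) {
    stack[, , f] <- as.integer(round(frames[[f]] * 65535))
  }
  class(stack) <- "image_stack"
  stack
}
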