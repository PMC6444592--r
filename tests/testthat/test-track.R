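test_that("a stationary spot yields one trajectory with all points", {
  locs <- data.frame(frame = 1:50, x_px = 10 + 1e-6 * (1:50), y_px = 20)
  tr <- link_localizations(locs, max_radius = 6)
  expect_equal(length(unique(tr$trajectory_id)), 1)
  expect_equal(nrow(tr), 50)
})

test_that("linking rejects duplicate localization rows", {
  locs <- data.frame(frame = c(1, 1), x_px = c(5, 5), y_px = c(5, 5))
  expect_error(link_localizations(locs), "duplicate")
})

test_that("linking matches the exhaustive assignment oracle", {
  # two well-separated moving spots
  locs <- do.call(rbind, lapply(1:10, function(f) {
    data.frame(frame = f, x_px = c(10 + f, 30 + f), y_px = c(10, 10))
  }))
  tr <- link_localizations(locs, max_radius = 6)
  expect_equal(length(unique(tr$trajectory_id)), 2)
  expect_true(all(table(tr$trajectory_id) == 10))

  # randomized small scenes: frame-pair assignment equals brute force
  set.seed(99)
  for (rep in 1:20) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    prev <- cbind(runif(n1, 0, 20), runif(n1, 0, 20))
    cur <- cbind(runif(n2, 0, 20), runif(n2, 0, 20))
    got <- chromodwell:::match_frame_pair(
      sqrt(outer(prev[, 1], cur[, 1], "-")^2 +
             outer(prev[, 2], cur[, 2], "-")^2), 6)
    want <- oracle_assignment(prev, cur, 6)
    d <- sqrt(outer(prev[, 1], cur[, 1], "-")^2 +
                outer(prev[, 2], cur[, 2], "-")^2)
    cost <- function(a) sum(d[cbind(which(!is.na(a)), a[!is.na(a)])])
    expect_equal(sum(!is.na(got)), sum(!is.na(want)))
    expect_equal(cost(got), cost(want), tolerance = 1e-9)
  }
})

test_that("linking conserves localizations and recovers ground truth when
           spots are well separated", {
  cfg <- sim_config(fraction_bound = 1, d_bound = 0.02,
                    localization_sigma = 20, n_molecules = 8,
                    n_frames = 30, bleach_rate = 0, field_size = c(256, 256),
                    seed = 5,
                    dwell_components = data.frame(fraction = 1, tau = 1e6))
  ts <- simulate_trajectories(cfg)
  tracks <- ts$tracks
  tr <- link_localizations(tracks[c("frame", "x_px", "y_px")], 6)
  expect_equal(nrow(tr), nrow(tracks))       # conservation
  # identity recovery: each linked trajectory maps to one molecule
  key <- paste(round(tracks$x_px, 9), round(tracks$y_px, 9))
  mol_of <- tracks$molecule_id[match(paste(round(tr$x_px, 9),
                                           round(tr$y_px, 9)), key)]
  expect_true(all(tapply(mol_of, tr$trajectory_id,
                         function(v) length(unique(v))) == 1))
  expect_equal(length(unique(tr$trajectory_id)), 8)
})

test_that("jump computation matches hand arithmetic", {
  tracks <- data.frame(trajectory_id = 1, frame = 1:3,
                       x_px = c(0, 3, 6), y_px = 0)
  j <- compute_jumps(tracks, 1, frame_interval = 0.0135, pixel_size = 156)
  expect_equal(sort(j$jumps), c(0.468, 0.468), tolerance = 1e-12)
  expect_equal(j$dt, 0.0135)
  # stationary trajectory: all jumps zero
  st <- data.frame(trajectory_id = 1, frame = 1:5, x_px = 2, y_px = 3)
  expect_true(all(compute_jumps(st, 1)$jumps == 0))
  # lag exceeding every trajectory warns and returns empty
  expect_warning(compute_jumps(st, 10), "empty")
})

test_that("dwell extraction uses the (n-1)*dt convention with censoring", {
  tracks <- data.frame(trajectory_id = rep(1, 11), frame = 1:11,
                       x_px = 0, y_px = 0)
  d <- compute_dwells(tracks, frame_interval = 0.5, last_frame = 100)
  expect_equal(d$dwells, 5.0)
  expect_false(d$censored)
  # touching the last frame flags censoring; +1-frame convention flag
  d2 <- compute_dwells(tracks, frame_interval = 0.5, last_frame = 11)
  expect_true(d2$censored)
  d3 <- compute_dwells(tracks, frame_interval = 0.5, last_frame = 100,
                       convention = "n")
  expect_equal(d3$dwells, 5.5)
})

test_that("pipeline dwells reproduce the input mixture (one-frame offset)", {
  comps <- data.frame(fraction = c(0.6, 0.4), tau = c(2, 12))
  cfg <- sim_config(frame_interval = 0.5, exposure = 0.5, n_frames = 200,
                    fraction_bound = 1, d_bound = 0.02,
                    localization_sigma = 0, bleach_rate = 0,
                    dwell_components = comps, n_molecules = 600,
                    field_size = c(2048, 2048), seed = 13)
  ts <- simulate_trajectories(cfg)
  d <- compute_dwells(ts$tracks, frame_interval = 0.5, last_frame = 200)
  keep <- !d$censored
  dw <- d$dwells[keep]
  # a dwell of (n-1) frames is observed when the true dwell exceeds n
  # frames, so the empirical survival at t equals the true survival at
  # t + dt, conditioned on trajectories long enough to yield a dwell
  # (>= 2 frames); compare on the frame grid within a KS-style band
  cdf <- mixture_cdf(comps$fraction, comps$tau)
  tt <- 0.5 * (1:40)
  emp <- vapply(tt, function(t0) mean(dw >= t0), numeric(1))
  theo <- (1 - cdf(tt + 0.5)) / (1 - cdf(1.0))
  expect_lt(max(abs(emp - theo)), 1.63 / sqrt(length(dw)))
})

test_that("track tables round-trip through CSV", {
  tracks <- data.frame(trajectory_id = c(1, 1, 2), frame = c(1, 2, 1),
                       x_px = c(1.5, 2.5, 8), y_px = c(3, 3.25, 9))
  path <- tempfile(fileext = ".csv")
  write_tracks(tracks, path)
  back <- read_tracks(path)
  expect_equal(as.data.frame(back), tracks)
})
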