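test_that("b/y fragment masses match hand-summed monoisotopic values", {
  fr <- theoretical_fragments("GK")
  expect_equal(fr$mz[fr$ion == "b1"], 58.0287, tolerance = 1e-3)
  expect_equal(fr$mz[fr$ion == "y1"], 147.1128, tolerance = 1e-3)
  expect_error(theoretical_fragments("GXK"), "unknown residue")
  expect_error(theoretical_fragments("GK", modified_positions = 2),
               "arginines")
})

test_that("citrulline shifts exactly the fragments containing the site", {
  pep <- "VLDRRVVNGK"
  un <- theoretical_fragments(pep)
  mod <- theoretical_fragments(pep, modified_positions = 4)
  shift <- mod$mz - un$mz
  contains <- ifelse(mod$type == "b", mod$index >= 4,
                     mod$index >= 10 - 4 + 1)
  expect_equal(shift[contains], rep(0.984016, sum(contains)),
               tolerance = 1e-9)
  expect_equal(shift[!contains], rep(0, sum(!contains)), tolerance = 1e-12)
})

test_that("top-peaks filter keeps the 10 most intense peaks per 100 amu", {
  set.seed(1)
  few <- data.frame(mz = seq(200, 290, by = 10), intensity = runif(10))
  expect_equal(nrow(top_peaks_per_window(few)), 10)
  many <- data.frame(mz = sort(runif(15, 300, 399)),
                     intensity = runif(15))
  kept <- top_peaks_per_window(many)
  expect_equal(nrow(kept), 10)
  expect_equal(sort(kept$intensity),
               sort(many$intensity, decreasing = TRUE)[10:1])
  # windows are independent
  two <- rbind(many, data.frame(mz = sort(runif(4, 420, 480)),
                                intensity = runif(4)))
  expect_equal(nrow(top_peaks_per_window(two)), 14)
})

test_that("fragment matching counts within-ppm hits, nearest first", {
  expect_equal(match_fragments(c(400, 500),
                               data.frame(mz = numeric(),
                                          intensity = numeric()))[["k"]], 0)
  peaks <- data.frame(mz = 500.005, intensity = 1)
  expect_equal(match_fragments(500.000, peaks, 20)[["k"]], 1)   # 10 ppm off
  expect_equal(match_fragments(500.000, data.frame(mz = 500.011,
                                                   intensity = 1),
                               20)[["k"]], 0)                   # 22 ppm off
  # one peak can satisfy at most one fragment
  kn <- match_fragments(c(500.000, 500.004),
                        data.frame(mz = 500.002, intensity = 1), 20)
  expect_equal(kn[["k"]], 1L)
  expect_equal(kn[["n"]], 2L)
})

test_that("the binomial match score follows the printed recipe", {
  s0 <- ptm_score(5, 0)
  expect_equal(s0$p_binom, 0.96^5, tolerance = 1e-12)
  expect_equal(s0$score, -10 * log10(0.96^5), tolerance = 1e-12)
  s2 <- ptm_score(5, 2)
  expect_equal(s2$p_binom, choose(5, 2) * 0.04^2 * 0.96^3, tolerance = 1e-12)
  expect_equal(s2$p_binom, dbinom(2, 5, 0.04), tolerance = 1e-12)
  # truncated-product variant drops (1-p)^(n-k)
  st <- ptm_score(5, 2, full_binomial = FALSE)
  expect_equal(st$p_binom, choose(5, 2) * 0.04^2, tolerance = 1e-12)
  # score is monotone increasing in k at fixed n
  scores <- vapply(0:12, function(k) ptm_score(12, k)$score, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_error(ptm_score(0, 0), "n must")
})

test_that("a single candidate arginine gets probability 1", {
  sp <- synth_spectrum("VLDRVVNGK", true_sites = 4, coverage = 1, seed = 1)
  res <- site_probabilities(sp)
  expect_equal(unname(res$site_probabilities), 1)
})

test_that("a non-discriminating spectrum gives exactly 0.50/0.50", {
  sp <- nondiscriminating_spectrum("VLDRRVVNGK", 1)
  res <- site_probabilities(sp)
  expect_identical(unname(res$site_probabilities[["R4"]]), 0.5)
  expect_identical(unname(res$site_probabilities[["R5"]]), 0.5)
  expect_equal(res$configurations$k[1], res$configurations$k[2])
})

test_that("one discriminating ion tips the balance as the enumeration
           oracle predicts", {
  pep <- "VLDRRVVNGK"
  sp0 <- nondiscriminating_spectrum(pep, 1)
  # add y6 (RVVNGK) of the R4 configuration: contains R5 unmodified and
  # no citrulline, so it discriminates for R4
  y6_r4 <- theoretical_fragments(pep, 4)
  y6_mz <- y6_r4$mz[y6_r4$ion == "y6"]
  peaks <- rbind(sp0$peaks, data.frame(mz = y6_mz, intensity = 1000))
  sp1 <- peptide_spectrum(pep, peaks, n_mods = 1)
  res <- site_probabilities(sp1)
  expect_gt(res$site_probabilities[["R4"]], 0.5)
  # independent two-configuration oracle with dbinom
  filtered <- top_peaks_per_window(sp1$peaks)
  p_cfg <- vapply(list(4, 5), function(site) {
    th <- theoretical_fragments(pep, site, range(sp1$peaks$mz))
    hit <- vapply(th$mz, function(m) {
      any(abs(filtered$mz - m) <= m * 20e-6)
    }, logical(1))
    dbinom(sum(hit), length(hit), 0.04)
  }, numeric(1))
  w <- (1 / p_cfg) / sum(1 / p_cfg)
  expect_equal(unname(res$site_probabilities[["R4"]]), w[1],
               tolerance = 1e-9)
})

test_that("site probabilities conserve mass and respect symmetry", {
  pep <- "VLDRRVVNGK"
  for (s in 1:5) {
    sp <- synth_spectrum(pep, true_sites = 4, coverage = 0.8,
                         noise_peaks = 20, seed = s)
    res <- site_probabilities(sp)
    expect_equal(sum(res$site_probabilities), 1, tolerance = 1e-9)
  }
  # swapping the two sites' discriminating ions swaps the probabilities
  shared <- nondiscriminating_spectrum(pep, 1)$peaks
  b4_of <- function(site) {
    th <- theoretical_fragments(pep, site)
    th$mz[th$ion == "b4"]       # b4 discriminates: contains R4 only
  }
  spA <- peptide_spectrum(pep, rbind(shared, data.frame(
    mz = b4_of(4), intensity = 500)), 1)
  spB <- peptide_spectrum(pep, rbind(shared, data.frame(
    mz = b4_of(5), intensity = 500)), 1)
  pA <- site_probabilities(spA)$site_probabilities
  pB <- site_probabilities(spB)$site_probabilities
  expect_equal(unname(pA[["R4"]]), unname(pB[["R5"]]), tolerance = 1e-12)
  expect_equal(unname(pA[["R5"]]), unname(pB[["R4"]]), tolerance = 1e-12)
})

test_that("full-coverage spectra localize the true site almost surely", {
  sp <- synth_spectrum("VLDRRVVNGK", true_sites = 4, coverage = 1,
                       noise_peaks = 0, seed = 2)
  res <- site_probabilities(sp)
  expect_gte(res$site_probabilities[["R4"]], 0.99)
  # coverage 0: uninformative, uniform probabilities
  sp0 <- synth_spectrum("VLDRRVVNGK", true_sites = 4, coverage = 0, seed = 3)
  res0 <- site_probabilities(sp0)
  expect_equal(unname(res0$site_probabilities),
               c(0.5, 0.5), tolerance = 1e-9)
  expect_error(synth_spectrum("VLDRRVVNGK", 4, coverage = 1.4), "coverage")
})

test_that("the true site wins on the bulk of informative synthetic
           spectra", {
  pep <- "VLDRRVVNGKVEYFLK"
  wins <- 0L; informative <- 0L
  for (s in 1:200) {
    true_site <- if (s %% 2 == 0) 4 else 5
    sp <- synth_spectrum(pep, true_sites = true_site, coverage = 0.85,
                         noise_peaks = 10, seed = 1000 + s)
    res <- site_probabilities(sp)
    # count spectra where the configurations actually differ in matches
    if (res$configurations$k[1] != res$configurations$k[2]) {
      informative <- informative + 1L
      best <- names(which.max(res$site_probabilities))
      if (best == paste0("R", true_site)) wins <- wins + 1L
    }
  }
  expect_gte(informative, 50L)
  expect_gte(wins / informative, 0.95)
})

test_that("peak lists round-trip through CSV and MGF", {
  peaks <- data.frame(mz = c(147.1128, 258.2, 500.5),
                      intensity = c(100, 50, 75))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(peaks, csv, row.names = FALSE)
  expect_equal(read_peaks(csv), peaks)
  mgf <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=synthetic", "PEPMASS=600.3",
               sprintf("%.4f %.1f", peaks$mz, peaks$intensity),
               "END IONS"), mgf)
  got <- read_peaks(mgf)
  expect_equal(got$mz, peaks$mz, tolerance = 1e-4)
  expect_equal(got$intensity, peaks$intensity)
})
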