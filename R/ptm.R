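# monoisotopic residue masses (Da); citrulline = Arg + mass_shift_cit
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
PROTON_MASS <- 1.00727646688
WATER_MASS <- 18.0105646863
CIT_MASS_SHIFT <- 0.984016

#' Construct a peptide/spectrum pair for PTM localization
#'
#' @param peptide Amino-acid string (uppercase one-letter codes), e.g.
#'   the LysC peptide `"VLDRRVVNGK"`.
#' @param peaks Data.frame with columns `mz` (Th) and `intensity` (> 0);
#'   re-sorted by m/z.
#' @param n_mods Number of citrulline modifications carried by the
#'   peptide; the peptide must contain at least this many arginines.
#' @param charge Precursor charge (informational; fragments are scored
#'   singly charged).
#' @param fragment_tolerance Fragment match tolerance in ppm (default 20).
#' @return An object of class `peptide_spectrum`.
#' @export
peptide_spectrum <- function(peptide, peaks, n_mods = 1L, charge = 2L,
                             fragment_tolerance = 20) {
  residues <- strsplit(peptide, "")[[1]]
  if (!all(residues %in% names(AA_MONO))) {
    stop("unknown residue letter(s): ",
         paste(setdiff(residues, names(AA_MONO)), collapse = ", "))
  }
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity <= 0)) stop("peak intensities must be > 0")
  n_arg <- sum(residues == "R")
  if (n_arg < n_mods) {
    stop("peptide has ", n_arg, " arginines but n_mods = ", n_mods)
  }
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peptide = peptide, peaks = peaks,
                 n_mods = as.integer(n_mods), charge = as.integer(charge),
                 fragment_tolerance = fragment_tolerance),
            class = "peptide_spectrum")
}

#' @export
print.peptide_spectrum <- function(x, ...) {
  cat(sprintf("peptide_spectrum: %s (+%d citrulline), %d peaks, %g ppm tolerance\n",
              x$peptide, x$n_mods, nrow(x$peaks), x$fragment_tolerance))
  invisible(x)
}

#' Theoretical b/y fragment ions of a (citrullinated) peptide
#'
#' Singly charged b- and y-ion m/z values from monoisotopic residue
#' masses; citrulline adds +0.984016 Da to the arginine it modifies, so
#' every fragment containing a modified site is shifted by that amount.
#'
#' @param peptide Amino-acid string.
#' @param modified_positions Integer vector of 1-based residue positions
#'   carrying citrulline; must all be arginines.
#' @param mass_range Optional `c(min, max)` m/z window (Th) restricting
#'   the returned ions to the observed range.
#' @return Data.frame with columns `ion` (e.g. "b3", "y6"), `type`,
#'   `index`, `mz`.
#' @examples
#' theoretical_fragments("GK")  # b1 = 58.0287, y1 = 147.1128
#' @export
theoretical_fragments <- function(peptide, modified_positions = integer(),
                                  mass_range = NULL) {
  residues <- strsplit(peptide, "")[[1]]
  if (!all(residues %in% names(AA_MONO))) {
    stop("unknown residue letter(s): ",
         paste(setdiff(residues, names(AA_MONO)), collapse = ", "))
  }
  L <- length(residues)
  if (length(modified_positions)) {
    if (any(modified_positions < 1 | modified_positions > L) ||
        any(residues[modified_positions] != "R")) {
      stop("modified positions must index arginines within the peptide")
    }
  }
  m <- unname(AA_MONO[residues])
  m[modified_positions] <- m[modified_positions] + CIT_MASS_SHIFT
  b_mz <- cumsum(m)[-L] + PROTON_MASS
  y_mz <- rev(cumsum(rev(m))[-L]) + WATER_MASS + PROTON_MASS
  out <- data.frame(
    ion = c(paste0("b", seq_len(L - 1L)), paste0("y", (L - 1L):1L)),
    type = rep(c("b", "y"), each = L - 1L),
    index = c(seq_len(L - 1L), (L - 1L):1L),
    mz = c(b_mz, y_mz))
  if (!is.null(mass_range)) {
    out <- out[out$mz >= mass_range[1] & out$mz <= mass_range[2], ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Keep the most intense peaks per m/z window
#'
#' Within each contiguous window (default 100 amu, counted from the
#' spectrum's lowest m/z), retains the `peaks_per_window` most intense
#' peaks (default 10).
#'
#' @param peaks Data.frame with `mz` and `intensity`.
#' @param peaks_per_window Peaks to keep per window.
#' @param window Window width in amu.
#' @return Filtered peak data.frame, sorted by m/z.
#' @export
top_peaks_per_window <- function(peaks, peaks_per_window = 10L,
                                 window = 100) {
  stopifnot(window > 0, peaks_per_window >= 1L)
  if (nrow(peaks) == 0L) return(peaks)
  bin <- floor((peaks$mz - min(peaks$mz)) / window)
  keep <- unlist(lapply(split(seq_len(nrow(peaks)), bin), function(idx) {
    idx[order(peaks$intensity[idx], decreasing = TRUE)][
      seq_len(min(peaks_per_window, length(idx)))]
  }), use.names = FALSE)
  out <- peaks[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match theoretical fragments to observed peaks
#'
#' Counts `n`, the number of theoretical fragments (in the observed
#' range), and `k`, how many are matched by a filtered peak within the
#' ppm tolerance. Candidate matches are resolved nearest-first and each
#' peak matches at most one fragment.
#'
#' @param theoretical Numeric vector of theoretical fragment m/z.
#' @param peaks Filtered peak data.frame (`mz`, `intensity`).
#' @param tolerance_ppm Match tolerance in ppm (default 20).
#' @return Named integer vector `c(k, n)`.
#' @export
match_fragments <- function(theoretical, peaks, tolerance_ppm = 20) {
  stopifnot(tolerance_ppm > 0)
  n <- length(theoretical)
  if (n == 0L || nrow(peaks) == 0L) return(c(k = 0L, n = n))
  cand <- NULL
  for (i in seq_len(n)) {
    tol <- theoretical[i] * tolerance_ppm * 1e-6
    hits <- which(abs(peaks$mz - theoretical[i]) <= tol)
    if (length(hits)) {
      cand <- rbind(cand, cbind(frag = i, peak = hits,
                                d = abs(peaks$mz[hits] - theoretical[i])))
    }
  }
  if (is.null(cand)) return(c(k = 0L, n = n))
  cand <- cand[order(cand[, "d"]), , drop = FALSE]
  used_f <- logical(n); used_p <- logical(nrow(peaks))
  k <- 0L
  for (j in seq_len(nrow(cand))) {
    fi <- cand[j, "frag"]; pi <- cand[j, "peak"]
    if (!used_f[fi] && !used_p[pi]) {
      used_f[fi] <- TRUE; used_p[pi] <- TRUE; k <- k + 1L
    }
  }
  c(k = k, n = n)
}

#' Binomial PTM match score
#'
#' Probability of observing `k` fragment matches out of `n` candidate
#' ions by chance, with per-ion match probability `match_p` (0.04), and
#' the derived localization score `-10 * log10(p)`. The default uses the
#' full binomial probability
#' `C(n, k) * match_p^k * (1 - match_p)^(n - k)`; setting
#' `full_binomial = FALSE` drops the `(1 - p)^(n - k)` factor.
#'
#' @param n Number of candidate theoretical fragments (> 0).
#' @param k Number of matches (0 <= k <= n).
#' @param match_p Per-fragment chance match probability (default 0.04).
#' @param full_binomial Use the full binomial pmf (default TRUE).
#' @return List with `p_binom` and `score`.
#' @examples
#' ptm_score(5, 2)
#' @export
ptm_score <- function(n, k, match_p = 0.04, full_binomial = TRUE) {
  if (n <= 0) stop("n must be > 0")
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  p <- if (full_binomial) {
    choose(n, k) * match_p^k * (1 - match_p)^(n - k)
  } else {
    choose(n, k) * match_p^k
  }
  list(p_binom = p, score = -10 * log10(p))
}

#' Per-site citrullination localization probabilities
#'
#' Enumerates every placement of the peptide's citrullines over its
#' candidate arginines, scores each configuration by binomial fragment
#' matching ([ptm_score()]) against the top-peaks-filtered spectrum, and
#' converts scores to configuration probabilities with weights
#' proportional to `1 / p_binom` (equivalently `10^(score / 10)`),
#' normalized over configurations. A site's localization probability is
#' the summed weight of the configurations that contain it.
#'
#' @param spectrum A [peptide_spectrum()].
#' @param peaks_per_window,window Peak filtering parameters (10 per
#'   100 amu).
#' @param match_p Chance match probability (0.04).
#' @param full_binomial See [ptm_score()].
#' @return An object of class `ptm_localization`: list with
#'   `site_probabilities` (named by residue position, summing to
#'   `n_mods`), `configurations` (per-configuration k, n, p, score,
#'   probability) and `candidate_sites`.
#' @export
site_probabilities <- function(spectrum, peaks_per_window = 10L,
                               window = 100, match_p = 0.04,
                               full_binomial = TRUE) {
  stopifnot(inherits(spectrum, "peptide_spectrum"))
  residues <- strsplit(spectrum$peptide, "")[[1]]
  cand <- which(residues == "R")
  if (length(cand) == 0L) stop("no candidate arginine in peptide")
  filtered <- top_peaks_per_window(spectrum$peaks, peaks_per_window, window)
  mass_range <- if (nrow(spectrum$peaks)) range(spectrum$peaks$mz) else NULL
  configs <- lapply(utils::combn(seq_along(cand), spectrum$n_mods,
                                 simplify = FALSE), function(i) cand[i])
  rows <- lapply(configs, function(sites) {
    th <- theoretical_fragments(spectrum$peptide, sites, mass_range)
    kn <- match_fragments(th$mz, filtered, spectrum$fragment_tolerance)
    sc <- ptm_score(max(kn[["n"]], 1L), kn[["k"]], match_p, full_binomial)
    data.frame(sites = paste(sites, collapse = "+"),
               k = kn[["k"]], n = kn[["n"]],
               p_binom = sc$p_binom, score = sc$score)
  })
  tab <- do.call(rbind, rows)
  w <- 1 / tab$p_binom
  tab$probability <- w / sum(w)
  site_p <- vapply(cand, function(s) {
    sum(tab$probability[vapply(configs, function(cf) s %in% cf, logical(1))])
  }, numeric(1))
  names(site_p) <- paste0("R", cand)
  structure(list(peptide = spectrum$peptide, n_mods = spectrum$n_mods,
                 site_probabilities = site_p, configurations = tab,
                 candidate_sites = cand),
            class = "ptm_localization")
}

#' @export
print.ptm_localization <- function(x, digits = 3, ...) {
  cat(sprintf("PTM localization for %s (+%d citrulline)\n", x$peptide,
              x$n_mods))
  cat("  site probabilities:",
      paste(sprintf("%s = %s", names(x$site_probabilities),
                    signif(x$site_probabilities, digits)), collapse = ", "),
      "\n")
  cat(sprintf("  %d configurations scored; best score %.2f\n",
              nrow(x$configurations), max(x$configurations$score)))
  invisible(x)
}

#' Generate a synthetic fragmentation spectrum
#'
#' Builds a peak list from the theoretical b/y ions of the true
#' modification configuration at a given fragment coverage, plus
#' uniform-random decoy peaks, for testing the localization scorer.
#'
#' @param peptide Amino-acid string.
#' @param true_sites 1-based arginine positions carrying citrulline.
#' @param coverage Fraction of theoretical ions present in `[0, 1]`.
#' @param noise_peaks Number of random decoy peaks.
#' @param intensity Mean signal peak intensity.
#' @param seed Optional integer seed.
#' @return A [peptide_spectrum()].
#' @export
synth_spectrum <- function(peptide, true_sites, coverage = 1,
                           noise_peaks = 0L, intensity = 1000,
                           seed = NULL) {
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  th <- theoretical_fragments(peptide, true_sites)
  keep <- stats::runif(nrow(th)) < coverage
  mz <- th$mz[keep]
  ints <- intensity * stats::rlnorm(sum(keep), 0, 0.3)
  if (noise_peaks > 0L) {
    lo <- min(th$mz) - 20; hi <- max(th$mz) + 20
    mz <- c(mz, stats::runif(noise_peaks, lo, hi))
    ints <- c(ints, intensity * 0.2 * stats::runif(noise_peaks))
  }
  if (length(mz) == 0L) {
    # uninformative spectrum: single far-off peak so the object is valid
    mz <- max(th$mz) + 50
    ints <- intensity * 0.01
  }
  peptide_spectrum(peptide, data.frame(mz = mz, intensity = ints),
                   n_mods = length(true_sites))
}

#' Peak list of ions shared by all modification configurations
#'
#' Returns the theoretical b/y ions whose m/z is identical (within the
#' tolerance) across every placement of `n_mods` citrullines on the
#' peptide's arginines — a spectrum containing only these ions carries
#' no site information, so all configurations score equally.
#'
#' @param peptide Amino-acid string.
#' @param n_mods Number of citrullines.
#' @param intensity Peak intensity assigned to every shared ion.
#' @param tolerance_ppm Equality tolerance in ppm.
#' @return A [peptide_spectrum()] containing only non-discriminating
#'   ions.
#' @export
nondiscriminating_spectrum <- function(peptide, n_mods = 1L,
                                       intensity = 1000,
                                       tolerance_ppm = 20) {
  residues <- strsplit(peptide, "")[[1]]
  cand <- which(residues == "R")
  configs <- lapply(utils::combn(seq_along(cand), n_mods,
                                 simplify = FALSE), function(i) cand[i])
  frag_sets <- lapply(configs, function(s) {
    theoretical_fragments(peptide, s)$mz
  })
  ref <- frag_sets[[1]]
  shared <- vapply(seq_along(ref), function(i) {
    all(vapply(frag_sets[-1], function(other) {
      any(abs(other - ref[i]) <= ref[i] * tolerance_ppm * 1e-6)
    }, logical(1)))
  }, logical(1))
  mz <- ref[shared]
  peptide_spectrum(peptide,
                   data.frame(mz = mz,
                              intensity = rep(intensity, length(mz))),
                   n_mods = n_mods)
}

#' Read a peak list from CSV or a minimal MGF file
#'
#' CSV needs columns `mz` and `intensity` (or two unnamed columns); MGF
#' is parsed for numeric "m/z intensity" lines between BEGIN IONS and
#' END IONS.
#'
#' @param path File path; format inferred from the `.mgf` extension.
#' @return Data.frame with `mz` and `intensity`.
#' @export
read_peaks <- function(path) {
  if (grepl("\\.mgf$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    dat <- lines[grepl("^[0-9]", lines)]
    parts <- strsplit(trimws(dat), "[ \t]+")
    data.frame(mz = as.numeric(vapply(parts, `[`, "", 1)),
               intensity = as.numeric(vapply(parts, `[`, "", 2)))
  } else {
    out <- utils::read.csv(path)
    if (!all(c("mz", "intensity") %in% names(out))) {
      names(out)[1:2] <- c("mz", "intensity")
    }
    out[c("mz", "intensity")]
  }
}
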