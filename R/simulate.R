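#' Default GC-dependent capture-rate multiplier
#'
#' A smooth unimodal bias curve peaking near GC 0.45 with range
#' \[0.5, 1.5\]: windows of intermediate GC amplify best, AT- or GC-extreme
#' windows are under-captured. Used by the simulators to emulate the
#' deviation-then-rescue behavior that GC normalization addresses.
#'
#' @param gc GC fractions.
#' @return Rate multipliers in \[0.5, 1.5\].
#' @export
gc_bias_curve <- function(gc) {
  0.5 + exp(-((gc - 0.45)^2) / (2 * 0.12^2))
}

#' Simulate a sparse capture depth profile
#'
#' Emulates the depth regime of inter-Alu capture sequencing: only a
#' fraction of windows is covered at all (the capture leaves most of the
#' genome empty), covered windows draw Poisson counts at
#' `base_lambda * gc multiplier * fold`, uncovered windows are zero.
#'
#' @param windows Window tibble (GC-annotated when `gc_bias = TRUE`).
#' @param base_lambda Mean depth of covered, unbiased, copy-neutral windows
#'   (default 100; the GHT normal approximation needs roughly >= 50).
#' @param coverage_fraction Fraction of windows with nonzero capture
#'   (default 0.3).
#' @param cnv_regions Optional tibble of injected CNVs with columns
#'   `start_window`, `end_window` (1-based inclusive row indices into
#'   `windows`) and `fold` (rate multiplier, e.g. 2 for a 2x gain, 0.5 for
#'   a loss).
#' @param gc_bias Apply [gc_bias_curve()] to the rate (requires `gc`).
#' @param coverage_mask Optional logical vector overriding the random
#'   coverage mask (used to share one mask between paired samples).
#' @param seed Optional seed; identical seed and arguments give an identical
#'   profile.
#' @return A depth profile; attributes `truth` (list with the arguments and
#'   the coverage mask) and `sample_id`.
#' @export
simulate_profile <- function(windows, base_lambda = 100, coverage_fraction = 0.3,
                             cnv_regions = NULL, gc_bias = FALSE,
                             coverage_mask = NULL, seed = NULL) {
  stopifnot(base_lambda >= 0, coverage_fraction > 0, coverage_fraction <= 1)
  n <- nrow(windows)
  run <- function() {
    mask <- coverage_mask %||% (stats::runif(n) < coverage_fraction)
    rate <- rep(base_lambda, n)
    if (gc_bias) {
      if (!"gc" %in% names(windows)) stop("gc_bias requires GC-annotated windows",
                                          call. = FALSE)
      rate <- rate * gc_bias_curve(windows$gc)
    }
    fold <- rep(1, n)
    if (!is.null(cnv_regions)) {
      stopifnot(all(cnv_regions$fold > 0))
      for (i in seq_len(nrow(cnv_regions))) {
        idx <- cnv_regions$start_window[i]:cnv_regions$end_window[i]
        fold[idx] <- cnv_regions$fold[i]
      }
    }
    depth <- ifelse(mask, stats::rpois(n, rate * fold), 0L)
    out <- dplyr::mutate(windows, depth = as.integer(depth))
    attr(out, "truth") <- list(
      base_lambda = base_lambda, coverage_fraction = coverage_fraction,
      cnv_regions = cnv_regions, gc_bias = gc_bias, coverage_mask = mask,
      seed = seed
    )
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a test/control pair
#'
#' The control is drawn copy-neutral (no CNV folds); the test carries the
#' requested `cnv_regions`. With `shared_coverage = TRUE` (default) both
#' samples use the same coverage mask, emulating a shared capture design so
#' that the common-window set equals the covered set.
#'
#' @inheritParams simulate_profile
#' @param shared_coverage Share one coverage mask between the two samples.
#' @return A list with elements `test` and `control` (depth profiles).
#' @export
simulate_pair <- function(windows, base_lambda = 100, coverage_fraction = 0.3,
                          cnv_regions = NULL, gc_bias = FALSE,
                          shared_coverage = TRUE, seed = NULL) {
  run <- function() {
    n <- nrow(windows)
    mask <- if (shared_coverage) stats::runif(n) < coverage_fraction else NULL
    control <- simulate_profile(windows, base_lambda, coverage_fraction,
                                cnv_regions = NULL, gc_bias = gc_bias,
                                coverage_mask = mask)
    test <- simulate_profile(windows, base_lambda, coverage_fraction,
                             cnv_regions = cnv_regions, gc_bias = gc_bias,
                             coverage_mask = mask)
    attr(test, "sample_id") <- "test"
    attr(control, "sample_id") <- "control"
    list(test = test, control = control)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a binary CNV cohort with known recurrent regions
#'
#' Generates an n-sample binary CNV matrix in which each injected recurrent
#' region is carried by each sample independently with its penetrance and
#' every other window is a background CNV independently at
#' `background_rate`.
#'
#' @param n_samples Number of cohort samples.
#' @param n_windows Number of windows (matrix rows).
#' @param recurrent_regions Optional tibble with columns `start_window`,
#'   `end_window`, `penetrance`.
#' @param background_rate Per-window background CNV probability
#'   (default 0.1).
#' @param seed Optional seed.
#' @return A list: `M` (binary matrix, windows x samples), `truth` (logical
#'   vector marking injected windows).
#' @export
simulate_cohort <- function(n_samples, n_windows, recurrent_regions = NULL,
                            background_rate = 0.1, seed = NULL) {
  stopifnot(background_rate >= 0, background_rate <= 1)
  run <- function() {
    M <- matrix(stats::rbinom(n_windows * n_samples, 1, background_rate),
                nrow = n_windows, ncol = n_samples)
    truth <- logical(n_windows)
    if (!is.null(recurrent_regions)) {
      stopifnot(all(recurrent_regions$penetrance >= 0),
                all(recurrent_regions$penetrance <= 1))
      for (i in seq_len(nrow(recurrent_regions))) {
        idx <- recurrent_regions$start_window[i]:recurrent_regions$end_window[i]
        truth[idx] <- TRUE
        M[idx, ] <- stats::rbinom(length(idx) * n_samples, 1,
                                  recurrent_regions$penetrance[i])
      }
    }
    rownames(M) <- paste0("w", seq_len(n_windows))
    colnames(M) <- paste0("s", seq_len(n_samples))
    list(M = M, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a two-class cohort feature table
#'
#' Builds a binary feature table for classifier evaluation: `n_per_class`
#' samples per class, `n_signal` class-associated windows carried at
#' `penetrance_case` in class "case" versus `penetrance_control` in class
#' "control", among `n_noise` background windows at `background_rate` in
#' both classes.
#'
#' @param n_per_class Samples per class (default 20).
#' @param n_signal Injected discriminative windows (default 10).
#' @param n_noise Background windows (default 2000).
#' @param penetrance_case,penetrance_control Carrier probabilities of the
#'   signal windows in the two classes (defaults 0.9 and 0.1).
#' @param background_rate Background CNV rate (default 0.1).
#' @param seed Optional seed.
#' @return A list: `x` (binary matrix, samples x features; signal features
#'   named `sig1..`), `y` (factor of class labels), `signal_features`.
#' @export
simulate_labeled_cohort <- function(n_per_class = 20, n_signal = 10,
                                    n_noise = 2000, penetrance_case = 0.9,
                                    penetrance_control = 0.1,
                                    background_rate = 0.1, seed = NULL) {
  run <- function() {
    n <- 2 * n_per_class
    y <- factor(rep(c("case", "control"), each = n_per_class))
    sig <- rbind(
      matrix(stats::rbinom(n_per_class * n_signal, 1, penetrance_case),
             nrow = n_per_class),
      matrix(stats::rbinom(n_per_class * n_signal, 1, penetrance_control),
             nrow = n_per_class)
    )
    noise <- matrix(stats::rbinom(n * n_noise, 1, background_rate), nrow = n)
    x <- cbind(sig, noise)
    colnames(x) <- c(paste0("sig", seq_len(n_signal)),
                     paste0("noise", seq_len(n_noise)))
    rownames(x) <- paste0(rep(c("case", "ctrl"), each = n_per_class),
                          rep(seq_len(n_per_class), 2))
    list(x = x, y = y, signal_features = paste0("sig", seq_len(n_signal)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
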