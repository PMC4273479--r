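#' GC-correct a read depth
#'
#' D_corrected = D_global * D_raw / D_GC, where D_global is the median depth
#' over the sample's analyzed windows and D_GC the median depth of the
#' window's 5%-GC group. A window whose group median is zero cannot be
#' corrected and is excluded upstream.
#'
#' @param d_raw Raw window depths.
#' @param d_global Sample-wide median depth (scalar).
#' @param d_gc Median depth of each window's GC group (recycled).
#' @return Corrected depths.
#' @export
gc_correct <- function(d_raw, d_global, d_gc) {
  if (any(d_gc <= 0)) stop("GC-group median depth must be positive", call. = FALSE)
  d_global * d_raw / d_gc
}

#' Standardized log-ratio Z scores
#'
#' Z = (ln r - mean ln r) / sd(ln r), with mean and sd taken over all
#' analyzed windows of the test sample (sample standard deviation, n - 1).
#'
#' @param r Positive corrected depth ratios.
#' @return Z scores with mean 0 and sd 1.
#' @export
z_scores <- function(r) {
  if (any(r <= 0)) stop("ratios must be positive to take logs", call. = FALSE)
  if (length(r) < 2) stop("need at least 2 windows", call. = FALSE)
  lr <- log(r)
  s <- stats::sd(lr)
  if (s == 0) stop("log-ratios are constant; Z scores are degenerate", call. = FALSE)
  (lr - mean(lr)) / s
}

#' Circular binary segmentation of a Z-score vector
#'
#' Recursively splits a window sequence at the boundary pair maximizing the
#' circular mean-shift statistic, accepting a split when its permutation
#' p-value falls below `alpha`, until no segment splits further. The
#' permutation test shuffles the segment's values with R's RNG and applies a
#' sequential early-stopping rule (see Details), so results are reproducible
#' under a fixed seed.
#'
#' @details The statistic for a candidate arc against its complement is the
#' absolute difference of means scaled by `sqrt(l * (n - l) / n)` and the
#' segment-global standard deviation; because the global sd is invariant
#' under permutation it cancels from exceedance comparisons. Permutations
#' are examined in blocks: the test stops "not significant" as soon as the
#' exceedance count guarantees p >= alpha, and stops "significant" at a
#' block boundary once the observed (low) exceedance count would itself be a
#' < 0.1% probability event if the true exceedance rate were alpha.
#'
#' @param z Numeric vector of window Z scores for one chromosome.
#' @param alpha Split significance level (default 0.01).
#' @param n_perm Maximum permutations per split test (default 10000).
#' @param min_width Minimum segment width in windows (default 2).
#' @param seed Optional integer; when given, the whole segmentation runs
#'   under this seed (identical seed + input => identical segments).
#' @return Tibble with one row per segment: `start_window`, `end_window`
#'   (1-based inclusive window indices), `n_windows`, `mean_z`.
#' @export
cbs_segment <- function(z, alpha = 0.01, n_perm = 10000, min_width = 2,
                        seed = NULL) {
  stopifnot(is.numeric(z), alpha > 0, alpha < 1, n_perm >= 1, min_width >= 1)
  run <- function() {
    bounds <- sort(unique(c(0L, cbs_changepoints(z, alpha, n_perm, min_width),
                            length(z))))
    tibble::tibble(
      start_window = utils::head(bounds, -1) + 1L,
      end_window = utils::tail(bounds, -1)
    ) |>
      dplyr::mutate(
        n_windows = .data$end_window - .data$start_window + 1L,
        mean_z = purrr::map2_dbl(.data$start_window, .data$end_window,
                                 ~ mean(z[.x:.y]))
      )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# recursive changepoint search on z[(offset+1)..(offset+n)]; returns global
# 0-based cut positions
cbs_changepoints <- function(z, alpha, n_perm, min_width, offset = 0L) {
  n <- length(z)
  if (n < 2 * min_width) return(integer(0))
  ms <- cbs_max_stat_cpp(z, min_width)
  if (ms$u <= 0 || ms$sd == 0) return(integer(0))
  pv <- cbs_perm_pvalue_cpp(z, ms$u, n_perm, alpha, min_width)
  if (!pv$significant) return(integer(0))
  i <- ms$i
  j <- ms$j
  cuts <- c(if (i > 0) offset + i, if (j < n) offset + j)
  pieces <- list()
  if (i > 0) pieces <- c(pieces, list(list(z = z[1:i], off = offset)))
  pieces <- c(pieces, list(list(z = z[(i + 1):j], off = offset + i)))
  if (j < n) pieces <- c(pieces, list(list(z = z[(j + 1):n], off = offset + j)))
  for (pc in pieces) {
    cuts <- c(cuts, cbs_changepoints(pc$z, alpha, n_perm, min_width, pc$off))
  }
  as.integer(cuts)
}

#' Classify segments into extended CNV states
#'
#' A segment is an extended copy-number gain when its mean Z >= `z_threshold`
#' and an extended loss when mean Z <= -`z_threshold` (both inclusive,
#' default 0.2); neutral otherwise.
#'
#' @param segments Segment tibble with a `mean_z` column.
#' @param z_threshold Symmetric classification threshold (default 0.2).
#' @return `segments` with an added `state` factor column.
#' @export
classify_segments <- function(segments, z_threshold = 0.2) {
  dplyr::mutate(segments, state = factor(
    dplyr::case_when(
      .data$mean_z >= z_threshold ~ "gain",
      .data$mean_z <= -z_threshold ~ "loss",
      TRUE ~ "neutral"
    ),
    levels = c("gain", "loss", "neutral")
  ))
}

#' Read-depth correlation QC between test and control
#'
#' Pearson correlation of window depths over the common (positive-depth)
#' windows. A high correlation between the test sample and its paired
#' control or the reference template is a prerequisite for meaningful
#' CBS-based extended calling.
#'
#' @param test,control Depth profiles on identical windows.
#' @return Pearson correlation coefficient.
#' @export
qc_correlation <- function(test, control) {
  common <- common_windows(test, control)
  if (nrow(common) < 3) stop("need at least 3 common windows", call. = FALSE)
  if (stats::sd(common$depth_test) == 0 || stats::sd(common$depth_control) == 0) {
    stop("zero depth variance; correlation undefined", call. = FALSE)
  }
  stats::cor(common$depth_test, common$depth_control)
}

#' Call extended CNVs by GC correction, Z scoring and CBS
#'
#' The extended-CNV pipeline: restrict to windows with positive depth in
#' both samples, GC-correct each sample's depths (median-based, per 5%-GC
#' group), form the corrected depth ratio and its standardized log Z score,
#' segment each chromosome with circular binary segmentation, and classify
#' segments by the +/-`z_threshold` rule. Intended for fine (5 kb) windows.
#'
#' @param test Depth profile of the test sample (GC-annotated).
#' @param control Paired control or reference template (GC-annotated
#'   windows).
#' @param alpha Split significance for CBS (default 0.01).
#' @param n_perm Maximum permutations per split test (default 10000).
#' @param min_width Minimum segment width in windows (default 2).
#' @param z_threshold Extended gain/loss classification threshold
#'   (default 0.2).
#' @param gc_correct Apply the median GC correction before forming ratios
#'   (default TRUE; requires a `gc` column). Windows with undefined GC are
#'   excluded in GC mode.
#' @param qc_min_cor Warn when the depth QC correlation falls below this
#'   (default 0.8).
#' @param seed Optional seed for the permutation tests.
#' @return A tibble of class `cbs_segments`, one row per segment: `chrom`,
#'   `start`, `end` (base coordinates), `n_windows`, `mean_z`, `state`.
#'   Attributes: `z` (window-level tibble with `z`), `qc_correlation`,
#'   `z_threshold`, `alpha`.
#' @export
call_extended <- function(test, control, alpha = 0.01, n_perm = 10000,
                          min_width = 2, z_threshold = 0.2, gc_correct = TRUE,
                          qc_min_cor = 0.8, seed = NULL) {
  common <- common_windows(test, control)
  qc <- stats::cor(common$depth_test, common$depth_control)
  if (is.finite(qc) && qc < qc_min_cor) {
    warning(sprintf(
      "depth correlation between test and control is %.3f (< %.2f); CBS calls may be unreliable",
      qc, qc_min_cor), call. = FALSE)
  }
  if (gc_correct) {
    if (!"gc" %in% names(common)) {
      stop("gc_correct = TRUE requires GC-annotated windows", call. = FALSE)
    }
    common <- dplyr::filter(common, !is.na(.data$gc))
    grp <- gc_group_index(common$gc)
    med_by_group <- function(depth) {
      m <- tapply(depth, grp, stats::median)
      as.numeric(m[as.character(grp)])
    }
    ct <- gc_correct(common$depth_test, stats::median(common$depth_test),
                     med_by_group(common$depth_test))
    cc <- gc_correct(common$depth_control, stats::median(common$depth_control),
                     med_by_group(common$depth_control))
  } else {
    ct <- common$depth_test
    cc <- common$depth_control
  }
  r <- ct / cc
  z <- z_scores(r)
  zt <- dplyr::mutate(common, z = z)
  seg_one <- function(df) {
    seg <- cbs_segment(df$z, alpha = alpha, n_perm = n_perm,
                       min_width = min_width)
    dplyr::mutate(seg,
                  chrom = df$chrom[1],
                  start = df$start[.data$start_window],
                  end = df$end[.data$end_window])
  }
  run <- function() {
    zt |>
      dplyr::group_split(.data$chrom) |>
      purrr::map(seg_one) |>
      purrr::list_rbind()
  }
  segs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  segs <- segs |>
    dplyr::arrange(match(.data$chrom, unique(zt$chrom)), .data$start) |>
    dplyr::select("chrom", "start", "end", "n_windows", "mean_z") |>
    classify_segments(z_threshold)
  attr(segs, "z") <- zt
  attr(segs, "qc_correlation") <- qc
  attr(segs, "z_threshold") <- z_threshold
  attr(segs, "alpha") <- alpha
  class(segs) <- c("cbs_segments", class(segs))
  segs
}

#' @export
print.cbs_segments <- function(x, ...) {
  cat("CBS extended CNV segments: ", nrow(x), " segments (",
      sum(x$state == "gain"), " gain, ", sum(x$state == "loss"),
      " loss); depth QC r = ", round(attr(x, "qc_correlation"), 4), "\n", sep = "")
  NextMethod()
}

#' @method tidy cbs_segments
#' @export
tidy.cbs_segments <- function(x, ...) {
  class(x) <- setdiff(class(x), "cbs_segments")
  attr(x, "z") <- NULL
  x
}

#' @method glance cbs_segments
#' @export
glance.cbs_segments <- function(x, ...) {
  tibble::tibble(
    n_segments = nrow(x),
    n_gain = sum(x$state == "gain"),
    n_loss = sum(x$state == "loss"),
    qc_correlation = attr(x, "qc_correlation"),
    z_threshold = attr(x, "z_threshold"),
    alpha = attr(x, "alpha")
  )
}
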