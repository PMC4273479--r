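#' Pool reference samples into a reference template
#'
#' Sums per-window depths over a set of reference-sample profiles on an
#' identical window tiling. Because window counts are modeled as Poisson, the
#' pooled count is again Poisson with rate equal to the sum of rates, so the
#' template can stand in for a paired control in unpaired analysis.
#' Additivity is exact integer arithmetic.
#'
#' @param profiles List of depth profiles on identical windows.
#' @return A depth profile whose `depth` is the per-window sum, with
#'   attributes `n_samples` and `sample_id = "template"`.
#' @export
build_template <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]
  key <- function(p) paste(p$chrom, p$start, p$end)
  for (p in profiles[-1]) {
    if (nrow(p) != nrow(ref) || !identical(key(p), key(ref))) {
      stop("profiles are on different window sets and cannot be pooled",
           call. = FALSE)
    }
  }
  pooled <- Reduce(`+`, lapply(profiles, function(p) p$depth))
  out <- dplyr::mutate(ref, depth = !!pooled)
  attr(out, "n_samples") <- length(profiles)
  attr(out, "sample_id") <- "template"
  out
}

#' GC-content group of a window
#'
#' Windows are stratified into 20 GC groups of 5% width each:
#' group = floor(gc / 0.05), with gc = 1 clamped into group 19.
#'
#' @param gc GC fractions in \[0, 1\] (NA allowed; propagates).
#' @return Integer group indices in 0..19 (NA for undefined GC).
#' @export
gc_group_index <- function(gc) {
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) {
    stop("gc fractions must lie in [0, 1]", call. = FALSE)
  }
  as.integer(pmin(floor(gc / 0.05), 19))
}

#' Mean depth per GC group
#'
#' Arithmetic mean of window depths within each 5%-GC group, over a supplied
#' analysis subset of windows. These are the group-level rate estimates used
#' by GC-normalized localized calling.
#'
#' @param depth Window depths.
#' @param gc GC fractions of the same windows.
#' @param subset Optional logical/integer index restricting the analysis set.
#' @return Tibble with columns `gc_group`, `mean_depth`, `n`. Groups with no
#'   windows are absent; windows with undefined GC are ignored.
#' @export
gc_group_means <- function(depth, gc, subset = NULL) {
  if (!is.null(subset)) {
    depth <- depth[subset]
    gc <- gc[subset]
  }
  tibble::tibble(gc_group = gc_group_index(gc), depth = depth) |>
    dplyr::filter(!is.na(.data$gc_group)) |>
    dplyr::group_by(.data$gc_group) |>
    dplyr::summarise(mean_depth = mean(.data$depth), n = dplyr::n(),
                     .groups = "drop")
}

#' Analysis window set common to a test and a control profile
#'
#' Only windows with strictly positive depth in both the test sample and the
#' control (paired control or reference template) carry ratio information;
#' all depth statistics of localized and extended calling are restricted to
#' this set.
#'
#' @param test,control Depth profiles on identical windows.
#' @return A tibble of the common windows with columns `chrom`, `start`,
#'   `end`, `depth_test`, `depth_control` and, when both inputs carry GC,
#'   `gc` (taken from the test profile).
#' @export
common_windows <- function(test, control) {
  if (nrow(test) != nrow(control) ||
      !identical(paste(test$chrom, test$start), paste(control$chrom, control$start))) {
    stop("test and control are on different window tilings", call. = FALSE)
  }
  keep <- test$depth > 0 & control$depth > 0
  if (!any(keep)) {
    stop("no window has positive depth in both samples; analysis impossible",
         call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = test$chrom[keep], start = test$start[keep], end = test$end[keep],
    depth_test = test$depth[keep], depth_control = control$depth[keep]
  )
  if ("gc" %in% names(test)) out$gc <- test$gc[keep]
  out
}
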