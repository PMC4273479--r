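#' Binary CNV matrix across a cohort
#'
#' Builds the m x n matrix M of per-window CNV status (1 = CNV of the
#' requested kind called, 0 = not) over a cohort of localized call tables.
#' A window enters the matrix only if it was analyzable (positive depth in
#' sample and control) in every sample, i.e. present in every call table.
#' Gains and losses are analyzed as separate matrices.
#'
#' @param calls Named list of `ght_calls` tibbles (one per sample), all
#'   produced on the same window tiling.
#' @param state `"gain"` or `"loss"`.
#' @return A list of class `cnv_matrix`: `windows` (tibble of the retained
#'   windows), `M` (integer matrix, windows x samples), `state`.
#' @export
build_cnv_matrix <- function(calls, state = c("gain", "loss")) {
  state <- match.arg(state)
  stopifnot(length(calls) >= 1)
  if (is.null(names(calls)) || any(!nzchar(names(calls)))) {
    names(calls) <- paste0("sample", seq_along(calls))
  }
  keys <- lapply(calls, function(x) paste(x$chrom, x$start, x$end))
  common <- Reduce(intersect, keys)
  if (!length(common)) stop("no window is analyzable in every sample", call. = FALSE)
  first <- calls[[1]]
  sel <- match(common, keys[[1]])
  windows <- tibble::tibble(chrom = first$chrom[sel], start = first$start[sel],
                            end = first$end[sel])
  M <- vapply(seq_along(calls), function(j) {
    idx <- match(common, keys[[j]])
    as.integer(calls[[j]]$state[idx] == state)
  }, integer(length(common)))
  dimnames(M) <- list(common, names(calls))
  structure(list(windows = windows, M = M, state = state), class = "cnv_matrix")
}

#' Exact Poisson-binomial probability mass function
#'
#' Distribution of the number of successes K among independent Bernoulli
#' trials with (generally unequal) success probabilities `p`. Computed by
#' iterative dynamic-programming convolution, which is exact and stable up to
#' cohort-scale n; with equal probabilities it reduces to the binomial pmf.
#'
#' @param p Vector of success probabilities in \[0, 1\].
#' @return Numeric vector of length `length(p) + 1` giving P(K = 0..n);
#'   sums to 1.
#' @export
poisson_binomial_pmf <- function(p) {
  if (any(p < 0 | p > 1) || anyNA(p)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  pmf <- 1
  for (pj in p) {
    pmf <- c(pmf * (1 - pj), 0) + c(0, pmf * pj)
  }
  pmf
}

#' Recurrence cutoff count from the Poisson-binomial tail
#'
#' The smallest count k* whose upper-tail probability P(K >= k*) falls below
#' `alpha`; windows carried by at least k* samples are called recurrent.
#' Returns n + 1 when no count qualifies (nothing can be flagged).
#'
#' @param p Per-sample CNV frequencies (Bernoulli rates).
#' @param alpha Tail threshold for recurrence (default 0.01).
#' @return Integer cutoff count k*.
#' @export
recurrence_cutoff <- function(p, alpha = 0.01) {
  pmf <- poisson_binomial_pmf(p)
  tail_prob <- rev(cumsum(rev(pmf)))  # tail_prob[k + 1] = P(K >= k)
  k <- which(tail_prob < alpha)
  if (!length(k)) length(p) + 1L else as.integer(k[1] - 1L)
}

#' Flag recurrent CNVs in a cohort matrix
#'
#' Estimates each sample's CNV frequency as its column mean of the binary
#' matrix, computes the exact Poisson-binomial distribution of the per-window
#' cross-cohort count under independence, and flags windows whose count
#' reaches the tail cutoff (tail probability < `alpha`).
#'
#' @param x A `cnv_matrix` from [build_cnv_matrix()], or a plain binary
#'   matrix (windows x samples).
#' @param alpha Recurrence tail threshold (default 0.01).
#' @param bonferroni If `TRUE`, divide `alpha` by the number of windows m
#'   before computing the cutoff. Off by default.
#' @return A list of class `recurrent_cnv`: `windows` tibble with `k` (count
#'   across samples), `tail_prob` = P(K >= k), `recurrent` flag; `p_sample`
#'   (per-sample frequencies); `cutoff` k*; `pmf`; `alpha` (effective);
#'   `state`.
#' @export
flag_recurrent <- function(x, alpha = 0.01, bonferroni = FALSE) {
  if (inherits(x, "cnv_matrix")) {
    M <- x$M
    windows <- x$windows
    state <- x$state
  } else {
    M <- as.matrix(x)
    windows <- tibble::tibble(window = rownames(M) %||% as.character(seq_len(nrow(M))))
    state <- NA_character_
  }
  if (ncol(M) < 2) stop("recurrence requires at least 2 samples", call. = FALSE)
  if (!all(M %in% c(0, 1))) stop("matrix must be binary 0/1", call. = FALSE)
  eff_alpha <- if (bonferroni) alpha / nrow(M) else alpha
  p_sample <- colMeans(M)
  pmf <- poisson_binomial_pmf(p_sample)
  tail_prob <- rev(cumsum(rev(pmf)))
  cutoff <- recurrence_cutoff(p_sample, eff_alpha)
  k <- rowSums(M)
  out <- list(
    windows = dplyr::mutate(windows, k = k,
                            tail_prob = tail_prob[pmin(k + 1L, length(tail_prob))],
                            recurrent = k >= cutoff),
    p_sample = p_sample, cutoff = cutoff, pmf = pmf,
    alpha = eff_alpha, state = state
  )
  class(out) <- "recurrent_cnv"
  out
}

#' @export
print.recurrent_cnv <- function(x, ...) {
  cat("Recurrent CNV analysis (", x$state, "): ", nrow(x$windows), " windows, ",
      length(x$p_sample), " samples\n", sep = "")
  cat("cutoff count k* = ", x$cutoff, " (tail alpha = ", format(x$alpha),
      "); ", sum(x$windows$recurrent), " recurrent window(s)\n", sep = "")
  invisible(x)
}

#' @method tidy recurrent_cnv
#' @export
tidy.recurrent_cnv <- function(x, ...) tibble::as_tibble(x$windows)

#' @method glance recurrent_cnv
#' @export
glance.recurrent_cnv <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$windows),
    n_samples = length(x$p_sample),
    cutoff = x$cutoff,
    n_recurrent = sum(x$windows$recurrent),
    alpha = x$alpha,
    state = x$state
  )
}
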