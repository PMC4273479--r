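#' Total-read adjusted read-depth ratio
#'
#' The raw per-window ratio z = R_t / R_c is rescaled by the total-read
#' counts of the two samples, r = z * N_c / N_t, so that a uniform difference
#' in sequencing depth does not masquerade as copy-number change.
#'
#' @param r_test,r_control Window depths in the test and control sample
#'   (control depth must be positive; zero-depth windows are excluded
#'   upstream by [common_windows()]).
#' @param n_test,n_control Total read counts of the two samples.
#' @return The adjusted ratio r (vectorized).
#' @export
adjusted_ratio <- function(r_test, r_control, n_test, n_control) {
  if (any(r_control <= 0)) {
    stop("control depth must be positive; exclude zero-depth windows first",
         call. = FALSE)
  }
  if (n_test <= 0 || n_control <= 0) {
    stop("total read counts must be positive", call. = FALSE)
  }
  (r_test / r_control) * (n_control / n_test)
}

#' Geary-Hinkley transformation of a depth ratio
#'
#' Transforms the adjusted ratio r of two approximately normal read depths
#' (Poisson counts at sufficiently high rate, so mean = variance = lambda)
#' into an approximately standard-normal statistic
#' t = (lambda_c * r - lambda_t) / sqrt(lambda_c * r^2 + lambda_t).
#' The normal approximation is good when window rates are high; the package's
#' own calibration runs use lambda >= 50.
#'
#' @param r Adjusted ratios.
#' @param lambda_t,lambda_c Mean read depth over the analyzed windows of the
#'   test and control sample (or per-GC-group means for normalized calling);
#'   recycled against `r`.
#' @return The t statistic (vectorized).
#' @export
ght_t <- function(r, lambda_t, lambda_c) {
  if (any(lambda_t <= 0) || any(lambda_c <= 0)) {
    stop("lambda parameters must be positive", call. = FALSE)
  }
  (lambda_c * r - lambda_t) / sqrt(lambda_c * r^2 + lambda_t)
}

#' Two-sided normal p-value of a GHT statistic
#'
#' p = 2 * (1 - Phi(t)) when r > 1, p = 2 * Phi(t) when r < 1, and p = 1 when
#' r = 1 (no evidence of change by definition).
#'
#' @param t GHT statistics.
#' @param r The matching adjusted ratios (decides the tail).
#' @return p-values in \[0, 1\] (vectorized).
#' @export
two_sided_p <- function(t, r) {
  if (any(!is.finite(t))) stop("t must be finite", call. = FALSE)
  p <- rep(1, length(t))
  up <- r > 1
  dn <- r < 1
  p[up] <- 2 * stats::pnorm(t[up], lower.tail = FALSE)
  p[dn] <- 2 * stats::pnorm(t[dn])
  pmin(p, 1)
}

#' Call localized CNVs with the Geary-Hinkley transformation
#'
#' Per-window gain/loss/neutral calls from read-depth ratios between a test
#' profile and either a paired control or a pooled reference template.
#' Windows with zero depth in either input are excluded (reported in the
#' `excluded` attribute with a reason). For each analysis window the adjusted
#' ratio r, the GHT statistic t and its two-sided normal p-value are
#' computed; a window is a gain when p < alpha and r > 1, a loss when
#' p < alpha and r < 1, and neutral otherwise (r = 1 is always neutral).
#'
#' With `gc_correct = TRUE` the rate parameters are estimated per 5%-GC
#' group (20 groups) instead of globally, which absorbs a shared smooth
#' GC-dependent capture bias. Groups with fewer than `min_group_size`
#' analysis windows fall back to the global rates with a warning.
#'
#' @param test Depth profile of the test sample.
#' @param control Depth profile of the paired control, or a reference
#'   template from [build_template()].
#' @param alpha Per-window significance threshold (default 0.05; no
#'   multiple-testing correction is applied at this stage).
#' @param gc_correct Use per-GC-group rate estimates (requires a `gc` column
#'   on both profiles' windows).
#' @param min_group_size Minimum analysis windows per GC group before falling
#'   back to global rates.
#' @return A tibble of class `ght_calls` with one row per analysis window:
#'   `chrom`, `start`, `end`, `depth_test`, `depth_control`, `r`, `t`, `p`,
#'   `state` (factor gain/loss/neutral), plus `gc`/`gc_group` in GC mode.
#'   Attributes: `excluded` (tibble of excluded windows with `reason`),
#'   `alpha`, `lambda_t`, `lambda_c`, `n_test`, `n_control`.
#' @export
call_localized <- function(test, control, alpha = 0.05, gc_correct = FALSE,
                           min_group_size = 30) {
  stopifnot(alpha > 0, alpha < 1)
  n_t <- total_reads(test)
  n_c <- total_reads(control)
  common <- common_windows(test, control)
  keep_key <- paste(common$chrom, common$start)
  all_key <- paste(test$chrom, test$start)
  excl_idx <- which(!(all_key %in% keep_key))
  excluded <- tibble::tibble(
    chrom = test$chrom[excl_idx], start = test$start[excl_idx],
    end = test$end[excl_idx],
    reason = dplyr::case_when(
      test$depth[excl_idx] <= 0 & control$depth[excl_idx] <= 0 ~ "zero depth in both",
      test$depth[excl_idx] <= 0 ~ "zero depth in test",
      TRUE ~ "zero depth in control"
    )
  )

  lambda_t_global <- mean(common$depth_test)
  lambda_c_global <- mean(common$depth_control)
  r <- adjusted_ratio(common$depth_test, common$depth_control, n_t, n_c)

  if (gc_correct) {
    if (!"gc" %in% names(common)) {
      stop("gc_correct = TRUE requires GC-annotated windows", call. = FALSE)
    }
    grp <- gc_group_index(common$gc)
    grp_t <- gc_group_means(common$depth_test, common$gc)
    grp_c <- gc_group_means(common$depth_control, common$gc)
    lam_t <- lambda_t_global + numeric(nrow(common))
    lam_c <- lambda_c_global + numeric(nrow(common))
    usable <- grp_t$gc_group[grp_t$n >= min_group_size]
    if (length(setdiff(unique(grp[!is.na(grp)]), usable))) {
      warning("some GC groups have fewer than ", min_group_size,
              " windows; global rates used there", call. = FALSE)
    }
    for (g in usable) {
      in_g <- !is.na(grp) & grp == g
      lam_t[in_g] <- grp_t$mean_depth[grp_t$gc_group == g]
      lam_c[in_g] <- grp_c$mean_depth[grp_c$gc_group == g]
    }
    t_stat <- ght_t(r, lam_t, lam_c)
  } else {
    t_stat <- ght_t(r, lambda_t_global, lambda_c_global)
  }

  p <- two_sided_p(t_stat, r)
  state <- dplyr::case_when(
    p < alpha & r > 1 ~ "gain",
    p < alpha & r < 1 ~ "loss",
    TRUE ~ "neutral"
  )
  out <- common
  out$r <- r
  out$t <- t_stat
  out$p <- p
  out$state <- factor(state, levels = c("gain", "loss", "neutral"))
  if (gc_correct) out$gc_group <- gc_group_index(common$gc)
  attr(out, "excluded") <- excluded
  attr(out, "alpha") <- alpha
  attr(out, "lambda_t") <- lambda_t_global
  attr(out, "lambda_c") <- lambda_c_global
  attr(out, "n_test") <- n_t
  attr(out, "n_control") <- n_c
  class(out) <- c("ght_calls", class(out))
  out
}

#' @export
print.ght_calls <- function(x, ...) {
  cat("GHT localized CNV calls: ", nrow(x), " windows (",
      sum(x$state == "gain"), " gain, ", sum(x$state == "loss"), " loss), alpha = ",
      attr(x, "alpha"), "\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy ght_calls
#' @export
tidy.ght_calls <- function(x, ...) {
  class(x) <- setdiff(class(x), "ght_calls")
  attr(x, "excluded") <- NULL
  x
}

#' @method glance ght_calls
#' @export
glance.ght_calls <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    n_gain = sum(x$state == "gain"),
    n_loss = sum(x$state == "loss"),
    n_excluded = nrow(attr(x, "excluded")),
    alpha = attr(x, "alpha"),
    lambda_t = attr(x, "lambda_t"),
    lambda_c = attr(x, "lambda_c")
  )
}
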