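#' Tile a genome into fixed-size windows
#'
#' Divides each chromosome into contiguous, non-overlapping windows of
#' `window_size` bases using 0-based half-open (BED) coordinates. The last
#' window on a chromosome is truncated at the chromosome end. All window-level
#' depth statistics in this package are computed on tilings produced here.
#'
#' @param chrom_sizes Either a named numeric vector of chromosome lengths or a
#'   two-column data frame (`chrom`, `size`).
#' @param window_size Window width in bases; the package default for
#'   segmentation inputs is 5 kb, while localized calling of cancer samples is
#'   usually run on 500 kb windows produced with [merge_windows()].
#' @param autosomes_only If `TRUE` (default), chromosomes named like sex
#'   chromosomes or mitochondria (`chrX`, `chrY`, `chrM`, `MT`) and unplaced
#'   contigs (names containing `_` or `Un`) are dropped. Chromosome names that
#'   match none of those patterns are always kept.
#' @return A tibble with columns `chrom`, `start`, `end`, one row per window,
#'   in input chromosome order.
#' @examples
#' make_windows(c(chr1 = 12000), window_size = 5000)
#' @export
make_windows <- function(chrom_sizes, window_size = 5000, autosomes_only = TRUE) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(ncol(chrom_sizes) >= 2)
    sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  } else {
    sizes <- chrom_sizes
  }
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    stop("chrom_sizes must carry chromosome names", call. = FALSE)
  }
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size < 1 ||
      window_size != as.integer(window_size)) {
    stop("window_size must be a positive integer number of bases", call. = FALSE)
  }
  if (any(sizes < 1)) stop("chromosome lengths must be positive", call. = FALSE)
  if (autosomes_only) {
    drop <- grepl("^(chr)?(X|Y|M|MT)$", names(sizes), ignore.case = TRUE) |
      grepl("_|Un", names(sizes))
    sizes <- sizes[!drop]
    if (!length(sizes)) stop("no chromosomes left after autosome filtering", call. = FALSE)
  }
  purrr::imap(sizes, function(len, chrom) {
    starts <- seq(0, len - 1, by = window_size)
    tibble::tibble(chrom = chrom, start = starts, end = pmin(starts + window_size, len))
  }) |>
    purrr::list_rbind()
}

#' Annotate windows with GC fraction
#'
#' Computes per-window GC content as (#G + #C) / (#A + #C + #G + #T) over the
#' window sequence. Ambiguous (non-ACGT) bases are ignored in both numerator
#' and denominator; a window with no unambiguous base gets `NA`, and such
#' windows are excluded from all GC-stratified statistics downstream.
#'
#' @param windows A window tibble from [make_windows()].
#' @param sequences Per-chromosome sequence: a named character vector, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @return `windows` with an added `gc` column in \[0, 1\] (or `NA`).
#' @export
annotate_gc <- function(windows, sequences) {
  if (is.character(sequences) && length(sequences) == 1 && file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  missing_chr <- setdiff(unique(windows$chrom), names(sequences))
  if (length(missing_chr)) {
    stop("no sequence for chromosome(s): ", paste(missing_chr, collapse = ", "),
         call. = FALSE)
  }
  gc <- rep(NA_real_, nrow(windows))
  for (chrom in unique(windows$chrom)) {
    idx <- which(windows$chrom == chrom)
    seq_len_chr <- Biostrings::width(sequences[chrom])
    if (any(windows$end[idx] > seq_len_chr)) {
      stop("window beyond end of sequence on ", chrom, call. = FALSE)
    }
    views <- Biostrings::Views(sequences[[chrom]],
                               start = windows$start[idx] + 1L,
                               end = windows$end[idx])
    counts <- Biostrings::letterFrequency(views, letters = c("A", "C", "G", "T"))
    denom <- rowSums(counts)
    gc[idx] <- ifelse(denom > 0, (counts[, "G"] + counts[, "C"]) / denom, NA_real_)
  }
  dplyr::mutate(windows, gc = gc)
}

#' Count reads into windows
#'
#' Assigns each read interval to exactly one window by its 5' start
#' coordinate (0-based) and returns a per-window depth profile. Reads whose
#' start falls outside every window (for example beyond a chromosome end, or
#' on a chromosome absent from the tiling) are not counted. The Poisson model
#' used for localized calling applies to these per-window start counts.
#'
#' @param reads A data frame of read intervals with columns `chrom`, `start`,
#'   `end` (BED3), e.g. from [read_bed()].
#' @param windows A window tibble from [make_windows()], optionally
#'   GC-annotated.
#' @param sample_id Optional sample label stored in the `sample_id` attribute.
#' @return A depth profile: the window tibble plus an integer `depth` column.
#' @export
count_depth <- function(reads, windows, sample_id = NULL) {
  bad <- which(reads$end <= reads$start)
  if (length(bad)) {
    stop("malformed read interval (end <= start) at record ", bad[1], call. = FALSE)
  }
  depth <- integer(nrow(windows))
  win_by_chrom <- split(seq_len(nrow(windows)), windows$chrom)
  reads_by_chrom <- split(reads$start, reads$chrom)
  for (chrom in intersect(names(reads_by_chrom), names(win_by_chrom))) {
    idx <- win_by_chrom[[chrom]]
    # tiling is contiguous from 0, so the window of a start is found by cut
    breaks <- c(windows$start[idx], windows$end[idx[length(idx)]])
    assigned <- findInterval(reads_by_chrom[[chrom]], breaks,
                             rightmost.closed = FALSE, left.open = FALSE)
    inside <- assigned >= 1 & assigned <= length(idx) &
      reads_by_chrom[[chrom]] >= windows$start[idx[1]]
    tab <- tabulate(assigned[inside], nbins = length(idx))
    depth[idx] <- depth[idx] + tab
  }
  out <- dplyr::mutate(windows, depth = depth)
  attr(out, "sample_id") <- sample_id
  out
}

#' Winsorize a depth profile at an upper quantile
#'
#' Caps window depths above the `upper_quantile` of the positive-depth
#' distribution at that quantile value (linear interpolation between order
#' statistics, `stats::quantile()` type 7). Depth profiles of sparse capture
#' data are strongly zero-inflated, so the quantile is taken over covered
#' (depth > 0) windows only. Winsorization is intended to be applied at the
#' base window size, before [merge_windows()].
#'
#' @param profile A depth profile (window tibble with a `depth` column).
#' @param upper_quantile Fraction in (0, 1); default 0.95 caps the top 5%.
#' @return The profile with capped `depth`. Idempotent.
#' @export
winsorize_depth <- function(profile, upper_quantile = 0.95) {
  if (!is.numeric(upper_quantile) || upper_quantile <= 0 || upper_quantile >= 1) {
    stop("upper_quantile must lie strictly between 0 and 1", call. = FALSE)
  }
  pos <- profile$depth[profile$depth > 0]
  if (!length(pos)) stop("profile has no covered window", call. = FALSE)
  cap <- stats::quantile(pos, upper_quantile, names = FALSE, type = 7)
  dplyr::mutate(profile, depth = pmin(.data$depth, cap))
}

#' Merge windows to a larger size
#'
#' Sums depths of `factor` consecutive base windows per chromosome, e.g.
#' 5 kb -> 500 kb with `factor = 100`. Total depth is preserved exactly.
#' Merged-window GC (when present) is the length-weighted mean of the
#' constituent GC fractions, ignoring windows with undefined GC.
#'
#' @param profile A depth profile at the base window size.
#' @param factor Positive integer number of base windows per merged window.
#' @return A depth profile on the merged tiling.
#' @export
merge_windows <- function(profile, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != as.integer(factor)) {
    stop("factor must be a positive integer", call. = FALSE)
  }
  if (factor == 1) return(profile)
  has_gc <- "gc" %in% names(profile)
  merged <- profile |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.block = (dplyr::row_number() - 1L) %/% as.integer(factor)) |>
    dplyr::group_by(.data$chrom, .data$.block)
  merged <- if (has_gc) {
    dplyr::summarise(
      merged,
      gc = {
        w <- .data$end - .data$start
        ok <- !is.na(.data$gc)
        if (any(ok)) sum(.data$gc[ok] * w[ok]) / sum(w[ok]) else NA_real_
      },
      depth = sum(.data$depth),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    )
  } else {
    dplyr::summarise(
      merged,
      depth = sum(.data$depth),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    )
  }
  out <- merged |>
    dplyr::arrange(match(.data$chrom, unique(profile$chrom)), .data$start) |>
    dplyr::select(dplyr::any_of(c("chrom", "start", "end", "gc", "depth")))
  attr(out, "sample_id") <- attr(profile, "sample_id")
  out
}

#' Total read count of a depth profile
#'
#' @param profile A depth profile.
#' @return Sum of window depths (the N of the total-read adjustment).
#' @export
total_reads <- function(profile) sum(profile$depth)

#' Read a chromosome-sizes table
#'
#' @param path Two-column TSV (chromosome, length), no header.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "size"),
                         col_types = readr::cols(readr::col_character(),
                                                 readr::col_double()))
  stats::setNames(tab$size, tab$chrom)
}

#' Read a BED3 file of read intervals
#'
#' @param path BED3 path (chrom, start, end; further columns ignored).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = FALSE, comment = "#",
                  col_types = readr::cols(.default = readr::col_guess())) |>
    dplyr::select(chrom = 1, start = 2, end = 3)
}

#' Read / write per-window depth tables
#'
#' The on-disk format is a TSV with header `chrom start end depth [gc]`;
#' integer depths round-trip bit-exactly.
#'
#' @param path File path.
#' @param profile A depth profile tibble.
#' @return `read_depth_tsv()` returns a depth profile tibble;
#'   `write_depth_tsv()` returns `path` invisibly.
#' @export
read_depth_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), .default = readr::col_double()
  ))
}

#' @rdname read_depth_tsv
#' @export
write_depth_tsv <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}
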