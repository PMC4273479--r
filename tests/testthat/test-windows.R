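test_that("window tiling follows the 0-based half-open convention", {
  w <- make_windows(c(chr1 = 12000), window_size = 5000)
  expect_equal(w$start, c(0, 5000, 10000))
  expect_equal(w$end, c(5000, 10000, 12000))

  expect_equal(nrow(make_windows(c(chr1 = 5000), 5000)), 1)
  w1 <- make_windows(c(chr1 = 4999), 5000)
  expect_equal(c(w1$start, w1$end), c(0, 4999))

  expect_error(make_windows(c(chr1 = 1000), 0), "positive")
  expect_error(make_windows(c(chr1 = 0), 5000), "positive")
})

test_that("tiling covers every base exactly once for arbitrary sizes", {
  sizes <- c(chr1 = 12345, chr2 = 5000, chr3 = 4999, chr4 = 15000)
  for (ws in c(1000, 4999, 5000, 20000)) {
    w <- make_windows(sizes, ws)
    covered <- tapply(w$end - w$start, w$chrom, sum)
    expect_equal(covered[names(sizes)], sizes[names(sizes)],
                 ignore_attr = TRUE)
    # non-overlap + contiguity: each window starts where the previous ended
    by_chr <- split(w, w$chrom)
    for (chr in by_chr) {
      expect_equal(chr$start[-1], chr$end[-nrow(chr)])
    }
  }
})

test_that("sex chromosomes and unplaced contigs are excluded by default", {
  sizes <- c(chr1 = 10000, chrX = 10000, chrY = 5000, chrM = 16571,
             chr1_random = 4000, chrUn_gl000220 = 3000)
  w <- make_windows(sizes, 5000)
  expect_setequal(unique(w$chrom), "chr1")
  w_all <- make_windows(sizes, 5000, autosomes_only = FALSE)
  expect_setequal(unique(w_all$chrom), names(sizes))
})

test_that("GC fraction counts unambiguous bases only", {
  w <- make_windows(c(chr1 = 12), window_size = 4, autosomes_only = TRUE)
  gc <- annotate_gc(w, c(chr1 = "GGCCACGTANGT"))$gc
  expect_equal(gc, c(1.0, 0.5, 1 / 3))

  wn <- make_windows(c(chr1 = 4), 4)
  expect_true(is.na(annotate_gc(wn, c(chr1 = "NNNN"))$gc))

  w_off <- make_windows(c(chr1 = 100), 50)
  expect_error(annotate_gc(w_off, c(chr1 = "ACGT")), "beyond")
  expect_error(annotate_gc(w, c(chr2 = "ACGT")), "no sequence")
})

test_that("reads are assigned to windows by their 5' start", {
  w <- toy_windows(2)
  reads <- tibble::tibble(chrom = "chr1", start = c(100, 4999, 5000),
                          end = c(200, 5100, 5120))
  prof <- count_depth(reads, w)
  expect_equal(prof$depth, c(2, 1))
  expect_equal(total_reads(prof), 3)

  empty <- count_depth(tibble::tibble(chrom = character(), start = numeric(),
                                      end = numeric()), w)
  expect_equal(empty$depth, c(0, 0))

  ten <- count_depth(tibble::tibble(chrom = "chr1", start = rep(10, 10),
                                    end = rep(40, 10)), w)
  expect_equal(ten$depth, c(10, 0))

  # reads past the chromosome end or on unknown chromosomes are not counted
  stray <- tibble::tibble(chrom = c("chr1", "chr9"), start = c(10000, 5),
                          end = c(10050, 50))
  expect_equal(total_reads(count_depth(stray, w)), 0)

  bad <- tibble::tibble(chrom = "chr1", start = c(5, 100), end = c(50, 90))
  expect_error(count_depth(bad, w), "record 2")
})

test_that("winsorization caps at the interpolated quantile of covered windows", {
  prof <- profile_with_depth(1:20)
  # independent oracle: sort-and-interpolate the order statistics directly
  x <- sort(1:20)
  h <- (20 - 1) * 0.95 + 1
  q_oracle <- x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  expect_equal(q_oracle, 19.05)
  wz <- winsorize_depth(prof)
  expect_equal(max(wz$depth), q_oracle)
  expect_equal(wz$depth[1:19], as.numeric(1:19))

  # zeros are excluded from the quantile
  prof0 <- profile_with_depth(c(rep(0, 80), 1:20))
  expect_equal(max(winsorize_depth(prof0)$depth), q_oracle)

  same <- profile_with_depth(rep(7, 10))
  expect_equal(winsorize_depth(same)$depth, rep(7, 10))

  expect_equal(winsorize_depth(prof, 0.999)$depth[20], 19.981)
  expect_error(winsorize_depth(prof, 1), "between 0 and 1")
  expect_error(winsorize_depth(profile_with_depth(rep(0, 5))), "covered")
})

test_that("winsorization is idempotent", {
  set.seed(42)
  prof <- profile_with_depth(rpois(200, 30))
  once <- winsorize_depth(prof)
  expect_equal(winsorize_depth(once)$depth, once$depth)
})

test_that("window merging sums depths and conserves the total", {
  prof <- profile_with_depth(c(1, 2, 3, 4))
  m <- merge_windows(prof, 2)
  expect_equal(m$depth, c(3, 7))
  expect_equal(m$start, c(0, 10000))
  expect_equal(m$end, c(10000, 20000))

  expect_equal(merge_windows(prof, 1)$depth, prof$depth)
  expect_error(merge_windows(prof, 2.5), "integer")

  set.seed(7)
  big <- profile_with_depth(rpois(1000, 20))
  for (f in c(3, 7, 100)) {
    expect_equal(total_reads(merge_windows(big, f)), total_reads(big))
  }
})

test_that("merged-window GC is the length-weighted mean", {
  prof <- profile_with_depth(c(5, 5, 5), gc = c(0.2, 0.6, NA))
  prof$end[3] <- prof$start[3] + 2500  # truncated last window
  m <- merge_windows(prof, 3)
  expect_equal(m$gc, (0.2 * 5000 + 0.6 * 5000) / 10000)
  all_na <- merge_windows(profile_with_depth(c(1, 1), gc = c(NA, NA)), 2)
  expect_true(is.na(all_na$gc))
})

test_that("depth tables round-trip through TSV bit-exactly", {
  prof <- profile_with_depth(c(0L, 3L, 17L, 0L, 250L), gc = c(0.1, 0.5, NA, 0.9, 0.45))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_tsv(prof, path)
  back <- read_depth_tsv(path)
  expect_equal(back$depth, as.numeric(prof$depth))
  expect_equal(back$gc, prof$gc)
  expect_equal(back$start, prof$start)
})
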