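# Shared fixtures built in code at test time.

# small fully covered tiling for arithmetic-level tests
toy_windows <- function(n = 10, size = 5000, chrom = "chr1") {
  make_windows(stats::setNames(n * size, chrom), window_size = size)
}

# a depth profile with explicitly given depths
profile_with_depth <- function(depth, size = 5000, chrom = "chr1", gc = NULL) {
  w <- toy_windows(length(depth), size, chrom)
  w$depth <- depth
  if (!is.null(gc)) w$gc <- gc
  w
}

# brute-force Poisson-binomial pmf by enumeration over all 2^n outcomes
enumerate_poibin <- function(p) {
  n <- length(p)
  pmf <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    prob <- prod(ifelse(bits == 1, p, 1 - p))
    pmf[sum(bits) + 1] <- pmf[sum(bits) + 1] + prob
  }
  pmf
}

# independent exhaustive circular max-stat search (mirror of the spec'd
# statistic, plain R)
brute_cbs_max <- function(z, min_width = 2) {
  n <- length(z)
  s <- c(0, cumsum(z))
  zbar <- mean(z)
  best <- -1
  best_ij <- c(NA, NA)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      l <- j - i
      if (l < min_width || n - l < min_width) next
      u <- abs(s[j + 1] - s[i + 1] - l * zbar) / sqrt(l * (1 - l / n))
      if (u > best + 1e-12) {
        best <- u
        best_ij <- c(i, j)
      }
    }
  }
  list(u = best, i = best_ij[1], j = best_ij[2])
}
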