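# Internal helpers shared across modules.

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed, kept within 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(i) * 12497L) %% 2147483629)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) return(v)
  v / n
}

# Angle between two 3-vectors in degrees, in [0, 180]. NA for zero vectors.
vec_angle <- function(a, b) {
  na <- vnorm(a); nb <- vnorm(b)
  if (na == 0 || nb == 0) return(NA_real_)
  ct <- sum(a * b) / (na * nb)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

deg <- function(x) x * 180 / pi

# Bin index on a fixed range with a small guard against floating-point
# fuzz at bin edges (a value mathematically on an edge belongs to the
# right-hand bin).
bin_index <- function(x, nbins, lo, hi) {
  as.integer(floor((x - lo) / (hi - lo) * nbins + 1e-9)) + 1L
}

# Fixed-range histogram used by all binned distributions. Values outside
# [lo, hi] are clipped into the boundary bins; hi itself falls in the last bin.
hist_counts <- function(x, nbins, lo, hi) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(numeric(nbins))
  idx <- bin_index(x, nbins, lo, hi)
  idx[idx < 1L] <- 1L
  idx[idx > nbins] <- nbins
  tabulate(idx, nbins)
}

# Unit-sum Gaussian kernel truncated to `size` taps.
gaussian_kernel <- function(size = 11L, sigma = 2) {
  half <- (size - 1L) / 2
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

# 'Same' 1D convolution with zero padding.
conv_same <- function(x, k) {
  n <- length(x); m <- length(k); half <- (m - 1L) %/% 2L
  out <- numeric(n)
  for (j in seq_len(m)) {
    shift <- j - 1L - half
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    out[ok] <- out[ok] + k[j] * x[src[ok]]
  }
  out
}

# Separable 'same' 2D convolution (rows then columns) with a 1D kernel.
conv_same_2d <- function(mat, k) {
  tmp <- t(apply(mat, 1L, conv_same, k = k))
  apply(tmp, 2L, conv_same, k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
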