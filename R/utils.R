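#' @keywords internal
"_PACKAGE"

# Deterministic per-subject substream seed. Keyed by (base seed, counter) so
# cohorts can be extended without perturbing earlier subjects, and results do
# not depend on generation order. Kept strictly below 2^31 - 1.
substream_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(counter) * 10007
  as.integer(s %% 2147483647)
}

# 1D Gaussian kernel truncated at 3 sigma, normalized to unit sum.
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded convolution matrix for one axis (zero-padded boundaries).
# Memoized: the same (n, kernel) pair recurs for every subject of a cohort.
.conv_cache <- new.env(parent = emptyenv())

conv_matrix <- function(n, kernel) {
  key <- paste(n, paste(signif(kernel, 12), collapse = ","), sep = "|")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- (length(kernel) - 1L) / 2L
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    ok <- idx >= 1L & idx <= n
    m[idx[ok], j] <- kernel[ok]
  }
  .conv_cache[[key]] <- m
  m
}

# Separable 3D Gaussian smoothing of an array, sigma in voxels per axis.
# Implemented as three banded matrix products; grids here are small enough
# that dense banded matrices are faster than FFT round trips.
smooth_gaussian3d <- function(x, sigma) {
  d <- dim(x)
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    k <- gaussian_kernel(sigma[ax])
    if (length(k) == 1L) next
    m <- conv_matrix(d[ax], k)
    perm <- c(ax, setdiff(1:3, ax))
    y <- aperm(x, perm)
    dy <- dim(y)
    y <- m %*% matrix(y, nrow = dy[1])
    dim(y) <- dy
    x <- aperm(y, order(perm))
  }
  x
}

# Numbers formatted to 10 significant digits so repeated runs give
# byte-identical CSV output.
format_numeric <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Write a data frame as a byte-stable CSV
#'
#' Numeric columns are serialized to 10 significant digits and missing values
#' to empty cells, so identical inputs always produce identical files.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stable_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- format_numeric(out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort CSV written by this package
#'
#' @param path file path.
#' @return data frame with empty cells read back as `NA`.
#' @export
read_stable_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

stop_pdtex <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
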