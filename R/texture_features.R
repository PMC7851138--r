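#' Texture extraction parameters
#'
#' @param G number of grey levels (>= 2).
#' @param mode quantization mode: `"roi_minmax"` (each ROI rescaled to its
#'   own range; makes second-order features invariant to affine intensity
#'   changes) or `"global"` (one fixed range for the whole study, so feature
#'   values are comparable across subjects on a common intensity scale).
#' @param range numeric `(lo, hi)` for `"global"` mode.
#' @param d co-occurrence distance in voxels.
#' @param glcm_3d if `TRUE`, use the 13 canonical 3D offsets instead of the
#'   four in-plane directions pooled across axial slices.
#' @param log_base base of the logarithm in entropy (`exp(1)` or 2).
#' @return list of class `texture_params`.
#' @export
texture_params <- function(G = 64L, mode = c("roi_minmax", "global"),
                           range = NULL, d = 1L, glcm_3d = FALSE,
                           log_base = exp(1)) {
  mode <- match.arg(mode)
  if (G < 2) stop_pdtex("G must be >= 2")
  if (mode == "global") {
    if (is.null(range) || length(range) != 2 || range[2] <= range[1]) {
      stop_pdtex("global mode needs range = c(lo, hi) with hi > lo")
    }
  }
  structure(list(G = as.integer(G), mode = mode, range = range,
                 d = as.integer(d), glcm_3d = isTRUE(glcm_3d),
                 log_base = log_base),
            class = "texture_params")
}

feature_names <- function() {
  c("mean", "sd", "kurtosis", "skewness",
    "homogeneity", "contrast", "entropy", "correlation",
    "sumSQR", "sumA", "sumV", "idm")
}

#' First-order texture features of an ROI intensity sample
#'
#' Population moments (divide by N). Kurtosis is non-excess
#' (`E[((X-mean)/sd)^4]`, approximately 3 for a normal sample); skewness is
#' `E[((X-mean)/sd)^3]`. For a constant ROI (sd = 0) kurtosis and skewness
#' are undefined and returned as `NA`; mean and sd remain valid.
#'
#' @param intensities numeric vector of at least 2 voxel values.
#' @return named numeric vector: mean, sd, kurtosis, skewness.
#' @export
first_order_features <- function(intensities) {
  if (length(intensities) < 2) stop_pdtex("need at least 2 voxels")
  m <- mean(intensities)
  ctr <- intensities - m
  s <- sqrt(mean(ctr^2))
  if (s == 0) {
    kurt <- NA_real_; skew <- NA_real_
  } else {
    z <- ctr / s
    kurt <- mean(z^4)
    skew <- mean(z^3)
  }
  c(mean = m, sd = s, kurtosis = kurt, skewness = skew)
}

#' Quantize ROI intensities to G grey levels
#'
#' Linear binning of `[lo, hi]` into `G` equal bins; values outside the range
#' are clamped. `roi_minmax` uses the ROI's own min/max; a constant ROI then
#' maps every voxel to level 0 (a documented degenerate case, not an error).
#'
#' @param intensities numeric vector (or array) of ROI values.
#' @param G number of grey levels.
#' @param mode `"roi_minmax"` or `"global"`.
#' @param range `(lo, hi)` for global mode.
#' @return list of class `quantized_roi`: integer `levels` in `[0, G-1]`
#'   (same shape as the input), `G`, `range` actually used, `mode`.
#' @export
quantize <- function(intensities, G, mode = c("roi_minmax", "global"),
                     range = NULL) {
  mode <- match.arg(mode)
  if (G < 2) stop_pdtex("G must be >= 2")
  if (mode == "roi_minmax") {
    lo <- min(intensities, na.rm = TRUE)
    hi <- max(intensities, na.rm = TRUE)
  } else {
    if (is.null(range) || range[2] <= range[1]) {
      stop_pdtex("global mode needs range = c(lo, hi) with hi > lo")
    }
    lo <- range[1]; hi <- range[2]
  }
  if (hi == lo) {
    lev <- ifelse(is.na(intensities), NA_integer_, 0L)
  } else {
    lev <- floor((intensities - lo) / (hi - lo) * G)
    lev <- pmin(pmax(lev, 0), G - 1)
    lev <- ifelse(is.na(intensities), NA_integer_, as.integer(lev))
  }
  if (!is.null(dim(intensities))) dim(lev) <- dim(intensities)
  structure(list(levels = lev, G = as.integer(G), range = c(lo, hi),
                 mode = mode),
            class = "quantized_roi")
}

# In-plane (dx, dy) voxel offsets at distance d for the requested angles.
# theta = 0 is the +x direction, 90 the +y direction.
inplane_offsets <- function(d, angles = c(0, 45, 90, 135)) {
  all <- list(`0` = c(d, 0L), `45` = c(d, d), `90` = c(0L, d),
              `135` = c(-d, d))
  bad <- setdiff(as.character(angles), names(all))
  if (length(bad)) stop_pdtex("unsupported direction(s): %s",
                              paste(bad, collapse = ", "))
  all[as.character(angles)]
}

# The 13 canonical unique 3D offsets at distance d (half of the 26-neighbour
# shell; the other half is covered by symmetrization).
offsets_3d <- function(d) {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)))) {
      out[[length(out) + 1L]] <- v * d
    }
  }
  out
}

# Count ordered co-occurring level pairs for one 2D slice and one offset;
# both voxels must be inside the mask. Returns a G x G count matrix.
glcm_count_2d <- function(lev, mask, offset, G) {
  dxr <- offset[1]; dyr <- offset[2]
  nr <- nrow(lev); nc <- ncol(lev)
  if (nr <= abs(dxr) || nc <= abs(dyr)) return(0)
  r <- seq.int(max(1, 1 - dxr), min(nr, nr - dxr))
  cc <- seq.int(max(1, 1 - dyr), min(nc, nc - dyr))
  a <- lev[r, cc, drop = FALSE]
  b <- lev[r + dxr, cc + dyr, drop = FALSE]
  ok <- mask[r, cc, drop = FALSE] & mask[r + dxr, cc + dyr, drop = FALSE]
  if (!any(ok)) return(0)
  tabulate(a[ok] * G + b[ok] + 1L, nbins = G * G)
}

glcm_count_3d <- function(lev, mask, offset, G) {
  d3 <- dim(lev)
  if (any(d3 <= abs(offset))) return(0)
  idx <- lapply(1:3, function(ax) {
    o <- offset[ax]
    seq.int(max(1, 1 - o), min(d3[ax], d3[ax] - o))
  })
  sh <- lapply(1:3, function(ax) idx[[ax]] + offset[ax])
  a <- lev[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  b <- lev[sh[[1]], sh[[2]], sh[[3]], drop = FALSE]
  ok <- mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE] &
        mask[sh[[1]], sh[[2]], sh[[3]], drop = FALSE]
  if (!any(ok)) return(0)
  tabulate(a[ok] * G + b[ok] + 1L, nbins = G * G)
}

#' Build a grey-level co-occurrence matrix for a masked 3D ROI
#'
#' Default scheme: for every axial slice (third array axis) and each of the
#' four in-plane directions (0, 45, 90, 135 degrees) at distance `d`, count
#' ordered voxel pairs lying wholly inside the mask; pool all counts into one
#' matrix, symmetrize by adding the transpose, and normalize to
#' probabilities. With `glcm_3d = TRUE` the 13 canonical 3D offsets are used
#' instead of the slice-wise in-plane set.
#'
#' @param q a [quantize()] result whose `levels` is a 3D array.
#' @param mask logical array of the ROI.
#' @param d pair distance in voxels.
#' @param glcm_3d use 3D offsets.
#' @param directions in-plane angles to use (subset of 0, 45, 90, 135);
#'   ignored when `glcm_3d = TRUE`.
#' @return list of class `glcm`: `P` (G x G probability matrix), `G`, `d`,
#'   `directions`, `n_pairs` (ordered pair count before symmetrization).
#' @export
build_glcm <- function(q, mask, d = 1L, glcm_3d = FALSE,
                       directions = c(0, 45, 90, 135)) {
  stopifnot(inherits(q, "quantized_roi"))
  lev <- q$levels
  if (is.null(dim(lev)) || length(dim(lev)) != 3) {
    stop_pdtex("quantized levels must be a 3D array")
  }
  if (!identical(dim(lev), dim(mask))) stop_pdtex("mask/levels grid mismatch")
  G <- q$G
  lev[!mask] <- 0L  # never counted; avoids NA arithmetic in shifts
  counts <- numeric(G * G)
  if (glcm_3d) {
    offs <- offsets_3d(d)
    for (o in offs) counts <- counts + glcm_count_3d(lev, mask, o, G)
    dirs <- "3d-13"
  } else {
    offs <- inplane_offsets(d, directions)
    nz <- dim(lev)[3]
    for (z in seq_len(nz)) {
      mz <- mask[, , z]
      if (!any(mz)) next
      lz <- lev[, , z]
      for (o in offs) counts <- counts + glcm_count_2d(lz, mz, o, G)
    }
    dirs <- paste(directions, collapse = ",")
  }
  total <- sum(counts)
  if (total == 0) {
    stop_pdtex("degenerate GLCM: no valid voxel pair at distance %d", d)
  }
  counts <- matrix(counts, G, G)
  P <- counts + t(counts)
  P <- P / sum(P)
  structure(list(P = P, G = G, d = as.integer(d), directions = dirs,
                 n_pairs = total),
            class = "glcm")
}

#' Second-order (Haralick) features of a GLCM
#'
#' Computes the eight co-occurrence features: homogeneity (the sum of squared
#' probabilities, i.e. angular second moment / energy in the classical
#' nomenclature), contrast, entropy (natural log by default, with
#' `0 log 0 = 0`), correlation, sum of squares (variance about the GLCM mean),
#' sum average, sum variance, and inverse difference moment. Grey levels are
#' 0-based, so the diagonal-sum index k runs over `[0, 2G-2]`. Correlation is
#' undefined (`NA`) when either marginal SD is zero.
#'
#' @param M a [build_glcm()] result, or a plain normalized symmetric matrix.
#' @param log_base logarithm base for entropy.
#' @return named numeric vector: homogeneity, contrast, entropy, correlation,
#'   sumSQR, sumA, sumV, idm.
#' @export
glcm_features <- function(M, log_base = exp(1)) {
  P <- if (inherits(M, "glcm")) M$P else M
  G <- nrow(P)
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  homogeneity <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  nz <- P > 0
  entropy <- -sum(P[nz] * log(P[nz], base = log_base))
  idm <- sum(P / (1 + (i - j)^2))
  px <- rowSums(P)
  py <- colSums(P)
  lv <- 0:(G - 1)
  mux <- sum(lv * px)
  muy <- sum(lv * py)
  sdx <- sqrt(sum((lv - mux)^2 * px))
  sdy <- sqrt(sum((lv - muy)^2 * py))
  correlation <- if (sdx * sdy == 0) NA_real_ else
    (sum(i * j * P) - mux * muy) / (sdx * sdy)
  mu <- sum(i * P)  # GLCM mean; equals mux for a symmetric matrix
  sumSQR <- sum((i - mu)^2 * P)
  # diagonal-sum distribution P_{x+y}(k), k = i + j in [0, 2G-2];
  # rowsum groups by anti-diagonal in one pass
  k <- 0:(2 * G - 2)
  pxy <- as.vector(rowsum(as.vector(P), as.vector(i + j)))
  sumA <- sum(k * pxy)
  sumV <- sum((k - sumA)^2 * pxy)
  c(homogeneity = homogeneity, contrast = contrast, entropy = entropy,
    correlation = correlation, sumSQR = sumSQR, sumA = sumA, sumV = sumV,
    idm = idm)
}

# Full 12-feature vector for one masked ROI.
roi_features <- function(image, mask, params) {
  vals <- image[mask]
  fo <- first_order_features(vals)
  # roi_minmax rescales to the ROI's own range, not the whole image's
  q <- if (params$mode == "roi_minmax") quantize_masked(image, mask, params)
       else quantize(image, params$G, "global", params$range)
  g <- build_glcm(q, mask, d = params$d, glcm_3d = params$glcm_3d)
  so <- glcm_features(g, log_base = params$log_base)
  c(fo, so)
}

quantize_masked <- function(image, mask, params) {
  vals <- image[mask]
  q <- quantize(vals, params$G, "roi_minmax")
  lev <- array(0L, dim(image))
  lev[mask] <- q$levels
  structure(list(levels = lev, G = q$G, range = q$range, mode = "roi_minmax"),
            class = "quantized_roi")
}

#' Hemisphere-averaged texture features for one structure
#'
#' Computes the 12-feature vector on the left and right ROI separately and
#' returns their element-wise mean (plus both per-hemisphere vectors). An
#' undefined feature (`NA`) in either hemisphere makes the averaged value
#' undefined.
#'
#' @param image 3D intensity array.
#' @param left_mask,right_mask logical ROI arrays; one may be `NULL` when
#'   `allow_single = TRUE` (the available side is returned unaveraged).
#' @param params a [texture_params()].
#' @param allow_single tolerate a missing hemisphere.
#' @return list: `features` (named 12-vector), `left`, `right`.
#' @export
structure_features <- function(image, left_mask, right_mask, params,
                               allow_single = FALSE) {
  stopifnot(inherits(params, "texture_params"))
  sides <- list(left = left_mask, right = right_mask)
  missing <- vapply(sides, is.null, logical(1))
  if (any(missing) && !allow_single) {
    stop_pdtex("missing %s hemisphere mask", names(sides)[missing][1])
  }
  vecs <- lapply(sides[!missing], function(m) roi_features(image, m, params))
  avg <- if (length(vecs) == 2) (vecs[[1]] + vecs[[2]]) / 2 else vecs[[1]]
  list(features = avg,
       left = if (missing[["left"]]) NULL else vecs[["left"]],
       right = if (missing[["right"]]) NULL else vecs[["right"]])
}

#' Texture feature table for one subject across all structures
#'
#' @param image,labels image and label arrays on the same grid.
#' @param label_map data frame with `structure`, `hemisphere`, `label`
#'   (two rows per structure).
#' @param params a [texture_params()].
#' @return data frame with one row per structure: the 12 hemisphere-averaged
#'   features plus `entropy_left`/`entropy_right` and quantization metadata.
#' @export
subject_texture_features <- function(image, labels, label_map, params) {
  structures <- unique(label_map$structure)
  rows <- lapply(structures, function(st) {
    sub <- label_map[label_map$structure == st, ]
    get_mask <- function(h) {
      lab <- sub$label[sub$hemisphere == h]
      if (length(lab) != 1) return(NULL)
      m <- labels == lab
      if (!any(m)) stop_pdtex("empty ROI: %s (%s)", st, h)
      m
    }
    sf <- structure_features(image, get_mask("left"), get_mask("right"), params)
    row <- as.data.frame(as.list(sf$features))
    row$entropy_left <- unname(sf$left["entropy"])
    row$entropy_right <- unname(sf$right["entropy"])
    cbind(data.frame(structure = st, stringsAsFactors = FALSE), row)
  })
  out <- do.call(rbind, rows)
  out$G <- params$G
  out$quant_mode <- params$mode
  out
}
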