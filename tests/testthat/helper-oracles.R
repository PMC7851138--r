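# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. Everything here is written as literal
# enumeration (explicit loops over voxels, pairs and matrix cells) and shares
# no code with the implementation under test.

# Ordered-pair enumeration GLCM: walk every voxel, apply each offset, count
# pairs with both ends inside the mask, then symmetrize and normalize.
oracle_glcm <- function(levels, mask, G, d = 1, angles = c(0, 45, 90, 135),
                        use_3d = FALSE) {
  dims <- dim(levels)
  counts <- matrix(0, G, G)
  if (use_3d) {
    offs <- list()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      v <- c(dx, dy, dz) * d
      if (all(v == 0)) next
      if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)))) {
        offs[[length(offs) + 1]] <- v
      }
    }
  } else {
    tab <- list(`0` = c(1, 0), `45` = c(1, 1), `90` = c(0, 1), `135` = c(-1, 1))
    offs <- lapply(tab[as.character(angles)], function(v) c(v * d, 0))
  }
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
    if (!mask[x, y, z]) next
    for (o in offs) {
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2] ||
          z2 < 1 || z2 > dims[3]) next
      if (!mask[x2, y2, z2]) next
      i <- levels[x, y, z] + 1; j <- levels[x2, y2, z2] + 1
      counts[i, j] <- counts[i, j] + 1
    }
  }
  sym <- counts + t(counts)
  if (sum(sym) == 0) stop("oracle: no valid pair")
  sym / sum(sym)
}

# Literal cell-by-cell evaluation of the eight co-occurrence feature sums.
oracle_glcm_features <- function(P) {
  G <- nrow(P)
  hom <- 0; con <- 0; ent <- 0; idm <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    p <- P[i + 1, j + 1]
    hom <- hom + p^2
    con <- con + (i - j)^2 * p
    if (p > 0) ent <- ent - p * log(p)
    idm <- idm + p / (1 + (i - j)^2)
  }
  px <- numeric(G); py <- numeric(G)
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    px[i + 1] <- px[i + 1] + P[i + 1, j + 1]
    py[j + 1] <- py[j + 1] + P[i + 1, j + 1]
  }
  mux <- 0; muy <- 0
  for (i in 0:(G - 1)) { mux <- mux + i * px[i + 1]; muy <- muy + i * py[i + 1] }
  vx <- 0; vy <- 0
  for (i in 0:(G - 1)) {
    vx <- vx + (i - mux)^2 * px[i + 1]
    vy <- vy + (i - muy)^2 * py[i + 1]
  }
  sij <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) sij <- sij + i * j * P[i + 1, j + 1]
  corr <- if (vx * vy == 0) NA_real_ else (sij - mux * muy) / sqrt(vx * vy)
  mu <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) mu <- mu + i * P[i + 1, j + 1]
  ssq <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    ssq <- ssq + (i - mu)^2 * P[i + 1, j + 1]
  }
  pxy <- numeric(2 * G - 1)
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    pxy[i + j + 1] <- pxy[i + j + 1] + P[i + 1, j + 1]
  }
  sa <- 0
  for (k in 0:(2 * G - 2)) sa <- sa + k * pxy[k + 1]
  sv <- 0
  for (k in 0:(2 * G - 2)) sv <- sv + (k - sa)^2 * pxy[k + 1]
  c(homogeneity = hom, contrast = con, entropy = ent, correlation = corr,
    sumSQR = ssq, sumA = sa, sumV = sv, idm = idm)
}

# Mann-Whitney pair-count AUC: fraction of (negative, positive) pairs where
# the positive scores higher, ties counting one half.
oracle_auc <- function(neg, pos) {
  s <- 0
  for (a in neg) for (b in pos) {
    if (b > a) s <- s + 1 else if (b == a) s <- s + 0.5
  }
  s / (length(neg) * length(pos))
}

# Benjamini-Hochberg step-up by the textbook formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (r in m:1) {
    running <- min(running, p[o[r]] * m / r)
    q[o[r]] <- min(running, 1)
  }
  q
}

# Random quantized masked ROI with at least one guaranteed in-plane pair.
random_roi <- function(dims = c(6, 6, 3), G = 8, fill = 0.7) {
  lev <- array(sample(0:(G - 1), prod(dims), replace = TRUE), dims)
  mask <- array(stats::runif(prod(dims)) < fill, dims)
  mask[1, 1, 1] <- TRUE
  mask[2, 1, 1] <- TRUE
  list(levels = lev, mask = mask, G = G)
}

as_quantized <- function(lev, G) {
  structure(list(levels = lev, G = as.integer(G), range = c(0, G - 1),
                 mode = "global"),
            class = "quantized_roi")
}
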