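#' Default structure table for the synthetic cohort
#'
#' Five bilateral deep grey-matter structures (substantia nigra, putamen,
#' caudate nucleus, thalamus, sub-thalamic nucleus) laid out as ellipsoids on
#' the synthetic grid. Centers and radii are in voxel units (0-based voxel
#' indices); `baseline` is the mean within-structure intensity in arbitrary
#' T1-like units. Shapes are schematic: sizes preserve the ordering
#' SN/STN small versus putamen/caudate/thalamus large, not real anatomy.
#'
#' @param scale scalar applied to all centers and radii, used to shrink the
#'   layout onto smaller grids for simulation studies.
#' @return data frame with one row per (structure, hemisphere): columns
#'   `structure`, `hemisphere`, `label`, `cx`, `cy`, `cz`, `rx`, `ry`, `rz`,
#'   `baseline`.
#' @export
default_structures <- function(scale = 1) {
  base <- data.frame(
    structure = rep(c("SN", "STN", "putamen", "caudate", "thalamus"), each = 2),
    hemisphere = rep(c("left", "right"), 5),
    label = 1:10,
    cx = rep(c(12, 28), 5),
    cy = 24,
    cz = rep(c(8, 14, 21, 28, 35), each = 2),
    rx = rep(c(3, 2.5, 4, 3, 4.5), each = 2),
    ry = rep(c(4, 2.5, 6, 5, 6), each = 2),
    rz = rep(c(2.5, 2.5, 3.5, 3, 3.5), each = 2),
    baseline = rep(c(110, 115, 125, 120, 130), each = 2),
    stringsAsFactors = FALSE
  )
  base$cx <- base$cx * scale
  base$cy <- base$cy * scale
  base$cz <- base$cz * scale
  base$rx <- pmax(2, base$rx * scale)
  base$ry <- pmax(2, base$ry * scale)
  base$rz <- pmax(2, base$rz * scale)
  base
}

#' Default clinical score model
#'
#' Each score is generated as `c0 - c1 * h + noise`, where `h` is the
#' subject's texture heterogeneity, so motor severity rises as regional
#' texture heterogeneity falls — the monotone link the analysis is designed
#' to detect. Scores are clipped to their instrument ranges; MDS-UPDRS parts
#' are rounded to integers and Hoehn-Yahr to the nearest 0.5.
#'
#' @return data frame with columns `score`, `c0`, `c1`, `sd`, `lo`, `hi`,
#'   `round_to`.
#' @export
default_clinical_model <- function() {
  data.frame(
    score = c("updrs1", "updrs2", "updrs3", "updrs4", "hoehn_yahr"),
    c0 = c(14, 22, 50, 12, 5),
    c1 = c(2, 4, 8, 2.5, 1),
    sd = c(1.5, 2, 2, 1.5, 0.4),
    lo = c(0, 0, 0, 0, 0),
    hi = c(52, 52, 132, 24, 5),
    round_to = c(1, 1, 1, 1, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic cohort configuration
#'
#' Describes the three study groups (healthy controls, early-stage PD,
#' late-stage PD), the image grid, the bilateral structure layout, the
#' per-group texture heterogeneity levels and the clinical score model.
#' The default heterogeneity gradient `h = 3 / 2 / 1` (CTRL / early / late)
#' realizes a monotone decrease of within-ROI texture heterogeneity with
#' disease stage.
#'
#' @param n_per_group named integer vector of group sizes; names must be
#'   exactly `CTRL`, `earlyPD`, `latePD`.
#' @param grid_shape integer triple, image dimensions in voxels.
#' @param voxel_size_mm positive numeric triple, voxel spacing.
#' @param structures structure table as from [default_structures()].
#' @param heterogeneity named numeric vector of group-mean heterogeneity
#'   `h_g >= 0` (standard deviation of the within-ROI texture field, in
#'   intensity units).
#' @param heterogeneity_sd between-subject SD of `h` around its group mean.
#' @param smoothness_mm correlation length (Gaussian sigma) of the texture
#'   field, in mm.
#' @param background_intensity,background_noise_sd intensity model outside
#'   all structures.
#' @param quantization list with `G`, `mode` and `range`: the fixed global
#'   grey-level binning the downstream texture extraction should use so that
#'   larger heterogeneity occupies more grey bins.
#' @param clinical_model score model as from [default_clinical_model()].
#' @param tiv_mean,tiv_sd normal model for total intracranial volume (cm^3).
#' @param ctrl_updrs4_missing if `TRUE` (default), controls get a missing
#'   MDS-UPDRS IV, mirroring the usual reporting for non-patients.
#' @param seed integer base seed; every random draw derives from it through
#'   per-subject substreams.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(CTRL = 20L, earlyPD = 20L, latePD = 20L),
                          grid_shape = c(40L, 48L, 44L),
                          voxel_size_mm = c(1, 1, 1),
                          structures = default_structures(),
                          heterogeneity = c(CTRL = 3, earlyPD = 2, latePD = 1),
                          heterogeneity_sd = 0.4,
                          smoothness_mm = 1.5,
                          background_intensity = 100,
                          background_noise_sd = 1,
                          quantization = list(G = 64L, mode = "global",
                                              range = c(50, 200)),
                          clinical_model = default_clinical_model(),
                          tiv_mean = 1180, tiv_sd = 140,
                          ctrl_updrs4_missing = TRUE,
                          seed = 7L) {
  groups <- c("CTRL", "earlyPD", "latePD")
  if (!identical(sort(names(n_per_group)), sort(groups))) {
    stop_pdtex("n_per_group must be named exactly %s", paste(groups, collapse = ", "))
  }
  if (!identical(sort(names(heterogeneity)), sort(groups))) {
    stop_pdtex("heterogeneity must be named exactly %s", paste(groups, collapse = ", "))
  }
  if (any(n_per_group < 1)) stop_pdtex("group sizes must be positive")
  if (any(heterogeneity < 0)) stop_pdtex("heterogeneity must be >= 0")
  if (any(voxel_size_mm <= 0)) stop_pdtex("voxel sizes must be positive")
  cfg <- list(n_per_group = n_per_group[groups],
              grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              structures = structures,
              heterogeneity = heterogeneity[groups],
              heterogeneity_sd = heterogeneity_sd,
              smoothness_mm = smoothness_mm,
              background_intensity = background_intensity,
              background_noise_sd = background_noise_sd,
              quantization = quantization,
              clinical_model = clinical_model,
              tiv_mean = tiv_mean, tiv_sd = tiv_sd,
              ctrl_updrs4_missing = ctrl_updrs4_missing,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_structures(cfg)
  cfg
}

#' Compact configuration for simulation studies
#'
#' Same structure set and generative model as [cohort_config()] on a
#' 32 x 36 x 32 grid with the layout scaled by 0.78, used for repeated-cohort
#' simulations (type-I calibration, seed sweeps) where hundreds of cohorts
#' are generated.
#'
#' @param ... passed on to [cohort_config()].
#' @return a `cohort_config`.
#' @export
compact_cohort_config <- function(...) {
  cohort_config(grid_shape = c(32L, 36L, 32L),
                structures = default_structures(scale = 0.78), ...)
}

# Voxelized ellipsoid on the image grid; centers/radii in 0-based voxel units.
ellipsoid_mask <- function(grid_shape, cx, cy, cz, rx, ry, rz) {
  x <- (seq_len(grid_shape[1]) - 1 - cx) / rx
  y <- (seq_len(grid_shape[2]) - 1 - cy) / ry
  z <- (seq_len(grid_shape[3]) - 1 - cz) / rz
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  d2 <= 1
}

# All structure masks for a config; cached in the config environment would be
# overkill at these grid sizes.
structure_masks <- function(config) {
  st <- config$structures
  masks <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    m <- ellipsoid_mask(config$grid_shape, st$cx[i], st$cy[i], st$cz[i],
                        st$rx[i], st$ry[i], st$rz[i])
    if (!any(m)) {
      stop_pdtex("structure %s (%s) has no voxels on the grid",
                 st$structure[i], st$hemisphere[i])
    }
    masks[[i]] <- m
  }
  names(masks) <- paste(st$structure, st$hemisphere, sep = "_")
  masks
}

validate_structures <- function(config) {
  st <- config$structures
  gs <- config$grid_shape
  lo <- c(st$cx - st$rx, st$cy - st$ry, st$cz - st$rz)
  hi <- c(st$cx + st$rx - (gs[1] - 1), st$cy + st$ry - (gs[2] - 1),
          st$cz + st$rz - (gs[3] - 1))
  if (any(lo < 0) || any(hi > 0)) {
    stop_pdtex("structure ellipsoids must fit inside the %s grid",
               paste(gs, collapse = "x"))
  }
  masks <- structure_masks(config)
  n <- length(masks)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (any(masks[[i]] & masks[[j]])) {
        stop_pdtex("structures overlap: %s and %s", names(masks)[i], names(masks)[j])
      }
    }
  }
  invisible(TRUE)
}

# Smoothed unit-variance Gaussian field on the bounding box of one mask.
# Normalized empirically within the mask, so `h` is the realized within-ROI
# intensity SD.
texture_field <- function(mask, sigma_vox) {
  idx <- which(mask, arr.ind = TRUE)
  pad <- max(1L, ceiling(3 * max(sigma_vox)))
  lo <- pmax(1L, apply(idx, 2, min) - pad)
  hi <- pmin(dim(mask), apply(idx, 2, max) + pad)
  dims <- hi - lo + 1L
  f <- array(stats::rnorm(prod(dims)), dims)
  f <- smooth_gaussian3d(f, sigma_vox)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  v <- f[sub]
  v <- v - mean(v)
  s <- stats::sd(v)
  if (s > 0) v <- v / s
  list(lo = lo, hi = hi, sub = sub, values = v)
}

draw_clinical <- function(model, h, group, ctrl_updrs4_missing) {
  vals <- stats::setNames(numeric(nrow(model)), model$score)
  for (i in seq_len(nrow(model))) {
    v <- model$c0[i] - model$c1[i] * h + stats::rnorm(1, 0, model$sd[i])
    v <- min(max(v, model$lo[i]), model$hi[i])
    vals[i] <- round(v / model$round_to[i]) * model$round_to[i]
  }
  if (ctrl_updrs4_missing && group == "CTRL" && "updrs4" %in% names(vals)) {
    vals["updrs4"] <- NA_real_
  }
  vals
}

# One subject's within-structure intensity patches plus clinical record.
# All draws come from the subject's own substream; structure order is fixed
# by the config, so results are independent of cohort assembly order.
generate_subject <- function(config, index, group, masks) {
  set.seed(substream_seed(config$seed, index))
  h_g <- config$heterogeneity[[group]]
  h <- if (h_g == 0) 0 else max(0, stats::rnorm(1, h_g, config$heterogeneity_sd))
  tiv <- stats::rnorm(1, config$tiv_mean, config$tiv_sd)
  clin <- draw_clinical(config$clinical_model, h, group, config$ctrl_updrs4_missing)
  sigma_vox <- config$smoothness_mm / config$voxel_size_mm
  st <- config$structures
  patches <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    fld <- texture_field(masks[[i]], sigma_vox)
    fld$intensity <- st$baseline[i] + h * fld$values
    patches[[i]] <- fld
  }
  names(patches) <- names(masks)
  list(index = index, group = group, h = h, tiv_cm3 = tiv, clinical = clin,
       patches = patches)
}

assemble_image <- function(config, subject, masks) {
  set.seed(substream_seed(config$seed, subject$index + 500000L))
  img <- array(config$background_intensity +
                 stats::rnorm(prod(config$grid_shape), 0, config$background_noise_sd),
               config$grid_shape)
  for (i in seq_along(masks)) {
    p <- subject$patches[[i]]
    img[masks[[i]]] <- p$intensity
  }
  img
}

label_volume <- function(config, masks) {
  lab <- array(0L, config$grid_shape)
  for (i in seq_along(masks)) lab[masks[[i]]] <- config$structures$label[i]
  lab
}

clinical_total <- function(clin) {
  parts <- clin[c("updrs1", "updrs2", "updrs3", "updrs4")]
  sum(parts, na.rm = TRUE)
}

#' Generate a synthetic three-group cohort
#'
#' Draws every subject from a per-subject substream of `config$seed`:
#' a heterogeneity level `h` around the group mean, a total intracranial
#' volume, clinical scores from the linear score model, and a smoothed
#' Gaussian texture field of SD `h` inside each structure. With
#' `write_images = TRUE`, writes one NIfTI image and one integer label mask
#' per subject plus a label-map JSON sidecar into `out_dir`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed); required when
#'   `write_images = TRUE`.
#' @param write_images write NIfTI files, or keep images in memory only.
#' @param compress use `.nii.gz` (default) or plain `.nii`.
#' @return list with `subjects` (data frame: subject_id, group, h, tiv_cm3,
#'   clinical scores, updrs_total, file paths), `config`, `label_map`, and —
#'   when `write_images = FALSE` — in-memory `images` and the shared `labels`
#'   array.
#' @export
generate_cohort <- function(config, out_dir = NULL, write_images = TRUE,
                            compress = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  masks <- structure_masks(config)
  labels <- label_volume(config, masks)
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(groups)
  if (write_images) {
    if (is.null(out_dir)) stop_pdtex("out_dir is required when writing images")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop_pdtex("cannot create output directory %s", out_dir)
  }
  ext <- if (compress) ".nii.gz" else ".nii"
  rows <- vector("list", n)
  images <- if (write_images) NULL else vector("list", n)
  mask_file <- NULL
  if (write_images) {
    # paths recorded relative to the cohort directory, so a cohort can be
    # moved (and reruns compared byte for byte)
    mask_file <- paste0("labels", ext)
    RNifti::writeNifti(RNifti::asNifti(labels, pixdim = config$voxel_size_mm),
                       file.path(out_dir, mask_file))
  }
  for (i in seq_len(n)) {
    subj <- generate_subject(config, i, groups[i], masks)
    img <- assemble_image(config, subj, masks)
    sid <- sprintf("sub-%03d", i)
    img_file <- NA_character_
    if (write_images) {
      img_file <- paste0(sid, "_T1w", ext)
      RNifti::writeNifti(RNifti::asNifti(img, pixdim = config$voxel_size_mm),
                         file.path(out_dir, img_file))
    } else {
      images[[i]] <- img
    }
    clin <- subj$clinical
    rows[[i]] <- data.frame(
      subject_id = sid, group = groups[i], h = subj$h, tiv_cm3 = subj$tiv_cm3,
      updrs1 = clin[["updrs1"]], updrs2 = clin[["updrs2"]],
      updrs3 = clin[["updrs3"]], updrs4 = clin[["updrs4"]],
      updrs_total = clinical_total(clin), hoehn_yahr = clin[["hoehn_yahr"]],
      image_path = img_file, mask_path = if (write_images) mask_file else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  subjects <- do.call(rbind, rows)
  lm <- config$structures[, c("structure", "hemisphere", "label")]
  out <- list(subjects = subjects, config = config, label_map = lm)
  if (!write_images) {
    names(images) <- subjects$subject_id
    out$images <- images
    out$labels <- labels
  }
  out
}

#' Write the clinical table and manifest for a generated cohort
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir directory for `clinical.csv`, `label_map.json` and
#'   `manifest.json`.
#' @return named list of written paths, invisibly.
#' @export
write_cohort_tables <- function(cohort, out_dir) {
  subjects <- cohort$subjects
  if (nrow(subjects) == 0) stop_pdtex("empty cohort")
  if (anyDuplicated(subjects$subject_id)) {
    stop_pdtex("duplicate subject_id: %s",
               subjects$subject_id[duplicated(subjects$subject_id)][1])
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  clinical_path <- file.path(out_dir, "clinical.csv")
  write_stable_csv(subjects, clinical_path)
  label_path <- file.path(out_dir, "label_map.json")
  jsonlite::write_json(cohort$label_map, label_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    n_subjects = nrow(subjects),
    groups = as.list(table(subjects$group)),
    grid_shape = cohort$config$grid_shape,
    voxel_size_mm = cohort$config$voxel_size_mm,
    seed = cohort$config$seed,
    quantization = cohort$config$quantization,
    files = list(clinical = basename(clinical_path),
                 label_map = basename(label_path)),
    subjects = subjects$subject_id
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(clinical = clinical_path, label_map = label_path,
                 manifest = manifest_path))
}
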