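#' Read a run configuration from YAML
#'
#' Maps a YAML document onto [cohort_config()], [texture_params()] and the
#' analysis thresholds. Recognized top-level keys: `cohort` (any
#' [cohort_config()] argument except `structures` and `clinical_model`),
#' `texture` (any [texture_params()] argument) and `analysis` (`seed`,
#' `alpha_anova`, `alpha_pairwise`, `alpha_corr`). Unknown keys anywhere are
#' rejected, so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return list with `cohort_config`, `texture_params`, `analysis`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("cohort", "texture", "analysis")
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop_pdtex("unknown %s key(s): %s", where,
                                paste(bad, collapse = ", "))
  }
  check_keys(raw, known_top, "config")
  coh_args <- raw$cohort %||% list()
  check_keys(coh_args, setdiff(names(formals(cohort_config)),
                               c("structures", "clinical_model")), "cohort")
  for (nm in c("n_per_group", "heterogeneity")) {
    if (!is.null(coh_args[[nm]])) coh_args[[nm]] <- unlist(coh_args[[nm]])
  }
  cfg <- do.call(cohort_config, coh_args)
  tex_args <- raw$texture %||% list()
  check_keys(tex_args, names(formals(texture_params)), "texture")
  if (!is.null(tex_args$range)) tex_args$range <- unlist(tex_args$range)
  tp <- if (length(tex_args)) do.call(texture_params, tex_args)
        else cohort_texture_params(cfg)
  an <- raw$analysis %||% list()
  check_keys(an, c("seed", "alpha_anova", "alpha_pairwise", "alpha_corr"),
             "analysis")
  list(cohort_config = cfg, texture_params = tp, analysis = an)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

second_order_names <- function() {
  c("homogeneity", "contrast", "entropy", "correlation", "sumSQR", "sumA",
    "sumV", "idm")
}

#' Texture parameters implied by a cohort configuration
#'
#' The synthetic study uses a fixed global quantization range so that texture
#' heterogeneity maps monotonically onto occupied grey bins across subjects.
#'
#' @param config a [cohort_config()].
#' @return a [texture_params()].
#' @export
cohort_texture_params <- function(config) {
  q <- config$quantization
  texture_params(G = q$G, mode = q$mode, range = q$range)
}

#' Simulate a cohort and write it to disk
#'
#' @param config a [cohort_config()].
#' @param out_dir cohort directory.
#' @param compress write `.nii.gz` (default) or `.nii`.
#' @return the generated cohort (invisibly), with table paths attached.
#' @export
run_simulate <- function(config, out_dir, compress = TRUE) {
  cohort <- generate_cohort(config, out_dir, write_images = TRUE,
                            compress = compress)
  paths <- write_cohort_tables(cohort, out_dir)
  cohort$paths <- paths
  invisible(cohort)
}

read_label_map <- function(cohort_dir) {
  lm <- jsonlite::read_json(file.path(cohort_dir, "label_map.json"),
                            simplifyVector = TRUE)
  as.data.frame(lm, stringsAsFactors = FALSE)
}

#' Extract texture features and volumetry from a cohort on disk
#'
#' Reads the cohort manifest, clinical table and label map, then computes the
#' 12-feature texture vector and the ROI volumetry for every subject.
#' Failures of individual subjects (unreadable files, grid mismatches) are
#' recorded and skipped; the run completes and reports them, rather than
#' aborting the batch.
#'
#' @param cohort_dir directory written by [run_simulate()].
#' @param params a [texture_params()]; default derives the global
#'   quantization recorded in the manifest.
#' @param out_dir directory for `features.csv` and `volumes.csv`; `NULL`
#'   skips writing.
#' @return list: `features`, `volumes` (data frames), `failures` (data frame
#'   of subject_id + message), `params`.
#' @export
run_extract <- function(cohort_dir, params = NULL, out_dir = cohort_dir) {
  manifest <- jsonlite::read_json(file.path(cohort_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  clinical <- read_stable_csv(file.path(cohort_dir, "clinical.csv"))
  label_map <- read_label_map(cohort_dir)
  if (is.null(params)) {
    q <- manifest$quantization
    params <- texture_params(G = q$G, mode = q$mode, range = q$range)
  }
  spacing <- as.numeric(manifest$voxel_size_mm)
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(cohort_dir, p))
  }
  feats <- list(); vols <- list(); fails <- list()
  labels_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(clinical))) {
    sid <- clinical$subject_id[i]
    res <- tryCatch({
      mp <- resolve(clinical$mask_path[i])
      labels <- if (!is.null(labels_cache[[mp]])) labels_cache[[mp]] else {
        l <- round(as.array(RNifti::readNifti(mp)))
        storage.mode(l) <- "integer"
        labels_cache[[mp]] <- l
        l
      }
      img <- as.array(RNifti::readNifti(resolve(clinical$image_path[i])))
      if (!identical(dim(img), dim(labels))) {
        stop_pdtex("image/mask grid mismatch for %s", sid)
      }
      ft <- subject_texture_features(img, labels, label_map, params)
      ft <- cbind(data.frame(subject_id = sid, stringsAsFactors = FALSE), ft)
      vl <- subject_volumetry(img, labels, label_map, spacing,
                              tiv_cm3 = clinical$tiv_cm3[i])
      vl <- cbind(data.frame(subject_id = sid, stringsAsFactors = FALSE), vl)
      list(ft = ft, vl = vl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(subject_id = sid,
                                                message = conditionMessage(res),
                                                stringsAsFactors = FALSE)
    } else {
      feats[[length(feats) + 1L]] <- res$ft
      vols[[length(vols) + 1L]] <- res$vl
    }
  }
  features <- do.call(rbind, feats)
  volumes <- do.call(rbind, vols)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(subject_id = character(0), message = character(0))
  if (nrow(failures) > 0) {
    warning(sprintf("%d subject(s) failed extraction: %s", nrow(failures),
                    paste(failures$subject_id, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stable_csv(features, file.path(out_dir, "features.csv"))
    write_stable_csv(volumes, file.path(out_dir, "volumes.csv"))
  }
  list(features = features, volumes = volumes, failures = failures,
       params = params)
}

#' Fast in-memory cohort feature simulation
#'
#' Generates the same subjects as [generate_cohort()] (identical substreams,
#' identical within-ROI intensities) but computes texture features directly
#' on each structure's bounding box without assembling or writing whole-head
#' images. Used for repeated-cohort simulation studies; for any subject the
#' features equal those obtained through the NIfTI write/read/extract path.
#'
#' @param config a [cohort_config()].
#' @param params texture parameters; default [cohort_texture_params()].
#' @return list: `features` (subject x structure rows), `clinical` (subject
#'   table without file paths).
#' @export
simulate_cohort_features <- function(config, params = cohort_texture_params(config)) {
  masks <- structure_masks(config)
  st <- config$structures
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  feats <- list(); clin <- list()
  structures <- unique(st$structure)
  for (i in seq_along(groups)) {
    subj <- generate_subject(config, i, groups[i], masks)
    sid <- sprintf("sub-%03d", i)
    for (s in structures) {
      vecs <- lapply(c("left", "right"), function(h) {
        k <- which(st$structure == s & st$hemisphere == h)
        p <- subj$patches[[k]]
        box <- array(0, dim(p$sub))
        box[p$sub] <- p$intensity
        roi_features(box, p$sub, params)
      })
      avg <- (vecs[[1]] + vecs[[2]]) / 2
      feats[[length(feats) + 1L]] <- cbind(
        data.frame(subject_id = sid, structure = s, stringsAsFactors = FALSE),
        as.data.frame(as.list(avg)))
    }
    cl <- subj$clinical
    clin[[length(clin) + 1L]] <- data.frame(
      subject_id = sid, group = groups[i], h = subj$h, tiv_cm3 = subj$tiv_cm3,
      updrs1 = cl[["updrs1"]], updrs2 = cl[["updrs2"]], updrs3 = cl[["updrs3"]],
      updrs4 = cl[["updrs4"]], updrs_total = clinical_total(cl),
      hoehn_yahr = cl[["hoehn_yahr"]], stringsAsFactors = FALSE)
  }
  list(features = do.call(rbind, feats), clinical = do.call(rbind, clin))
}

# ANOVA screen for every (structure, feature); returns tidy table.
anova_screen <- function(data, feature_cols, alpha = 0.05) {
  rows <- list()
  for (s in unique(data$structure)) {
    d <- data[data$structure == s, ]
    for (f in feature_cols) {
      a <- anova_per_feature(d[[f]], d$group)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = s, feature = f, F = a$F, p = a$p,
        degenerate = a$degenerate, significant = !is.na(a$p) && a$p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Pairwise Welch tests for the ANOVA-gated features, BH-corrected within
# structure across the whole (feature x pair) family.
pairwise_screen <- function(data, anova_tab, alpha = 0.02) {
  out <- list()
  for (s in unique(anova_tab$structure)) {
    gated <- anova_tab$feature[anova_tab$structure == s & anova_tab$significant]
    if (length(gated) == 0) next
    d <- data[data$structure == s, ]
    fam <- list()
    for (f in gated) {
      groups <- factor(d$group)
      for (pr in utils::combn(levels(groups), 2, simplify = FALSE)) {
        a <- d[[f]][groups == pr[1]]; b <- d[[f]][groups == pr[2]]
        tt <- stats::t.test(a, b)
        fam[[length(fam) + 1L]] <- data.frame(
          structure = s, feature = f, group1 = pr[1], group2 = pr[2],
          t = unname(tt$statistic), p = unname(tt$p.value),
          stringsAsFactors = FALSE)
      }
    }
    fam <- do.call(rbind, fam)
    fam$q <- fdr_adjust(fam$p)
    fam$significant <- fam$q < alpha
    out[[length(out) + 1L]] <- fam
  }
  if (length(out) == 0) {
    return(data.frame(structure = character(0), feature = character(0),
                      group1 = character(0), group2 = character(0),
                      t = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  do.call(rbind, out)
}

# Wide subject x (structure.feature) matrix for the LASSO stage.
feature_matrix <- function(data, which_features) {
  subjects <- unique(data$subject_id)
  cols <- list(subject_id = subjects)
  for (i in seq_len(nrow(which_features))) {
    s <- which_features$structure[i]; f <- which_features$feature[i]
    d <- data[data$structure == s, c("subject_id", f)]
    cols[[paste(s, f, sep = ".")]] <- d[[f]][match(subjects, d$subject_id)]
  }
  out <- as.data.frame(cols, check.names = FALSE)
  out
}

#' Run the full inference chain on a cohort feature table
#'
#' Reproduces the marker-evaluation chain: per-(structure, feature) ANOVA
#' screen at `alpha_anova`, FDR-corrected pairwise Welch tests within
#' structure at `alpha_pairwise`, multinomial LASSO over the three groups on
#' the ANOVA-significant features, ROC (AUC, specificity, sensitivity at
#' Youden's J) of each LASSO-selected feature for early- versus late-stage
#' discrimination, and FDR-corrected Spearman correlations of the selected
#' features with the motor scores (MDS-UPDRS III, Hoehn-Yahr, MDS-UPDRS
#' total).
#'
#' @param features long feature table (`subject_id`, `structure`, feature
#'   columns) from [run_extract()] or [simulate_cohort_features()].
#' @param clinical clinical table (`subject_id`, `group`, scores).
#' @param seed seed for the LASSO fold assignment.
#' @param alpha_anova,alpha_pairwise,alpha_corr significance thresholds.
#' @param feature_cols feature columns to analyze (default the 12 texture
#'   features).
#' @param volumes optional volumetry table (`subject_id`, `structure`,
#'   `hemisphere`, `normalized_volume`); when given, a per-(structure,
#'   hemisphere) ANOVA of normalized volumes is added.
#' @return list of result tables: `anova`, `pairwise`, `lasso_selected`,
#'   `roc`, `spearman`, `volume_anova`, plus `settings`.
#' @export
run_analyze <- function(features, clinical, seed = 1L,
                        alpha_anova = 0.05, alpha_pairwise = 0.02,
                        alpha_corr = 0.05, feature_cols = feature_names(),
                        volumes = NULL) {
  unknown <- setdiff(feature_cols, names(features))
  if (length(unknown) > 0) {
    warning(sprintf("ignoring unknown feature column(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    feature_cols <- intersect(feature_cols, names(features))
  }
  matched <- intersect(unique(features$subject_id), clinical$subject_id)
  coverage <- length(matched) / length(unique(features$subject_id))
  if (coverage < 0.5) stop_pdtex("subject join coverage %.0f%% < 50%%",
                                 100 * coverage)
  if (coverage < 1) {
    warning(sprintf("join covers %d of %d feature subjects", length(matched),
                    length(unique(features$subject_id))), call. = FALSE)
  }
  data <- merge(features, clinical, by = "subject_id")
  anova_tab <- anova_screen(data, feature_cols, alpha_anova)
  pairwise_tab <- pairwise_screen(data, anova_tab, alpha_pairwise)
  gated <- anova_tab[anova_tab$significant, c("structure", "feature")]
  lasso_selected <- character(0)
  roc_tab <- NULL
  spearman_tab <- NULL
  if (nrow(gated) > 0) {
    fm <- feature_matrix(data, gated)
    cl <- clinical[match(fm$subject_id, clinical$subject_id), ]
    x <- as.matrix(fm[, -1, drop = FALSE])
    lasso_selected <- suppressWarnings(lasso_select(x, cl$group, seed = seed))
    attr(lasso_selected, "fit") <- NULL
    # ROC: early vs late discrimination of each selected feature
    pd <- cl$group %in% c("earlyPD", "latePD")
    roc_rows <- lapply(lasso_selected, function(nm) {
      rr <- roc_evaluate(fm[[nm]][pd], cl$group[pd], positive = "latePD")
      data.frame(feature = nm, auc = rr$auc, specificity = rr$specificity,
                 sensitivity = rr$sensitivity, stringsAsFactors = FALSE)
    })
    if (length(roc_rows)) roc_tab <- do.call(rbind, roc_rows)
    # Spearman with motor scores, FDR within structure
    if (length(lasso_selected)) {
      score_cols <- intersect(c("updrs3", "hoehn_yahr", "updrs_total"),
                              names(cl))
      sel_struct <- sub("\\..*$", "", lasso_selected)
      sp_rows <- lapply(unique(sel_struct), function(s) {
        nms <- lasso_selected[sel_struct == s]
        tab <- spearman_fdr(fm[, nms, drop = FALSE],
                            cl[, score_cols, drop = FALSE],
                            alpha = alpha_corr)
        cbind(data.frame(structure = s, stringsAsFactors = FALSE), tab)
      })
      spearman_tab <- do.call(rbind, sp_rows)
    }
  }
  volume_anova <- NULL
  if (!is.null(volumes)) {
    v <- merge(volumes, clinical[, c("subject_id", "group")], by = "subject_id")
    v$structure_hemi <- paste(v$structure, v$hemisphere, sep = "_")
    rows <- lapply(unique(v$structure_hemi), function(sh) {
      d <- v[v$structure_hemi == sh, ]
      a <- anova_per_feature(d$normalized_volume, d$group)
      data.frame(structure_hemi = sh, F = a$F, p = a$p,
                 stringsAsFactors = FALSE)
    })
    volume_anova <- do.call(rbind, rows)
  }
  list(anova = anova_tab, pairwise = pairwise_tab,
       lasso_selected = as.character(lasso_selected), roc = roc_tab,
       spearman = spearman_tab, volume_anova = volume_anova,
       settings = list(seed = seed, alpha_anova = alpha_anova,
                       alpha_pairwise = alpha_pairwise,
                       alpha_corr = alpha_corr))
}

#' Write analysis results as JSON and tidy CSVs
#'
#' Every artifact embeds the settings echo and the package version for
#' provenance.
#'
#' @param results list from [run_analyze()].
#' @param out_dir output directory.
#' @return named list of written paths, invisibly.
#' @export
write_analysis <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (nm in c("anova", "pairwise", "roc", "spearman", "volume_anova")) {
    if (!is.null(results[[nm]]) && nrow(results[[nm]]) >= 0) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write_stable_csv(results[[nm]], p)
      paths[[nm]] <- p
    }
  }
  payload <- results
  payload$package_version <- as.character(utils::packageVersion("pdtexture"))
  p <- file.path(out_dir, "results.json")
  jsonlite::write_json(payload, p, dataframe = "rows", auto_unbox = TRUE,
                       digits = 10, na = "null")
  paths$results <- p
  invisible(paths)
}

#' Simulate, extract and analyze in one call
#'
#' @param config a [cohort_config()].
#' @param out_dir run directory (`cohort/` and `analysis/` subdirectories).
#' @param analysis_seed seed for the LASSO stage.
#' @param ... passed to [run_analyze()].
#' @return list: `cohort`, `extraction`, `results`, `paths`.
#' @export
run_all <- function(config, out_dir, analysis_seed = 1L, ...) {
  cohort_dir <- file.path(out_dir, "cohort")
  analysis_dir <- file.path(out_dir, "analysis")
  cohort <- run_simulate(config, cohort_dir)
  extraction <- run_extract(cohort_dir, out_dir = cohort_dir)
  results <- run_analyze(extraction$features, cohort$subjects,
                         seed = analysis_seed, volumes = extraction$volumes,
                         ...)
  paths <- write_analysis(results, analysis_dir)
  list(cohort = cohort, extraction = extraction, results = results,
       paths = paths)
}
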