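#' Default end-to-end study configuration
#'
#' Parameters for a full simulated study: cohort sizes (34 young + 19 late
#' middle-aged), one planted unusable structural image (so 52 subjects
#' reach the structural/statistical stage, as in the emulated design),
#' five subjects without physiological recordings (their first-level models
#' simply lose the physiological columns), the oddball task (270 stimuli,
#' 20% targets, 2 s ISI), and planted ground-truth effects: a positive
#' age -> LC-contrast slope and a null LC-contrast -> LC-response
#' association.
#'
#' Phantom and BOLD grids default to reduced sizes that preserve every
#' geometric relationship (cylinders well inside the slab, reference patch
#' clear of the LC) while keeping a 53-subject run fast; pass larger
#' \code{structural$dim} / \code{bold$dim} for full-scale runs.
#'
#' @param seed integer seed driving the entire run.
#' @return Nested configuration list understood by
#'   \code{\link{run_full_study}}.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_young = 34L, n_older = 19L,
                  n_unusable_structural = 1L, n_missing_physio = 5L),
    structural = list(dim = c(48L, 48L, 40L), voxel_size = c(0.7, 0.7, 0.75),
                      noise_sd = 0.5, upsample = 2L, rater_jitter = 0.15,
                      pons_mean = 100),
    effects = list(contrast_base = 0.28, contrast_age_slope = 0.0012,
                   contrast_sd = 0.015, response_mean = 0.5,
                   response_sd = 0.15, response_contrast_slope = 0,
                   response_age_slope = 0),
    task = list(n_stimuli = 270L, p_target = 0.2, isi = 2.0),
    bold = list(dim = c(16L, 16L, 16L), voxel_size = 2.1, tr = 2.34,
                noise_sd = 1, smooth_fwhm = 0, drift_range = 2,
                motion_scale = 0.2, physio_scale = 0.3),
    glm = list(hp_cutoff = 128, cardiac_order = 3L, resp_order = 4L),
    motion = list(max_trans_mm = 1.0, max_rot_deg = 1.0,
                  exclude_trans_mm = 3, exclude_rot_deg = 3),
    svc = list(alpha = 0.05)
  )
}

#' Run the full simulated study
#'
#' Executes every stage in order with a single seed: cohort generation,
#' motion screening (3 mm / 3 degree limits), the structural LC contrast
#' chain (rater masks, intersection, upsampling, skeletonization,
#' pons-normalized contrast) for subjects with usable structural data, the
#' probabilistic LC template, per-subject event-related GLMs with nuisance
#' regressors and ROI beta extraction, the group-level model with
#' small-volume correction, and the three participant-level linear models.
#' Exclusions mirror the emulated study: the motion screen first, then
#' structural usability (one planted failure leaves n = 52 for the
#' contrast models), then physio availability (regressor set shrinks, the
#' subject is retained, and the group level keeps all motion-screened
#' subjects).
#'
#' @param config configuration list from \code{\link{default_config}}.
#' @param out_dir output directory for artifacts; created if missing.
#' @return The manifest (also written as \code{manifest.json}): seeds,
#'   per-stage counts, planted effect parameters, and relative paths of all
#'   written artifacts (cohort, contrasts, betas, participant table, model
#'   results, template, peak table).
#' @export
run_full_study <- function(config = default_config(), out_dir = tempdir()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  ## stage 1: cohort ------------------------------------------------------
  cohort <- stage("cohort", generate_cohort(config$cohort$n_young,
                                            config$cohort$n_older))
  n_total <- nrow(cohort)
  # planted exclusions: one unusable structural image among the young,
  # missing physio anywhere
  if (config$cohort$n_unusable_structural > 0) {
    idx <- sample(which(cohort$group == "young"),
                  config$cohort$n_unusable_structural)
    cohort$usable_structural[idx] <- FALSE
  }
  if (config$cohort$n_missing_physio > 0) {
    idx <- sample(seq_len(n_total), config$cohort$n_missing_physio)
    cohort$usable_physio[idx] <- FALSE
  }
  ## stage 2: motion screen ----------------------------------------------
  n_vol <- as.integer(ceiling(config$task$n_stimuli * config$task$isi /
                                config$bold$tr))
  motions <- stage("motion", {
    m <- lapply(seq_len(n_total), function(i)
      generate_motion(n_vol, config$motion$max_trans_mm,
                      config$motion$max_rot_deg))
    names(m) <- cohort$id
    m
  })
  kept_motion <- exclude_by_motion(motions, config$motion$exclude_trans_mm,
                                   config$motion$exclude_rot_deg)
  cohort <- cohort[cohort$id %in% kept_motion, , drop = FALSE]
  ## stage 3: structural contrast ----------------------------------------
  eff <- config$effects
  age_c <- cohort$age - mean(cohort$age)
  cohort$true_contrast <- eff$contrast_base + eff$contrast_age_slope * age_c +
    stats::rnorm(nrow(cohort), 0, eff$contrast_sd)
  cohort$true_contrast <- pmax(cohort$true_contrast, 0.02)
  sc <- config$structural
  contrast_rows <- list()
  template_masks <- list()
  truths <- list()
  for (i in seq_len(nrow(cohort))) {
    geom <- lc_geometry(dim = sc$dim, voxel_size = sc$voxel_size,
                        contrast_amplitude = cohort$true_contrast[i],
                        pons_mean = sc$pons_mean)
    ph <- stage("structural", generate_lc_volume(geom, noise_sd = sc$noise_sd))
    truths[[cohort$id[i]]] <- ph$truth
    if (!cohort$usable_structural[i]) next
    ml <- simulate_rater_masks(ph$truth, "left", sc$rater_jitter,
                               factor = sc$upsample)
    mr <- simulate_rater_masks(ph$truth, "right", sc$rater_jitter,
                               factor = sc$upsample)
    res <- stage("contrast",
                 compute_lc_contrast(ph$volume, ml, mr,
                                     ph$truth$pons_anchor,
                                     factor = sc$upsample))
    contrast_rows[[cohort$id[i]]] <-
      data.frame(id = cohort$id[i], lc_contrast = res$contrast$bilateral,
                 lc_contrast_left = res$contrast$left,
                 lc_contrast_right = res$contrast$right,
                 stringsAsFactors = FALSE)
    inter <- intersect_masks(ml$rater1, ml$rater2)
    inter_r <- intersect_masks(mr$rater1, mr$rater2)
    template_masks[[cohort$id[i]]] <-
      list(voxels = rbind(inter$voxels, inter_r$voxels),
           grid_dim = inter$grid_dim)
    # keep the subject's skeletons for functional ROI extraction
    attr(contrast_rows[[cohort$id[i]]], "skeletons") <- res$skeletons
  }
  contrasts <- do.call(rbind, contrast_rows)
  rownames(contrasts) <- NULL
  template <- stage("template",
                    build_probabilistic_template(
                      template_masks,
                      voxel_size = sc$voxel_size / sc$upsample))
  ## stage 4: functional --------------------------------------------------
  bc <- config$bold
  cohort$true_response <- eff$response_mean +
    eff$response_age_slope * age_c +
    eff$response_contrast_slope * (cohort$true_contrast -
                                     mean(cohort$true_contrast)) +
    stats::rnorm(nrow(cohort), 0, eff$response_sd)
  beta_rows <- list()
  beta_maps <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$id[i]
    design <- generate_event_design(config$task$n_stimuli,
                                    config$task$p_target, config$task$isi)
    physio <- if (cohort$usable_physio[i])
      generate_physio(attr(design, "total_duration"), fs = 50) else NULL
    sim <- stage("bold",
                 generate_bold(design, truths[[id]],
                               amplitude = cohort$true_response[i],
                               motion = motions[[id]], physio = physio,
                               tr = bc$tr, noise_sd = bc$noise_sd,
                               dim = bc$dim, voxel_size = bc$voxel_size,
                               drift_range = bc$drift_range,
                               motion_scale = bc$motion_scale,
                               physio_scale = bc$physio_scale))
    bold <- sim$bold
    if (bc$smooth_fwhm > 0) {
      for (v in seq_len(n_volumes(bold)))
        bold$data[, , , v] <- smooth_volume(bold$data[, , , v],
                                            bc$smooth_fwhm, bc$voxel_size)
    }
    vt <- (seq_len(n_volumes(bold)) - 1) * bc$tr
    nuis <- build_nuisance(motions[[id]], physio, vt,
                           config$glm$cardiac_order, config$glm$resp_order)
    X <- build_design(design, nuis, n_volumes(bold), bc$tr,
                      config$glm$hp_cutoff)
    fit <- stage("glm", fit_glm(bold, X))
    beta_maps[[id]] <- fit$beta_map
    if (id %in% names(contrast_rows)) {
      skel <- attr(contrast_rows[[id]], "skeletons")
      roi <- stage("roi",
                   extract_roi_beta(fit, skel,
                                    sc$voxel_size / sc$upsample,
                                    bc$voxel_size))
      beta_rows[[id]] <- data.frame(id = id, lc_response = roi$bilateral,
                                    lc_response_left = roi$left,
                                    lc_response_right = roi$right,
                                    stringsAsFactors = FALSE)
    }
  }
  betas <- do.call(rbind, beta_rows)
  rownames(betas) <- NULL
  ## stage 5: group level -------------------------------------------------
  covs <- cohort[, c("age", "sex", "bmi")]
  group_fit <- stage("second_level",
                     second_level(beta_maps, covs, dim_space = bc$dim))
  lcv <- functional_lc_voxels(truths[[cohort$id[1]]], bc$dim, bc$voxel_size)
  search <- array(FALSE, bc$dim)
  search[rbind(lcv$left, lcv$right)] <- TRUE
  peaks <- stage("svc", small_volume_correct(group_fit, search,
                                             alpha = config$svc$alpha))
  ## stage 6: participant-level models ------------------------------------
  stats_table <- merge(merge(cohort, contrasts, by = "id"), betas, by = "id")
  models <- stage("models", lc_models(stats_table))
  ## artifacts ------------------------------------------------------------
  paths <- list(cohort = "cohort.csv", contrasts = "contrasts.csv",
                betas = "betas.csv", participants = "participants.csv",
                models = "model_results.csv", template = "lc_template.nii.gz",
                peaks = "peaks.csv")
  utils::write.csv(cohort, file.path(out_dir, paths$cohort), row.names = FALSE)
  utils::write.csv(contrasts, file.path(out_dir, paths$contrasts),
                   row.names = FALSE)
  utils::write.csv(betas, file.path(out_dir, paths$betas), row.names = FALSE)
  utils::write.csv(stats_table, file.path(out_dir, paths$participants),
                   row.names = FALSE)
  model_tab <- do.call(rbind, lapply(names(models), function(nm) {
    tb <- models[[nm]]$table
    cbind(model = nm, tb)
  }))
  utils::write.csv(model_tab, file.path(out_dir, paths$models),
                   row.names = FALSE)
  write_nifti_volume(template, file.path(out_dir, paths$template))
  utils::write.csv(peaks, file.path(out_dir, paths$peaks), row.names = FALSE)
  manifest <- list(
    seed = config$seed,
    counts = list(
      simulated = n_total,
      after_motion_screen = nrow(cohort),
      excluded_motion = n_total - nrow(cohort),
      usable_structural = sum(cohort$usable_structural),
      entered_statistics = nrow(stats_table),
      missing_physio = sum(!cohort$usable_physio),
      second_level_n = length(beta_maps),
      second_level_df = group_fit$df
    ),
    effects = eff,
    focal = list(
      contrast_age = models$contrast_age$focal[, c("estimate", "t", "p")],
      response_age = models$response_age$focal[, c("estimate", "t", "p")],
      response_contrast =
        models$response_contrast$focal[, c("estimate", "t", "p")]
    ),
    artifacts = paths
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and merges it over \code{\link{default_config}}
#' (missing fields keep their defaults).
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_lists(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Render a human-readable study report
#'
#' Formats the manifest and its artifacts into a deterministic plain-text
#' summary: per-stage subject counts, a demographic table, the three model
#' results, and the small-volume-corrected peak table. Every number is read
#' back from the manifest artifacts.
#'
#' @param out_dir directory containing \code{manifest.json} and the
#'   artifacts it names.
#' @return Character vector of report lines (invisibly also written to
#'   \code{report.txt} in \code{out_dir}).
#' @export
make_report <- function(out_dir) {
  mpath <- file.path(out_dir, "manifest.json")
  if (!file.exists(mpath)) stop("missing artifact: manifest.json")
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  need <- unlist(man$artifacts)
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop("missing artifact: ", paste(missing, collapse = ", "))
  lines <- c("LC structural-functional study report",
             strrep("=", 40),
             sprintf("seed: %d", man$seed),
             sprintf("subjects simulated: %d", man$counts$simulated),
             sprintf("after motion screen: %d", man$counts$after_motion_screen),
             sprintf("usable structural: %d", man$counts$usable_structural),
             sprintf("entered statistics: %d", man$counts$entered_statistics),
             sprintf("second level: n = %d, df = %d",
                     man$counts$second_level_n, man$counts$second_level_df),
             "")
  parts <- utils::read.csv(file.path(out_dir, man$artifacts$participants))
  if (nrow(parts) == 0) {
    lines <- c(lines, "Cohort: no subjects", "")
  } else {
    lines <- c(lines, "Cohort characteristics (mean (SD)):")
    for (g in unique(parts$group)) {
      p <- parts[parts$group == g, ]
      lines <- c(lines, sprintf(
        "  %s (n=%d): age %.2f (%.2f), BMI %.2f (%.2f), education %.2f (%.2f), %d F / %d M",
        g, nrow(p), mean(p$age), stats::sd(p$age), mean(p$bmi),
        stats::sd(p$bmi), mean(p$education), stats::sd(p$education),
        sum(p$sex == "F"), sum(p$sex == "M")))
    }
    lines <- c(lines, "")
  }
  mods <- utils::read.csv(file.path(out_dir, man$artifacts$models))
  lines <- c(lines, "Model results (focal terms):")
  if (nrow(mods)) {
    foc <- mods[mods$focal == TRUE | mods$focal == "TRUE", , drop = FALSE]
    for (i in seq_len(nrow(foc)))
      lines <- c(lines, sprintf(
        "  %s: %s  b = %.5g, t = %.3f, p = %.4f, 95%% CI (%.5g, %.5g)",
        foc$model[i], foc$term[i], foc$estimate[i], foc$t[i], foc$p[i],
        foc$ci_lo[i], foc$ci_hi[i]))
  } else lines <- c(lines, "  no models (no subjects)")
  lines <- c(lines, "")
  pk <- utils::read.csv(file.path(out_dir, man$artifacts$peaks))
  lines <- c(lines, "Small-volume-corrected LC peaks:")
  if (nrow(pk) == 0) {
    lines <- c(lines, "  none significant")
  } else {
    for (i in seq_len(nrow(pk)))
      lines <- c(lines, sprintf(
        "  %s: k = %d, t = %.3f, p_FWE = %.4f, peak (%d, %d, %d)",
        pk$region[i], pk$cluster_size[i], pk$t[i], pk$p_fwe[i],
        pk$peak_x[i], pk$peak_y[i], pk$peak_z[i]))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(lines)
}
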