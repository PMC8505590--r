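#' Configuration of one per-patient agent comparison
#'
#' Bundles the four acquisitions (unenhanced + contrast-enhanced for each
#' examination), the shared lesion ROI, the agent labels, and every module
#' parameter block. Volumes and the ROI may be given either as file paths
#' (NIfTI-1) or as in-memory [image_volume] / [roi_mask] objects.
#'
#' @param pre1,post1,pre2,post2 the four acquisitions (paths or
#'   [image_volume]s); examination 1 defines the reference frame.
#' @param roi lesion ROI (path or [roi_mask]) on the examination-1 grid,
#'   drawn once and shared across both examinations.
#' @param agents length-2 character: the agent given at examination 1 and
#'   examination 2 respectively.
#' @param patient patient identifier echoed into reports.
#' @param bias a [bias_params].
#' @param reg a [registration_params].
#' @param ga a [ga_params] (its seed is re-derived from `seed`).
#' @param k,p_sat fuzzification calibration constants
#'   (see [derive_thresholds()]).
#' @param zone,level equivalence-zone half-width and confidence level.
#' @param min_avg exclusion threshold for [enhancement_present()].
#' @param seed global integer seed; recorded in every output.
#' @param out_dir optional directory for QEMs, change map, scatter CSVs and
#'   the JSON report.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pre1, post1, pre2, post2, roi,
                       agents = c("gadoteridol", "gadobutrol"),
                       patient = 1L,
                       bias = bias_params(), reg = registration_params(),
                       ga = ga_params(), k = 2, p_sat = 99,
                       zone = 0.2, level = 0.90, min_avg = 0.01,
                       seed = 1L, out_dir = NULL) {
  imgs <- list(pre1 = pre1, post1 = post1, pre2 = pre2, post2 = post2)
  paths <- vapply(imgs, function(v) if (is.character(v)) v else NA_character_,
                  character(1))
  known <- paths[!is.na(paths)]
  if (anyDuplicated(known))
    stop("the four image paths must be distinct")
  stopifnot(length(agents) == 2L, is.character(agents))
  structure(list(pre1 = pre1, post1 = post1, pre2 = pre2, post2 = post2,
                 roi = roi, agents = agents, patient = patient,
                 bias = bias, reg = reg, ga = ga, k = k, p_sat = p_sat,
                 zone = zone, level = level, min_avg = min_avg,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

resolve_volume <- function(v) if (is.character(v)) read_volume(v) else v

mapping_record <- function(m)
  list(x = m$x, y = m$y, fitness = attr(m, "fitness"),
       oracle_fitness = attr(m, "oracle_fitness"), seed = attr(m, "seed"))

transform_record <- function(tf)
  list(rotation_deg = tf$rotation, translation_mm = tf$translation,
       centre_mm = tf$centre, mi = attr(tf, "mi"))

#' Run the full per-patient two-agent comparison
#'
#' Executes the whole pipeline on one patient: bias-field correction of all
#' four images, rigid mutual-information registration of the other three
#' images onto the examination-1 unenhanced image ("all to one"), intensity
#' harmonisation onto the same reference (fit on brain tissue outside the
#' lesion ROI, so genuine enhancement is not harmonised away), QEM
#' construction for each agent under one shared threshold calibration
#' derived from examination 1, the QE change map, per-ROI summaries, the
#' equivalence-zone test, and the no-enhancement exclusion flag. All derived
#' parameters (noise sigma, thresholds, transforms, mapping control points)
#' are echoed into the report as an audit trail. Deterministic under a
#' fixed `config$seed`.
#'
#' @param config a [run_config].
#' @return An object of class `patient_report`; if `config$out_dir` is set,
#'   QEMs, the change map, scatter CSVs and `report.json` are also written
#'   there.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  vols <- run_stage("load", lapply(config[c("pre1", "post1", "pre2", "post2")],
                                   resolve_volume))
  roi <- run_stage("load", {
    r <- config$roi
    if (is.character(r)) read_mask(r, vols$pre1) else r
  })
  check_same_grid(vols$pre1, roi, "reference volume and ROI")

  bias_out <- run_stage("bias_correction",
                        lapply(vols, correct_bias, mask = NULL,
                               params = config$bias))
  corr <- lapply(bias_out, `[[`, "corrected")
  fixed <- corr$pre1

  transforms <- run_stage("registration", {
    tf_post1 <- register_rigid(corr$post1, fixed, config$reg)
    tf_pre2 <- register_rigid(corr$pre2, fixed, config$reg)
    # within one examination the patient position is shared, and the
    # enhanced image registered against an unenhanced reference is the one
    # prone to local optima: seed it with its companion's transform
    tf_post2 <- register_rigid(corr$post2, fixed, config$reg, init = tf_pre2)
    list(post1 = tf_post1, pre2 = tf_pre2, post2 = tf_post2)
  })
  aligned <- run_stage("registration", {
    out <- lapply(names(transforms), function(nm)
      resample(corr[[nm]], transforms[[nm]], fixed))
    names(out) <- names(transforms)
    out
  })

  brain <- run_stage("harmonisation", otsu_mask(fixed))
  exclude <- roi_mask(!brain$data | roi$data, fixed)
  mappings <- run_stage("harmonisation", {
    maps <- lapply(seq_along(aligned), function(i) {
      ga <- config$ga
      ga$seed <- config$seed * 100L + i
      fit_harmonisation(aligned[[i]], fixed, exclude = exclude, params = ga)
    })
    names(maps) <- names(aligned)
    maps
  })
  harm <- lapply(names(mappings), function(nm)
    apply_mapping(aligned[[nm]], mappings[[nm]]))
  names(harm) <- names(mappings)

  qem <- run_stage("enhancement", {
    background <- roi_mask(!brain$data, fixed)
    sigma <- estimate_noise_sigma(fixed, background)
    sub1 <- image_volume(harm$post1$data - fixed$data, fixed$spacing,
                         fixed$origin)
    fuzz <- tryCatch(derive_thresholds(sub1, brain, sigma, k = config$k,
                                       p_sat = config$p_sat),
                     error = function(e) {
                       if (!grepl("no enhancement signal",
                                  conditionMessage(e)))
                         stop(e)
                       NULL
                     })
    if (is.null(fuzz)) {
      # nothing in the first exam rises above the noise floor: the QEMs are
      # identically zero and the patient will be flagged excluded downstream
      zero <- function(agent) structure(
        list(data = array(0, dim = dim(fixed$data)), spacing = fixed$spacing,
             origin = fixed$origin,
             provenance = list(agent = agent, theta_low = NA_real_,
                               theta_high = NA_real_)),
        class = c("qe_map", "image_volume"))
      list(q1 = zero(config$agents[1]), q2 = zero(config$agents[2]),
           sigma = sigma,
           fuzz = list(theta_low = NA_real_, theta_high = NA_real_,
                       k = config$k, p_sat = config$p_sat))
    } else {
      q1 <- compute_qem(fixed, harm$post1, fuzz, agent = config$agents[1])
      q2 <- compute_qem(harm$pre2, harm$post2, fuzz, agent = config$agents[2])
      list(q1 = q1, q2 = q2, sigma = sigma, fuzz = fuzz)
    }
  })

  result <- run_stage("roi_analysis", {
    cm <- change_map(qem$q1, qem$q2)
    s1 <- summarise_roi(qem$q1, roi)
    s2 <- summarise_roi(qem$q2, roi)
    eq <- equivalence_test(qem$q1, qem$q2, roi, zone = config$zone,
                           level = config$level)
    enh <- enhancement_present(qem$q1, roi, config$min_avg) ||
      enhancement_present(qem$q2, roi, config$min_avg)
    list(cm = cm, s1 = s1, s2 = s2, eq = eq, enhancing = enh)
  })

  report <- structure(list(
    patient = config$patient,
    agents = config$agents,
    seed = config$seed,
    version = as.character(utils::packageVersion("qea")),
    excluded = !result$enhancing,
    exclusion_reason = if (!result$enhancing)
      "absence of lesion signal enhancement on the generated QEM" else NA_character_,
    noise_sigma = qem$sigma,
    thresholds = unclass(qem$fuzz),
    transforms = lapply(transforms, transform_record),
    mappings = lapply(mappings, mapping_record),
    summaries = stats::setNames(list(unclass(result$s1), unclass(result$s2)),
                                config$agents),
    equivalence = unclass(result$eq),
    params = list(bias = unclass(config$bias), reg = unclass(config$reg),
                  ga = unclass(config$ga), k = config$k,
                  p_sat = config$p_sat, zone = config$zone,
                  level = config$level, min_avg = config$min_avg)),
    class = "patient_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_volume(structure(qem$q1[c("data", "spacing", "origin")],
                           class = "image_volume"),
                 file.path(od, paste0("qem_", config$agents[1], ".nii.gz")))
    write_volume(structure(qem$q2[c("data", "spacing", "origin")],
                           class = "image_volume"),
                 file.path(od, paste0("qem_", config$agents[2], ".nii.gz")))
    write_volume(structure(result$cm[c("data", "spacing", "origin")],
                           class = "image_volume"),
                 file.path(od, "qe_change_map.nii.gz"))
    utils::write.csv(scatter_data(fixed, harm$post1, roi),
                     file.path(od, paste0("scatter_", config$agents[1], ".csv")),
                     row.names = FALSE)
    utils::write.csv(scatter_data(harm$pre2, harm$post2, roi),
                     file.path(od, paste0("scatter_", config$agents[2], ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(unclass(report), file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(report, "qem") <- list(q1 = qem$q1, q2 = qem$q2, change = result$cm)
  report
}

#' @export
print.patient_report <- function(x, ...) {
  cat("<patient_report> patient ", x$patient, " (",
      paste(x$agents, collapse = " vs "), ")\n", sep = "")
  if (x$excluded) cat("  EXCLUDED: ", x$exclusion_reason, "\n", sep = "")
  for (a in x$agents)
    cat("  ", a, ": net QE ", round(x$summaries[[a]]$net_qe, 1), ", avg ",
        round(x$summaries[[a]]$avg_qe, 3), "\n", sep = "")
  cat("  equivalence: mean diff ", signif(x$equivalence$mean_diff, 3),
      ", verdict ", if (x$equivalence$equivalent) "equivalent"
      else "not equivalent", "\n", sep = "")
  invisible(x)
}

#' Run a cohort of per-patient comparisons and the cohort statistics
#'
#' Runs [run_compare()] for every configuration, applies the
#' no-enhancement exclusion rule at cohort level, builds the per-patient
#' summary table, and runs the full between-agent statistical battery
#' ([agent_stats_report()]) on the included patients. All configurations
#' must use the same two agent labels (examination order may differ).
#'
#' @param configs list of [run_config] objects.
#' @param out_dir optional directory for `cohort_summary.csv` and
#'   `cohort_stats.json`.
#' @return A list with `reports` (all patient reports), `excluded`
#'   (data frame of patient and reason), `summary` (long per-patient/agent
#'   table), `records` (wide table fed to the statistics), and `stats`.
#' @export
run_cohort <- function(configs, out_dir = NULL) {
  stopifnot(length(configs) >= 1L)
  agents <- sort(configs[[1]]$agents)
  for (cfg in configs)
    if (!setequal(cfg$agents, agents))
      stop("all patients must compare the same two agents")
  reports <- lapply(configs, run_compare)
  excluded <- do.call(rbind, lapply(reports, function(r)
    if (r$excluded) data.frame(patient = r$patient,
                               reason = r$exclusion_reason)))
  included <- Filter(function(r) !r$excluded, reports)
  if (length(included) < 2L)
    stop("fewer than 2 patients remain after the enhancement exclusion rule")
  summary_tab <- do.call(rbind, lapply(included, function(r) {
    do.call(rbind, lapply(r$agents, function(a) {
      s <- r$summaries[[a]]
      data.frame(patient = r$patient, agent = a, net_qe = s$net_qe,
                 n_voxels = s$n_voxels, volume_cm3 = s$volume_cm3,
                 max_extent_mm = s$max_extent_mm, avg_qe = s$avg_qe)
    }))
  }))
  records <- do.call(rbind, lapply(included, function(r) {
    row <- data.frame(patient = r$patient, first_agent = r$agents[1])
    for (a in r$agents) {
      row[[paste0("net_", a)]] <- r$summaries[[a]]$net_qe
      row[[paste0("avg_", a)]] <- r$summaries[[a]]$avg_qe
    }
    row[, c("patient", "first_agent", paste0("net_", agents),
            paste0("avg_", agents))]
  }))
  stats_out <- agent_stats_report(records, agents = agents)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(agents = agents,
           n_included = length(included),
           excluded = if (is.null(excluded)) list() else excluded,
           net_t = unclass(stats_out$net_t),
           avg_t = unclass(stats_out$avg_t),
           net_pearson = stats_out$net_pearson,
           avg_pearson = stats_out$avg_pearson,
           avg_bland_altman = stats_out$avg_bland_altman[
             c("mean_diff", "sd_diff", "limits")],
           preference = stats_out$preference),
      file.path(out_dir, "cohort_stats.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(reports = reports, excluded = excluded, summary = summary_tab,
       records = records, stats = stats_out)
}
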