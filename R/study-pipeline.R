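# Cohort orchestration: run the vessel, ERG, and OCT stages over a manifest
# of animals and emit tidy per-animal tables plus mean +/- SEM group
# summaries per genotype x age. Inferential statistics (repeated-measures
# ANOVA, post hoc tests) are deliberately left to standard statistical
# software; the long-format tables written here are their direct input.

#' Read a cohort manifest
#'
#' CSV columns: `animal_id, genotype, age_group, modality, path,
#' eye_or_retina`, one row per eye/retina recording. `modality` is one of
#' `vessel` (path: vessel-trace JSON, with the image as `<stem>.tif` or
#' `<stem>.png` beside it), `erg` (path: directory of sweep CSV + JSON
#' sidecar pairs, one per intensity), or `oct` (path: boundary JSON).
#'
#' @param path Manifest CSV path.
#' @return Validated manifest data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  need <- c("animal_id", "genotype", "age_group", "modality", "path",
            "eye_or_retina")
  miss <- setdiff(need, names(m))
  if (length(miss)) stopf("manifest missing columns: %s", paste(miss, collapse = ", "))
  if (any(!nzchar(m$genotype)) || any(!nzchar(m$age_group))) {
    stopf("genotype and age_group labels must be non-empty")
  }
  key <- paste(m$animal_id, m$modality, m$eye_or_retina)
  if (anyDuplicated(key)) stopf("duplicate (animal, modality, eye/retina) rows")
  m
}

process_vessel_entry <- function(path, config) {
  ds <- read_vessel_json(path, source = "manual")
  stem <- sub("\\.json$", "", path)
  img_path <- if (file.exists(paste0(stem, ".tif"))) paste0(stem, ".tif")
  else paste0(stem, ".png")
  image <- read_retinal_image(img_path)
  circle <- ds$circle
  if (is.null(circle)) stopf("no reference circle in %s", path)
  cfg <- config$vessel %||% vessel_config()
  results <- lapply(ds$traces, function(tr) measure_vessel(image, tr, circle, cfg))
  summ <- summarize_retina(results)
  out <- data.frame(measure = c(paste0(summ$class, "_mean_width_um"),
                                paste0(summ$class, "_count")),
                    value = c(summ$mean_width_um, summ$vessel_count))
  out[!is.na(out$value), , drop = FALSE]
}

process_erg_entry <- function(path, config) {
  csvs <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (length(csvs) == 0) stopf("no sweep CSVs in %s", path)
  traces <- lapply(csvs, function(f) average_sweeps(read_erg_sweeps(f)))
  an <- analyze_intensity_series(
    traces,
    nr_range = config$nr_range %||% c(-3.8, 1.0),
    lp_range = config$lp_range %||% c(-1.1, 2.2),
    op_band = config$op_band %||% c(60, 235))
  f <- an$features
  out <- data.frame(
    measure = c(sprintf("a_amplitude_uv@%.1f", f$intensity_log),
                sprintf("b_amplitude_uv@%.1f", f$intensity_log),
                sprintf("op_magnitude_uv@%.1f", f$intensity_log)),
    value = c(f$a_amplitude_uv, f$b_amplitude_uv, f$op_magnitude_uv))
  if (!is.null(an$naka_rushton)) {
    cf <- coef(an$naka_rushton)
    out <- rbind(out, data.frame(measure = c("vmax_uv", "k_log"),
                                 value = c(cf[["vmax_uv"]], cf[["k_log"]])))
  }
  if (!is.null(an$lamb_pugh)) {
    cf <- coef(an$lamb_pugh)
    out <- rbind(out, data.frame(measure = c("rmax_uv", "tc_ms", "td_ms"),
                                 value = c(cf[["r_max_uv"]], cf[["t_c_ms"]],
                                           cf[["t_d_ms"]])))
  }
  out[!is.na(out$value), , drop = FALSE]
}

process_oct_entry <- function(path, config) {
  prof <- thickness_profile(read_oct_boundaries(path))
  data.frame(measure = sprintf("oct_%s@%+d", prof$layer, prof$offset_um),
             value = prof$thickness_um)
}

#' Run a cohort study
#'
#' Processes every manifest row with the stage matching its modality,
#' pre-averages eyes/retinas within each animal, and summarizes per
#' (genotype, age_group, measure) as mean +/- SEM. Rows whose files are
#' missing or fail to parse are recorded in the log and skipped; the run
#' continues. Deterministic given inputs and config.
#'
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @param config Named list of stage options (`vessel` = [vessel_config()],
#'   `nr_range`, `lp_range`, `op_band`).
#' @param out_dir Optional output directory; when given, writes
#'   `per_animal/per_animal.csv`, `summaries/group_summary.csv`, and
#'   `run.log` (with the full config echoed for provenance).
#' @return List with `per_animal`, `summary`, and `log` (character vector).
#' @export
run_study <- function(manifest, config = list(), out_dir = NULL) {
  manifest <- validate_manifest(manifest)
  log <- character(0)
  entries <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch(withCallingHandlers({
      vals <- switch(row$modality,
                     vessel = process_vessel_entry(row$path, config),
                     erg = process_erg_entry(row$path, config),
                     oct = process_oct_entry(row$path, config),
                     stopf("unknown modality '%s'", row$modality))
      cbind(animal_id = row$animal_id, genotype = row$genotype,
            age_group = row$age_group, modality = row$modality,
            eye_or_retina = row$eye_or_retina, vals,
            stringsAsFactors = FALSE)
    }, warning = function(w) {
      log <<- c(log, sprintf("warning row %d (%s, %s): %s", i, row$animal_id,
                             row$modality, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      log <<- c(log, sprintf("ERROR row %d (%s, %s): %s", i, row$animal_id,
                             row$modality, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      entries[[length(entries) + 1]] <- res
      log <- c(log, sprintf("ok row %d (%s, %s): %d measures", i,
                            row$animal_id, row$modality, nrow(res)))
    }
  }
  if (length(entries) == 0) stopf("no manifest rows processed successfully")
  long <- do.call(rbind, entries)
  # pre-average eyes/retinas within animal before grouping
  per_animal <- stats::aggregate(
    value ~ animal_id + genotype + age_group + modality + measure,
    data = long, FUN = mean)
  per_animal <- per_animal[order(per_animal$animal_id, per_animal$modality,
                                 per_animal$measure), ]
  rownames(per_animal) <- NULL
  summary <- summarize_groups(per_animal)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "per_animal"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "summaries"), showWarnings = FALSE)
    utils::write.csv(per_animal,
                     file.path(out_dir, "per_animal", "per_animal.csv"),
                     row.names = FALSE)
    utils::write.csv(summary,
                     file.path(out_dir, "summaries", "group_summary.csv"),
                     row.names = FALSE)
    writeLines(c("# run log", log, "# config",
                 yaml::as.yaml(config_echo(config))),
               file.path(out_dir, "run.log"))
  }
  list(per_animal = per_animal, summary = summary, log = log)
}

config_echo <- function(config) {
  rapply(config, function(x) if (is.function(x)) "<function>" else x,
         how = "replace")
}

#' Group summaries as mean +/- SEM
#'
#' One row per (grouping keys) cell with n, mean, and SEM = sd/sqrt(n). For
#' n = 1 the SEM is reported as absent (`NA`). Row order is deterministic.
#'
#' @param per_animal Data frame with one row per animal per measure (column
#'   `value`).
#' @param keys Grouping columns.
#' @return Data frame `<keys>, n, mean, sem`.
#' @export
summarize_groups <- function(per_animal,
                             keys = c("genotype", "age_group", "measure")) {
  stopifnot(nrow(per_animal) >= 1, all(keys %in% names(per_animal)),
            "value" %in% names(per_animal))
  f <- stats::as.formula(paste("value ~", paste(keys, collapse = " + ")))
  agg <- stats::aggregate(f, data = per_animal, FUN = function(v) {
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- cbind(agg[keys], as.data.frame(agg$value))
  out <- out[do.call(order, out[keys]), ]
  rownames(out) <- NULL
  out
}

#' MRI axial resolution expressed in dioptres
#'
#' Converts an axial spatial resolution into the smallest detectable
#' refractive-error change, given the axial-length change corresponding to
#' one dioptre in the mouse eye, rounded to the nearest dioptre. At the
#' standard small-animal coil resolution of 80 um and 6.5 um per dioptre this
#' limits detection to about 12 D.
#'
#' @param resolution_um Axial resolution, um.
#' @param um_per_dioptre Axial-length change per dioptre, um/D.
#' @return Integer dioptre equivalence.
#' @export
dioptre_equivalent <- function(resolution_um = 80, um_per_dioptre = 6.5) {
  stopifnot(resolution_um > 0, um_per_dioptre > 0)
  round(resolution_um / um_per_dioptre)
}
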