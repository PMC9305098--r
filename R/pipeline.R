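## End-to-end pipeline: QC -> preprocess -> map -> metrics -> fits ->
## comparisons -> segmented fits -> report, with provenance logging.

#' Pipeline run configuration
#'
#' @param input_dir Directory holding the input bundle (the dialect written
#'   by [write_cohort()]: `<id>_octa.pgm` (+ `.json`), `<id>_rnfl.csv`,
#'   `sap.csv`/`sap.json`, `geometry.csv`).
#' @param out_dir Output directory.
#' @param trajectory_config Optional path to a trajectory atlas JSON.
#' @param alpha Significance levels for the location maps.
#' @param exclude Extra location exclusions.
#' @param window_mm,offset,scales_mm,vesselness_threshold Preprocessing
#'   parameters (see [preprocess_octa()]).
#' @param target_px Normalized frame size (pixels); the physical target is
#'   always 4.11 mm.  Smaller frames trade resolution for speed.
#' @param include_large_vessel_area Passed to [focal_cd()].
#' @param seed Seed recorded for provenance (the pipeline itself is
#'   deterministic).
#' @return List of class `run_config` (validated: all paths must exist).
#' @export
run_config <- function(input_dir, out_dir = file.path(input_dir, "results"),
                       trajectory_config = NULL,
                       alpha = c(0.05, 0.001), exclude = integer(0),
                       window_mm = 0.1, offset = 0.02,
                       scales_mm = c(0.03, 0.06, 0.09, 0.12),
                       vesselness_threshold = 0.5, target_px = 960L,
                       include_large_vessel_area = FALSE, seed = 1L) {
  if (!dir.exists(input_dir)) stopf("input_dir does not exist: %s", input_dir)
  for (f in c("sap.csv", "sap.json", "geometry.csv"))
    if (!file.exists(file.path(input_dir, f)))
      stopf("missing input file: %s", file.path(input_dir, f))
  if (!is.null(trajectory_config) && !file.exists(trajectory_config))
    stopf("trajectory config not found: %s", trajectory_config)
  if (any(alpha <= 0 | alpha >= 1)) stopf("alpha values must lie in (0, 1)")
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from JSON
#'
#' @param path JSON file whose fields mirror the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("run config not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' Run the full focal structure-function pipeline
#'
#' Stages: reliability QC on the SAP exams; OCT-A preprocessing
#' (binarize, Frangi large-vessel isolation, removal, normalization);
#' per-eye trajectory fitting and wedge construction; focal metric
#' extraction; per-location model fits and comparisons; segmented
#' mixed-model fits for both structural channels.  Every stage appends a
#' provenance record (parameters plus input-file hashes) and failures abort
#' with the stage name.
#'
#' @param config A [run_config()].
#' @return List with `records`, `maps` (location_maps output), `global`,
#'   `segmented` (fCD and fRNFLT fits), `table3`, `qc`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(seed = config$seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  params <- stage("trajectory-config",
                  trajectory_params(config$trajectory_config))
  ## --- ingest + QC
  exams <- stage("sap-ingest",
                 read_sap(file.path(config$input_dir, "sap.csv"),
                          file.path(config$input_dir, "sap.json")))
  qc <- lapply(exams, vf_check_reliability)
  keep <- names(exams)[vapply(qc, function(q) q$pass, TRUE)]
  dropped_qc <- setdiff(names(exams), keep)
  exams <- exams[keep]
  if (!length(exams)) stopf("pipeline stage 'qc' failed: no exam passed reliability QC")
  geometry <- stage("geometry-ingest",
                    read_geometry(file.path(config$input_dir, "geometry.csv")))
  grid <- vf_build_grid("right")
  locs <- vf_analysis_locations(grid, config$exclude)
  ## --- per-subject imaging chain
  maps <- list(); profiles <- list(); rois <- list(); globals <- list()
  files <- character(0)
  for (sid in keep) {
    ipath <- file.path(config$input_dir, paste0(sid, "_octa.pgm"))
    ppath <- file.path(config$input_dir, paste0(sid, "_rnfl.csv"))
    if (!file.exists(ipath)) stopf("pipeline stage 'octa-ingest' failed: missing %s", ipath)
    if (!file.exists(ppath)) stopf("pipeline stage 'rnfl-ingest' failed: missing %s", ppath)
    files <- c(files, ipath, ppath)
    img <- stage("octa-ingest", read_octa_image(ipath))
    pm <- stage(paste0("preprocess:", sid),
                preprocess_octa(img, config$window_mm, config$offset,
                                config$scales_mm, config$vesselness_threshold,
                                target_px = config$target_px))
    profiles[[sid]] <- stage("rnfl-ingest", read_rnfl_profile(ppath))
    g <- geometry[geometry$subject_id == sid, ]
    if (!nrow(g)) stopf("pipeline stage 'map' failed: no geometry for subject %s", sid)
    geom <- eye_geometry(fovea_xy = c(g$fovea_x_px, g$fovea_y_px),
                         disc_xy = c(g$disc_x_px, g$disc_y_px),
                         mm_per_px = img$mm_per_px)
    tr <- stage(paste0("map:", sid), fit_to_eye(params, geom))
    rois[[sid]] <- stage(paste0("wedges:", sid),
                         build_all_wedges(locs, tr, params,
                                          dim(pm$perfused), pm$mm_per_px))
    maps[[sid]] <- pm
    gm <- global_metrics(pm, profiles[[sid]])
    globals[[sid]] <- data.frame(subject_id = sid, md = exams[[sid]]$md,
                                 global_cd = gm$global_cd,
                                 global_rnflt = gm$global_rnflt)
  }
  records <- stage("metrics",
                   assemble_records(exams, maps, profiles, rois,
                                    config$include_large_vessel_area))
  fits <- stage("fits", fit_all_locations(records))
  lmaps <- stage("comparisons", location_maps(fits, config$alpha))
  gtab <- do.call(rbind, globals)
  gfit <- stage("global", tryCatch(global_fit(gtab), error = function(e) NULL))
  seg_cd <- stage("segmented-fCD", fit_segmented_lmm(records, "fCD"))
  seg_t <- stage("segmented-fRNFLT", fit_segmented_lmm(records, "fRNFLT"))
  tab3 <- report_table3(seg_t, seg_cd)
  ## --- outputs + provenance
  utils::write.csv(records, file.path(config$out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(lmaps$per_location,
                   file.path(config$out_dir, "location_results.csv"),
                   row.names = FALSE)
  utils::write.csv(tab3, file.path(config$out_dir, "segmented_table.csv"),
                   row.names = FALSE)
  seg_json <- function(s) s[c("predictor_id", "psi", "fvfd_at_bp", "slope_before",
                              "slope_change", "slope_after", "ci_psi",
                              "ci_slope_before", "ci_slope_change", "sigma_b",
                              "sigma_e", "davies_p", "converged", "n_iter", "n")]
  prov$files <- as.list(tools::md5sum(sort(unique(files))))
  prov$params <- config[c("window_mm", "offset", "scales_mm",
                          "vesselness_threshold", "target_px", "alpha",
                          "exclude", "include_large_vessel_area")]
  prov$qc_dropped <- dropped_qc
  summary <- list(summary = lmaps$summary,
                  global_r_p = if (!is.null(gfit)) as.list(gfit$r_p) else NULL,
                  segmented = list(fCD = seg_json(seg_cd), fRNFLT = seg_json(seg_t)),
                  provenance = prov)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(records = records, maps = lmaps, global = gfit,
                 segmented = list(fCD = seg_cd, fRNFLT = seg_t),
                 table3 = tab3, qc = qc, provenance = prov))
}

#' Command-line entry point
#'
#' Thin dispatcher used by `inst/cli/focalsf.R`; subcommands mirror the
#' pipeline stages: `simulate`, `run-all`, `segmented`, `fit`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
focalsf_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: focalsf <command> [options]",
    "  simulate  --out-dir DIR [--n N] [--seed S] [--no-noise]",
    "  run-all   --in DIR [--out-dir DIR] [--seed S]",
    "  fit       --table records.csv [--out-dir DIR]",
    "  segmented --table records.csv --predictor fCD|fRNFLT [--out FILE]",
    sep = "\n")
  if (!length(argv)) { message(usage); return(invisible(1L)) }
  cmd <- argv[1]; argv <- argv[-1]
  opt <- function(name, default = NULL) {
    i <- which(argv == paste0("--", name))
    if (!length(i)) return(default)
    argv[i + 1L]
  }
  flag <- function(name) any(argv == paste0("--", name))
  switch(cmd,
    "simulate" = {
      out <- opt("out-dir"); if (is.null(out)) { message(usage); return(invisible(1L)) }
      n <- as.integer(opt("n", "6")); seed <- as.integer(opt("seed", "1"))
      b <- simulate_cohort(cohort_config(n_subjects = n), seed = seed,
                           noise = !flag("no-noise"))
      write_cohort(b, out)
      message("wrote cohort to ", out)
    },
    "run-all" = {
      ind <- opt("in"); if (is.null(ind)) { message(usage); return(invisible(1L)) }
      cfg <- run_config(ind, out_dir = opt("out-dir", file.path(ind, "results")),
                        seed = as.integer(opt("seed", "1")))
      run_pipeline(cfg)
      message("results in ", cfg$out_dir)
    },
    "fit" = {
      tab <- opt("table"); if (is.null(tab)) { message(usage); return(invisible(1L)) }
      records <- utils::read.csv(tab)
      lm <- location_maps(fit_all_locations(records))
      out <- opt("out-dir", dirname(tab))
      utils::write.csv(lm$per_location, file.path(out, "location_results.csv"),
                       row.names = FALSE)
      message("wrote ", file.path(out, "location_results.csv"))
    },
    "segmented" = {
      tab <- opt("table"); pred <- opt("predictor", "fCD")
      if (is.null(tab)) { message(usage); return(invisible(1L)) }
      f <- fit_segmented_lmm(utils::read.csv(tab), pred)
      print(f)
      outf <- opt("out")
      if (!is.null(outf))
        jsonlite::write_json(unclass(f)[c("predictor_id", "psi", "slope_before",
                                          "slope_change", "ci_psi", "davies_p",
                                          "converged", "n")],
                             outf, auto_unbox = TRUE, digits = NA)
    },
    { message("unknown command '", cmd, "'\n", usage); return(invisible(1L)) })
  invisible(0L)
}
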