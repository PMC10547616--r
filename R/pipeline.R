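# End-to-end orchestration: single-patient quantification (reference stats
# -> thresholds -> mask -> watershed -> component filter -> MTV/TLG) and the
# cohort validation, with CSV/JSON writers used by the command-line front
# end in inst/exec/marrowmtv.

#' Quantify one patient under a set of threshold approaches
#'
#' Runs the three-step automated method for every requested approach:
#' reference-organ statistics are computed once, each approach is resolved
#' to its axial/extremity thresholds, the skeletal mask is thresholded
#' (inclusive >=), watershed-refined, small components are removed, and
#' MTV/TLG are computed. Deterministic end to end.
#'
#' @param study a `patient_study` (or a list with `study` as returned by
#'   [generate_phantom()]).
#' @param approaches list of `threshold_approach` objects (default the six
#'   shipped approaches) or an integer vector of default ids.
#' @param min_volume_ml component removal cutoff in mL (default 1.0).
#' @param connectivity voxel adjacency for watershed and components
#'   (default 18).
#' @param per_label component computation within watershed labels (default)
#'   or on the union mask.
#' @param classify append the visual-read surrogate columns.
#' @return list: `metrics` (one row per approach), `components` (named list
#'   of component tables), `reference_stats`.
#' @export
quantify_patient <- function(study, approaches = default_approaches(),
                             min_volume_ml = 1.0, connectivity = 18L,
                             per_label = TRUE, classify = FALSE) {
  if (!inherits(study, "patient_study") && !is.null(study$study))
    study <- study$study
  stopifnot(inherits(study, "patient_study"))
  if (is.numeric(approaches)) approaches <- default_approaches(approaches)
  if (inherits(approaches, "threshold_approach"))
    approaches <- list(approaches)
  if (!length(approaches)) stop("at least one approach must be selected")
  if (min_volume_ml <= 0) stop("min_volume_ml must be > 0")

  needs_stats <- any(vapply(approaches, function(a)
    a$axial$type == "relative" || a$extremity$type == "relative", TRUE))
  stats <- tryCatch(compute_reference_stats(study), error = function(e) {
    if (needs_stats) stop("reference statistics stage failed: ",
                          conditionMessage(e))
    NULL
  })

  rows <- list(); comps <- list()
  for (a in approaches) {
    id <- paste0("approach_", a$id)
    thr <- resolve_thresholds(a, stats)
    mask <- apply_threshold(study, thr, approach_id = a$id)
    labeling <- flood_assign(study$suv, mask, connectivity = connectivity)
    ref <- filter_components(labeling, seg = study$seg,
                             min_volume_ml = min_volume_ml,
                             per_label = per_label)
    m <- compute_metrics(study$suv, ref$mask, ref$components,
                         seg = study$seg, patient_id = study$patient_id)
    if (classify) {
      cls <- classify_study(study, ref$components, stats = stats)
      m <- cbind(m, cls)
    }
    rows[[id]] <- m
    comps[[id]] <- ref$components
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, components = comps, reference_stats = stats)
}

#' Quantify a patient from files
#'
#' File-level wrapper around [read_study()] + [quantify_patient()], writing
#' the per-patient metrics CSV and per-approach component CSVs.
#'
#' @param pet_path,seg_path,label_dict_path input files (NIfTI, NIfTI, JSON).
#' @param out_dir output directory (created if needed); NULL writes nothing.
#' @param ... passed to [quantify_patient()].
#' @return the [quantify_patient()] result, invisibly when writing.
#' @export
quantify_files <- function(pet_path, seg_path, label_dict_path,
                           out_dir = NULL, ...) {
  study <- read_study(pet_path, seg_path, label_dict_path)
  res <- quantify_patient(study, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    for (nm in names(res$components)) {
      utils::write.csv(res$components[[nm]],
                       file.path(out_dir, paste0("components_", nm, ".csv")),
                       row.names = FALSE)
    }
    return(invisible(res))
  }
  res
}

#' Validate a cohort table and write the report
#'
#' Runs [run_validation()] on a cohort table (or CSV path) and, when
#' `out_dir` is given, writes one CSV per report section plus a combined
#' JSON. Bootstrap randomness is controlled by `seed`.
#'
#' @param cohort a `cohort_table` data.frame or a CSV path.
#' @param out_dir optional output directory.
#' @param approaches approach ids to report.
#' @param boot bootstrap replicates for AUC CIs.
#' @param seed RNG seed for the bootstrap (NULL leaves the RNG alone).
#' @return the report list from [run_validation()].
#' @export
validate_cohort <- function(cohort, out_dir = NULL, approaches = 1:6,
                            boot = 2000L, seed = NULL) {
  if (is.character(cohort)) {
    if (!file.exists(cohort)) stop("cohort CSV not found: ", cohort)
    cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  report <- run_validation(cohort, approaches = approaches, boot = boot)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report)) {
      if (is.null(report[[nm]])) next
      utils::write.csv(report[[nm]],
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(report[!vapply(report, is.null, TRUE)],
                         file.path(out_dir, "report.json"),
                         auto_unbox = FALSE, digits = NA, na = "null")
  }
  report
}
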