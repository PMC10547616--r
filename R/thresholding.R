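# Reference-organ statistics and approach-specific SUV thresholding.
#
# The skeleton is split into axial bones and bones of the extremities, which
# carry different physiological FDG uptake; each approach assigns one SUV
# threshold per group, either relative to a reference organ with low uptake
# variability (liver, gluteus maximus) or as an absolute SUV. Voxels with
# SUV above OR EQUAL to their group threshold are marked as infiltrated.

#' Reference-organ SUV statistics
#'
#' Computes the liver median and maximum and the gluteus-maximus median over
#' the full organ masks. Medians are used for the relative thresholds because
#' they are robust to outlier voxels from small segmentation or alignment
#' inconsistencies; an even voxel count takes the midpoint of the two central
#' order statistics.
#'
#' @param study a `patient_study`.
#' @return object of class `reference_stats`: `liver_median`, `liver_max`,
#'   `gluteus_median`, `n_liver`, `n_gluteus`.
#' @export
compute_reference_stats <- function(study) {
  stopifnot(inherits(study, "patient_study"))
  seg <- study$seg
  liver_ids <- .labels_for_group(seg, "REFERENCE_LIVER")
  glut_ids <- .labels_for_group(seg, "REFERENCE_GLUTEUS")
  liver <- study$suv$values[seg$labels %in% liver_ids]
  glut <- study$suv$values[seg$labels %in% glut_ids]
  if (!length(liver)) stop("empty liver mask: reference statistics undefined")
  if (!length(glut))
    stop("empty gluteus maximus mask: reference statistics undefined")
  structure(list(liver_median = stats::median(liver),
                 liver_max = max(liver),
                 gluteus_median = stats::median(glut),
                 n_liver = length(liver), n_gluteus = length(glut)),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf(
    "<reference_stats> liver median %.3f / max %.3f (n=%d), gluteus median %.3f (n=%d)\n",
    x$liver_median, x$liver_max, x$n_liver, x$gluteus_median, x$n_gluteus))
  invisible(x)
}

.rule <- function(organ = NULL, statistic = NULL, multiplier = NULL,
                  absolute = NULL) {
  if (!is.null(absolute)) {
    if (absolute < 0) stop("absolute threshold must be >= 0")
    return(list(type = "absolute", absolute = as.numeric(absolute)))
  }
  if (!organ %in% c("liver", "gluteus")) stop("organ must be liver or gluteus")
  if (!statistic %in% c("median", "max")) stop("statistic must be median or max")
  if (multiplier <= 0) stop("multiplier must be > 0")
  list(type = "relative", organ = organ, statistic = statistic,
       multiplier = as.numeric(multiplier))
}

#' Declarative SUV threshold approach
#'
#' One rule per bone group: either (reference organ, statistic, multiplier)
#' or an absolute SUV.
#'
#' @param id approach identifier (1-6 for the shipped defaults, or a custom
#'   name).
#' @param axial,extremity rules built with the `organ`/`statistic`/
#'   `multiplier` or `absolute` elements, e.g.
#'   `list(organ = "liver", statistic = "median", multiplier = 1.1)` or
#'   `list(absolute = 2.5)`.
#' @return object of class `threshold_approach`.
#' @export
threshold_approach <- function(id, axial, extremity) {
  ax <- do.call(.rule, axial)
  ex <- do.call(.rule, extremity)
  structure(list(id = id, axial = ax, extremity = ex),
            class = "threshold_approach")
}

#' The six shipped threshold approaches
#'
#' Approach 1: axial = liver median x 1.1, extremities = gluteus median x 4.
#' Approach 2: axial = liver median x 1.5, same extremity rule.
#' Approach 3: axial = liver median x 2, same extremity rule.
#' Approach 4: every bone at SUV >= 2.5.
#' Approach 5: axial >= 2.5, extremities >= 2.0.
#' Approach 6: the liver SUVmax for all bones.
#'
#' @param ids subset of 1:6 to return (default all).
#' @return named list of `threshold_approach` objects.
#' @export
default_approaches <- function(ids = 1:6) {
  if (!length(ids)) stop("at least one approach must be selected")
  glut4 <- list(organ = "gluteus", statistic = "median", multiplier = 4)
  all6 <- list(
    threshold_approach(1L, list(organ = "liver", statistic = "median",
                                multiplier = 1.1), glut4),
    threshold_approach(2L, list(organ = "liver", statistic = "median",
                                multiplier = 1.5), glut4),
    threshold_approach(3L, list(organ = "liver", statistic = "median",
                                multiplier = 2), glut4),
    threshold_approach(4L, list(absolute = 2.5), list(absolute = 2.5)),
    threshold_approach(5L, list(absolute = 2.5), list(absolute = 2.0)),
    threshold_approach(6L, list(organ = "liver", statistic = "max",
                                multiplier = 1),
                       list(organ = "liver", statistic = "max",
                            multiplier = 1))
  )
  idx <- match(ids, 1:6)
  if (anyNA(idx)) stop("approach ids must be in 1:6")
  out <- all6[idx]
  names(out) <- paste0("approach_", ids)
  out
}

#' Read custom approaches from a JSON config
#'
#' Accepts an array of objects with fields `id`, `axial`, `extremity`, each
#' rule either `{"organ": "liver", "statistic": "median", "multiplier": 1.1}`
#' or `{"absolute": 2.5}` — the same grammar as the shipped defaults.
#'
#' @param path JSON file path.
#' @return named list of `threshold_approach` objects.
#' @export
read_approaches <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(cfg, function(a) {
    threshold_approach(a$id, a$axial, a$extremity)
  })
  names(out) <- vapply(out, function(a) paste0("approach_", a$id), "")
  out
}

.resolve_rule <- function(rule, stats) {
  if (rule$type == "absolute") return(rule$absolute)
  key <- paste(rule$organ, rule$statistic, sep = "_")
  val <- switch(key,
                liver_median = stats$liver_median,
                liver_max = stats$liver_max,
                gluteus_median = stats$gluteus_median,
                stop("no reference statistic available for ",
                     rule$organ, " ", rule$statistic))
  if (is.null(val)) stop("missing reference statistic: ", key)
  rule$multiplier * val
}

#' Resolve an approach to numeric thresholds
#'
#' @param approach a `threshold_approach`.
#' @param stats a `reference_stats` (may be omitted for purely absolute
#'   approaches).
#' @return list with numeric elements `axial` and `extremity` (SUV).
#' @export
resolve_thresholds <- function(approach, stats = NULL) {
  stopifnot(inherits(approach, "threshold_approach"))
  needs_stats <- approach$axial$type == "relative" ||
    approach$extremity$type == "relative"
  if (needs_stats && is.null(stats))
    stop("approach ", approach$id, " references a reference organ but no ",
         "reference statistics were supplied")
  list(axial = .resolve_rule(approach$axial, stats),
       extremity = .resolve_rule(approach$extremity, stats))
}

#' Apply resolved thresholds inside the skeletal mask
#'
#' Marks every AXIAL or EXTREMITY voxel whose SUV is above or equal to its
#' group threshold (inclusive comparison). Reference organs, EXCLUDED labels
#' (skull) and background are never marked.
#'
#' @param study a `patient_study`.
#' @param thresholds list with `axial` and `extremity` numeric thresholds,
#'   as returned by [resolve_thresholds()].
#' @param approach_id identifier recorded as provenance.
#' @return object of class `infiltration_mask`: logical 3D `mask`,
#'   `thresholds`, `approach_id`, `spacing`, `voxel_volume_ml`.
#' @export
apply_threshold <- function(study, thresholds, approach_id = NA) {
  stopifnot(inherits(study, "patient_study"))
  if (!is.finite(thresholds$axial) || !is.finite(thresholds$extremity))
    stop("thresholds must be finite")
  seg <- study$seg
  axial_ids <- .labels_for_group(seg, "AXIAL")
  ext_ids <- .labels_for_group(seg, "EXTREMITY")
  suv <- study$suv$values
  m <- (seg$labels %in% axial_ids & suv >= thresholds$axial) |
    (seg$labels %in% ext_ids & suv >= thresholds$extremity)
  structure(list(mask = array(m, dim = dim(suv)),
                 thresholds = list(axial = thresholds$axial,
                                   extremity = thresholds$extremity),
                 approach_id = approach_id,
                 spacing = study$suv$spacing,
                 voxel_volume_ml = study$suv$voxel_volume_ml),
            class = "infiltration_mask")
}

#' @export
print.infiltration_mask <- function(x, ...) {
  cat(sprintf(
    "<infiltration_mask> approach %s: %d voxels (%.2f mL) at t_axial=%.3f, t_extremity=%.3f\n",
    as.character(x$approach_id), sum(x$mask), sum(x$mask) * x$voxel_volume_ml,
    x$thresholds$axial, x$thresholds$extremity))
  invisible(x)
}
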