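# Rule-based surrogate of the visual read: diffuse-uptake grade relative to
# the liver, and the A/B/C patient grouping from focal-lesion count plus
# diffuse grade. Used to label synthetic cohorts and for sanity reporting;
# it does not attempt to replicate human reader judgment.

#' Grade diffuse bone-marrow uptake against the liver
#'
#' negative/mild when below the liver, moderate above 1.1x liver, intense
#' above 2x liver. The printed bins leave (1.0, 1.1] x liver undefined; this
#' implementation resolves that gap to negative/mild (declared, configurable
#' via `moderate_factor`).
#'
#' @param bm_suv bone-marrow reference SUV (iliac / lower-lumbar surrogate).
#' @param liver_suv liver reference SUV (> 0).
#' @param moderate_factor,intense_factor grade multipliers (defaults 1.1, 2).
#' @return one of `"negative_mild"`, `"moderate"`, `"intense"`.
#' @export
grade_diffuse <- function(bm_suv, liver_suv, moderate_factor = 1.1,
                          intense_factor = 2) {
  if (any(liver_suv <= 0)) stop("liver reference SUV must be > 0")
  ifelse(bm_suv > intense_factor * liver_suv, "intense",
         ifelse(bm_suv > moderate_factor * liver_suv, "moderate",
                "negative_mild"))
}

#' Assign the A/B/C visual group
#'
#' Group A: no focal lesions and negative/mild diffuse uptake. Group B: 1-3
#' focal lesions and/or moderate diffuse uptake. Group C: more than 3 focal
#' lesions and/or intense diffuse uptake. Monotone in both inputs.
#'
#' @param n_focal number of focal lesions (>= 0).
#' @param grade diffuse grade from [grade_diffuse()].
#' @return `"A"`, `"B"` or `"C"`.
#' @export
assign_group <- function(n_focal, grade) {
  stopifnot(all(n_focal >= 0))
  grade <- match.arg(grade, c("negative_mild", "moderate", "intense"),
                     several.ok = TRUE)
  ifelse(n_focal > 3 | grade == "intense", "C",
         ifelse(n_focal >= 1 | grade == "moderate", "B", "A"))
}

#' Count surviving lesion components as a focal-lesion surrogate
#'
#' The visual read counts FDG-avid foci; on synthetic data the surviving
#' refined components stand in for that count.
#'
#' @param components component table from [filter_components()].
#' @return integer count.
#' @export
count_focal_surrogate <- function(components) {
  if (is.null(components)) return(0L)
  nrow(components)
}

#' Classify a study with the visual-read surrogate
#'
#' Computes the bone-marrow reference SUV as the median over designated
#' iliac/lumbar labels (default: `pelvic_bones` and `vertebrae`), grades the
#' diffuse uptake against the liver median, and assigns the A/B/C group using
#' the surviving component count under the given approach.
#'
#' @param study a `patient_study`.
#' @param components component table from [filter_components()].
#' @param stats optional precomputed `reference_stats`.
#' @param bm_labels label names used for the bone-marrow reference SUV.
#' @return data.frame row: `bm_reference_suv`, `liver_reference_suv`,
#'   `diffuse_grade`, `n_focal`, `group`.
#' @export
classify_study <- function(study, components, stats = NULL,
                           bm_labels = c("pelvic_bones", "vertebrae")) {
  stopifnot(inherits(study, "patient_study"))
  if (is.null(stats)) stats <- compute_reference_stats(study)
  ids <- .labels_for_name(study$seg, bm_labels)
  vox <- study$suv$values[study$seg$labels %in% ids]
  if (!length(vox))
    stop("no voxels under the bone-marrow reference labels: ",
         paste(bm_labels, collapse = ", "))
  bm <- stats::median(vox)
  g <- grade_diffuse(bm, stats$liver_median)
  nf <- count_focal_surrogate(components)
  data.frame(bm_reference_suv = bm, liver_reference_suv = stats$liver_median,
             diffuse_grade = g, n_focal = nf,
             group = assign_group(nf, g), stringsAsFactors = FALSE)
}
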