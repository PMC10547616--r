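# Core volumetric data types shared by all pipeline stages.
#
# Grids use R's native column-major 3D arrays with 0-based voxel indices in
# all reported coordinates. SUV is stored as provided (body-weight SUV,
# conventionally g/mL); no decay or glucose correction is applied.

#' Bone grouping vocabulary
#'
#' `BONE_GROUPS` are the recognized group names; `AXIAL_BONES` and
#' `EXTREMITY_BONES` list the 7 axial and 10 appendicular bone labels of the
#' 17-bone scheme.
#'
#' @name bone_groups
#' @export
BONE_GROUPS <- c("AXIAL", "EXTREMITY", "REFERENCE_LIVER", "REFERENCE_GLUTEUS",
                 "EXCLUDED", "BACKGROUND")

#' @rdname bone_groups
#' @export
AXIAL_BONES <- c("vertebrae", "scapulae", "clavicles", "sternum", "ribs",
                 "sacrum", "pelvic_bones")

#' @rdname bone_groups
#' @export
EXTREMITY_BONES <- c("humeri", "ulnae", "radii", "hands", "femora",
                     "patellae", "tibiae", "fibulae", "tali", "feet")

#' SUV volume
#'
#' A 3D grid of standardized uptake values with physical voxel spacing and a
#' voxel-to-world affine sufficient to round-trip NIfTI.
#'
#' @param values 3D numeric array of SUV; all finite and >= 0.
#' @param spacing per-axis voxel edge length in mm (> 0, anisotropy allowed).
#' @param affine optional 4x4 voxel-to-world matrix (default diagonal from
#'   spacing).
#' @return an object of class `suv_volume` with fields `values`, `spacing`,
#'   `affine` and `voxel_volume_ml` (product of spacings / 1000).
#' @export
suv_volume <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(values)) != 3L) stop("SUV grid must be 3D")
  if (!all(is.finite(values))) stop("SUV values must all be finite")
  if (any(values < 0)) stop("SUV values must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive lengths (mm)")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(values = values, spacing = spacing, affine = affine,
                 voxel_volume_ml = prod(spacing) / 1000),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("<suv_volume> ", paste(dim(x$values), collapse = "x"),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm (", signif(x$voxel_volume_ml, 4), " mL/voxel), SUV range [",
      signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n",
      sep = "")
  invisible(x)
}

#' Segmentation map
#'
#' A co-registered integer label grid plus a label dictionary and the bone
#' grouping scheme used for thresholding. Every nonzero label in the grid must
#' appear in the dictionary; a skull label, if present, must be in the
#' EXCLUDED group (it is never thresholded, to avoid spill-in of the intense
#' physiological brain uptake).
#'
#' @param labels 3D integer array (0 = background).
#' @param label_dict data.frame with columns `id`, `name`, `group`; `group`
#'   must be one of AXIAL, EXTREMITY, REFERENCE_LIVER, REFERENCE_GLUTEUS,
#'   EXCLUDED, BACKGROUND.
#' @param spacing voxel spacing in mm.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return an object of class `segmentation_map`.
#' @export
segmentation_map <- function(labels, label_dict, spacing = c(1, 1, 1),
                             affine = NULL) {
  if (length(dim(labels)) != 3L) stop("label grid must be 3D")
  storage.mode(labels) <- "integer"
  label_dict <- as.data.frame(label_dict)
  req <- c("id", "name", "group")
  if (!all(req %in% names(label_dict)))
    stop("label dictionary needs columns: ", paste(req, collapse = ", "))
  bad_grp <- setdiff(unique(label_dict$group), BONE_GROUPS)
  if (length(bad_grp))
    stop("unknown bone group(s): ", paste(bad_grp, collapse = ", "))
  if (anyDuplicated(label_dict$id)) stop("duplicate label ids in dictionary")
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, label_dict$id)
  if (length(missing))
    stop("label id(s) in grid absent from dictionary: ",
         paste(missing, collapse = ", "))
  skull <- label_dict$name == "skull"
  if (any(skull) && any(label_dict$group[skull] != "EXCLUDED"))
    stop("a skull label must be in the EXCLUDED group")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive lengths (mm)")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(labels = labels, label_dict = label_dict, spacing = spacing,
                 affine = affine),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  present <- setdiff(unique(as.vector(x$labels)), 0L)
  cat("<segmentation_map> ", paste(dim(x$labels), collapse = "x"),
      " voxels, ", length(present), " labels present (",
      nrow(x$label_dict), " in dictionary)\n", sep = "")
  invisible(x)
}

#' Per-voxel bone-group grid
#'
#' Maps every voxel of a segmentation to exactly one group (BACKGROUND for
#' label 0), as a character array aligned with the label grid.
#'
#' @param seg a `segmentation_map`.
#' @return character 3D array of group names.
#' @export
group_grid <- function(seg) {
  lut <- c("BACKGROUND", rep(NA_character_, max(c(seg$label_dict$id, 0L))))
  lut[seg$label_dict$id + 1L] <- seg$label_dict$group
  g <- lut[as.vector(seg$labels) + 1L]
  array(g, dim = dim(seg$labels))
}

.labels_for_group <- function(seg, group) {
  seg$label_dict$id[seg$label_dict$group %in% group]
}

.labels_for_name <- function(seg, name) {
  seg$label_dict$id[seg$label_dict$name %in% name]
}

#' Bundle an SUV volume and its segmentation
#'
#' @param suv a `suv_volume`.
#' @param seg a `segmentation_map`, geometrically aligned with `suv`.
#' @param patient_id identifier string.
#' @return an object of class `patient_study`.
#' @export
patient_study <- function(suv, seg, patient_id = "patient") {
  stopifnot(inherits(suv, "suv_volume"), inherits(seg, "segmentation_map"))
  if (!identical(dim(suv$values), dim(seg$labels)))
    stop("SUV and segmentation grids differ in shape")
  if (max(abs(suv$spacing - seg$spacing)) > 1e-6)
    stop("SUV and segmentation grids differ in spacing")
  structure(list(suv = suv, seg = seg, patient_id = patient_id),
            class = "patient_study")
}

#' Default skeletal label dictionary
#'
#' The 17-bone scheme (7 axial + 10 extremity bone labels) plus liver,
#' gluteus maximus and an optional skull label (EXCLUDED).
#'
#' @return data.frame with columns `id`, `name`, `group`.
#' @export
default_label_dict <- function() {
  data.frame(
    id = seq_len(20L),
    name = c(AXIAL_BONES, EXTREMITY_BONES, "liver", "gluteus_maximus", "skull"),
    group = c(rep("AXIAL", 7L), rep("EXTREMITY", 10L),
              "REFERENCE_LIVER", "REFERENCE_GLUTEUS", "EXCLUDED"),
    stringsAsFactors = FALSE
  )
}

#' Read a label dictionary from JSON
#'
#' Expects an array of objects `{"id": int, "name": str, "group": str}`.
#'
#' @param path JSON file path.
#' @return data.frame with columns `id`, `name`, `group`.
#' @export
read_label_dict <- function(path) {
  if (!file.exists(path)) stop("label dictionary not found: ", path)
  d <- jsonlite::fromJSON(path)
  d <- as.data.frame(d)
  if (!all(c("id", "name", "group") %in% names(d)))
    stop("label dictionary JSON needs fields id, name, group")
  d$id <- as.integer(d$id)
  d
}

#' Write a label dictionary to JSON
#' @param dict data.frame with columns `id`, `name`, `group`.
#' @param path output path.
#' @export
write_label_dict <- function(dict, path) {
  jsonlite::write_json(dict[, c("id", "name", "group")], path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a PET study from NIfTI files
#'
#' Reads the SUV PET volume, the skeletal label map and the JSON label
#' dictionary, and returns an aligned `patient_study`. If the label grid
#' differs in geometry from the PET grid it is transferred to the PET grid by
#' nearest-neighbor resampling through the header affines (labels are
#' categorical; interpolation would invent anatomy).
#'
#' @param pet_path NIfTI path of the SUV volume.
#' @param seg_path NIfTI path of the integer label volume.
#' @param label_dict_path JSON label dictionary path.
#' @param patient_id identifier (default: PET file stem).
#' @param require_reference error when liver or gluteus labels are absent
#'   from the dictionary (they are needed by the reference-organ approaches);
#'   default TRUE.
#' @return a `patient_study`.
#' @export
read_study <- function(pet_path, seg_path, label_dict_path,
                       patient_id = NULL, require_reference = TRUE) {
  pet <- read_nifti(pet_path)
  segr <- read_nifti(seg_path)
  dict <- read_label_dict(label_dict_path)
  if (require_reference) {
    for (grp in c("REFERENCE_LIVER", "REFERENCE_GLUTEUS")) {
      if (!any(dict$group == grp))
        stop("label dictionary lacks the required reference organ group: ", grp)
    }
  }
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(pet_path))
  suv <- suv_volume(pet$data, pet$spacing, pet$affine)
  seg <- segmentation_map(segr$data, dict, segr$spacing, segr$affine)
  same_geom <- identical(dim(suv$values), dim(seg$labels)) &&
    max(abs(suv$spacing - seg$spacing)) <= 1e-6
  if (!same_geom)
    seg <- resample_labels(seg, target_shape = dim(suv$values),
                           target_spacing = suv$spacing,
                           target_affine = suv$affine)
  patient_study(suv, seg, patient_id)
}

#' Nearest-neighbor label transfer onto a target grid
#'
#' Transfers a categorical label grid onto a new geometry through the two
#' voxel-to-world affines: each target voxel center is mapped to world space,
#' pulled back into the source grid, and assigned the label of the nearest
#' source voxel (0 outside the source field of view). The output label set is
#' always a subset of the input label set, and the operation is the identity
#' on matching geometry.
#'
#' @param seg a `segmentation_map`.
#' @param target_shape integer length-3 grid shape.
#' @param target_spacing numeric length-3 spacing (mm).
#' @param target_affine optional 4x4 target voxel-to-world affine.
#' @return a `segmentation_map` on the target geometry.
#' @export
resample_labels <- function(seg, target_shape, target_spacing,
                            target_affine = NULL) {
  stopifnot(inherits(seg, "segmentation_map"))
  target_shape <- as.integer(target_shape)
  if (is.null(target_affine)) target_affine <- diag(c(target_spacing, 1))
  if (identical(target_shape, dim(seg$labels)) &&
      max(abs(target_affine - seg$affine)) <= 1e-9) {
    out <- seg
    out$spacing <- as.numeric(target_spacing)
    return(out)
  }
  src_inv <- tryCatch(solve(seg$affine),
                      error = function(e) stop("non-invertible source affine"))
  m <- src_inv %*% target_affine            # target voxel -> source voxel
  nx <- target_shape[1]; ny <- target_shape[2]; nz <- target_shape[3]
  ix <- rep.int(seq_len(nx) - 1L, ny * nz)
  iy <- rep.int(rep(seq_len(ny) - 1L, each = nx), nz)
  iz <- rep(seq_len(nz) - 1L, each = nx * ny)
  sx <- round(m[1, 1] * ix + m[1, 2] * iy + m[1, 3] * iz + m[1, 4])
  sy <- round(m[2, 1] * ix + m[2, 2] * iy + m[2, 3] * iz + m[2, 4])
  sz <- round(m[3, 1] * ix + m[3, 2] * iy + m[3, 3] * iz + m[3, 4])
  d <- dim(seg$labels)
  inside <- sx >= 0 & sx < d[1] & sy >= 0 & sy < d[2] & sz >= 0 & sz < d[3]
  out <- integer(nx * ny * nz)
  lin <- sx[inside] + d[1] * (sy[inside] + d[2] * sz[inside]) + 1
  out[inside] <- seg$labels[lin]
  segmentation_map(array(out, dim = target_shape), seg$label_dict,
                   as.numeric(target_spacing), target_affine)
}

#' Convert an activity concentration to body-weight SUV
#'
#' SUV = activity concentration (Bq/mL) x body weight (g) / injected dose (Bq).
#' Convenience for PET data not yet expressed in SUV units.
#'
#' @param activity_conc_bq_ml activity concentration, Bq/mL (> 0).
#' @param injected_dose_bq injected dose, Bq (> 0).
#' @param body_weight_g body weight, g (> 0).
#' @return SUV (dimensionless, conventionally g/mL).
#' @export
suv_from_activity <- function(activity_conc_bq_ml, injected_dose_bq,
                              body_weight_g) {
  if (any(activity_conc_bq_ml <= 0) || injected_dose_bq <= 0 ||
      body_weight_g <= 0)
    stop("all inputs to suv_from_activity must be > 0")
  activity_conc_bq_ml * body_weight_g / injected_dose_bq
}

#' Write an SUV volume or label grid to NIfTI
#'
#' @param x a `suv_volume` or `segmentation_map`.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "suv_volume"))
    write_nifti(x$values, path, x$spacing, x$affine, datatype = 64L)
  else if (inherits(x, "segmentation_map"))
    write_nifti(x$labels, path, x$spacing, x$affine, datatype = 8L)
  else stop("x must be a suv_volume or segmentation_map")
  invisible(path)
}
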