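# Whole-body and per-group MTV / TLG from the refined infiltration mask.

#' Compute MTV and TLG for a refined mask
#'
#' MTV (mL) is the physical volume of the refined mask; TLG (g) is
#' SUVmean x MTV over the same voxels (equivalently the SUV integral times
#' the voxel volume), treating SUV as g/mL so that SUV x mL carries grams.
#' An empty mask legitimately yields MTV = TLG = 0 (strict thresholds can
#' segment nothing).
#'
#' @param suv a `suv_volume`.
#' @param refined_mask a refined `infiltration_mask` from
#'   [filter_components()].
#' @param components the surviving-component table from
#'   [filter_components()] (optional; used for the component count).
#' @param seg optional `segmentation_map` for the axial/extremity sub-totals.
#' @param patient_id identifier carried into the record.
#' @return object of class `patient_metrics` (also a one-row data.frame):
#'   `patient_id`, `approach_id`, `mtv_ml`, `tlg_g`, `suv_mean_lesional`,
#'   `n_components`, `axial_mtv_ml`, `extremity_mtv_ml`, `axial_tlg_g`,
#'   `extremity_tlg_g`, `t_axial`, `t_extremity`.
#' @export
compute_metrics <- function(suv, refined_mask, components = NULL, seg = NULL,
                            patient_id = "patient") {
  stopifnot(inherits(suv, "suv_volume"),
            inherits(refined_mask, "infiltration_mask"))
  if (!identical(dim(suv$values), dim(refined_mask$mask)))
    stop("refined mask and SUV volume differ in shape")
  vox_ml <- suv$voxel_volume_ml
  idx <- which(refined_mask$mask)
  vals <- suv$values[idx]
  mtv <- length(idx) * vox_ml
  suv_mean <- if (length(idx)) mean(vals) else NA_real_
  tlg <- if (length(idx)) suv_mean * mtv else 0

  ax_mtv <- ex_mtv <- ax_tlg <- ex_tlg <- NA_real_
  if (!is.null(seg)) {
    lab <- seg$labels[idx]
    ax <- lab %in% .labels_for_group(seg, "AXIAL")
    ex <- lab %in% .labels_for_group(seg, "EXTREMITY")
    ax_mtv <- sum(ax) * vox_ml
    ex_mtv <- sum(ex) * vox_ml
    ax_tlg <- sum(vals[ax]) * vox_ml
    ex_tlg <- sum(vals[ex]) * vox_ml
  }
  out <- data.frame(
    patient_id = patient_id,
    approach_id = as.character(refined_mask$approach_id),
    mtv_ml = mtv, tlg_g = tlg,
    suv_mean_lesional = suv_mean,
    n_components = if (is.null(components)) NA_integer_ else nrow(components),
    axial_mtv_ml = ax_mtv, extremity_mtv_ml = ex_mtv,
    axial_tlg_g = ax_tlg, extremity_tlg_g = ex_tlg,
    t_axial = refined_mask$thresholds$axial,
    t_extremity = refined_mask$thresholds$extremity,
    stringsAsFactors = FALSE
  )
  class(out) <- c("patient_metrics", class(out))
  out
}
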