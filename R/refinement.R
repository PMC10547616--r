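# Spill-over refinement: Meyer-flooding watershed over the infiltration mask,
# then removal of small 18-connected components.
#
# Tracer signal from adjacent hot tissue can bleed into the bone mask because
# of the limited PET spatial resolution. The refinement assigns every mask
# voxel to the basin of its local SUV maximum and drops basins (18-connected
# components) smaller than 1 mL, which removes thin spill-over rinds that do
# not belong to a substantial focal or diffuse uptake region.
#
# Determinism contract (Meyer's flooding leaves plateau and tie policy open;
# these rules pin both down so labelings are reproducible and testable):
#   - regional maxima: connected plateaus (equal SUV, mask-internal
#     adjacency) none of whose voxels has a strictly greater neighbor in the
#     mask; each regional maximum is ONE region, seeded at its
#     lexicographically (z,y,x) smallest voxel — so equal-height maxima
#     joined by a plateau merge into a single region;
#   - strict ascent: a voxel with a strictly greater neighbor is claimed by
#     its highest-SUV strictly greater neighbor, ties broken by
#     lexicographically (z,y,x) smallest voxel — descending-SUV claim order;
#   - draining plateaus: a plateau that does have a strictly greater
#     neighbor somewhere routes every member without one through the
#     plateau's lexicographically smallest exit (exit = member with a
#     strictly greater neighbor).
# Every mask voxel is assigned (no watershed-line voxels), flooding never
# leaves the mask, and every region is connected by construction (each voxel
# is adjacent to its claimant).

# Voxel adjacency offsets. 18-connectivity (the default everywhere) means
# faces + edges (at most 2 nonzero offsets), not corners; 6 is faces only,
# 26 the full cube.
.offsets <- function(connectivity = 18L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nz <- rowSums(g != 0)
  max_nz <- switch(as.character(connectivity), `6` = 1L, `18` = 2L,
                   `26` = 3L, stop("connectivity must be 6, 18 or 26"))
  as.matrix(g[nz >= 1L & nz <= max_nz, ])
}

# Neighbor matrix: for each of n mask voxels (mask order), the mask-order
# position of each neighbor inside the mask, 0 when absent.
.neighbor_matrix <- function(mask_lin, dims, connectivity = 18L) {
  off <- .offsets(connectivity)
  n <- length(mask_lin)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  lin0 <- mask_lin - 1L
  ix <- lin0 %% nx
  iy <- (lin0 %/% nx) %% ny
  iz <- lin0 %/% (nx * ny)
  pos <- integer(prod(dims))
  pos[mask_lin] <- seq_len(n)
  nb <- matrix(0L, nrow = n, ncol = nrow(off))
  for (j in seq_len(nrow(off))) {
    dx <- off[j, 1]; dy <- off[j, 2]; dz <- off[j, 3]
    jx <- ix + dx; jy <- iy + dy; jz <- iz + dz
    ok <- jx >= 0L & jx < nx & jy >= 0L & jy < ny & jz >= 0L & jz < nz
    tgt <- jx[ok] + nx * (jy[ok] + ny * jz[ok]) + 1L
    v <- integer(n)
    v[ok] <- pos[tgt]
    nb[, j] <- v
  }
  list(nb = nb, ix = ix, iy = iy, iz = iz)
}

#' Assign mask voxels to their local maxima (Meyer flooding)
#'
#' Partitions the infiltration mask into watershed regions of the SUV
#' landscape restricted to the mask: local maxima (mask voxels with no
#' strictly greater 18-neighbor inside the mask) seed regions, and the
#' remaining voxels are claimed in descending-SUV order by their
#' highest-SUV already-claimed neighbor. Ties in SUV are broken in
#' lexicographic (z, y, x) voxel order, which makes the labeling fully
#' deterministic; an equal-height plateau merges into one region seeded at
#' its lexicographically smallest maximum. Every voxel is assigned (no
#' watershed-line voxels), and flooding never crosses mask boundaries.
#'
#' @param suv a `suv_volume`.
#' @param mask an `infiltration_mask` aligned with `suv`.
#' @param connectivity voxel adjacency (6, 18 or 26; default 18, the
#'   connectivity also used for component filtering).
#' @return object of class `region_labeling`: `region` (3D integer array,
#'   0 outside the mask), `n_regions`, `seeds` (data.frame of 0-based seed
#'   voxel coordinates and seed SUV per region), plus internal fields used
#'   by [filter_components()]. An empty mask yields 0 regions.
#' @export
flood_assign <- function(suv, mask, connectivity = 18L) {
  stopifnot(inherits(suv, "suv_volume"), inherits(mask, "infiltration_mask"))
  dims <- dim(suv$values)
  if (!identical(dims, dim(mask$mask)))
    stop("mask and SUV volume differ in shape")
  mask_lin <- which(mask$mask)
  n <- length(mask_lin)
  region <- array(0L, dim = dims)
  if (n == 0L) {
    return(structure(list(region = region, n_regions = 0L,
                          seeds = data.frame(region = integer(), x = integer(),
                                             y = integer(), z = integer(),
                                             suv = numeric()),
                          mask_lin = mask_lin, lab = integer(),
                          suv_vals = numeric(), nb = NULL, dims = dims,
                          spacing = mask$spacing,
                          voxel_volume_ml = mask$voxel_volume_ml,
                          thresholds = mask$thresholds,
                          approach_id = mask$approach_id),
                     class = "region_labeling"))
  }
  geom <- .neighbor_matrix(mask_lin, dims, connectivity)
  nb <- geom$nb
  v_suv <- suv$values[mask_lin]

  # strict total order: rank 1 = highest SUV, ties lexicographic (z,y,x)
  ord <- order(-v_suv, geom$iz, geom$iy, geom$ix)
  r <- integer(n)
  r[ord] <- seq_len(n)

  # strict-ascent claimant: strictly greater neighbor of minimal rank
  # (= highest SUV, lexicographic tie-break), 0 when none exists
  INF <- n + 1L
  best <- rep.int(INF, n)
  parent <- integer(n)
  for (j in seq_len(ncol(nb))) {
    nbj <- nb[, j]
    has <- nbj > 0L
    rj <- rep.int(INF, n)
    greater <- has
    greater[has] <- v_suv[nbj[has]] > v_suv[has]
    rj[greater] <- r[nbj[greater]]
    upd <- rj < best
    best[upd] <- rj[upd]
    parent[upd] <- nbj[upd]
  }
  has_greater <- parent > 0L

  # plateaus: connected components of equal SUV inside the mask
  comp <- .components(nb, v_suv)
  ncomp <- max(comp)
  comp_drains <- logical(ncomp)
  comp_drains[comp[has_greater]] <- TRUE

  # lexicographic representative per plateau: min-rank member (seed of a
  # regional maximum) and min-rank exit (router of a draining plateau)
  min_member <- integer(ncomp)
  fs <- !duplicated(comp[ord])
  min_member[comp[ord[fs]]] <- ord[fs]
  exit_of <- integer(ncomp)
  ex <- which(has_greater)
  ex <- ex[order(r[ex])]
  fs <- !duplicated(comp[ex])
  exit_of[comp[ex[fs]]] <- ex[fs]

  # regional maxima become regions, in descending seed-SUV order
  max_comps <- which(!comp_drains)
  max_comps <- max_comps[order(r[min_member[max_comps]])]
  n_regions <- length(max_comps)
  region_of_comp <- integer(ncomp)
  region_of_comp[max_comps] <- seq_len(n_regions)
  lab <- integer(n)
  is_max_comp <- !comp_drains
  lab[is_max_comp[comp]] <- region_of_comp[comp[is_max_comp[comp]]]

  # flood: descending SUV, strict climbers of a given SUV before plateau
  # members routed through an exit, then lexicographic
  ord2 <- order(-v_suv, !has_greater, geom$iz, geom$iy, geom$ix)
  for (i in ord2) {
    if (lab[i] > 0L) next
    lab[i] <- if (has_greater[i]) lab[parent[i]] else lab[exit_of[comp[i]]]
  }
  region[mask_lin] <- lab
  seeds <- min_member[max_comps]
  seed_df <- data.frame(region = seq_len(n_regions),
                        x = geom$ix[seeds], y = geom$iy[seeds],
                        z = geom$iz[seeds], suv = v_suv[seeds])
  structure(list(region = region, n_regions = n_regions, seeds = seed_df,
                 mask_lin = mask_lin, lab = lab, suv_vals = v_suv, nb = nb,
                 coords = data.frame(x = geom$ix, y = geom$iy, z = geom$iz),
                 dims = dims, spacing = mask$spacing,
                 voxel_volume_ml = mask$voxel_volume_ml,
                 thresholds = mask$thresholds,
                 approach_id = mask$approach_id),
            class = "region_labeling")
}

#' @export
print.region_labeling <- function(x, ...) {
  cat("<region_labeling> ", length(x$mask_lin), " mask voxels in ",
      x$n_regions, " watershed regions\n", sep = "")
  invisible(x)
}

# 18-connected components of mask voxels sharing a field value, by BFS on the
# precomputed neighbor matrix. Returns a component id per mask voxel.
.components <- function(nb, field) {
  n <- length(field)
  comp <- integer(n)
  ncomp <- 0L
  queue <- integer(n)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    comp[s] <- ncomp
    queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      nbs <- nb[v, ]
      nbs <- nbs[nbs > 0L]
      nbs <- nbs[comp[nbs] == 0L & field[nbs] == field[v]]
      if (length(nbs)) {
        comp[nbs] <- ncomp
        queue[(tail + 1L):(tail + length(nbs))] <- nbs
        tail <- tail + length(nbs)
      }
    }
  }
  comp
}

#' Remove small components and summarize the survivors
#'
#' Computes 18-connected components among voxels sharing one watershed label
#' (set `per_label = FALSE` to use the union mask instead), removes every
#' component whose physical volume is strictly below `min_volume_ml` (the
#' default 1 mL; a component of exactly 1 mL survives), and returns the
#' refined mask together with one record per surviving lesion component,
#' sorted by descending volume.
#'
#' @param labeling a `region_labeling` from [flood_assign()].
#' @param seg optional `segmentation_map` for bone-group attribution of each
#'   component.
#' @param min_volume_ml removal cutoff in mL (default 1.0).
#' @param per_label compute components within each watershed label (default,
#'   the documented reading) or on the union mask.
#' @return list with `mask` (refined `infiltration_mask`) and `components`
#'   (data.frame: id, voxel_count, volume_ml, suv_mean, suv_max, seed_x/y/z
#'   0-based voxel coordinates of the component maximum, groups).
#' @export
filter_components <- function(labeling, seg = NULL, min_volume_ml = 1.0,
                              per_label = TRUE) {
  stopifnot(inherits(labeling, "region_labeling"))
  if (min_volume_ml <= 0) stop("min_volume_ml must be > 0")
  vox_ml <- labeling$voxel_volume_ml
  if (!is.finite(vox_ml) || vox_ml <= 0) stop("non-positive voxel volume")
  n <- length(labeling$mask_lin)
  empty <- data.frame(id = integer(), voxel_count = integer(),
                      volume_ml = numeric(), suv_mean = numeric(),
                      suv_max = numeric(), seed_x = integer(),
                      seed_y = integer(), seed_z = integer(),
                      groups = character())
  refined <- structure(list(mask = array(FALSE, dim = labeling$dims),
                            thresholds = labeling$thresholds,
                            approach_id = labeling$approach_id,
                            spacing = labeling$spacing,
                            voxel_volume_ml = vox_ml),
                       class = "infiltration_mask")
  if (n == 0L) return(list(mask = refined, components = empty))

  field <- if (per_label) labeling$lab else rep.int(1L, n)
  comp <- .components(labeling$nb, field)
  sizes <- tabulate(comp)
  vol <- sizes * vox_ml
  keep_comp <- which(vol >= min_volume_ml)
  keep_vox <- comp %in% keep_comp
  refined$mask[labeling$mask_lin[keep_vox]] <- TRUE
  if (!length(keep_comp)) return(list(mask = refined, components = empty))

  suv <- labeling$suv_vals
  cx <- labeling$coords$x; cy <- labeling$coords$y; cz <- labeling$coords$z
  grp_of <- NULL
  if (!is.null(seg)) {
    lut <- c("BACKGROUND", rep(NA_character_, max(c(seg$label_dict$id, 0L))))
    lut[seg$label_dict$id + 1L] <- seg$label_dict$group
    grp_of <- lut[seg$labels[labeling$mask_lin] + 1L]
  }
  recs <- lapply(keep_comp, function(k) {
    sel <- which(comp == k)
    # component maximum, lexicographic (z,y,x) tie-break
    o <- sel[order(-suv[sel], cz[sel], cy[sel], cx[sel])][1L]
    data.frame(voxel_count = length(sel),
               volume_ml = length(sel) * vox_ml,
               suv_mean = mean(suv[sel]), suv_max = suv[o],
               seed_x = cx[o], seed_y = cy[o], seed_z = cz[o],
               groups = if (is.null(grp_of)) NA_character_ else
                 paste(sort(unique(grp_of[sel])), collapse = "+"))
  })
  out <- do.call(rbind, recs)
  out <- out[order(-out$volume_ml, out$seed_z, out$seed_y, out$seed_x), ]
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  list(mask = refined, components = out)
}
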