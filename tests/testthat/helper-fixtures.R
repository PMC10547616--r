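# Shared fixtures: a tiny hand-laid study, a small randomized phantom spec,
# and independent oracles (steepest-ascent watershed, pairwise AUC,
# label-sequence JT enumeration) used by the dual-route tests.

# A 6x6x6 study with liver, gluteus, one axial bone (vertebrae), one
# extremity bone (femora) and an EXCLUDED skull corner. SUV defaults to the
# per-organ base values; tests overwrite voxels as needed.
tiny_study <- function(suv = NULL, spacing = c(1, 1, 1)) {
  d <- c(6L, 6L, 6L)
  lab <- array(0L, dim = d)
  dict <- default_label_dict()
  id <- function(nm) dict$id[dict$name == nm]
  lab[1:2, 1:2, 1:2] <- id("liver")
  lab[5:6, 1:2, 1:2] <- id("gluteus_maximus")
  lab[3:4, 3:4, 1:6] <- id("vertebrae")
  lab[1:2, 5:6, 1:6] <- id("femora")
  lab[5:6, 5:6, 5:6] <- id("skull")
  if (is.null(suv)) {
    suv <- array(0.4, dim = d)
    suv[lab == id("liver")] <- 2.0
    suv[lab == id("gluteus_maximus")] <- 0.5
    suv[lab == id("vertebrae")] <- 1.2
    suv[lab == id("femora")] <- 0.7
    suv[lab == id("skull")] <- 4.0
  }
  patient_study(suv_volume(suv, spacing),
                segmentation_map(lab, dict, spacing),
                patient_id = "tiny")
}

tiny_ids <- function() {
  dict <- default_label_dict()
  setNames(dict$id, dict$name)
}

# small fast phantom for suite-level checks
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(32L, 32L, 64L), spacing = c(4, 4, 4),
               seed = seed, ...)
}

# randomized small phantom: uptake levels and lesion peaks drawn per seed
random_phantom_spec <- function(seed, noise_sd = 0.08, psf_sigma_mm = 3) {
  set.seed(seed + 90000L)
  les <- default_lesions()
  les$peak_suv <- runif(4, 3.0, 8.0)
  les$radius_mm <- runif(4, 9, 13)
  phantom_spec(shape = c(32L, 32L, 64L), spacing = c(4, 4, 4),
               diffuse_axial = runif(1, 0.8, 1.3),
               diffuse_extremity = runif(1, 0.5, 0.8),
               liver_suv = runif(1, 1.8, 2.4),
               gluteus_suv = runif(1, 0.4, 0.6),
               lesions = les, psf_sigma_mm = psf_sigma_mm,
               noise_sd = noise_sd, seed = seed)
}

# ---- independent oracles ---------------------------------------------------

# steepest-ascent watershed oracle, per mask voxel and with the package's
# declared tie rules, but implemented by direct array recursion (no shared
# code with flood_assign()):
#   - a voxel with a strictly greater in-mask neighbor climbs to the
#     strictly greater neighbor of maximal SUV, lexicographic (z,y,x)
#     tie-break, and recurses;
#   - otherwise the voxel's equal-SUV plateau is explored exhaustively;
#     a plateau with no strictly greater neighbor anywhere is a regional
#     maximum whose lexicographically smallest member names the region;
#     a draining plateau continues the climb from its lexicographically
#     smallest exit (member owning a strictly greater neighbor).
oracle_flood <- function(suv, mask) {
  d <- dim(suv)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[rowSums(off != 0) >= 1 & rowSums(off != 0) <= 2, ]
  lex_lt <- function(a, b) {         # (z,y,x) lexicographic, 1-based coords
    if (a[3] != b[3]) return(a[3] < b[3])
    if (a[2] != b[2]) return(a[2] < b[2])
    a[1] < b[1]
  }
  in_mask_neighbors <- function(p) {
    out <- list()
    for (r in seq_len(nrow(off))) {
      q <- p + as.numeric(off[r, ])
      if (any(q < 1) || any(q > d)) next
      if (mask[q[1], q[2], q[3]]) out[[length(out) + 1L]] <- q
    }
    out
  }
  strict_step <- function(p) {
    v <- suv[p[1], p[2], p[3]]
    best <- NULL; best_suv <- -Inf
    for (q in in_mask_neighbors(p)) {
      w <- suv[q[1], q[2], q[3]]
      if (w <= v) next
      if (w > best_suv || (w == best_suv && lex_lt(q, best))) {
        best <- q; best_suv <- w
      }
    }
    best
  }
  plateau_of <- function(p) {        # exhaustive equal-SUV flood fill
    v <- suv[p[1], p[2], p[3]]
    seen <- list(p); frontier <- list(p)
    key <- function(q) paste(q, collapse = ",")
    seen_keys <- key(p)
    while (length(frontier)) {
      nxt <- list()
      for (q in frontier) for (w in in_mask_neighbors(q)) {
        if (suv[w[1], w[2], w[3]] != v) next
        if (key(w) %in% seen_keys) next
        seen_keys <- c(seen_keys, key(w))
        seen[[length(seen) + 1L]] <- w
        nxt[[length(nxt) + 1L]] <- w
      }
      frontier <- nxt
    }
    seen
  }
  lex_min <- function(pts) {
    best <- pts[[1]]
    for (q in pts[-1]) if (lex_lt(q, best)) best <- q
    best
  }
  res <- array(0L, dim = d)
  for (k in which(mask)) {
    p <- arrayInd(k, d)[1, ]
    repeat {
      nxt <- strict_step(p)
      if (!is.null(nxt)) { p <- nxt; next }
      plateau <- plateau_of(p)
      exits <- Filter(function(q) !is.null(strict_step(q)), plateau)
      if (!length(exits)) { p <- lex_min(plateau); break }   # regional max
      p <- strict_step(lex_min(exits))
    }
    res[k] <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))  # seed id
  }
  res
}

# canonical form of a labeling: region id = smallest linear index it contains
canonical_regions <- function(lab_arr) {
  idx <- which(lab_arr != 0)
  split_min <- tapply(idx, lab_arr[idx], min)
  out <- array(0L, dim = dim(lab_arr))
  out[idx] <- as.integer(split_min[as.character(lab_arr[idx])])
  out
}

# AUC by exhaustive pair counting: wins + half ties over all pos/neg pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# JT statistic by direct pair counting (no ranks)
oracle_jt_stat <- function(groups) {
  k <- length(groups); jt <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    for (u in groups[[i]]) for (v in groups[[j]])
      jt <- jt + (u < v) + 0.5 * (u == v)
  jt
}

# exact JT null distribution by enumerating all distinct label sequences
# (multiset permutations generated lexicographically), one JT per sequence
oracle_jt_dist <- function(pooled, sizes) {
  labels0 <- rep(seq_along(sizes), sizes)
  seqs <- list()
  gen <- function(prefix, remaining) {
    if (!length(remaining)) {
      seqs[[length(seqs) + 1L]] <<- prefix
      return(invisible())
    }
    for (g in unique(remaining)) {
      gen(c(prefix, g), remaining[-match(g, remaining)])
    }
  }
  gen(integer(0), sort(labels0))
  vapply(seqs, function(s) {
    oracle_jt_stat(split(pooled, s))
  }, 1.0)
}
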