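# Reference statistics, approach resolution, mask application

test_that("reference medians follow the order-statistic midpoint rule", {
  st <- tiny_study()
  ids <- tiny_ids()
  liver_idx <- which(st$seg$labels == ids[["liver"]])
  # odd count: plant {1.8, 2.0, 2.2} + filler at 2.0 is avoided by using
  # a dedicated small study where the liver has exactly 3 voxels
  d <- c(4L, 4L, 4L)
  lab <- array(0L, dim = d)
  lab[1:3, 1, 1] <- ids[["liver"]]
  lab[1:2, 2, 1] <- ids[["gluteus_maximus"]]
  lab[1, 3, 1] <- ids[["vertebrae"]]
  suv <- array(0, dim = d)
  suv[1:3, 1, 1] <- c(1.8, 2.0, 2.2)
  suv[1:2, 2, 1] <- c(0.4, 0.6)
  st3 <- patient_study(suv_volume(suv),
                       segmentation_map(lab, default_label_dict()))
  rs <- compute_reference_stats(st3)
  expect_equal(rs$liver_median, 2.0)
  expect_equal(rs$liver_max, 2.2)
  expect_equal(rs$gluteus_median, 0.5)       # even count: midpoint

  # even liver count {1.0, 3.0} -> midpoint 2.0, max 3.0
  suv[1:3, 1, 1] <- c(1.0, 3.0, 0)
  lab[3, 1, 1] <- 0L
  st2 <- patient_study(suv_volume(suv),
                       segmentation_map(lab, default_label_dict()))
  rs2 <- compute_reference_stats(st2)
  expect_equal(rs2$liver_median, 2.0)
  expect_equal(rs2$liver_max, 3.0)
})

test_that("large-organ median matches a full-sort oracle", {
  st <- tiny_study()
  ids <- tiny_ids()
  set.seed(11)
  liver_idx <- which(st$seg$labels == ids[["liver"]])
  vals <- sample(seq(0.5, 3.5, length.out = 1000), length(liver_idx),
                 replace = TRUE)
  suv <- st$suv$values
  suv[liver_idx] <- vals
  st <- tiny_study(suv = suv)
  rs <- compute_reference_stats(st)
  sorted <- sort(vals)
  n <- length(sorted)
  oracle <- if (n %% 2 == 1) sorted[(n + 1) / 2] else
    (sorted[n / 2] + sorted[n / 2 + 1]) / 2
  expect_equal(rs$liver_median, oracle)
  expect_equal(rs$liver_max, max(vals))
})

test_that("the six shipped approaches resolve to the published rules", {
  stats <- structure(list(liver_median = 2.0, liver_max = 3.1,
                          gluteus_median = 0.5, n_liver = 10, n_gluteus = 10),
                     class = "reference_stats")
  apps <- default_approaches()
  t1 <- resolve_thresholds(apps$approach_1, stats)
  expect_equal(t1, list(axial = 2.2, extremity = 2.0))
  t2 <- resolve_thresholds(apps$approach_2, stats)
  expect_equal(t2, list(axial = 3.0, extremity = 2.0))
  t3 <- resolve_thresholds(apps$approach_3, stats)
  expect_equal(t3, list(axial = 4.0, extremity = 2.0))
  t4 <- resolve_thresholds(apps$approach_4, stats)
  expect_equal(t4, list(axial = 2.5, extremity = 2.5))
  t5 <- resolve_thresholds(apps$approach_5, stats)
  expect_equal(t5, list(axial = 2.5, extremity = 2.0))
  t6 <- resolve_thresholds(apps$approach_6, stats)
  expect_equal(t6, list(axial = 3.1, extremity = 3.1))
  # absolute approaches need no stats; relative ones do
  expect_silent(resolve_thresholds(apps$approach_4, NULL))
  expect_error(resolve_thresholds(apps$approach_1, NULL), "reference")
})

test_that("custom approaches round-trip through the JSON grammar", {
  cfg <- tempfile(fileext = ".json")
  writeLines(paste0(
    '[{"id": "custom", ',
    '"axial": {"organ": "liver", "statistic": "median", "multiplier": 1.3},',
    '"extremity": {"absolute": 1.9}}]'), cfg)
  apps <- read_approaches(cfg)
  stats <- structure(list(liver_median = 2.0, liver_max = 3.0,
                          gluteus_median = 0.5), class = "reference_stats")
  expect_equal(resolve_thresholds(apps$approach_custom, stats),
               list(axial = 2.6, extremity = 1.9))
  unlink(cfg)
})

test_that("thresholding is inclusive and confined to the skeleton", {
  st <- tiny_study()
  ids <- tiny_ids()
  suv <- st$suv$values
  suv[3, 3, 1] <- 2.2                      # axial voxel exactly at t_ax
  suv[1, 5, 1] <- 2.0                      # extremity voxel exactly at t_ex
  suv[5, 5, 5] <- 9.0                      # hot skull voxel: EXCLUDED
  suv[1, 1, 1] <- 9.0                      # hot liver voxel: reference organ
  st <- tiny_study(suv = suv)
  m <- apply_threshold(st, list(axial = 2.2, extremity = 2.0), 1)
  expect_true(m$mask[3, 3, 1])
  expect_true(m$mask[1, 5, 1])
  expect_false(m$mask[5, 5, 5])
  expect_false(m$mask[1, 1, 1])
  expect_equal(sum(m$mask), 2L)

  # all-zero SUV gives an empty mask
  cold <- tiny_study(suv = array(0, dim = c(6, 6, 6)))
  expect_equal(sum(apply_threshold(cold, list(axial = 1, extremity = 1))$mask),
               0L)
})

test_that("mask cardinality equals the exhaustive voxel-scan oracle", {
  set.seed(21)
  for (rep in 1:5) {
    st <- tiny_study(suv = array(runif(216, 0, 4), dim = c(6, 6, 6)))
    thr <- list(axial = runif(1, 0.5, 3), extremity = runif(1, 0.5, 3))
    m <- apply_threshold(st, thr)
    g <- group_grid(st$seg)
    oracle <- sum(g == "AXIAL" & st$suv$values >= thr$axial) +
      sum(g == "EXTREMITY" & st$suv$values >= thr$extremity)
    expect_equal(sum(m$mask), oracle)
    # every set voxel is skeletal and above its group threshold
    expect_true(all(g[m$mask] %in% c("AXIAL", "EXTREMITY")))
    sel_ax <- m$mask & g == "AXIAL"
    expect_true(all(st$suv$values[sel_ax] >= thr$axial))
  }
})

test_that("masks nest anti-monotonically in the thresholds", {
  set.seed(22)
  st <- tiny_study(suv = array(runif(216, 0, 5), dim = c(6, 6, 6)))
  stats <- compute_reference_stats(st)
  apps <- default_approaches()
  m <- lapply(apps, function(a)
    apply_threshold(st, resolve_thresholds(a, stats), a$id))
  expect_true(all(m$approach_3$mask <= m$approach_2$mask))
  expect_true(all(m$approach_2$mask <= m$approach_1$mask))
  expect_true(all(m$approach_4$mask <= m$approach_5$mask))
})

test_that("masks are invariant under label-id permutation", {
  set.seed(23)
  st <- tiny_study(suv = array(runif(216, 0, 4), dim = c(6, 6, 6)))
  dict <- st$seg$label_dict
  perm <- sample(dict$id)
  remap <- setNames(perm, dict$id)
  new_lab <- array(0L, dim = dim(st$seg$labels))
  nz <- st$seg$labels != 0L
  new_lab[nz] <- remap[as.character(st$seg$labels[nz])]
  dict2 <- dict
  dict2$id <- remap[as.character(dict$id)]
  st2 <- patient_study(st$suv, segmentation_map(new_lab, dict2), "perm")
  thr <- list(axial = 1.1, extremity = 0.9)
  expect_identical(apply_threshold(st, thr)$mask,
                   apply_threshold(st2, thr)$mask)
})
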