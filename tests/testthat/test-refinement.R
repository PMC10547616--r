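# Watershed assignment and small-component filtering

# wrap a raw SUV array + logical mask into the pipeline types on a single
# all-axial segmentation, so refinement can be tested in isolation
mask_fixture <- function(suv_arr, mask_arr, spacing = c(1, 1, 1)) {
  suv <- suv_volume(suv_arr, spacing)
  structure(list(mask = mask_arr, thresholds = list(axial = 0, extremity = 0),
                 approach_id = "test", spacing = spacing,
                 voxel_volume_ml = prod(spacing) / 1000),
            class = "infiltration_mask")
}

test_that("a unimodal blob floods to exactly one region", {
  d <- c(5L, 5L, 5L)
  suv <- array(0, dim = d)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    suv[i, j, k] <- 5 - sqrt((i - 3)^2 + (j - 3)^2 + (k - 3)^2)
  mask <- suv > 2.5
  lab <- flood_assign(suv_volume(suv), mask_fixture(suv, mask))
  expect_equal(lab$n_regions, 1L)
  expect_equal(sum(lab$region > 0), sum(mask))
  expect_equal(unname(unlist(lab$seeds[1, c("x", "y", "z")])), c(2, 2, 2))
})

test_that("a two-peak line splits at the valley with the stated tie rule", {
  # SUV along a 1x1x7 line: 3 2 1 0.5 1 2 3 -> two basins of sizes 4 and 3;
  # the valley voxel climbs toward its lexicographically smaller neighbor
  d <- c(7L, 1L, 1L)
  suv <- array(c(3, 2, 1, 0.5, 1, 2, 3), dim = d)
  mask <- array(TRUE, dim = d)
  lab <- flood_assign(suv_volume(suv), mask_fixture(suv, mask))
  expect_equal(lab$n_regions, 2L)
  r <- lab$region[, 1, 1]
  expect_equal(r[1:4], rep(r[1], 4))       # valley joins the left basin
  expect_equal(r[5:7], rep(r[5], 3))
  expect_false(r[1] == r[5])
})

test_that("an empty mask yields zero regions, not an error", {
  d <- c(3L, 3L, 3L)
  suv <- array(1, dim = d)
  lab <- flood_assign(suv_volume(suv),
                      mask_fixture(suv, array(FALSE, dim = d)))
  expect_equal(lab$n_regions, 0L)
  f <- filter_components(lab)
  expect_equal(sum(f$mask$mask), 0L)
  expect_equal(nrow(f$components), 0L)
})

test_that("equal-height plateaus merge into one region seeded lexicographically first", {
  d <- c(5L, 1L, 1L)
  suv <- array(c(5, 3, 3, 3, 2), dim = d)
  mask <- array(TRUE, dim = d)
  lab <- flood_assign(suv_volume(suv), mask_fixture(suv, mask))
  expect_equal(lab$n_regions, 1L)          # plateau drains into the peak
  suv2 <- array(c(3, 3, 1, 3, 3), dim = d)
  lab2 <- flood_assign(suv_volume(suv2), mask_fixture(suv2, mask))
  expect_equal(lab2$n_regions, 2L)         # two separate plateaus
  expect_equal(lab2$seeds$x, c(0, 3))      # each seeded at its first voxel
})

test_that("flooding partitions the mask and matches the steepest-ascent oracle", {
  set.seed(31)
  for (rep in 1:20) {
    d <- c(5L, 5L, 5L)
    suv <- array(round(runif(prod(d), 0, 5), 1), dim = d)  # force ties
    mask <- array(runif(prod(d)) < 0.6, dim = d)
    lab <- flood_assign(suv_volume(suv), mask_fixture(suv, mask))
    expect_equal(sum(lab$region > 0), sum(mask))           # partition
    expect_equal(sum(tabulate(lab$lab)), sum(mask))
    oracle <- oracle_flood(suv, mask)
    expect_identical(canonical_regions(lab$region), canonical_regions(oracle))
    # seed SUV is the maximum of its region
    for (rg in seq_len(lab$n_regions)) {
      expect_equal(lab$seeds$suv[rg], max(suv[lab$region == rg]))
    }
  }
})

test_that("identical inputs give identical labelings across runs", {
  set.seed(32)
  d <- c(6L, 6L, 6L)
  suv <- array(round(runif(prod(d), 0, 4), 1), dim = d)
  mask <- array(runif(prod(d)) < 0.5, dim = d)
  a <- flood_assign(suv_volume(suv), mask_fixture(suv, mask))
  b <- flood_assign(suv_volume(suv), mask_fixture(suv, mask))
  expect_identical(a$region, b$region)
  expect_identical(a$seeds, b$seeds)
})

test_that("the 1 mL cutoff removes strictly smaller components only", {
  # 999 voxels at 1 mm^3 = 0.999 mL -> removed; 1000 voxels = 1.000 mL -> kept
  d <- c(10L, 10L, 21L)
  suv <- array(0, dim = d)
  mask <- array(FALSE, dim = d)
  mask[, , 1:10] <- TRUE                    # 1000 voxels
  mask[, , 12:21] <- TRUE; mask[10, 10, 21] <- FALSE   # 999 voxels
  suv[mask] <- 2
  suv[5, 5, 5] <- 3                         # one maximum per slab
  suv[5, 5, 16] <- 3
  lab <- flood_assign(suv_volume(suv), mask_fixture(suv, mask))
  expect_equal(lab$n_regions, 2L)
  f <- filter_components(lab, min_volume_ml = 1.0)
  expect_equal(nrow(f$components), 1L)
  expect_equal(f$components$voxel_count, 1000L)
  expect_equal(f$components$volume_ml, 1.0)
  expect_equal(sum(f$mask$mask), 1000L)
})

test_that("volumes use physical voxel size and survivors sort by volume", {
  # three well-separated slabs of 0.5 / 1.5 / 2.0 mL at 1x1x2 mm voxels
  d <- c(25L, 10L, 16L)
  vox_ml <- 2 / 1000
  mask <- array(FALSE, dim = d)
  suv <- array(0, dim = d)
  mask[1:5, 1:10, 1:5] <- TRUE              # 250 vox = 0.5 mL
  mask[8:22, 1:10, 1:5] <- TRUE             # 750 vox = 1.5 mL
  mask[1:20, 1:10, 8:12] <- TRUE            # 1000 vox = 2.0 mL
  suv[mask] <- 2
  suv[3, 5, 3] <- 4; suv[15, 5, 3] <- 4; suv[10, 5, 10] <- 4
  lab <- flood_assign(suv_volume(suv, spacing = c(1, 1, 2)),
                      mask_fixture(suv, mask, spacing = c(1, 1, 2)))
  expect_equal(lab$n_regions, 3L)
  f <- filter_components(lab, min_volume_ml = 1.0)
  expect_equal(nrow(f$components), 2L)
  expect_equal(f$components$volume_ml, c(2.0, 1.5))
  expect_equal(sum(f$mask$mask) * vox_ml, 3.5)
  # refined mask is a subset of the raw mask
  expect_true(all(!f$mask$mask | mask))
})

test_that("component records carry seed coordinates and SUV summaries", {
  d <- c(12L, 12L, 12L)
  suv <- array(0, dim = d)
  mask <- array(FALSE, dim = d)
  mask[2:11, 2:11, 2:11] <- TRUE            # 1000 voxels = 1 mL
  suv[mask] <- 2
  suv[6, 7, 8] <- 5
  lab <- flood_assign(suv_volume(suv), mask_fixture(suv, mask))
  f <- filter_components(lab)
  expect_equal(nrow(f$components), 1L)
  expect_equal(f$components$suv_max, 5)
  expect_equal(f$components$suv_mean, mean(suv[mask]))
  expect_equal(unname(unlist(f$components[1, c("seed_x", "seed_y", "seed_z")])),
               c(5, 6, 7))                  # 0-based
})
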