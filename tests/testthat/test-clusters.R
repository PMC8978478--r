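test_that("a suprathreshold block becomes one cluster with exact geometry", {
  z <- array(0, c(6, 6, 6))
  z[2:3, 2:3, 2] <- -3
  tab <- detectClusters(z, voxelSize = c(2, 2, 2))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$polarity, "pothole")
  expect_identical(tab$nVoxels, 4L)
  expect_equal(tab$volumeMM3, 32)
  expect_equal(tab$peakAbsZ, 3)
  expect_equal(c(tab$centroidX, tab$centroidY, tab$centroidZ),
               c(2.5, 2.5, 2))

  # anisotropic voxels: volume comes from the header, not a constant
  tabAniso <- detectClusters(z, voxelSize = c(1, 2, 3))
  expect_equal(tabAniso$volumeMM3, 4 * 6)

  expect_identical(nrow(detectClusters(array(0, c(5, 5, 5)),
                                       voxelSize = c(2, 2, 2))), 0L)
})

test_that("corner-touching voxels merge only under 26-connectivity", {
  z <- array(0, c(5, 5, 5))
  z[2, 2, 2] <- 3
  z[3, 3, 3] <- 3
  n <- function(conn) nrow(detectClusters(z, connectivity = conn,
                                          voxelSize = c(2, 2, 2)))
  expect_identical(n(26), 1L)
  expect_identical(n(18), 2L)
  expect_identical(n(6), 2L)
  expect_error(detectClusters(z, connectivity = 10, voxelSize = c(2, 2, 2)),
               "connectivity")
})

test_that("component labeling equals the flood-fill oracle on random grids", {
  withr::with_seed(71, {
    for (rep in 1:20) {
      dm <- sample(5:12, 3, replace = TRUE)
      mask <- array(runif(prod(dm)) < runif(1, 0.2, 0.6), dm)
      for (conn in c(6, 18, 26)) {
        lab <- labelComponents(mask, conn)
        expect_identical(labelPartition(lab), floodOracle(mask, conn))
      }
    }
  })
})

test_that("strict inequalities govern z and volume thresholds", {
  z <- array(0, c(6, 6, 6))
  z[1:2, 1:2, 1] <- 2          # exactly at threshold: not a molehill
  expect_identical(nrow(detectClusters(z, voxelSize = c(2, 2, 2))), 0L)
  expect_identical(nrow(detectClusters(z, inclusive = TRUE,
                                       voxelSize = c(2, 2, 2))), 1L)

  z[1:2, 1:2, 1] <- 2.5        # 4 voxels, 32 mm3
  tab <- detectClusters(z, voxelSize = c(2, 2, 2))
  expect_identical(nrow(filterByMinVolume(tab, 25)), 1L)
  expect_identical(nrow(filterByMinVolume(tab, 32)), 0L)  # strict >
  expect_identical(nrow(filterByMinVolume(tab, 32, inclusive = TRUE)), 1L)
  expect_identical(nrow(filterByMinVolume(tab, 50)), 0L)
  expect_identical(nrow(filterByMinVolume(tab[0, ], 25)), 0L)
})

test_that("count profile composes detect + filter and respects symmetry", {
  z <- array(0, c(8, 8, 8))
  z[2:4, 2:3, 2] <- -4          # 6 voxels = 48 mm3 pothole
  prof <- countProfile(z, voxelSize = c(2, 2, 2))
  expect_identical(prof$count[prof$polarity == "pothole"],
                   c(1L, 0L, 0L, 0L))
  expect_identical(prof$count[prof$polarity == "molehill"], rep(0L, 4))

  withr::with_seed(72, {
    for (rep in 1:10) {
      z <- array(rnorm(10^3, sd = 1.5), c(10, 10, 10))
      prof <- countProfile(z, thresholds = c(0, 8, 16, 25),
                           voxelSize = c(2, 2, 2))

      # compositional oracle
      clus <- detectClusters(z, voxelSize = c(2, 2, 2))
      for (thr in c(0, 8, 16, 25)) {
        for (pol in c("pothole", "molehill")) {
          kept <- filterByMinVolume(clus[clus$polarity == pol, ], thr)
          expect_identical(
            prof$count[prof$polarity == pol & prof$thresholdMM3 == thr],
            nrow(kept))
        }
      }

      # negation swaps polarities exactly
      profNeg <- countProfile(-z, thresholds = c(0, 8, 16, 25),
                              voxelSize = c(2, 2, 2))
      expect_identical(prof$count[prof$polarity == "pothole"],
                       profNeg$count[profNeg$polarity == "molehill"])
      expect_identical(prof$count[prof$polarity == "molehill"],
                       profNeg$count[profNeg$polarity == "pothole"])

      # counts non-increasing along the volume ladder
      for (pol in c("pothole", "molehill"))
        expect_true(all(diff(prof$count[prof$polarity == pol]) <= 0))
    }
  })

  expect_error(countProfile(z, thresholds = c(50, 25),
                            voxelSize = c(2, 2, 2)), "increasing")
})

test_that("cluster ordering is deterministic: volume then lowest coordinate", {
  z <- array(0, c(10, 10, 10))
  z[8:9, 8:9, 8] <- 5    # 4 voxels at high coordinates
  z[2, 2, 2] <- 5        # 1 voxel, low coordinates
  z[2:3, 5:6, 2] <- 5    # 4 voxels, lower coordinates than the first
  tab <- detectClusters(z, connectivity = 6, voxelSize = c(2, 2, 2))
  expect_identical(tab$nVoxels, c(4L, 4L, 1L))
  expect_identical(tab$voxels[[1]][1, ], c(2L, 5L, 2L))
})
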