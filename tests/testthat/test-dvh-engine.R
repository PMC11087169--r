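test_that("cumulative DVH is exact for uniform and two-level fields", {
  g <- uniformGrid(60)
  m <- fullMask()
  dvh <- cumulativeDVH(g, m, binWidth = 0.5)
  expect_equal(dvh$volume[dvh$dose <= 60 + 1e-9], rep(100, sum(dvh$dose <= 60 + 1e-9)))
  expect_equal(dvh$volume[dvh$dose > 60 + 1e-9], rep(0, sum(dvh$dose > 60 + 1e-9)))

  vals <- array(35, dim = c(4, 4, 4)); vals[1:32] <- 70
  g2 <- DoseGrid(vals, spacing = 2)
  dvh2 <- cumulativeDVH(g2, fullMask(c(4, 4, 4)), binWidth = 1)
  expect_equal(dvh2$volume[dvh2$dose <= 35], rep(100, 36))
  expect_equal(unique(dvh2$volume[dvh2$dose > 35 & dvh2$dose <= 70]), 50)
  expect_equal(unique(dvh2$volume[dvh2$dose > 70]), 0)
})

test_that("DVH invariants hold and match voxel enumeration on random grids", {
  for (seed in 1:5) {
    rg <- randomGridAndMask(seed)
    dvh <- cumulativeDVH(rg$grid, rg$mask, binWidth = 2)
    expect_equal(dvh$volume[1], 100)
    expect_true(all(diff(dvh$volume) <= 1e-9))
    expect_gte(dvh$volume[nrow(dvh)], 0)
    doses <- doseValues(rg$grid)[rg$mask@mask]
    expect_equal(dvh$volume, oracleDVH(doses, dvh$dose))
  }
})

test_that("volumeAtDose is inclusive, vanishes above the maximum, and matches counting", {
  g <- uniformGrid(54)
  m <- fullMask()
  expect_equal(volumeAtDose(g, m, 54), 100)       # >= is inclusive
  expect_equal(volumeAtDose(g, m, 54.001), 0)
  expect_equal(volumeAtDose(g, m, 0), 100)
  for (seed in 6:9) {
    rg <- randomGridAndMask(seed)
    doses <- doseValues(rg$grid)[rg$mask@mask]
    for (thr in c(0, 20, 40.5, 79, 100))
      expect_equal(volumeAtDose(rg$grid, rg$mask, thr),
                   oracleVolumeAtDose(doses, thr))
    # non-increasing in the threshold
    v <- vapply(seq(0, 85, by = 5), function(t)
      volumeAtDose(rg$grid, rg$mask, t), numeric(1))
    expect_true(all(diff(v) <= 1e-9))
  }
})

test_that("doseAtVolume follows the sorted-dose interpolation rule", {
  g <- uniformGrid(63)
  expect_equal(doseAtVolume(g, fullMask(), 98), 63)
  expect_equal(doseAtVolume(g, fullMask(), 2), 63)

  # 100 equal-volume voxels with doses 1..100: the oracle gives exactly 3 Gy
  # at the 98% volume level under the declared interpolation rule
  g100 <- DoseGrid(array(1:100, dim = c(10, 10, 1)), spacing = 1)
  m100 <- fullMask(c(10, 10, 1))
  expect_equal(oracleDoseAtVolume(1:100, 98), 3)
  expect_equal(doseAtVolume(g100, m100, 98), 3)
  expect_equal(doseAtVolume(g100, m100, 100), 1)   # minimum at 100% volume

  for (seed in 10:13) {
    rg <- randomGridAndMask(seed)
    doses <- doseValues(rg$grid)[rg$mask@mask]
    for (v in c(2, 50, 95, 98, 100))
      expect_equal(doseAtVolume(rg$grid, rg$mask, v),
                   oracleDoseAtVolume(doses, v))
    dd <- vapply(seq(5, 100, by = 5), function(v)
      doseAtVolume(rg$grid, rg$mask, v), numeric(1))
    expect_true(all(diff(dd) <= 1e-9))   # non-increasing in volume
  }
})

test_that("doseAtCc applies the descending-sort partial-voxel rule", {
  g <- uniformGrid(45)
  expect_equal(doseAtCc(g, fullMask(), 0.03), 45)
  vol <- structureVolumeCc(fullMask(), g)
  expect_equal(doseAtCc(g, fullMask(), vol), 45)

  # one 0.027 cc voxel at 70 Gy in a 30 Gy background: the 0.03 cc boundary
  # splits the second voxel, whose dose is reported
  vals <- array(30, dim = c(6, 6, 6)); vals[3, 3, 3] <- 70
  g2 <- DoseGrid(vals, spacing = 3)
  expect_equal(voxelVolumeCc(g2), 0.027)
  expect_equal(doseAtCc(g2, fullMask(c(6, 6, 6)), 0.03), 30)
  expect_equal(oracleDoseAtCc(as.vector(vals), 0.027, 0.03), 30)
  expect_equal(doseAtCc(g2, fullMask(c(6, 6, 6)), 0.02), 70)

  # full-volume limit reaches the structure minimum; beyond it is an error
  rg <- randomGridAndMask(20)
  svol <- structureVolumeCc(rg$mask, rg$grid)
  expect_equal(doseAtCc(rg$grid, rg$mask, svol),
               min(doseValues(rg$grid)[rg$mask@mask]))
  expect_error(doseAtCc(rg$grid, rg$mask, svol + 1), "exceeds structure volume")
})

test_that("degenerate inputs raise the declared errors", {
  g <- uniformGrid(10)
  empty <- StructureMask("Gone", "oar", array(FALSE, dim = c(5, 5, 4)))
  expect_error(cumulativeDVH(g, empty), "absent")
  bad <- fullMask(c(4, 4, 4))
  expect_error(volumeAtDose(g, bad, 5), "congruent")
  expect_error(DoseGrid(array(-1, dim = c(2, 2, 2))), ">= 0")
  expect_error(DoseGrid(array(1, dim = c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
})

test_that("extractEndpoints matches direct construction and handles absences", {
  dims <- c(8, 8, 6)
  ctv <- array(FALSE, dim = dims); ctv[3:6, 3:6, 2:5] <- TRUE
  oar <- array(FALSE, dim = dims); oar[1:2, 1:2, 1:6] <- TRUE
  vals <- array(0, dim = dims); vals[ctv] <- 70
  g <- DoseGrid(vals, spacing = 4)
  ss <- StructureSet(StructureMask("CTV-High", "target", ctv),
                     StructureMask("Right Parotid", "oar", oar))
  rx <- Prescription(c("CTV-High" = 70), 35)
  ep <- extractEndpoints(g, ss, rx)
  expect_equal(ep$V100[ep$structure == "CTV-High"], 100)
  expect_equal(ep$D98[ep$structure == "CTV-High"], 100)
  expect_equal(ep$Dmax[ep$structure == "CTV-High"], 100)
  expect_equal(ep$Dmean[ep$structure == "Right Parotid"], 0)
  expect_equal(ep$"D0.03cc"[ep$structure == "Right Parotid"], 0)

  # absent structure emits the missing marker (NA row)
  ep2 <- extractEndpoints(g, ss, rx, expected = c("CTV-High", "CTV-Mid",
                                                  "Right Parotid"))
  expect_true(all(is.na(ep2[ep2$structure == "CTV-Mid",
                            c("V100", "D98", "Dmax", "Dmean", "D0.03cc")])))

  # target without a prescription level is a configuration error
  expect_error(extractEndpoints(g, ss, Prescription(c("CTV-Mid" = 60), 35)),
               "no prescription")
})

test_that("endpoints are invariant under voxel reordering and zero-padding", {
  rg <- randomGridAndMask(31, dims = c(6, 6, 5))
  rx <- Prescription(c("CTV-High" = 40), 30)
  tgt <- StructureMask("CTV-High", "target", rg$mask@mask)
  ss <- StructureSet(tgt)
  ep <- extractEndpoints(rg$grid, ss, rx)

  # permute all voxels with one permutation applied to grid and mask alike
  set.seed(1)
  p <- sample(prod(dim(rg$grid@values)))
  gp <- DoseGrid(array(doseValues(rg$grid)[p], dim = dim(rg$grid@values)),
                 spacing = gridSpacing(rg$grid))
  mp <- StructureMask("CTV-High", "target",
                      array(tgt@mask[p], dim = dim(tgt@mask)))
  ep_perm <- extractEndpoints(gp, StructureSet(mp), rx)
  expect_equal(ep_perm, ep)

  # embed in a larger grid with zero dose outside the mask
  dims2 <- c(9, 9, 8)
  vals2 <- array(0, dim = dims2); mask2 <- array(FALSE, dim = dims2)
  vals2[1:6, 1:6, 1:5] <- doseValues(rg$grid)
  mask2[1:6, 1:6, 1:5] <- tgt@mask
  ep_pad <- extractEndpoints(DoseGrid(vals2, spacing = gridSpacing(rg$grid)),
                             StructureSet(StructureMask("CTV-High", "target",
                                                        mask2)), rx)
  expect_equal(ep_pad, ep)
})
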