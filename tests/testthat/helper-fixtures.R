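# fixtures are built in code; grids are tiny so the brute-force oracles
# below (straight per-voxel loops, independent of the package's vectorized
# implementations) stay fast

uniformGrid <- function(dose, dims = c(5, 5, 4), spacing = 2) {
  DoseGrid(array(dose, dim = dims), spacing = spacing)
}

fullMask <- function(dims = c(5, 5, 4), name = "CTV-High", role = "target") {
  StructureMask(name, role, array(TRUE, dim = dims))
}

randomGridAndMask <- function(seed, dims = c(10, 9, 8), spacing = 3,
                              maxDose = 80) {
  set.seed(seed)
  g <- DoseGrid(array(runif(prod(dims), 0, maxDose), dim = dims),
                spacing = spacing)
  m <- array(runif(prod(dims)) < 0.4, dim = dims)
  if (!any(m)) m[1] <- TRUE
  list(grid = g, mask = StructureMask("S", "oar", m))
}

# ---- voxel-enumeration oracles ---------------------------------------------

oracleVolumeAtDose <- function(doses, threshold) {
  count <- 0
  for (d in doses) if (d >= threshold - 1e-9) count <- count + 1
  100 * count / length(doses)
}

# linear interpolation on the cumulative DVH between adjacent sorted voxel
# doses, written as an explicit loop
oracleDoseAtVolume <- function(doses, volumePct) {
  d <- sort(doses)
  n <- length(d)
  v <- (n - seq_len(n) + 1) / n
  q <- volumePct / 100
  if (q >= v[1]) return(d[1])
  if (q <= v[n]) return(d[n])
  for (i in seq_len(n - 1)) {
    if (q <= v[i] && q >= v[i + 1]) {
      if (v[i] == v[i + 1]) return(d[i])
      w <- (v[i] - q) / (v[i] - v[i + 1])
      return(d[i] + w * (d[i + 1] - d[i]))
    }
  }
  d[n]
}

oracleDoseAtCc <- function(doses, voxelCc, cc) {
  d <- sort(doses, decreasing = TRUE)
  acc <- 0
  for (i in seq_along(d)) {
    acc <- acc + voxelCc
    if (acc >= cc - 1e-9) return(d[i])
  }
  d[length(d)]
}

oracleDVH <- function(doses, edges) {
  vapply(edges, function(t) oracleVolumeAtDose(doses, t), numeric(1))
}

# build a dose grid realizing a requested endpoint vector (the
# construction-by-inversion fixture): a chosen fraction of target voxels at
# the prescription, the rest just below it, and uniform OAR doses
doseForEndpoints <- function(frame, structures, rx, v100, oarMean) {
  vals <- array(0, dim = dim(frame@values))
  for (nm in names(oarMean))
    vals[structures[[nm]]@mask] <- oarMean[[nm]]
  for (nm in names(v100)) {
    idx <- which(structures[[nm]]@mask)
    k <- round(length(idx) * v100[[nm]] / 100)
    level <- rx@levels[[nm]]
    vals[idx] <- 0.9 * level
    if (k > 0) vals[idx[seq_len(k)]] <- level
  }
  DoseGrid(vals, spacing = frame@spacing, origin = frame@origin)
}

# small phantom + short course for policy tests
smallSpec <- function(nFractions = 8) {
  prim <- function(name, role, center, radii)
    list(name = name, role = role, center = center, radii = radii)
  phantomSpec(
    shape = c(26, 26, 20), spacing = 5, origin = c(2.5, 2.5, 2.5),
    structures = list(
      `CTV-High` = prim("CTV-High", "target", c(65, 70, 50), c(16, 14, 15)),
      `CTV-Low` = prim("CTV-Low", "target", c(65, 68, 48), c(30, 24, 28)),
      `Right Parotid` = prim("Right Parotid", "oar", c(22, 72, 55), c(10, 11, 12)),
      Brainstem = prim("Brainstem", "oar", c(65, 78, 86), c(7, 7, 11))
    ),
    rx = Prescription(c("CTV-High" = 70, "CTV-Low" = 56), nFractions)
  )
}
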