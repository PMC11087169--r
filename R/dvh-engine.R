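#' @include AllClasses.R
NULL

.maskDoses <- function(dose, mask) {
  m <- if (is(mask, "StructureMask")) mask@mask else mask
  if (!identical(dim(m), dim(dose@values)))
    stop("mask is not congruent with the dose grid (shape mismatch)")
  if (!any(m))
    stop("structure absent: mask '",
         if (is(mask, "StructureMask")) mask@name else "?", "' is empty")
  dose@values[m]
}

#' Cumulative dose-volume histogram
#'
#' Computes the cumulative DVH of a structure: for each dose threshold, the
#' percentage of the structure's own volume receiving at least that dose
#' (inclusive). The curve starts at 100% at threshold 0 and is non-increasing.
#'
#' @param dose a [DoseGrid-class].
#' @param mask a [StructureMask-class] congruent with `dose`.
#' @param binWidth histogram bin width in Gy-RBE (default 0.01). The curve is
#'   for display; endpoint metrics are computed bin-free from sorted voxel
#'   doses.
#' @return data.frame with columns `dose` (Gy-RBE) and `volume` (percent).
#' @examples
#' g <- DoseGrid(array(60, dim = c(5, 5, 5)))
#' m <- StructureMask("CTV-High", "target", array(TRUE, dim = c(5, 5, 5)))
#' head(cumulativeDVH(g, m, binWidth = 10))
#' @export
cumulativeDVH <- function(dose, mask, binWidth = 0.01) {
  stopifnot(is.numeric(binWidth), binWidth > 0)
  d <- .maskDoses(dose, mask)
  edges <- seq(0, max(d) + binWidth, by = binWidth)
  counts <- vapply(edges, function(t) sum(d >= t - .eps), numeric(1))
  data.frame(dose = edges, volume = 100 * counts / length(d))
}

#' Volume receiving at least a dose threshold
#'
#' Percentage of the structure's volume with dose >= `threshold` (inclusive
#' comparison, matching "receives >= 100% of its prescription dose").
#'
#' @inheritParams cumulativeDVH
#' @param threshold dose threshold in Gy-RBE.
#' @return percent of structure volume (0..100).
#' @export
volumeAtDose <- function(dose, mask, threshold) {
  stopifnot(is.finite(threshold))
  d <- .maskDoses(dose, mask)
  100 * sum(d >= threshold - .eps) / length(d)
}

#' Dose covering a given volume fraction
#'
#' The largest dose d such that at least `volumePct` percent of the structure
#' receives >= d. Computed from the sorted voxel doses with linear
#' interpolation on the cumulative DVH between adjacent voxel doses;
#' `volumePct = 100` returns the structure minimum and volume fractions below
#' one voxel return the maximum.
#'
#' @inheritParams cumulativeDVH
#' @param volumePct volume percentage in (0, 100].
#' @return dose in Gy-RBE.
#' @export
doseAtVolume <- function(dose, mask, volumePct) {
  stopifnot(is.finite(volumePct), volumePct > 0, volumePct <= 100)
  d <- sort(.maskDoses(dose, mask))
  n <- length(d)
  if (n == 1L) return(d)
  v <- (n - seq_len(n) + 1) / n   # cumulative volume fraction receiving >= d[i]
  q <- volumePct / 100
  # v is strictly decreasing in i; interpolate dose over ascending volume
  stats::approx(x = rev(v), y = rev(d), xout = q, rule = 2, ties = "ordered")$y
}

#' Minimal dose within the hottest volume
#'
#' Sorts voxel doses in descending order, accumulates voxel volumes, and
#' returns the dose of the voxel in which the cumulative volume first reaches
#' `cc`. When the boundary splits a voxel, that voxel's dose is reported
#' (conservative; no sub-voxel dose model).
#'
#' @inheritParams cumulativeDVH
#' @param cc hot volume in cm^3 (0 < cc <= structure volume).
#' @return dose in Gy-RBE.
#' @export
doseAtCc <- function(dose, mask, cc) {
  stopifnot(is.finite(cc), cc > 0)
  d <- .maskDoses(dose, mask)
  vv <- voxelVolumeCc(dose)
  vol <- length(d) * vv
  if (cc > vol + .eps)
    stop(sprintf("requested hot volume %.4g cc exceeds structure volume %.4g cc",
                 cc, vol))
  d <- sort(d, decreasing = TRUE)
  k <- which(cumsum(rep(vv, length(d))) >= cc - .eps)[1]
  d[k]
}

#' Extract the clinical endpoint metrics for a set of structures
#'
#' Builds the per-structure endpoint table: targets carry V100 (% of own
#' volume at >= 100% of their own prescription), D98 and Dmax (as % of their
#' own prescription); OARs carry Dmean (Gy-RBE) and D0.03cc (Gy-RBE). Absent
#' structures (empty masks listed in `absent`, or missing from `structures`)
#' yield a row of NA.
#'
#' @param dose a [DoseGrid-class].
#' @param structures a [StructureSet-class].
#' @param rx a [Prescription-class]; every present target must have a level.
#' @param expected character vector of structure names the table should cover
#'   (defaults to the names in `structures`); names not present give NA rows.
#' @return data.frame with columns structure, role, V100, D98, Dmax (percent),
#'   Dmean, D0.03cc (Gy-RBE).
#' @export
extractEndpoints <- function(dose, structures, rx,
                             expected = structureNames(structures)) {
  rows <- lapply(expected, function(nm) {
    out <- data.frame(structure = nm, role = NA_character_, V100 = NA_real_,
                      D98 = NA_real_, Dmax = NA_real_, Dmean = NA_real_,
                      D0.03cc = NA_real_, stringsAsFactors = FALSE)
    if (!nm %in% structureNames(structures)) return(out)
    msk <- structures[[nm]]
    if (!any(msk@mask)) return(out)   # explicitly absent structure
    out$role <- msk@role
    if (msk@role == "target") {
      if (!nm %in% names(rx@levels))
        stop("target '", nm, "' has no prescription level")
      level <- rx@levels[[nm]]
      out$V100 <- volumeAtDose(dose, msk, level)
      out$D98 <- 100 * doseAtVolume(dose, msk, 98) / level
      out$Dmax <- 100 * max(.maskDoses(dose, msk)) / level
    } else {
      d <- .maskDoses(dose, msk)
      out$Dmean <- mean(d)
      out$D0.03cc <- doseAtCc(dose, msk, 0.03)
    }
    out
  })
  do.call(rbind, rows)
}
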