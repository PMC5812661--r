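#' Slice-summation liver volumetry
#'
#' The liver volume is the sum over slices of the segmented liver area
#' times the slice thickness; longitudinal volumes are normalized to the
#' preoperative (day-0) volume and reported in percent.
#'
#' @name volumetry
NULL

#' Liver volume from binary mask slices
#'
#' \eqn{V = \sum_{slices} (\mathrm{voxel count} \times \mathrm{voxel
#' area}) \times \mathrm{slice thickness}}.
#'
#' @param mask logical/0-1 array (2D or 3D) of liver voxels
#' @param voxelArea in-plane voxel area in mm^2
#' @param sliceThickness slice thickness in mm, > 0
#' @return volume in mm^3 (0 with a warning for an empty mask)
#' @examples
#' m <- array(TRUE, c(10, 10))
#' liverVolume(m, 0.117^2, 0.234)
#' @export
liverVolume <- function(mask, voxelArea, sliceThickness) {
  if (sliceThickness <= 0) stop("sliceThickness must be positive")
  if (voxelArea <= 0) stop("voxelArea must be positive")
  n <- sum(mask != 0)
  if (n == 0L) {
    warning("empty liver mask: volume is 0")
    return(0)
  }
  n * voxelArea * sliceThickness
}

#' Relative liver volume series
#'
#' Normalizes per-day absolute volumes to the day-0 (preoperative) volume;
#' day 0 is 100 percent by construction.
#'
#' @param volumes numeric vector of absolute volumes (mm^3)
#' @param days numeric vector of measurement days (must contain 0)
#' @param animalId optional identifier carried into the output
#' @return data.frame with columns `animal_id`, `day`, `volume_mm3`,
#'   `relative_pct`
#' @examples
#' relativeVolume(c(1000, 464), c(0, 1))
#' @export
relativeVolume <- function(volumes, days, animalId = NA_character_) {
  stopifnot(length(volumes) == length(days))
  if (!any(days == 0)) stop("a day-0 (baseline) volume is required")
  v0 <- volumes[days == 0][1]
  if (is.na(v0) || v0 <= 0) stop("day-0 volume must be positive")
  if (any(volumes < 0)) stop("volumes must be non-negative")
  data.frame(animal_id = animalId, day = days, volume_mm3 = volumes,
             relative_pct = 100 * volumes / v0)
}
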