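#' Region-of-interest definition and statistics
#'
#' Polygonal ROIs on one slice of a parametric map: three parenchymal
#' polygons placed away from large vessels, plus a background polygon
#' outside the body used for noise estimation.
#'
#' @name roi
NULL

#' Rasterize a polygon onto a voxel grid
#'
#' A voxel belongs to the polygon iff its centre is inside under the
#' even-odd (crossing) rule; centres exactly on a boundary are included.
#' Vertices are (x = column, y = row) voxel-centre coordinates.
#'
#' @param poly n x 2 vertex matrix
#' @param dim grid size (rows handled as y, columns as x), length 2
#' @return logical matrix of dimension `dim`
#' @export
rasterizePolygon <- function(poly, dim) {
  stopifnot(is.matrix(poly), ncol(poly) == 2L, nrow(poly) >= 3L,
            length(dim) == 2L)
  nr <- dim[1]; nc <- dim[2]
  cx <- rep(seq_len(nc), each = nr)       # x = column index
  cy <- rep(seq_len(nr), times = nc)      # y = row index
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- rep(FALSE, nr * nc)
  onEdge <- rep(FALSE, nr * nc)
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # boundary inclusion: centre on the segment
    dx <- xj - xi; dy <- yj - yi
    seglen2 <- dx * dx + dy * dy
    if (seglen2 > 0) {
      t <- ((cx - xi) * dx + (cy - yi) * dy) / seglen2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (cx - (xi + t * dx))^2 + (cy - (yi + t * dy))^2
      onEdge <- onEdge | d2 < 1e-18
    }
    crosses <- ((yi > cy) != (yj > cy)) &
      (cx < (xj - xi) * (cy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside | onEdge, nr, nc)
}

#' Regular polygon approximating a circle
#'
#' @param center c(x, y) in voxel coordinates
#' @param radius radius in voxels
#' @param nVertices number of vertices
#' @return vertex matrix usable in an [ROISet-class]
#' @export
circlePolygon <- function(center, radius, nVertices = 16L) {
  a <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  cbind(x = center[1] + radius * cos(a), y = center[2] + radius * sin(a))
}

#' Default background-noise polygon
#'
#' A fixed rectangle in the upper-left corner of the image, outside the
#' body, used to estimate the noise level.
#'
#' @param dim image dimensions (rows, cols)
#' @param size rectangle edge length in voxels
#' @return vertex matrix
#' @export
defaultBackgroundRoi <- function(dim, size = max(3L, floor(min(dim) / 6))) {
  cbind(x = c(0.6, size + 0.4, size + 0.4, 0.6),
        y = c(0.6, 0.6, size + 0.4, size + 0.4))
}

#' Automatically place parenchymal ROIs on a phantom
#'
#' Deterministic stand-in for the manual ROI drawing of a reader: places
#' `n` non-overlapping circular ROIs inside the liver parenchyma, away
#' from vessels and the liver boundary. Candidate centres are ranked by
#' their distance to the nearest non-parenchyma voxel (greedy
#' farthest-first), so the ROIs sit in the largest vessel-free regions.
#'
#' If the requested radius does not fit (small phantom, unlucky vessel
#' placement), the radius is shrunk deterministically in 10 percent steps
#' down to `minRadius` before giving up, so automated cohort runs do not
#' abort on tight geometries.
#'
#' @param phantom a [LiverPhantom-class] (2D or first slice of 3D)
#' @param n number of parenchymal ROIs
#' @param radius ROI radius in voxels
#' @param slice slice index
#' @param minRadius smallest radius tried by the fallback; 2.1 voxels is
#'   the smallest circle whose 16-gon rasterization keeps >= 10 voxels
#' @return an [ROISet-class] (ROIs named roi1..roiN plus background)
#' @export
autoPlaceRois <- function(phantom, n = 3L, radius = 2.4, slice = 1L,
                          minRadius = 2.1) {
  stopifnot(is(phantom, "LiverPhantom"))
  lab <- phantom@labels[, , slice]
  par <- lab == 1L
  if (!any(par)) stop("phantom has no parenchyma on this slice")
  nr <- nrow(lab); nc <- ncol(lab)
  coords <- which(par, arr.ind = TRUE)
  bad <- which(lab != 1L, arr.ind = TRUE)
  # distance of each parenchyma voxel to the nearest non-parenchyma voxel
  dmin <- apply(coords, 1, function(p)
    sqrt(min((bad[, 1] - p[1])^2 + (bad[, 2] - p[2])^2)))
  ord <- order(-dmin, coords[, 1], coords[, 2])
  tryRadius <- radius
  centers <- matrix(numeric(0), 0, 2)
  repeat {
    centers <- matrix(numeric(0), 0, 2)
    for (k in ord) {
      if (dmin[k] < tryRadius + 0.5) next  # circle touches vessel/boundary
      p <- coords[k, ]
      if (nrow(centers) &&
          any((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 <
                (2 * tryRadius + 1)^2)) next
      centers <- rbind(centers, p)
      if (nrow(centers) == n) break
    }
    if (nrow(centers) == n) break
    if (tryRadius * 0.9 < minRadius)
      stop("could not place ", n, " vessel-free ROIs of radius >= ",
           minRadius, "; enlarge the phantom")
    tryRadius <- tryRadius * 0.9
  }
  rois <- lapply(seq_len(n), function(i)
    circlePolygon(c(centers[i, 2], centers[i, 1]), tryRadius))  # x=col, y=row
  names(rois) <- paste0("roi", seq_len(n))
  new("ROISet", rois = rois,
      background = defaultBackgroundRoi(c(nr, nc)),
      slice = as.integer(slice), source = "autoPlaceRois")
}

#' ROI statistic on a parameter map
#'
#' Rasterizes each parenchymal polygon (voxel-centre even-odd rule),
#' computes the mean of the unmasked voxels in each ROI, and aggregates
#' as the mean of the ROI means and their standard deviation — the
#' three-ROI convention of the reader analysis.
#'
#' @param map a [ParameterMap-class]
#' @param rois an [ROISet-class]
#' @param minVoxels minimum rasterized voxels per ROI
#' @return list: `mean`, `sd`, `perRoi` (named vector of ROI means),
#'   `nVoxels`
#' @export
roiStatistic <- function(map, rois, minVoxels = 10L) {
  stopifnot(is(map, "ParameterMap"), is(rois, "ROISet"))
  vals <- map@values
  msk <- map@mask
  if (length(dim(vals)) == 3L) {
    vals <- vals[, , rois@slice]
    msk <- msk[, , rois@slice]
  }
  d <- dim(vals)
  perRoi <- numeric(0)
  nVox <- integer(0)
  for (nm in names(rois@rois)) {
    sel <- rasterizePolygon(rois@rois[[nm]], d)
    if (!any(sel)) stop("ROI '", nm, "' rasterizes to zero voxels")
    if (sum(sel) < minVoxels)
      stop("ROI '", nm, "' rasterizes to fewer than ", minVoxels, " voxels")
    maskedFrac <- mean(!msk[sel])
    if (maskedFrac > 0.5)
      warning("ROI '", nm, "' has ", round(100 * maskedFrac),
              "% masked voxels")
    perRoi[nm] <- mean(vals[sel & msk])
    nVox[nm] <- sum(sel & msk)
  }
  list(mean = mean(perRoi),
       sd = if (length(perRoi) > 1L) stats::sd(perRoi) else 0,
       perRoi = perRoi, nVoxels = nVox)
}
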