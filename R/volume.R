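#' Voxel volume with a world affine
#'
#' A minimal container for 3D (or 4D) voxel data together with the 4x4
#' voxel-to-world (RAS mm) affine. Voxel indices are 0-based in world
#' computations, matching the NIfTI convention; R array indexing stays
#' 1-based internally.
#'
#' @param data Numeric array, 3D (scalar/label map) or 4D (multi-volume).
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world
#'   RAS mm coordinates.
#' @param type Either "metric" (continuous, interpolated) or "label"
#'   (integer codes, never interpolated).
#' @return An object of class `fw_volume`.
#' @export
fw_volume <- function(data, affine, type = c("metric", "label")) {
  type <- match.arg(type)
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L))) {
    abort("`data` must be a 3D or 4D array.")
  }
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L))) {
    abort("`affine` must be a 4x4 matrix.")
  }
  if (type == "label" && any(data[is.finite(data)] %% 1 != 0)) {
    abort("Label volumes must contain integer codes.")
  }
  structure(list(data = data, affine = affine, type = type),
            class = "fw_volume")
}

#' @export
print.fw_volume <- function(x, ...) {
  cat(sprintf("<fw_volume[%s]> dim %s, voxel size %s mm\n", x$type,
              paste(dim(x$data), collapse = "x"),
              paste(signif(voxel_size(x), 3), collapse = "x")))
  invisible(x)
}

#' @export
dim.fw_volume <- function(x) dim(x$data)

#' Voxel edge lengths in mm
#' @param vol An `fw_volume` (or a 4x4 affine).
#' @return Numeric length-3 vector of voxel sizes.
#' @export
voxel_size <- function(vol) {
  aff <- if (inherits(vol, "fw_volume")) vol$affine else vol
  sqrt(colSums(aff[1:3, 1:3]^2))
}

#' Default centered RAS affine for a grid
#'
#' Places the grid so the world origin sits at the grid center, with +x to
#' the right: the midsagittal plane is x = 0 and the left hemisphere is
#' world x < 0.
#'
#' @param grid_dim Integer length-3 grid dimensions.
#' @param voxel_mm Isotropic voxel size in mm.
#' @return 4x4 affine matrix.
#' @export
centered_affine <- function(grid_dim, voxel_mm = 2) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * (grid_dim - 1) / 2
  aff
}

# world (N x 3, mm) -> 0-based continuous voxel coordinates (N x 3)
world_to_voxel <- function(vol, pts) {
  pts <- rbind_points(pts)
  inv <- solve(vol$affine)
  v <- cbind(pts, 1) %*% t(inv)
  v[, 1:3, drop = FALSE]
}

voxel_to_world <- function(affine, vox) {
  vox <- rbind_points(vox)
  w <- cbind(vox, 1) %*% t(affine)
  w[, 1:3, drop = FALSE]
}

rbind_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  storage.mode(pts) <- "double"
  pts
}

#' Sample a metric volume at world points by trilinear interpolation
#'
#' Points falling outside the voxel lattice return `NA`. Label volumes are
#' refused: labels must never be interpolated (use [sample_label()]).
#'
#' @param vol An `fw_volume` of type "metric".
#' @param pts N x 3 matrix of world RAS mm coordinates.
#' @return Numeric vector of length N.
#' @export
sample_trilinear <- function(vol, pts) {
  if (vol$type == "label") abort("Refusing to interpolate a label volume.")
  v <- world_to_voxel(vol, pts)
  d <- dim(vol$data)[1:3]
  n <- nrow(v)
  out <- rep(NA_real_, n)
  ok <- v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
        v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
        v[, 3] >= 0 & v[, 3] <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  v <- v[ok, , drop = FALSE]
  i0 <- pmin(floor(v), matrix(rep(d - 2, each = nrow(v)), ncol = 3))
  i0 <- pmax(i0, 0)
  fr <- v - i0
  acc <- numeric(nrow(v))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz) + 1L
    acc <- acc + w * vol$data[idx]
  }
  out[ok] <- acc
  out
}

#' Look up label codes at world points (nearest voxel)
#'
#' Uses the voxel whose center is nearest to the point (floor of the
#' continuous voxel coordinate + 0.5); points outside the grid return `NA`.
#'
#' @param vol An `fw_volume` of type "label".
#' @param pts N x 3 matrix of world RAS mm coordinates.
#' @return Integer vector of length N.
#' @export
sample_label <- function(vol, pts) {
  v <- world_to_voxel(vol, pts)
  i <- floor(v + 0.5)
  d <- dim(vol$data)[1:3]
  n <- nrow(i)
  out <- rep(NA_integer_, n)
  ok <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 &
        i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
        i[, 3] >= 0 & i[, 3] <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  out[ok] <- as.integer(vol$data[i[ok, , drop = FALSE] + 1L])
  out
}
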