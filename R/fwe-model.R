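#' Bi-tensor free-water forward model
#'
#' Predicts the diffusion signal of a two-compartment voxel: a tissue
#' compartment with diffusion tensor D and an isotropic free-water
#' compartment with fixed diffusivity `d_iso`,
#' \deqn{S_i = S_0 [ (1-f) e^{-b_i g_i^T D g_i} + f e^{-b_i d_{iso}} ].}
#'
#' @param tensor Symmetric positive semidefinite 3x3 tissue tensor (mm^2/s).
#' @param f Free-water signal fraction in [0, 1].
#' @param s0 Non-weighted (b = 0) signal.
#' @param scheme A [make_diffusion_scheme()] object.
#' @param d_iso Free-water diffusivity in mm^2/s (default 3.0e-3, body
#'   temperature water).
#' @return Numeric signal vector, one value per scheme volume; equals `s0`
#'   exactly at b = 0.
#' @export
predict_signal <- function(tensor, f, s0, scheme, d_iso = 3.0e-3) {
  validate_scheme(scheme)
  if (f < 0 || f > 1) abort("`f` must lie in [0, 1].")
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1e-12)) {
    abort("Tissue tensor must be positive semidefinite.")
  }
  q <- scheme$bvals * rowSums((scheme$bvecs %*% tensor) * scheme$bvecs)
  s0 * ((1 - f) * exp(-q) + f * exp(-scheme$bvals * d_iso))
}

#' Fractional anisotropy and mean diffusivity of a tensor
#'
#' Standard eigenvalue formulas: MD is the eigenvalue mean; FA is
#' \eqn{\sqrt{3/2}\,\lVert\lambda - MD\rVert / \lVert\lambda\rVert},
#' clipped to [0, 1]. Negative eigenvalues (numerically non-PSD input) are
#' clamped to 0 with a warning.
#'
#' @param tensor Symmetric 3x3 tensor.
#' @return Named numeric vector `c(fa = , md = )`.
#' @export
tensor_scalars <- function(tensor) {
  if (max(abs(tensor - t(tensor))) > 1e-10 * max(abs(tensor), 1e-12)) {
    abort("`tensor` must be symmetric.")
  }
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-12 * max(abs(ev), 1e-300)
  if (any(ev < -tol)) {
    warn(sprintf("Clamped %d negative eigenvalue(s) to 0.",
                 sum(ev < -tol)))
  }
  ev <- pmax(ev, 0)
  md <- mean(ev)
  nrm <- sqrt(sum(ev^2))
  fa <- if (nrm == 0) 0 else sqrt(1.5) * sqrt(sum((ev - md)^2)) / nrm
  c(fa = min(max(fa, 0), 1), md = md)
}

#' Axially symmetric tensor from FA, MD and a principal direction
#'
#' Constructs the prolate tensor with eigenvalues
#' \eqn{\lambda_1 = MD(1 + 2\alpha)}, \eqn{\lambda_2 = \lambda_3 =
#' MD(1 - \alpha)} where \eqn{\alpha = FA / \sqrt{3 - 2 FA^2}}, so the
#' requested FA and MD are reproduced exactly. This is the ground-truth
#' parameterization used by the phantom generator.
#'
#' @param fa Fractional anisotropy in [0, 1].
#' @param md Mean diffusivity in mm^2/s (>= 0).
#' @param direction Principal eigenvector (any nonzero 3-vector).
#' @return Symmetric 3x3 tensor.
#' @export
tensor_from_fa_md <- function(fa, md, direction = c(0, 0, 1)) {
  if (fa < 0 || fa > 1) abort("`fa` must lie in [0, 1].")
  if (md < 0) abort("`md` must be non-negative.")
  alpha <- fa / sqrt(3 - 2 * fa^2)
  l1 <- md * (1 + 2 * alpha)
  l2 <- max(md * (1 - alpha), 0)   # fa = 1 gives exactly 0, not -eps
  n <- direction / sqrt(sum(direction^2))
  l2 * diag(3) + (l1 - l2) * tcrossprod(n)
}

# design matrix mapping the 6 unique tensor components
# (xx, yy, zz, xy, xz, yz) to b * g' D g, one row per volume
tensor_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(b * g[, 1]^2, b * g[, 2]^2, b * g[, 3]^2,
        2 * b * g[, 1] * g[, 2], 2 * b * g[, 1] * g[, 3],
        2 * b * g[, 2] * g[, 3])
}

d6_to_tensor <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

tensor_to_d6 <- function(tensor) {
  c(tensor[1, 1], tensor[2, 2], tensor[3, 3],
    tensor[1, 2], tensor[1, 3], tensor[2, 3])
}

# Vectorized eigenvalues of symmetric 3x3 tensors stored as N x 6 rows
# (xx, yy, zz, xy, xz, yz); analytic trigonometric solution. Returns an
# N x 3 matrix, columns sorted descending.
eig_sym3_values <- function(d6) {
  d6 <- matrix(d6, ncol = 6)
  a11 <- d6[, 1]; a22 <- d6[, 2]; a33 <- d6[, 3]
  a12 <- d6[, 4]; a13 <- d6[, 5]; a23 <- d6[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  n <- nrow(d6)
  out <- matrix(q, n, 3)
  nz <- p > 0
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[nz] + 2 * p[nz] * cos(phi)
    e3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[nz] - e1 - e3
    out[nz, ] <- cbind(e1, e2, e3)
  }
  out
}

# FA and MD from eigenvalue rows (negative eigenvalues clamped to 0)
scalars_from_eigs <- function(ev) {
  ev <- pmax(ev, 0)
  md <- rowMeans(ev)
  nrm <- sqrt(rowSums(ev^2))
  dev <- sqrt(rowSums((ev - md)^2))
  fa <- ifelse(nrm > 0, sqrt(1.5) * dev / nrm, 0)
  cbind(fa = pmin(pmax(fa, 0), 1), md = md)
}
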