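#' Fit configuration for the free-water model
#'
#' @param d_iso Free-water diffusivity in mm^2/s. 3.0e-3 is the standard
#'   body-temperature value.
#' @param lambda Weight of the spatial-continuity (Tikhonov) penalty on the
#'   finite-difference gradient of the free-water fraction f. 0 disables it.
#' @param max_iter Maximum alternating iterations.
#' @param step_size Initial gradient step on logit(f).
#' @param tol Relative objective-change convergence tolerance.
#' @param md_tissue Typical tissue mean diffusivity (mm^2/s) used only to
#'   anchor the log-linear initialization of f.
#' @param md_max Tissue-compartment mean-diffusivity ceiling (mm^2/s).
#'   With a single shell the (f, D) decomposition is degenerate: a uniform
#'   eigenvalue shift of the tissue tensor can absorb any free-water
#'   amplitude. Capping tissue MD at a plausible white-matter value breaks
#'   that degeneracy and lets the signal amplitude identify f. NULL
#'   disables the ceiling (multi-shell data do not need it).
#' @return A list of class `fw_fit_config`.
#' @export
fw_fit_config <- function(d_iso = 3.0e-3, lambda = 0.1, max_iter = 200,
                          step_size = 1, tol = 1e-7, md_tissue = 0.6e-3,
                          md_max = 0.7e-3) {
  if (d_iso <= 0) abort("`d_iso` must be positive.")
  if (lambda < 0) abort("`lambda` must be non-negative.")
  if (!is.null(md_max) && md_max <= 0) abort("`md_max` must be positive.")
  structure(list(d_iso = d_iso, lambda = lambda, max_iter = max_iter,
                 step_size = step_size, tol = tol, md_tissue = md_tissue,
                 md_max = md_max),
            class = "fw_fit_config")
}

# Gather per-voxel signal rows (mask voxels x volumes) from a 4D array.
mask_signals <- function(dwi, mask) {
  d <- dim(dwi)
  idx <- which(mask)
  nvol <- d[4]
  s <- matrix(0, length(idx), nvol)
  nvox <- prod(d[1:3])
  for (v in seq_len(nvol)) s[, v] <- dwi[idx + (v - 1) * nvox]
  s
}

#' Initialize the free-water fit
#'
#' The fraction f starts from log-linear interpolation of the mean weighted
#' attenuation between a pure-tissue prediction (isotropic tensor at
#' `md_tissue`) and a pure-water prediction (`d_iso`), clipped to
#' [0.01, 0.99]. Tissue tensors start from ordinary least-squares DTI on
#' signals corrected with that initial f. All-zero signal voxels are
#' dropped from the mask with a warning.
#'
#' @param dwi 4D signal array (or `fw_volume`).
#' @param scheme Diffusion scheme.
#' @param mask Logical 3D array.
#' @param config [fw_fit_config()].
#' @return List with `f0` (vector over mask voxels), `d6` (N x 6 tensor
#'   components), `mask` (possibly reduced), `s0` (vector).
#' @export
initialize_fit <- function(dwi, scheme, mask, config = fw_fit_config()) {
  dwi <- as_dwi_array(dwi)
  validate_scheme(scheme)
  w <- scheme$bvals > 0
  s <- mask_signals(dwi, mask)
  s0 <- rowMeans(s[, !w, drop = FALSE])
  bad <- !is.finite(s0) | s0 <= 0 | rowSums(abs(s)) == 0
  if (any(bad)) {
    warn(sprintf("Excluding %d voxel(s) with zero/invalid signal from mask.",
                 sum(bad)))
    mask[which(mask)[bad]] <- FALSE
    s <- s[!bad, , drop = FALSE]
    s0 <- s0[!bad]
  }
  bmean <- mean(scheme$bvals[w])
  att <- rowMeans(s[, w, drop = FALSE]) / s0
  att <- pmax(att, 1e-6)
  log_at <- -bmean * config$md_tissue
  log_aw <- -bmean * config$d_iso
  f0 <- (log(att) - log_at) / (log_aw - log_at)
  f0 <- pmin(pmax(f0, 0.01), 0.99)
  d6 <- ols_tensor(s, s0, f0, scheme, config$d_iso)
  list(f0 = f0, d6 = d6, mask = mask, s0 = s0)
}

# OLS log-linear tensor fit on free-water-corrected weighted signals.
ols_tensor <- function(s, s0, f, scheme, d_iso) {
  w <- scheme$bvals > 0
  bmat <- tensor_design(scheme)[w, , drop = FALSE]
  aw <- exp(-scheme$bvals[w] * d_iso)
  st <- s[, w, drop = FALSE] - (f * s0) %o% aw
  st <- st / (1 - f)
  st <- pmax(st, 1e-6 * s0)
  y <- log(st / s0)           # N x nvol, model y = -B d6
  pinv <- solve(crossprod(bmat), t(bmat))
  -t(pinv %*% t(y))           # N x 6
}

# mask edge list for the finite-difference gradient penalty:
# pairs (i, j) of mask-vector positions that are +x/+y/+z neighbors
mask_edges <- function(mask) {
  d <- dim(mask)
  pos <- array(NA_integer_, d)
  pos[mask] <- seq_len(sum(mask))
  edges <- NULL
  shift_pairs <- function(ax) {
    n <- d[ax]
    ia <- lapply(1:3, function(k) if (k == ax) seq_len(n - 1) else seq_len(d[k]))
    ib <- lapply(1:3, function(k) if (k == ax) 1 + seq_len(n - 1) else seq_len(d[k]))
    a <- pos[ia[[1]], ia[[2]], ia[[3]]]
    b <- pos[ib[[1]], ib[[2]], ib[[3]]]
    ok <- !is.na(a) & !is.na(b)
    cbind(a[ok], b[ok])
  }
  do.call(rbind, lapply(1:3, shift_pairs))
}

#' Fit the single-shell bi-tensor free-water model
#'
#' Minimizes the sum of squared signal residuals plus a spatial-continuity
#' penalty \eqn{\lambda \sum \lVert\nabla f\rVert^2} over the mask. f is
#' parameterized through a logistic transform (so it stays in (0, 1)) and
#' updated by backtracking gradient descent; tissue tensors are updated by
#' per-voxel corrected least squares with eigenvalue clamping to stay
#' positive semidefinite, each voxel's update accepted only when it lowers
#' that voxel's residual. The recorded objective is non-increasing.
#'
#' With a single shell and \eqn{\lambda = 0} the (f, D) decomposition is not
#' uniquely identifiable; the regularization and the informative
#' initialization are what make recovery meaningful.
#'
#' @param dwi 4D signal array or `fw_volume`.
#' @param scheme Diffusion scheme (single-shell expected; multi-shell is
#'   accepted as-is).
#' @param mask Logical 3D array of voxels to fit.
#' @param config [fw_fit_config()].
#' @param init Optional initialization, as returned by [initialize_fit()].
#' @return An object of class `fw_fit` with fields `fwf_map`, `fw_fa_map`,
#'   `fw_md_map` (3D arrays, NA outside mask), `tensor_d6` (N x 6),
#'   `mask`, `affine`, and `convergence` (iterations, objective trace).
#' @export
fit_free_water <- function(dwi, scheme, mask, config = fw_fit_config(),
                           init = NULL) {
  affine <- if (inherits(dwi, "fw_volume")) dwi$affine else diag(4)
  dwi <- as_dwi_array(dwi)
  validate_scheme(scheme)
  if (!any(mask)) abort("`mask` is empty.")
  if (is.null(init)) init <- initialize_fit(dwi, scheme, mask, config)
  mask <- init$mask
  s <- mask_signals(dwi, mask)
  wsel <- scheme$bvals > 0
  sw <- s[, wsel, drop = FALSE]
  bmat <- tensor_design(scheme)[wsel, , drop = FALSE]
  aw <- exp(-scheme$bvals[wsel] * config$d_iso)
  s0 <- init$s0
  f <- init$f0
  d6 <- clamp_psd(init$d6, config$md_max)
  edges <- mask_edges(mask)
  lam <- config$lambda

  sse_vox <- function(f, d6) {
    et <- exp(-tcrossprod(d6, bmat))            # N x nvol tissue attenuation
    pred <- s0 * ((1 - f) * et + f * rep(1, length(f)) %o% aw)
    rowSums((pred - sw)^2)
  }
  penalty <- function(f) {
    if (lam == 0 || nrow(edges) == 0) return(0)
    lam * sum((f[edges[, 1]] - f[edges[, 2]])^2)
  }
  objective <- function(f, d6) sum(sse_vox(f, d6)) + penalty(f)

  obj <- objective(f, d6)
  trace <- obj
  step <- config$step_size
  converged <- FALSE

  for (it in seq_len(config$max_iter)) {
    # --- tensor update: corrected WLLS, per-voxel accept/reject ---
    d6_new <- clamp_psd(ols_tensor(s, s0, f, scheme, config$d_iso),
                        config$md_max)
    old_sse <- sse_vox(f, d6)
    new_sse <- sse_vox(f, d6_new)
    keep <- new_sse < old_sse
    d6[keep, ] <- d6_new[keep, ]

    # --- f update: backtracking gradient step on logit(f) ---
    et <- exp(-tcrossprod(d6, bmat))
    pred <- s0 * ((1 - f) * et + f * rep(1, length(f)) %o% aw)
    r <- pred - sw
    dS_df <- s0 * (rep(1, length(f)) %o% aw - et)
    g <- 2 * rowSums(r * dS_df)
    if (lam > 0 && nrow(edges) > 0) {
      dd <- 2 * lam * (f[edges[, 1]] - f[edges[, 2]])
      gpen <- numeric(length(f))
      t1 <- rowsum(dd, edges[, 1])
      gpen[as.integer(rownames(t1))] <- gpen[as.integer(rownames(t1))] + t1[, 1]
      t2 <- rowsum(-dd, edges[, 2])
      gpen[as.integer(rownames(t2))] <- gpen[as.integer(rownames(t2))] + t2[, 1]
      g <- g + gpen
    }
    z <- stats::qlogis(pmin(pmax(f, 1e-6), 1 - 1e-6))
    gz <- g * f * (1 - f)
    cur <- objective(f, d6)
    ok_step <- FALSE
    st <- step
    for (bt in 1:20) {
      z_new <- z - st * gz
      f_new <- stats::plogis(z_new)
      cand <- objective(f_new, d6)
      if (cand < cur) { ok_step <- TRUE; break }
      st <- st / 2
    }
    if (ok_step) {
      f <- f_new
      obj_new <- cand
      step <- min(st * 2, config$step_size * 8)
    } else {
      obj_new <- cur
    }
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= config$tol * max(abs(obj), 1e-12)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }

  ev <- eig_sym3_values(d6)
  if (any(ev < 0)) {
    # final safety clamp for scalar maps
    ev <- pmax(ev, 0)
  }
  sc <- scalars_from_eigs(ev)
  dims <- dim(mask)
  to_map <- function(v) { m <- array(NA_real_, dims); m[mask] <- v; m }
  structure(list(
    fwf_map = to_map(f),
    fw_fa_map = to_map(sc[, "fa"]),
    fw_md_map = to_map(sc[, "md"]),
    tensor_d6 = d6,
    s0 = s0,
    mask = mask,
    affine = affine,
    config = config,
    convergence = list(iterations = length(trace) - 1L,
                       objective = trace, converged = converged)
  ), class = "fw_fit")
}

# Project N x 6 tensors onto the feasible set: eigenvalues >= 0, and
# (when md_max is set) mean diffusivity <= md_max via a uniform eigenvalue
# shift -- the direction along which free water masquerades as tissue.
clamp_psd <- function(d6, md_max = NULL) {
  if (!is.null(md_max)) {
    md <- (d6[, 1] + d6[, 2] + d6[, 3]) / 3
    delta <- pmax(0, md - md_max)
    d6[, 1:3] <- d6[, 1:3] - delta
  }
  ev <- eig_sym3_values(d6)
  bad <- which(ev[, 3] < -1e-15)
  for (i in bad) {
    e <- eigen(d6_to_tensor(d6[i, ]), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    if (!is.null(md_max) && mean(lam) > md_max) {
      lam <- pmax(lam - (mean(lam) - md_max), 0)
    }
    d6[i, ] <- tensor_to_d6(e$vectors %*% diag(lam) %*% t(e$vectors))
  }
  d6
}

as_dwi_array <- function(dwi) {
  if (inherits(dwi, "fw_volume")) dwi <- dwi$data
  if (length(dim(dwi)) != 4) abort("DWI must be a 4D array.")
  dwi
}

#' Conventional single-tensor DTI fit (ordinary least squares)
#'
#' Used as the uncorrected reference against which the free-water-corrected
#' maps are compared.
#'
#' @inheritParams fit_free_water
#' @return List with `fa_map`, `md_map` 3D arrays (NA outside mask).
#' @export
fit_dti <- function(dwi, scheme, mask) {
  dwi <- as_dwi_array(dwi)
  validate_scheme(scheme)
  s <- mask_signals(dwi, mask)
  w <- scheme$bvals > 0
  s0 <- rowMeans(s[, !w, drop = FALSE])
  bmat <- tensor_design(scheme)[w, , drop = FALSE]
  y <- log(pmax(s[, w, drop = FALSE], 1e-6 * s0) / s0)
  pinv <- solve(crossprod(bmat), t(bmat))
  d6 <- -t(pinv %*% t(y))
  sc <- scalars_from_eigs(eig_sym3_values(d6))
  dims <- dim(mask)
  to_map <- function(v) { m <- array(NA_real_, dims); m[mask] <- v; m }
  list(fa_map = to_map(sc[, "fa"]), md_map = to_map(sc[, "md"]))
}

#' @export
print.fw_fit <- function(x, ...) {
  cv <- x$convergence
  cat(sprintf(
    "<fw_fit> %d voxels, %d iterations (%s), objective %.4g -> %.4g\n",
    sum(x$mask), cv$iterations,
    if (cv$converged) "converged" else "max iterations",
    cv$objective[1], tail(cv$objective, 1)))
  invisible(x)
}

#' Per-voxel tidy view of a free-water fit
#'
#' @param x An `fw_fit`.
#' @param ... Unused.
#' @return Tibble with voxel indices (0-based), fwf, fw_fa, fw_md.
#' @export
tidy.fw_fit <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE) - 1L
  tibble::tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    fwf = x$fwf_map[x$mask],
    fw_fa = x$fw_fa_map[x$mask],
    fw_md = x$fw_md_map[x$mask]
  )
}

#' One-row fit summary
#'
#' @param x An `fw_fit`.
#' @param ... Unused.
#' @return Tibble with voxel count, iterations, initial/final objective,
#'   convergence flag, and map means.
#' @export
glance.fw_fit <- function(x, ...) {
  cv <- x$convergence
  tibble::tibble(
    n_voxels = sum(x$mask),
    iterations = cv$iterations,
    converged = cv$converged,
    objective_initial = cv$objective[1],
    objective_final = tail(cv$objective, 1),
    mean_fwf = mean(x$fwf_map[x$mask]),
    mean_fw_fa = mean(x$fw_fa_map[x$mask]),
    mean_fw_md = mean(x$fw_md_map[x$mask])
  )
}

#' Turn a fitted object into a tidy tibble
#' @param x A fitted object.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a fitted object
#' @param x A fitted object.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
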