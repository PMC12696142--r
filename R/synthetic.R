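#' Configuration of the synthetic phantom cohort
#'
#' Encodes the study conditions the generator emulates: three pathology
#' groups with nested tumor compartments of group-dependent size
#' (glioblastoma > astrocytoma > oligodendroglioma for enhancing/necrotic;
#' oligodendrogliomas are typically non-enhancing), bilateral homologous
#' bundles profiled at 100 nodes, elevated free-water fraction inside
#' edema, and pathology-specific FA/MD asymmetry that decays exponentially
#' with along-tract distance from the tumor margin (negative FA peak for
#' glioblastoma and astrocytoma, positive for oligodendroglioma).
#'
#' @param n_subjects Named counts per pathology group.
#' @param grid_dim Grid dimensions (voxels).
#' @param voxel_mm Isotropic voxel size (mm).
#' @param radii_mm Per-group ellipsoid radii (mm) for necrotic, enhancing,
#'   edema compartments; must be nested necrotic <= enhancing <= edema.
#' @param axis_scale Per-axis ellipsoid scale factors.
#' @param tumor_center_mm Tumor center in left-canonical world mm
#'   (mirrored for right-hemisphere tumors).
#' @param center_jitter_mm Per-subject uniform jitter of the center (mm).
#' @param peak_asymmetry Named signed peak FA asymmetry per group
#'   (fractional, e.g. -0.04 = -4 percent at the margin).
#' @param asymmetry_sd Between-subject SD of the peak asymmetry.
#' @param decay_nodes Exponential decay scale of the asymmetry
#'   (along-tract nodes).
#' @param baseline_fa,baseline_fa_sd White-matter FA baseline and
#'   between-subject SD.
#' @param baseline_md,baseline_md_sd MD baseline (mm^2/s) and SD.
#' @param baseline_fwf Background free-water fraction.
#' @param edema_fwf Free-water fraction inside edema.
#' @param snr b = 0 signal over Rician noise sigma.
#' @param n_directions,b_value,n_b0 Acquisition scheme (55 directions at
#'   b = 2,000 s/mm^2 plus one b = 0 by default).
#' @param n_streamlines,spread_mm Streamlines per bundle and jitter scale.
#' @param n_nodes Profile nodes per tract.
#' @param involvement_threshold Percent threshold defining the tumor
#'   margin in ground-truth distances.
#' @param ventricle_radii_mm Ellipsoid radii of the ventricle region
#'   excluded from the brain mask for volume normalization.
#' @param irregular If TRUE, tumor compartments are irregular blobs
#'   (smoothly modulated ellipsoids) instead of exact ellipsoids.
#' @param seed Master seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(
    n_subjects = c(glioblastoma = 10, astrocytoma = 10, oligodendroglioma = 10),
    grid_dim = c(64L, 64L, 64L), voxel_mm = 2,
    radii_mm = list(glioblastoma = c(necrotic = 5, enhancing = 9, edema = 16),
                    astrocytoma = c(necrotic = 3.5, enhancing = 6.5, edema = 13),
                    oligodendroglioma = c(necrotic = 0, enhancing = 0, edema = 11)),
    axis_scale = c(1, 0.9, 0.85),
    tumor_center_mm = c(-24, 0, 0),
    center_jitter_mm = 2,
    peak_asymmetry = c(glioblastoma = -0.04, astrocytoma = -0.02,
                       oligodendroglioma = 0.05),
    asymmetry_sd = 0.01,
    decay_nodes = 8,
    baseline_fa = 0.45, baseline_fa_sd = 0.02,
    baseline_md = 0.75e-3, baseline_md_sd = 0.03e-3,
    baseline_fwf = 0.05, edema_fwf = 0.45,
    snr = 40, n_directions = 55, b_value = 2000, n_b0 = 1,
    n_streamlines = 12, spread_mm = 2,
    n_nodes = 100, involvement_threshold = 5,
    ventricle_radii_mm = c(6, 16, 10),
    irregular = FALSE,
    seed = 1) {
  cfg <- as.list(environment())
  for (g in names(cfg$radii_mm)) {
    r <- cfg$radii_mm[[g]]
    if (!(r["necrotic"] <= r["enhancing"] && r["enhancing"] <= r["edema"])) {
      abort(sprintf("Radii for %s must be nested necrotic <= enhancing <= edema.", g))
    }
  }
  if (cfg$snr <= 0) abort("`snr` must be positive.")
  if (cfg$decay_nodes <= 0) abort("`decay_nodes` must be positive.")
  for (fr in c(cfg$baseline_fa, cfg$baseline_fwf, cfg$edema_fwf)) {
    if (fr < 0 || fr > 1) abort("FA/FWF values must lie in [0, 1].")
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %s subjects (%s), grid %s @ %g mm, seed %d\n",
              sum(x$n_subjects),
              paste(names(x$n_subjects), x$n_subjects, sep = "=", collapse = ", "),
              paste(x$grid_dim, collapse = "x"), x$voxel_mm, x$seed))
  invisible(x)
}

# world coordinate arrays of every voxel center
grid_world <- function(grid_dim, affine) {
  ii <- (seq_len(grid_dim[1]) - 1)
  jj <- (seq_len(grid_dim[2]) - 1)
  kk <- (seq_len(grid_dim[3]) - 1)
  list(
    x = array(affine[1, 1] * ii + affine[1, 4], grid_dim),
    y = aperm(array(affine[2, 2] * jj + affine[2, 4],
                    grid_dim[c(2, 1, 3)]), c(2, 1, 3)),
    z = aperm(array(affine[3, 3] * kk + affine[3, 4],
                    grid_dim[c(3, 1, 2)]), c(2, 3, 1))
  )
}

#' Generate a nested tumor segmentation
#'
#' Concentric ellipsoidal compartments with BraTS-style labels
#' (1 = necrotic core, 4 = enhancing tumor, 2 = edema, 0 = background),
#' nested necrotic inside enhancing inside edema. Compartments with zero
#' radius are absent (oligodendrogliomas are typically non-enhancing).
#' With `config$irregular = TRUE` the shared ellipsoid surface is smoothly
#' modulated by a seeded angular perturbation, preserving nesting.
#'
#' @param config A [cohort_config()].
#' @param hemisphere Tumor hemisphere, "left" or "right".
#' @param group Pathology group name (indexes `config$radii_mm`).
#' @param center Tumor center in world mm (default: the configured center,
#'   mirrored for right-hemisphere tumors).
#' @param seed Seed for the irregular-surface modulation.
#' @return `fw_volume` of type "label".
#' @export
generate_tumor_segmentation <- function(config, hemisphere = "left",
                                        group = "glioblastoma",
                                        center = NULL, seed = 0) {
  stopifnot(hemisphere %in% c("left", "right"))
  aff <- centered_affine(config$grid_dim, config$voxel_mm)
  if (is.null(center)) {
    center <- config$tumor_center_mm
    if (hemisphere == "right") center[1] <- -center[1]
  }
  if (sign(center[1]) != (if (hemisphere == "left") -1 else 1)) {
    abort("Tumor center must lie in the requested hemisphere.")
  }
  radii <- config$radii_mm[[group]]
  gw <- grid_world(config$grid_dim, aff)
  dx <- gw$x - center[1]; dy <- gw$y - center[2]; dz <- gw$z - center[3]
  ax <- config$axis_scale
  half_extent <- (config$grid_dim - 1) / 2 * config$voxel_mm
  if (any(abs(center) + radii["edema"] * ax > half_extent)) {
    abort("Tumor extends outside the grid.")
  }
  mod <- 1
  if (isTRUE(config$irregular)) {
    r <- local_rng(seed)
    co <- r$norm(6, sd = 0.08)
    nn <- sqrt(dx^2 + dy^2 + dz^2); nn[nn == 0] <- 1
    ux <- dx / nn; uy <- dy / nn; uz <- dz / nn
    mod <- 1 + co[1] * ux + co[2] * uy + co[3] * uz +
      co[4] * ux * uy + co[5] * uy * uz + co[6] * ux * uz
    mod <- pmin(pmax(mod, 0.75), 1.25)
  }
  u_of <- function(r) {
    if (r <= 0) return(array(Inf, config$grid_dim))
    (dx / (r * ax[1]))^2 + (dy / (r * ax[2]))^2 + (dz / (r * ax[3]))^2
  }
  thr <- mod^2
  lab <- array(0L, config$grid_dim)
  lab[u_of(radii["edema"]) <= thr] <- 2L
  lab[u_of(radii["enhancing"]) <= thr] <- 4L
  lab[u_of(radii["necrotic"]) <= thr] <- 1L
  fw_volume(lab, aff, type = "label")
}

# built-in core trajectories (left-canonical frame, world mm), t in [0, 1]
builtin_core <- function(tract_name) {
  switch(tract_name,
    bundle_a = function(t) cbind(-24 + 4 * sin(pi * t),
                                 -45 + 90 * t,
                                 8 * sin(pi * t)),
    bundle_b = function(t) cbind(-40 + 4 * sin(pi * t),
                                 -45 + 90 * t,
                                 -10 + 4 * sin(2 * pi * t)),
    bundle_c = function(t) cbind(-20 - 4 * sin(pi * t),
                                 -45 + 90 * t,
                                 25 - 5 * sin(pi * t)),
    abort(sprintf("Unknown synthetic tract '%s'.", tract_name))
  )
}

#' Generate a synthetic streamline bundle
#'
#' Streamlines are smooth jitters of a core trajectory (constant + linear +
#' bump offsets with seeded Gaussian coefficients). The right-hemisphere
#' homologue of a bundle is the exact mirror image of the left one through
#' the midsagittal plane (x = 0): the same seed yields mirrored point sets.
#'
#' @param tract_name One of the built-in synthetic tracts ("bundle_a",
#'   "bundle_b", "bundle_c"), or any name when `core` is supplied.
#' @param hemisphere "left" or "right".
#' @param grid List with `dim` and `voxel_mm` (or a `cohort_config`).
#' @param n_streamlines Number of streamlines (>= 1).
#' @param spread_mm Jitter scale in mm (0 reproduces the core exactly).
#' @param seed Seed (hemisphere-independent, so homologues mirror).
#' @param core Optional core trajectory function t -> N x 3, or an N x 3
#'   matrix of core points, in the left-canonical frame.
#' @param n_points Points per streamline.
#' @return A `tract_bundle`.
#' @export
generate_bundle <- function(tract_name, hemisphere = "left", grid,
                            n_streamlines = 12, spread_mm = 2, seed = 0,
                            core = NULL, n_points = 50) {
  stopifnot(hemisphere %in% c("left", "right"))
  if (n_streamlines < 1) abort("`n_streamlines` must be >= 1.")
  gd <- if (inherits(grid, "cohort_config")) grid$grid_dim else grid$dim
  vs <- if (inherits(grid, "cohort_config")) grid$voxel_mm else grid$voxel_mm
  aff <- centered_affine(gd, vs)
  t <- seq(0, 1, length.out = n_points)
  core_pts <- if (is.null(core)) builtin_core(tract_name)(t)
              else if (is.function(core)) core(t)
              else rbind_points(core)
  r <- local_rng(seed)
  bump <- 4 * t * (1 - t)
  sls <- lapply(seq_len(n_streamlines), function(i) {
    c0 <- r$norm(3, sd = spread_mm / 2)
    c1 <- r$norm(3, sd = spread_mm / 2)
    c2 <- r$norm(3, sd = spread_mm / 2)
    off <- outer(rep(1, length(t)), c0) + outer(t, c1) + outer(bump, c2)
    pts <- core_pts + off
    if (hemisphere == "right") pts[, 1] <- -pts[, 1]
    pts
  })
  half <- (gd - 1) / 2 * vs
  for (sl in sls) {
    if (any(abs(sl) > rep(half, each = nrow(sl)))) {
      abort("Generated streamline leaves the grid.")
    }
  }
  tract_bundle(sls, tract = tract_name, hemisphere = hemisphere,
               affine = aff, ref_dim = gd)
}

#' Generate ground-truth metric fields with injected asymmetry
#'
#' White-matter baselines everywhere; FWF elevated inside edema; on the
#' tumor side, FA is multiplied by \eqn{1 + a\,e^{-d/\tau}} and MD by
#' \eqn{1 - a\,e^{-d/\tau}} in voxels around ipsilateral bundle nodes,
#' where d is the node's along-tract distance from the tumor margin and a
#' the signed peak asymmetry. The contralateral hemisphere is untouched.
#' Bundles whose distances are all undefined (no involved node) are left
#' at baseline.
#'
#' @param segmentation Label `fw_volume` from
#'   [generate_tumor_segmentation()].
#' @param config A [cohort_config()].
#' @param bundles_ipsi List of ipsilateral `tract_bundle`s.
#' @param node_distances List (parallel to `bundles_ipsi`) of per-node
#'   distances in node units, as from [node_distance_to_margin()].
#' @param peak_asymmetry Signed peak fractional asymmetry a.
#' @param baseline List with `fa`, `md`, `fwf` baseline values.
#' @param paint_radius_vox Neighborhood half-width (voxels) painted around
#'   each node point.
#' @return List of metric `fw_volume`s: `fw_fa`, `fw_md`, `fwf`, plus
#'   `direction` (3-component array of principal directions, bundle
#'   tangents near bundles, +z elsewhere).
#' @export
generate_metric_fields <- function(segmentation, config, bundles_ipsi,
                                   node_distances, peak_asymmetry,
                                   baseline = list(fa = NULL, md = NULL,
                                                   fwf = NULL),
                                   paint_radius_vox = 1) {
  gd <- dim(segmentation$data)
  aff <- segmentation$affine
  fa0 <- baseline$fa %||% config$baseline_fa
  md0 <- baseline$md %||% config$baseline_md
  fwf0 <- baseline$fwf %||% config$baseline_fwf
  fa <- array(fa0, gd); md <- array(md0, gd); fwf <- array(fwf0, gd)
  fwf[segmentation$data == 2] <- config$edema_fwf
  dirx <- array(0, gd); diry <- array(0, gd); dirz <- array(1, gd)

  offs <- as.matrix(expand.grid(-paint_radius_vox:paint_radius_vox,
                                -paint_radius_vox:paint_radius_vox,
                                -paint_radius_vox:paint_radius_vox))
  tau <- config$decay_nodes
  vol_tmp <- fw_volume(array(0, gd), aff)

  paint_bundle <- function(bundle, dists) {
    rp <- resampled_points(bundle, config$n_nodes)
    vox <- floor(world_to_voxel(vol_tmp, rp$points) + 0.5)
    # per-node tangents from the first streamline's resampled core
    core <- resample_streamline(bundle$streamlines[[1]], config$n_nodes)
    tang <- rbind(core[2, ] - core[1, ],
                  core[-1, , drop = FALSE] - core[-nrow(core), , drop = FALSE])
    tang <- tang / sqrt(rowSums(tang^2))
    ord <- order(dists, decreasing = TRUE, na.last = FALSE)
    for (nd in ord) {
      sel <- rp$node == nd
      vv <- vox[sel, , drop = FALSE]
      vv <- vv[rep(seq_len(nrow(vv)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = sum(sel)), , drop = FALSE]
      ok <- vv[, 1] >= 0 & vv[, 1] < gd[1] & vv[, 2] >= 0 & vv[, 2] < gd[2] &
        vv[, 3] >= 0 & vv[, 3] < gd[3]
      idx <- vv[ok, , drop = FALSE] + 1L
      dirx[idx] <<- tang[nd, 1]; diry[idx] <<- tang[nd, 2]
      dirz[idx] <<- tang[nd, 3]
      d <- dists[nd]
      if (!is.na(d)) {
        fac <- peak_asymmetry * exp(-d / tau)
        fa[idx] <<- fa0 * (1 + fac)
        md[idx] <<- md0 * (1 - fac)
      }
    }
  }
  for (i in seq_along(bundles_ipsi)) {
    paint_bundle(bundles_ipsi[[i]], node_distances[[i]])
  }
  fa <- pmin(pmax(fa, 0), 1)
  md <- pmax(md, 0)
  list(fw_fa = fw_volume(fa, aff), fw_md = fw_volume(md, aff),
       fwf = fw_volume(fwf, aff),
       direction = list(x = dirx, y = diry, z = dirz))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate diffusion-weighted signals from the bi-tensor model
#'
#' Builds an axially symmetric tissue tensor per voxel from (FA, MD,
#' principal direction), evaluates the two-compartment forward model for
#' every scheme volume, and applies Rician noise with
#' \eqn{\sigma = S_0 / SNR} (use `snr = Inf` for noiseless signals).
#'
#' @param fa_field,md_field,fwf_field Metric `fw_volume`s (or arrays).
#' @param direction_field List of arrays `x`, `y`, `z` (unit vectors).
#' @param scheme Diffusion scheme.
#' @param snr Signal-to-noise ratio (> 0; Inf disables noise).
#' @param seed Noise seed.
#' @param s0 b = 0 signal level.
#' @param d_iso Free-water diffusivity (mm^2/s).
#' @param mask Optional logical array restricting simulation (background
#'   voxels get zero signal).
#' @return `fw_volume` with 4D data (grid x volumes).
#' @export
simulate_dwi <- function(fa_field, md_field, fwf_field, direction_field,
                         scheme, snr = 40, seed = 0, s0 = 1,
                         d_iso = 3.0e-3, mask = NULL) {
  validate_scheme(scheme)
  if (snr <= 0) abort("`snr` must be positive.")
  aff <- if (inherits(fa_field, "fw_volume")) fa_field$affine else diag(4)
  fa <- if (inherits(fa_field, "fw_volume")) fa_field$data else fa_field
  md <- if (inherits(md_field, "fw_volume")) md_field$data else md_field
  f <- if (inherits(fwf_field, "fw_volume")) fwf_field$data else fwf_field
  if (any(fa < 0 | fa > 1)) abort("FA must lie in [0, 1].")
  if (any(md < 0)) abort("MD must be non-negative.")
  gd <- dim(fa)
  if (is.null(mask)) mask <- array(TRUE, gd)
  idx <- which(mask)
  n <- length(idx)
  fav <- fa[idx]; mdv <- md[idx]; fv <- f[idx]
  nv <- cbind(direction_field$x[idx], direction_field$y[idx],
              direction_field$z[idx])
  alpha <- fav / sqrt(3 - 2 * fav^2)
  l1 <- mdv * (1 + 2 * alpha)
  l2 <- mdv * (1 - alpha)
  b <- scheme$bvals
  gmat <- scheme$bvecs
  dot2 <- (nv %*% t(gmat))^2                      # n x nvol
  q <- (l2 %o% b) + (l1 - l2) * dot2 * rep(b, each = n)
  et <- exp(-q)
  ew <- exp(-b * d_iso)
  sig <- s0 * ((1 - fv) * et + fv * rep(1, n) %o% ew)
  if (is.finite(snr)) {
    r <- local_rng(seed)
    sigma <- s0 / snr
    e1 <- matrix(r$norm(n * length(b), sd = sigma), n, length(b))
    e2 <- matrix(r$norm(n * length(b), sd = sigma), n, length(b))
    sig <- sqrt((sig + e1)^2 + e2^2)
  }
  out <- array(0, c(gd, length(b)))
  nvox <- prod(gd)
  for (v in seq_along(b)) out[idx + (v - 1) * nvox] <- sig[, v]
  fw_volume(out, aff)
}

synthetic_tract_names <- function() c("bundle_a", "bundle_b", "bundle_c")

# Demographics emulating group structure: glioblastoma patients older.
sample_demographics <- function(group, r) {
  mean_age <- c(glioblastoma = 62, astrocytoma = 45, oligodendroglioma = 44)
  age <- round(pmin(pmax(r$norm(1, mean_age[[group]], 10), 19), 97))
  sex <- if (r$unif(1) < 0.4) "F" else "M"
  list(age = age, sex = sex)
}

#' Generate one synthetic subject
#'
#' @param config A [cohort_config()].
#' @param subject_id Subject identifier.
#' @param group Pathology group.
#' @param seed Subject seed.
#' @return List with `record` (one-row tibble: subject_id, pathology, age,
#'   sex, tumor_hemisphere, truth parameters), `segmentation`, `bundles`
#'   (named by tract and hemisphere), `fields` (ground-truth metric
#'   volumes), `node_distances` (per ipsilateral tract).
#' @export
generate_subject <- function(config, subject_id, group, seed) {
  r <- local_rng(seed)
  hemi <- if (r$unif(1) < 0.5) "left" else "right"
  demo <- sample_demographics(group, r)
  center <- config$tumor_center_mm +
    r$unif(3, -config$center_jitter_mm, config$center_jitter_mm)
  if (hemi == "right") center[1] <- -center[1]
  seg <- generate_tumor_segmentation(config, hemi, group, center = center,
                                     seed = seed)
  bundles <- list()
  for (tn in synthetic_tract_names()) {
    bseed <- (seed + utf8ToInt(substr(tn, nchar(tn), nchar(tn)))) %% 2147483647
    for (h in c("left", "right")) {
      b <- generate_bundle(tn, h, config, config$n_streamlines,
                           config$spread_mm, seed = bseed)
      bundles[[paste(tn, h, sep = "_")]] <- orient_bundle(b)
    }
  }
  ipsi <- bundles[grepl(paste0("_", hemi, "$"), names(bundles))]
  node_distances <- lapply(ipsi, function(b) {
    inv <- node_involvement(b, seg, config$n_nodes)
    node_distance_to_margin(inv$combined, config$involvement_threshold)
  })
  peak <- config$peak_asymmetry[[group]] + r$norm(1, sd = config$asymmetry_sd)
  base <- list(fa = min(max(r$norm(1, config$baseline_fa,
                                   config$baseline_fa_sd), 0.1), 0.9),
               md = max(r$norm(1, config$baseline_md, config$baseline_md_sd),
                        1e-4),
               fwf = config$baseline_fwf)
  fields <- generate_metric_fields(seg, config, ipsi, node_distances, peak,
                                   baseline = base)
  vols <- tumor_volume_stats(seg, config)
  record <- tibble::tibble(
    subject_id = subject_id, pathology = group, age = demo$age,
    sex = demo$sex, tumor_hemisphere = hemi, seed = seed,
    vol_prop_necrotic = vols$proportion_brain[vols$compartment == "necrotic"],
    vol_prop_enhancing = vols$proportion_brain[vols$compartment == "enhancing"],
    vol_prop_edema = vols$proportion_brain[vols$compartment == "edema"],
    peak_asymmetry = peak, baseline_fa = base$fa, baseline_md = base$md,
    baseline_fwf = base$fwf,
    tumor_center_x = center[1], tumor_center_y = center[2],
    tumor_center_z = center[3])
  list(record = record, segmentation = seg, bundles = bundles,
       fields = fields, node_distances = node_distances)
}

#' Generate the full synthetic cohort
#'
#' Per-subject seeds are derived deterministically from the master seed and
#' subject index; identical configs reproduce identical cohorts. When
#' `out_dir` is given, all volumes (NIfTI), bundles (TRK), gradient tables
#' (FSL bval/bvec) and a JSON manifest with ground-truth parameters are
#' written to disk.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory.
#' @param include_dwi Also simulate and (if writing) store the noisy 4D
#'   DWI per subject.
#' @param keep_volumes Keep per-subject volumes in the returned object
#'   (set FALSE to save memory; records and profiles can still be computed
#'   streamingly with [cohort_profiles()]).
#' @return List with `subjects` (tibble of records), `data` (per-subject
#'   lists, if kept), `manifest` (paths and parameters).
#' @export
generate_cohort <- function(config, out_dir = NULL, include_dwi = FALSE,
                            keep_volumes = TRUE) {
  groups <- rep(names(config$n_subjects), times = config$n_subjects)
  n <- length(groups)
  records <- vector("list", n)
  data <- if (keep_volumes) vector("list", n) else NULL
  manifest <- list(tool = "fwtract", version = as.character(utils::packageVersion("fwtract")),
                   master_seed = config$seed, subjects = list())
  scheme <- make_diffusion_scheme(config$n_directions, config$b_value,
                                  config$n_b0, seed = config$seed)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    sid <- sprintf("sub-%03d", i)
    sseed <- (config$seed * 1009L + i) %% 2147483647L
    sub <- tryCatch(
      generate_subject(config, sid, groups[i], sseed),
      error = function(e) abort(sprintf("Subject %s failed: %s", sid,
                                        conditionMessage(e))))
    if (include_dwi) {
      sub$dwi <- simulate_dwi(sub$fields$fw_fa, sub$fields$fw_md,
                              sub$fields$fwf, sub$fields$direction,
                              scheme, snr = config$snr, seed = sseed + 1)
    }
    records[[i]] <- sub$record
    entry <- c(as.list(sub$record), list(tracts = synthetic_tract_names()))
    if (!is.null(out_dir)) {
      sdir <- file.path(out_dir, sid)
      dir.create(sdir, showWarnings = FALSE)
      paths <- list(
        segmentation = file.path(sdir, "seg.nii.gz"),
        fw_fa = file.path(sdir, "truth_fa.nii.gz"),
        fw_md = file.path(sdir, "truth_md.nii.gz"),
        fwf = file.path(sdir, "truth_fwf.nii.gz"))
      write_volume(sub$segmentation, paths$segmentation)
      write_volume(sub$fields$fw_fa, paths$fw_fa)
      write_volume(sub$fields$fw_md, paths$fw_md)
      write_volume(sub$fields$fwf, paths$fwf)
      for (bn in names(sub$bundles)) {
        paths[[bn]] <- file.path(sdir, paste0(bn, ".trk"))
        write_bundle(sub$bundles[[bn]], paths[[bn]])
      }
      if (include_dwi) {
        paths$dwi <- file.path(sdir, "dwi.nii.gz")
        write_volume(sub$dwi, paths$dwi)
        write_scheme(scheme, file.path(sdir, "dwi"))
        paths$bval <- file.path(sdir, "dwi.bval")
        paths$bvec <- file.path(sdir, "dwi.bvec")
      }
      entry$paths <- lapply(paths, normalizePath)
    }
    manifest$subjects[[sid]] <- entry
    if (keep_volumes) data[[i]] <- sub
  }
  subjects <- dplyr::bind_rows(records)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(subjects = subjects, data = data, manifest = manifest,
       scheme = scheme, config = config)
}

#' Cohort profile table (streaming)
#'
#' Generates each subject in turn, profiles its bundles against the
#' ground-truth metric fields and segmentation, and discards the volumes,
#' returning the stacked long profile table. This keeps memory flat for
#' large cohorts.
#'
#' @param config A [cohort_config()].
#' @return List with `subjects` tibble and `profiles` tibble (columns
#'   subject_id, tract, hemisphere, node, fw_fa, fw_md, fwf, involvement
#'   fractions).
#' @export
cohort_profiles <- function(config) {
  groups <- rep(names(config$n_subjects), times = config$n_subjects)
  recs <- vector("list", length(groups))
  profs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sid <- sprintf("sub-%03d", i)
    sseed <- (config$seed * 1009L + i) %% 2147483647L
    sub <- generate_subject(config, sid, groups[i], sseed)
    metrics <- sub$fields[c("fw_fa", "fw_md", "fwf")]
    p <- purrr::map_dfr(sub$bundles, function(b) {
      tract_profile(b, metrics, sub$segmentation, config$n_nodes)
    })
    p$subject_id <- sid
    recs[[i]] <- sub$record
    profs[[i]] <- p
  }
  list(subjects = dplyr::bind_rows(recs),
       profiles = dplyr::bind_rows(profs) |>
         dplyr::relocate("subject_id"))
}
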