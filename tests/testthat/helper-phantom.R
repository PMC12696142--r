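# Shared fixture builders (all generated in code; no data files).

# two-block free-water phantom: lower half tissue f, upper half edema f
block_phantom <- function(gd = c(12L, 12L, 12L), fa = 0.7, md = 0.7e-3,
                          f_tissue = 0.1, f_edema = 0.6, voxel_mm = 2) {
  half <- gd[3] %/% 2
  f <- array(f_tissue, gd)
  f[, , (half + 1):gd[3]] <- f_edema
  aff <- centered_affine(gd, voxel_mm)
  list(fa = fw_volume(array(fa, gd), aff),
       md = fw_volume(array(md, gd), aff),
       fwf = fw_volume(f, aff),
       direction = list(x = array(0, gd), y = array(0, gd),
                        z = array(1, gd)),
       affine = aff, gd = gd, half = half,
       f_tissue = f_tissue, f_edema = f_edema, fa_true = fa, md_true = md)
}

# straight-line bundle through a grid, one or more identical streamlines
line_bundle <- function(from, to, n_streamlines = 1, n_points = 30,
                        tract = "t", hemisphere = "left",
                        affine = centered_affine(c(64, 64, 64), 2)) {
  t <- seq(0, 1, length.out = n_points)
  sl <- cbind(from[1] + t * (to[1] - from[1]),
              from[2] + t * (to[2] - from[2]),
              from[3] + t * (to[3] - from[3]))
  tract_bundle(rep(list(sl), n_streamlines), tract = tract,
               hemisphere = hemisphere, affine = affine)
}

# random smooth polyline with strictly positive arc length
random_polyline <- function(n_points = 20) {
  steps <- matrix(stats::rnorm(3 * (n_points - 1), sd = 2), ncol = 3)
  apply(rbind(stats::rnorm(3, sd = 5), steps), 2, cumsum)
}

# profile tibble builder: one subject, explicit per-node values/fractions;
# scalar inputs are recycled over 100 nodes
make_profile <- function(tract, hemisphere, fw_fa, combined = 0,
                         n_nodes = NULL) {
  if (is.null(n_nodes)) {
    n_nodes <- max(length(fw_fa), length(combined))
    if (n_nodes == 1) n_nodes <- 100
  }
  tibble::tibble(tract = tract, hemisphere = hemisphere,
                 node = seq_len(n_nodes),
                 fw_fa = rep_len(fw_fa, n_nodes),
                 combined = rep_len(combined, n_nodes))
}

# ipsi value giving an exact percent asymmetry A against contra value c
ipsi_for_asym <- function(A, contra = 1) contra * (200 + A) / (200 - A)

small_scheme <- function(n_dir = 30, seed = 0) {
  make_diffusion_scheme(n_dir, 2000, 1, seed)
}
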