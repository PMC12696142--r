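test_that("forward model reproduces closed-form limits", {
  sch <- small_scheme(30)
  D <- tensor_from_fa_md(0.7, 0.7e-3)
  s <- predict_signal(D, 0.3, 2.5, sch)
  expect_equal(s[sch$bvals == 0], 2.5)            # b = 0 gives s0 exactly
  # pure free water: every weighted volume at exp(-b * d_iso)
  s_fw <- predict_signal(matrix(0, 3, 3), 1, 1, sch, d_iso = 3.0e-3)
  expect_equal(unname(s_fw[sch$bvals > 0]), rep(exp(-6), 30), tolerance = 1e-12)
  # pure tissue, isotropic tensor: direction independence
  m <- 0.9e-3
  s_iso <- predict_signal(diag(rep(m, 3)), 0, 1.3, sch)
  expect_equal(unname(s_iso[sch$bvals > 0]), rep(1.3 * exp(-2000 * m), 30),
               tolerance = 1e-12)
  expect_error(predict_signal(diag(c(-1e-3, 1e-3, 1e-3)), 0.2, 1, sch),
               "positive semidefinite")
  expect_error(predict_signal(D, 1.2, 1, sch), "0, 1")
})

test_that("tensor scalars match the eigenvalue formulas", {
  expect_equal(tensor_scalars(diag(rep(0.8e-3, 3))),
               c(fa = 0, md = 0.8e-3))
  expect_equal(tensor_scalars(diag(c(1e-3, 0, 0))),
               c(fa = 1, md = 1e-3 / 3))
  # hand-evaluated oracle for eigenvalues (1.5, 0.3, 0.3) x 1e-3
  sc <- tensor_scalars(diag(c(1.5e-3, 0.3e-3, 0.3e-3)))
  expect_equal(unname(sc["fa"]), 0.7698004, tolerance = 1e-6)
  expect_equal(unname(sc["md"]), 0.7e-3)
  expect_warning(tensor_scalars(diag(c(-1e-4, 1e-3, 1e-3))), "Clamped")
})

test_that("axially symmetric construction inverts the scalar map", {
  for (fa in c(0, 0.3, 0.7, 1)) {
    D <- tensor_from_fa_md(fa, 0.7e-3, c(1, 2, -1))
    sc <- tensor_scalars(D)
    expect_equal(unname(sc["fa"]), fa, tolerance = 1e-10)
    expect_equal(unname(sc["md"]), 0.7e-3, tolerance = 1e-12)
  }
})

test_that("vectorized symmetric eigenvalues agree with base eigen", {
  set.seed(11)
  for (i in 1:50) {
    A <- matrix(rnorm(9), 3, 3); A <- (A + t(A)) / 2
    d6 <- c(A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[1, 3], A[2, 3])
    ours <- fwtract:::eig_sym3_values(matrix(d6, 1))
    ref <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(as.vector(ours), ref, tolerance = 1e-10)
  }
})

test_that("initialization lands in the documented limits", {
  sch <- small_scheme(30)
  cfg <- fw_fit_config()
  gd <- c(3L, 3L, 3L)
  mask <- array(TRUE, gd)
  b <- 2000
  att_water <- exp(-b * cfg$d_iso)
  att_tissue <- exp(-b * cfg$md_tissue)
  mk_dwi <- function(att) {
    arr <- array(0, c(gd, length(sch$bvals)))
    for (v in seq_along(sch$bvals)) {
      arr[, , , v] <- if (sch$bvals[v] == 0) 1 else att
    }
    arr
  }
  init_w <- initialize_fit(mk_dwi(att_water), sch, mask, cfg)
  expect_true(all(init_w$f0 == 0.99))              # pure-water clip
  init_t <- initialize_fit(mk_dwi(att_tissue), sch, mask, cfg)
  expect_true(all(init_t$f0 == 0.01))              # pure-tissue clip
  # voxel at the log-linear midpoint of the two references
  att_mid <- exp(0.5 * log(att_water) + 0.5 * log(att_tissue))
  init_m <- initialize_fit(mk_dwi(att_mid), sch, mask, cfg)
  expect_true(all(abs(init_m$f0 - 0.5) < 0.15))
})

test_that("zero-signal voxels are dropped from the mask with a warning", {
  sch <- small_scheme(16)
  gd <- c(2L, 2L, 2L)
  arr <- array(0.5, c(gd, length(sch$bvals)))
  arr[1, 1, 1, ] <- 0
  mask <- array(TRUE, gd)
  expect_warning(init <- initialize_fit(arr, sch, mask, fw_fit_config()),
                 "zero/invalid")
  expect_equal(sum(init$mask), 7)
})

test_that("fit stays at a noiseless optimum and keeps the objective monotone", {
  sch <- small_scheme(30)
  gd <- c(4L, 4L, 4L)
  n <- prod(gd)
  D <- tensor_from_fa_md(0.7, 0.65e-3, c(0, 0, 1))
  sig <- predict_signal(D, 0.3, 1, sch)
  dwi <- array(rep(sig, each = n), c(gd, length(sch$bvals)))
  mask <- array(TRUE, gd)
  init <- list(f0 = rep(0.3, n),
               d6 = matrix(rep(fwtract:::tensor_to_d6(D), each = n), n),
               mask = mask, s0 = rep(1, n))
  fit <- fit_free_water(dwi, sch, mask, fw_fit_config(lambda = 0), init = init)
  expect_lt(max(abs(fit$fwf_map - 0.3)), 1e-3)
  expect_true(all(diff(fit$convergence$objective) <= 1e-9))
})

test_that("strong smoothing keeps an already-constant f map constant", {
  sch <- small_scheme(30)
  gd <- c(4L, 4L, 4L)
  n <- prod(gd)
  D <- tensor_from_fa_md(0.6, 0.65e-3, c(0, 1, 0))
  sig <- predict_signal(D, 0.4, 1, sch)
  dwi <- array(rep(sig, each = n), c(gd, length(sch$bvals)))
  mask <- array(TRUE, gd)
  fit <- fit_free_water(dwi, sch, mask, fw_fit_config(lambda = 100,
                                                      max_iter = 60))
  expect_lt(diff(range(fit$fwf_map)), 1e-3)
})

test_that("round-trip: fitted parameters reproduce the input signal", {
  sch <- small_scheme(30)
  ph <- block_phantom(gd = c(6L, 6L, 6L))
  dwi <- simulate_dwi(ph$fa, ph$md, ph$fwf, ph$direction, sch, snr = Inf)
  mask <- array(TRUE, ph$gd)
  fit <- fit_free_water(dwi, sch, mask, fw_fit_config(max_iter = 120))
  idx <- which(mask)
  nvox <- prod(ph$gd)
  worst <- 0
  for (k in c(1, 50, 150, 216)) {
    D <- fwtract:::d6_to_tensor(fit$tensor_d6[k, ])
    pred <- predict_signal(D, fit$fwf_map[idx[k]], fit$s0[k], sch)
    meas <- dwi$data[idx[k] + (seq_along(sch$bvals) - 1) * nvox]
    worst <- max(worst, max(abs(pred - meas)))
  }
  expect_lt(worst, 0.02)   # within the SNR-40 noise scale on unit s0
})

test_that("free-water correction raises FA where free water is substantial", {
  sch <- small_scheme(40)
  ph <- block_phantom(gd = c(8L, 8L, 8L), f_tissue = 0.05, f_edema = 0.45)
  dwi <- simulate_dwi(ph$fa, ph$md, ph$fwf, ph$direction, sch, snr = Inf)
  mask <- array(TRUE, ph$gd)
  fit <- fit_free_water(dwi, sch, mask, fw_fit_config(max_iter = 120))
  dti <- fit_dti(dwi, sch, mask)
  edema <- ph$fwf$data >= 0.3
  expect_true(mean(fit$fw_fa_map[edema]) > mean(dti$fa_map[edema]))
})

test_that("tidy and glance summarize a fit", {
  sch <- small_scheme(16)
  ph <- block_phantom(gd = c(4L, 4L, 4L))
  dwi <- simulate_dwi(ph$fa, ph$md, ph$fwf, ph$direction, sch, snr = Inf)
  mask <- array(TRUE, ph$gd)
  fit <- fit_free_water(dwi, sch, mask, fw_fit_config(max_iter = 10))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 64)
  expect_true(all(td$fwf >= 0 & td$fwf <= 1))
  gl <- glance(fit)
  expect_equal(gl$n_voxels, 64)
  expect_lte(gl$objective_final, gl$objective_initial)
})
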