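cfg_small <- cohort_config(
  n_subjects = c(glioblastoma = 1, astrocytoma = 1, oligodendroglioma = 1),
  seed = 7)

test_that("tumor compartments are nested with BraTS-style labels", {
  seg <- generate_tumor_segmentation(cfg_small, "left", "glioblastoma")
  labs <- sort(unique(as.vector(seg$data)))
  expect_true(all(labs %in% c(0L, 1L, 2L, 4L)))
  expect_true(all(c(1L, 2L, 4L) %in% labs))
  # nesting: every necrotic voxel sits inside the enhancing ellipsoid,
  # every labeled voxel inside the edema ellipsoid (exhaustive predicate)
  cfgn <- cfg_small
  cfgn$radii_mm$glioblastoma <- c(necrotic = 6, enhancing = 12, edema = 20)
  seg2 <- generate_tumor_segmentation(cfgn, "left", "glioblastoma")
  gw <- fwtract:::grid_world(dim(seg2$data), seg2$affine)
  ctr <- cfgn$tumor_center_mm; ax <- cfgn$axis_scale
  u <- function(r) ((gw$x - ctr[1]) / (r * ax[1]))^2 +
    ((gw$y - ctr[2]) / (r * ax[2]))^2 + ((gw$z - ctr[3]) / (r * ax[3]))^2
  expect_true(all(u(12)[seg2$data == 1L] <= 1 + 1e-9))
  expect_true(all(u(20)[seg2$data != 0L] <= 1 + 1e-9))
  # voxel-count nesting across every generated subject
  for (g in names(cfg_small$n_subjects)) {
    s <- generate_tumor_segmentation(cfg_small, "right", g)
    n_nec <- sum(s$data == 1L)
    n_tum <- sum(s$data %in% c(1L, 4L))
    n_all <- sum(s$data != 0L)
    expect_true(n_nec <= n_tum && n_tum <= n_all)
  }
})

test_that("non-enhancing tumors and degenerate nestings generate cleanly", {
  seg <- generate_tumor_segmentation(cfg_small, "left", "oligodendroglioma")
  expect_equal(sum(seg$data == 4L), 0)             # no enhancement
  expect_equal(sum(seg$data == 1L), 0)             # no necrotic core
  expect_gt(sum(seg$data == 2L), 0)
  expect_setequal(unique(as.vector(seg$data)), c(0L, 2L))
  # geometry error when the tumor cannot fit
  cfg_big <- cfg_small
  cfg_big$radii_mm$glioblastoma["edema"] <- 100
  expect_error(generate_tumor_segmentation(cfg_big, "left", "glioblastoma"),
               "outside the grid")
  expect_error(generate_tumor_segmentation(cfg_small, "right",
                                           "glioblastoma",
                                           center = c(-20, 0, 0)),
               "hemisphere")
})

test_that("irregular-blob segmentations preserve nesting and determinism", {
  cfgi <- cfg_small; cfgi$irregular <- TRUE
  s1 <- generate_tumor_segmentation(cfgi, "left", "glioblastoma", seed = 4)
  s2 <- generate_tumor_segmentation(cfgi, "left", "glioblastoma", seed = 4)
  expect_identical(s1$data, s2$data)
  s3 <- generate_tumor_segmentation(cfgi, "left", "glioblastoma", seed = 5)
  expect_false(identical(s1$data, s3$data))
  expect_true(sum(s1$data == 1L) <= sum(s1$data %in% c(1L, 4L)))
})

test_that("bundles mirror across the midsagittal plane and are seeded", {
  grid <- list(dim = c(64L, 64L, 64L), voxel_mm = 2)
  bl <- generate_bundle("bundle_a", "left", grid, 5, 2, seed = 8)
  br <- generate_bundle("bundle_a", "right", grid, 5, 2, seed = 8)
  for (k in seq_along(bl$streamlines)) {
    mirrored <- bl$streamlines[[k]]
    mirrored[, 1] <- -mirrored[, 1]
    expect_equal(br$streamlines[[k]], mirrored)
  }
  # degenerate: one streamline, zero spread reproduces the core
  b1 <- generate_bundle("bundle_a", "left", grid, 1, 0, seed = 0)
  core <- fwtract:::builtin_core("bundle_a")(seq(0, 1, length.out = 50))
  expect_equal(b1$streamlines[[1]], core)
  # determinism
  b2 <- generate_bundle("bundle_b", "left", grid, 5, 2, seed = 8)
  b3 <- generate_bundle("bundle_b", "left", grid, 5, 2, seed = 8)
  expect_identical(b2$streamlines, b3$streamlines)
  expect_error(generate_bundle("nope", "left", grid, 1, 0, 0), "Unknown")
})

test_that("metric fields inject the documented asymmetry structure", {
  cfg <- cfg_small
  seg <- generate_tumor_segmentation(cfg, "left", "glioblastoma")
  grid <- list(dim = cfg$grid_dim, voxel_mm = cfg$voxel_mm)
  bundle <- orient_bundle(generate_bundle("bundle_a", "left", grid,
                                          cfg$n_streamlines, cfg$spread_mm,
                                          seed = 2))
  inv <- node_involvement(bundle, seg, cfg$n_nodes)
  dists <- node_distance_to_margin(inv$combined, 5)
  expect_true(any(dists == 0, na.rm = TRUE))
  fields <- generate_metric_fields(seg, cfg, list(bundle), list(dists),
                                   peak_asymmetry = 0.05)
  # FWF elevated inside edema relative to contralateral white matter
  edema <- seg$data == 2L
  contra_wm <- array(FALSE, dim(seg$data))
  contra_wm[33:64, , ] <- TRUE
  expect_gt(mean(fields$fwf$data[edema]),
            mean(fields$fwf$data[contra_wm]))
  # at the margin (d = 0) FA is scaled by 1 + a exactly
  expect_equal(max(fields$fw_fa$data), cfg$baseline_fa * 1.05,
               tolerance = 1e-9)
  # MD perturbed with the opposite sign
  expect_equal(min(fields$fw_md$data), cfg$baseline_md * 0.95,
               tolerance = 1e-9)
  # zero injected asymmetry: FA field untouched everywhere
  f0 <- generate_metric_fields(seg, cfg, list(bundle), list(dists),
                               peak_asymmetry = 0)
  expect_true(all(f0$fw_fa$data == cfg$baseline_fa))
})

test_that("DWI simulation matches the forward model and is reproducible", {
  sch <- small_scheme(16)
  ph <- block_phantom(gd = c(5L, 5L, 5L))
  noiseless <- simulate_dwi(ph$fa, ph$md, ph$fwf, ph$direction, sch,
                            snr = Inf)
  D <- tensor_from_fa_md(ph$fa_true, ph$md_true, c(0, 0, 1))
  ref <- predict_signal(D, ph$f_tissue, 1, sch)
  expect_equal(noiseless$data[1, 1, 1, ], unname(ref), tolerance = 1e-12)
  # pure free water: weighted volumes at s0 * exp(-b * d_iso)
  fw1 <- fw_volume(array(1, c(5, 5, 5)), ph$affine)
  pure <- simulate_dwi(ph$fa, ph$md, fw1, ph$direction, sch, snr = Inf)
  expect_equal(unname(pure$data[2, 2, 2, which(sch$bvals > 0)]),
               rep(exp(-6), 16), tolerance = 1e-12)
  # seeded repeatability
  n1 <- simulate_dwi(ph$fa, ph$md, ph$fwf, ph$direction, sch, 40, seed = 5)
  n2 <- simulate_dwi(ph$fa, ph$md, ph$fwf, ph$direction, sch, 40, seed = 5)
  expect_identical(n1$data, n2$data)
  n3 <- simulate_dwi(ph$fa, ph$md, ph$fwf, ph$direction, sch, 40, seed = 6)
  expect_false(identical(n1$data, n3$data))
  bad_fa <- fw_volume(array(1.4, c(5, 5, 5)), ph$affine)
  expect_error(simulate_dwi(bad_fa, ph$md, ph$fwf, ph$direction, sch),
               "FA")
})

test_that("cohort bookkeeping: group sizes, seeds, manifest determinism", {
  cfg <- cohort_config(n_subjects = c(glioblastoma = 4, astrocytoma = 2,
                                      oligodendroglioma = 2), seed = 12)
  ch <- generate_cohort(cfg, keep_volumes = FALSE)
  expect_equal(nrow(ch$subjects), 8)
  expect_equal(sum(ch$subjects$pathology == "glioblastoma"), 4)
  expect_equal(sum(ch$subjects$pathology == "astrocytoma"), 2)
  expect_equal(sum(ch$subjects$pathology == "oligodendroglioma"), 2)
  expect_true(all(ch$subjects$tumor_hemisphere %in% c("left", "right")))
  ch2 <- generate_cohort(cfg, keep_volumes = FALSE)
  expect_identical(ch$subjects, ch2$subjects)
  # volume ordering: glioblastoma tumors largest in enhancing compartment
  mean_by <- tapply(ch$subjects$vol_prop_enhancing, ch$subjects$pathology,
                    mean)
  expect_gt(mean_by["glioblastoma"], mean_by["astrocytoma"])
  expect_equal(unname(mean_by["oligodendroglioma"]), 0)
})

test_that("mirror symmetry: zero asymmetry and zero variation give equal profiles", {
  cfg <- cohort_config(
    n_subjects = c(glioblastoma = 1, astrocytoma = 0, oligodendroglioma = 0),
    peak_asymmetry = c(glioblastoma = 0, astrocytoma = 0,
                       oligodendroglioma = 0),
    asymmetry_sd = 0, seed = 3)
  sub <- generate_subject(cfg, "s", "glioblastoma", 99)
  metrics <- sub$fields[c("fw_fa", "fw_md")]
  for (tn in c("bundle_a", "bundle_b")) {
    pl <- tract_profile(sub$bundles[[paste0(tn, "_left")]], metrics, NULL)
    pr <- tract_profile(sub$bundles[[paste0(tn, "_right")]], metrics, NULL)
    expect_lt(max(abs(pl$fw_fa - pr$fw_fa)), 1e-6)
    expect_lt(max(abs(pl$fw_md - pr$fw_md)), 1e-9)
  }
})

test_that("ground-truth FWF is higher inside edema than contralateral tissue", {
  cfg <- cfg_small
  sub <- generate_subject(cfg, "s", "glioblastoma", 5)
  seg <- sub$segmentation
  fwf <- sub$fields$fwf$data
  edema <- seg$data == 2L
  gw <- fwtract:::grid_world(dim(seg$data), seg$affine)
  contra <- if (sub$record$tumor_hemisphere == "left") gw$x > 0 else gw$x < 0
  expect_gt(mean(fwf[edema]), mean(fwf[contra]))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(snr = 0), "snr")
  expect_error(cohort_config(decay_nodes = -1), "decay_nodes")
  expect_error(cohort_config(
    radii_mm = list(glioblastoma = c(necrotic = 9, enhancing = 5, edema = 16),
                    astrocytoma = c(necrotic = 3, enhancing = 6, edema = 13),
                    oligodendroglioma = c(necrotic = 0, enhancing = 0,
                                          edema = 11))), "nested")
  expect_error(cohort_config(edema_fwf = 1.4), "0, 1")
})
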