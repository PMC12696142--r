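test_that("percent asymmetry matches the printed formula and its symmetries", {
  expect_equal(node_asymmetry(0.5, 0.5), 0)
  expect_equal(node_asymmetry(0.6, 0.4), 40)
  expect_equal(node_asymmetry(0.4, 0.6), -40)
  expect_true(is.na(node_asymmetry(0, 0)))
  expect_error(node_asymmetry(-0.1, 0.5), "non-negative")
  set.seed(7)
  a <- runif(500); b <- runif(500)
  A <- node_asymmetry(a, b)
  expect_equal(A, -node_asymmetry(b, a))                  # antisymmetry
  expect_true(all(abs(A) <= 200))                         # bounds
  expect_equal(node_asymmetry(3 * a, 3 * b), A)           # scale invariance
  expect_equal(node_asymmetry(a, a), rep(0, 500))
})

test_that("bilateral averaging handles missing homologues", {
  expect_equal(bilateral_group(0.2, 0.4), 0.3)
  expect_equal(bilateral_group(0.7, 0.7), 0.7)
  expect_equal(bilateral_group(0.1, NA), 0.1)
  expect_true(is.na(bilateral_group(NA_real_, NA_real_)))
})

test_that("subject involvement pools hemispheres and binarizes correctly", {
  mk <- function(fr_l, fr_r) {
    dplyr::bind_rows(
      make_profile("tA", "left", fw_fa = 0.5, combined = fr_l),
      make_profile("tA", "right", fw_fa = 0.5, combined = fr_r))
  }
  # no node above 5%
  s0 <- subject_involvement(mk(rep(0.03, 100), rep(0.05, 100)), 5)
  expect_true(all(!s0$involved[s0$compartment == "combined"]))
  expect_true(all(s0$proportion_involved[s0$compartment == "combined"] == 0))
  # exactly one node of 200 above threshold
  fr <- rep(0, 100); fr[40] <- 0.06
  s1 <- subject_involvement(mk(fr, rep(0, 100)), 5)
  cmb <- s1[s1$compartment == "combined", ]
  expect_true(cmb$involved)
  expect_equal(cmb$proportion_involved, 1 / 200)
  expect_equal(cmb$n_nodes_total, 200)
  # 10 left + 30 right involved of 200 -> 0.20
  fl <- rep(0, 100); fl[1:10] <- 0.5
  fr2 <- rep(0, 100); fr2[1:30] <- 0.5
  s2 <- subject_involvement(mk(fl, fr2), 5)
  expect_equal(s2$proportion_involved[s2$compartment == "combined"], 0.20)
})

test_that("involvement summaries match a brute-force recount", {
  set.seed(31)
  for (i in 1:25) {
    fr <- round(runif(60), 2)
    prof <- make_profile("t", "left", fw_fa = 0.5, combined = fr)
    th <- sample(c(1, 5, 10, 15), 1)
    s <- subject_involvement(prof, th)
    cmb <- s[s$compartment == "combined", ]
    brute <- sum(fr > th / 100)
    expect_equal(cmb$proportion_involved, brute / 60)
    expect_equal(cmb$involved, brute > 0)
  }
})

test_that("threshold sweep proportions are non-increasing", {
  set.seed(13)
  prof <- make_profile("t", "left", fw_fa = 0.5, combined = runif(100))
  sw <- threshold_sweep(prof, 1:15)
  by_tract <- split(sw[sw$compartment == "combined", ],
                    sw$tract[sw$compartment == "combined"])
  for (tb in by_tract) {
    tb <- tb[order(tb$threshold), ]
    expect_true(all(diff(tb$proportion_involved) <= 0))
  }
  expect_error(threshold_sweep(prof, c(-1, 5)), "0, 100")
})

test_that("contralateral mean pools nodes and excludes missing values", {
  prof <- dplyr::bind_rows(
    make_profile("tA", "left", fw_fa = 0.4),
    make_profile("tB", "left", fw_fa = 0.6),
    make_profile("tA", "right", fw_fa = 9))
  cm <- contralateral_mean(prof, tumor_hemisphere = "right",
                           metrics = "fw_fa")
  expect_equal(cm$value, 0.5)                      # (0.4 + 0.6) / 2 pooled
  expect_equal(cm$n_nodes, 200)
  # 3 missing nodes are excluded from the mean
  prof2 <- make_profile("tA", "left", fw_fa = rep(2, 100))
  prof2$fw_fa[c(5, 50, 95)] <- NA
  prof2$fw_fa[1] <- 4
  cm2 <- contralateral_mean(prof2, "right", "fw_fa")
  expect_equal(cm2$n_nodes, 97)
  expect_equal(cm2$value, (4 + 96 * 2) / 97)
  expect_warning(contralateral_mean(prof2, "left", "fw_fa"),
                 "No contralateral")
})

test_that("eligibility is strict at the threshold and respects missingness", {
  ip <- make_profile("t", "left", fw_fa = 0.5, combined = 0)
  co <- make_profile("t", "right", fw_fa = 0.5, combined = 0)
  expect_equal(eligible_node_pairs(ip, co, "fw_fa", 5), 1:100)
  ip2 <- ip; ip2$combined[7] <- 0.05               # exactly at 5%: excluded
  expect_false(7 %in% eligible_node_pairs(ip2, co, "fw_fa", 5))
  co2 <- co; co2$fw_fa[9] <- NA                    # missing pair: excluded
  expect_false(9 %in% eligible_node_pairs(ip, co2, "fw_fa", 5))
  expect_error(eligible_node_pairs(ip, co[1:50, ], "fw_fa", 5),
               "same number of nodes")
})

test_that("distance to margin equals the exhaustive double-loop oracle", {
  fr <- rep(0, 100); fr[40:60] <- 0.5
  d <- node_distance_to_margin(fr, 5)
  expect_equal(d[35], 5)
  expect_equal(d[10], 30)
  expect_equal(d[50], 0)
  expect_true(all(is.na(node_distance_to_margin(rep(0, 100), 5))))
  oracle <- function(fr, th) {
    inv <- which(fr > th / 100)
    if (length(inv) == 0) return(rep(NA_integer_, length(fr)))
    sapply(seq_along(fr), function(i) {
      best <- Inf
      for (j in inv) best <- min(best, abs(i - j))
      as.integer(best)
    })
  }
  set.seed(17)
  for (i in 1:50) {
    fr <- ifelse(runif(150) < 0.1, runif(150, 0.06, 1), 0)
    expect_identical(node_distance_to_margin(fr, 5), oracle(fr, 5))
  }
})

test_that("distance bins follow the printed segments", {
  bins <- asym_distance_bins()
  expect_equal(fwtract:::assign_segment(c(1, 5, 6, 10, 11, 16, 20, 21, 99),
                                        bins),
               c("1-5", "1-5", "6-10", "6-10", "11-15", "16-20", "16-20",
                 ">=21", ">=21"))
  bad <- bins; bad$lo[2] <- 4                      # overlapping bins
  expect_error(fwtract:::validate_bins(bad), "overlap")
  gap <- bins; gap$lo[2] <- 7
  expect_error(fwtract:::validate_bins(gap), "partition")
})

test_that("whole-tract asymmetry uses two-stage, not pooled, averaging", {
  # tract A: 2 eligible nodes at +10%; tract B: 50 eligible nodes at +1%
  ipsiA <- make_profile("A", "left", fw_fa = 1, combined = 1)
  ipsiA$fw_fa[1:2] <- ipsi_for_asym(10)
  ipsiA$combined[1:2] <- 0
  contraA <- make_profile("A", "right", fw_fa = 1, combined = 0)
  ipsiB <- make_profile("B", "left", fw_fa = 1, combined = 1)
  ipsiB$fw_fa[1:50] <- ipsi_for_asym(1)
  ipsiB$combined[1:50] <- 0
  contraB <- make_profile("B", "right", fw_fa = 1, combined = 0)
  prof <- dplyr::bind_rows(ipsiA, contraA, ipsiB, contraB)
  two_stage <- whole_tract_asymmetry(prof, "left", metrics = "fw_fa")
  expect_equal(two_stage$asymmetry, 5.5, tolerance = 1e-10)
  pooled <- whole_tract_asymmetry(prof, "left", metrics = "fw_fa",
                                  pooled = TRUE)
  expect_equal(pooled$asymmetry, (2 * 10 + 50 * 1) / 52, tolerance = 1e-10)
  # two tracts with per-tract means +10 and -10 cancel
  ipsiC <- make_profile("C", "left", fw_fa = ipsi_for_asym(-10), combined = 0)
  contraC <- make_profile("C", "right", fw_fa = 1, combined = 0)
  ipsiD <- make_profile("D", "left", fw_fa = ipsi_for_asym(10), combined = 0)
  contraD <- make_profile("D", "right", fw_fa = 1, combined = 0)
  prof2 <- dplyr::bind_rows(ipsiC, contraC, ipsiD, contraD)
  expect_equal(whole_tract_asymmetry(prof2, "left",
                                     metrics = "fw_fa")$asymmetry, 0,
               tolerance = 1e-10)
  # perfectly symmetric subject: exactly zero
  sym <- dplyr::bind_rows(make_profile("A", "left", fw_fa = 0.47),
                          make_profile("A", "right", fw_fa = 0.47))
  expect_equal(whole_tract_asymmetry(sym, "left",
                                     metrics = "fw_fa")$asymmetry, 0)
})

test_that("distance-binned asymmetry groups eligible nodes by segment", {
  # involved nodes 48..52; node k at distance |k - nearest involved|
  fr <- rep(0, 100); fr[48:52] <- 0.5
  ipsi <- make_profile("A", "left", fw_fa = 1, combined = fr)
  asym_by_node <- numeric(100)
  d <- node_distance_to_margin(fr, 5)
  asym_by_node[d >= 1 & d <= 5] <- 10
  asym_by_node[d >= 6] <- 2
  ipsi$fw_fa <- ipsi_for_asym(asym_by_node)
  contra <- make_profile("A", "right", fw_fa = 1, combined = 0)
  prof <- dplyr::bind_rows(ipsi, contra)
  db <- distance_binned_asymmetry(prof, "left", metrics = "fw_fa")
  expect_equal(db$asymmetry[db$segment == "1-5"], 10, tolerance = 1e-10)
  expect_equal(db$asymmetry[db$segment == ">=21"], 2, tolerance = 1e-10)
  # a tract with no involved nodes is excluded by default
  prof_no <- dplyr::bind_rows(
    make_profile("B", "left", fw_fa = ipsi_for_asym(10), combined = 0),
    make_profile("B", "right", fw_fa = 1, combined = 0))
  db0 <- distance_binned_asymmetry(prof_no, "left", metrics = "fw_fa")
  expect_true(all(is.na(db0$asymmetry)))
  # ...or assigned to the most distal segment on request
  db1 <- distance_binned_asymmetry(prof_no, "left", metrics = "fw_fa",
                                   uninvolved = "distal")
  expect_equal(db1$asymmetry[db1$segment == ">=21"], 10, tolerance = 1e-10)
  expect_true(all(is.na(db1$asymmetry[db1$segment != ">=21"])))
})

test_that("subjects with all nodes proximal leave distal segments empty", {
  fr <- rep(0.5, 100); fr[1:5] <- 0                # involved except nodes 1-5
  ipsi <- make_profile("A", "left", fw_fa = ipsi_for_asym(3), combined = fr)
  contra <- make_profile("A", "right", fw_fa = 1, combined = 0)
  db <- distance_binned_asymmetry(dplyr::bind_rows(ipsi, contra), "left",
                                  metrics = "fw_fa")
  expect_false(is.na(db$asymmetry[db$segment == "1-5"]))
  expect_true(all(is.na(db$asymmetry[db$segment != "1-5"])))
})
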