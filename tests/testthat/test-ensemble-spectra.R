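make_desc <- function(classes, osc = NULL, energy = NULL) {
  n <- length(classes)
  if (is.null(osc)) osc <- rep(0.1, n)
  if (is.null(energy)) energy <- seq(3, 5, length.out = n)
  arch <- list(monomer = c(1, 0, 0, 0), exciton = c(0.5, 0, 0, 0.5),
               excimer = c(0.5, 0, 0.5, 0),
               charge_transfer = c(0, 0, 1, 0))
  om <- t(vapply(classes, function(cl) arch[[cl]], numeric(4)))
  colnames(om) <- c("om_1_1", "om_1_2", "om_2_1", "om_2_2")
  rec <- cbind(data.frame(frame = seq_len(n) - 1L, state = 1L,
                          energy_ev = energy, osc = osc),
               as.data.frame(om))
  analyze_records(rec)
}

test_that("DOS class fractions are state-count percentages", {
  d <- make_desc(rep("monomer", 8))
  expect_equal(as.numeric(class_fractions(d)), c(100, 0, 0, 0))

  d2 <- make_desc(c("monomer", "charge_transfer"))
  expect_equal(as.numeric(class_fractions(d2)), c(50, 0, 0, 50))
  expect_equal(sum(class_fractions(d2)), 100)
  expect_error(class_fractions(d2[0, ]), "empty")
})

test_that("spectrum fractions weight states by oscillator strength", {
  # dark CT states vanish from the spectrum
  d <- make_desc(c("monomer", "monomer", "charge_transfer"),
                 osc = c(0.2, 0.2, 0))
  fr <- intensity_fractions(d)
  expect_equal(unname(fr["charge_transfer"]), 0)
  expect_equal(sum(fr), 100)

  # equal strengths: spectrum fractions collapse onto DOS fractions
  d2 <- make_desc(c("monomer", "excimer", "excimer", "charge_transfer"),
                  osc = rep(0.3, 4))
  expect_equal(as.numeric(intensity_fractions(d2)),
               as.numeric(class_fractions(d2)))

  d3 <- make_desc(c("monomer", "charge_transfer"), osc = c(0.9, 0.1))
  expect_equal(as.numeric(intensity_fractions(d3)), c(90, 0, 0, 10))

  d0 <- make_desc(c("monomer", "monomer"), osc = c(0, 0))
  expect_error(intensity_fractions(d0), "zero")
})

test_that("broadened curves integrate correctly and are additive", {
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  d1 <- make_desc("monomer", energy = 4.0)
  g <- energy_grid(4 - 5 * 0.3, 4 + 5 * 0.3, n_points = 2001, fwhm = 0.3)
  dec1 <- broadened_decomposition(d1, g, weighting = "count")
  expect_equal(trap(dec1$energy, dec1$curves$total), 1, tolerance = 1e-6)

  # two identical states double the curve
  d2 <- make_desc(c("monomer", "monomer"), energy = c(4, 4))
  dec2 <- broadened_decomposition(d2, g, weighting = "count")
  expect_equal(dec2$curves$total, 2 * dec1$curves$total, tolerance = 1e-12)

  # class curves sum pointwise to the total, both weightings
  e <- make_ensemble(n_frames = 40, n_states_per_frame = 10, seed = 17)
  desc <- analyze_records(e$records)
  gg <- energy_grid(1, 8, n_points = 501, fwhm = 0.3)
  for (w in c("count", "oscillator")) {
    dec <- broadened_decomposition(desc, gg, weighting = w)
    resum <- rowSums(dec$curves[state_classes()])
    expect_equal(resum, dec$curves$total, tolerance = 1e-8)
  }
  # DOS curve integrates to the number of states on a covering grid
  dec_dos <- broadened_decomposition(desc, gg, weighting = "count")
  expect_equal(trap(dec_dos$energy, dec_dos$curves$total), 400,
               tolerance = 0.1)

  expect_warning(
    broadened_decomposition(desc, energy_grid(3, 4, fwhm = 0.3)),
    "does not cover")
  expect_error(energy_grid(1, 8, fwhm = 0), "fwhm")
})

test_that("CTN/DL_av map has unit mass and threshold-quadrant consistency", {
  d1 <- make_desc(rep("monomer", 5))
  m1 <- ctn_dlav_map(d1)
  expect_equal(sum(m1$mass), 1, tolerance = 1e-12)
  expect_equal(sum(m1$mass > 0), 1)

  e <- make_ensemble(n_frames = 100, n_states_per_frame = 10, seed = 18,
                     mixing_noise = 0.08)
  desc <- analyze_records(e$records)
  m <- ctn_dlav_map(desc)  # 0.05 bins include 1.25, 0.2 and 0.8
  expect_equal(sum(m$mass), 1, tolerance = 1e-12)
  dl_mid <- (m$dl_breaks[-1] + head(m$dl_breaks, -1)) / 2
  ct_mid <- (m$ctn_breaks[-1] + head(m$ctn_breaks, -1)) / 2
  quad <- function(dl_lo, dl_hi, ct_lo, ct_hi)
    100 * sum(m$mass[dl_mid > dl_lo & dl_mid < dl_hi,
                     ct_mid > ct_lo & ct_mid < ct_hi])
  fr <- class_fractions(desc)
  expect_equal(quad(1, 1.25, 0, 0.2), unname(fr["monomer"]),
               tolerance = 1e-10)
  expect_equal(quad(1.25, 2, 0, 0.2), unname(fr["exciton"]),
               tolerance = 1e-10)
  expect_equal(quad(1, 2, 0.2, 0.8), unname(fr["excimer"]),
               tolerance = 1e-10)
  expect_equal(quad(1, 2, 0.8, 1), unname(fr["charge_transfer"]),
               tolerance = 1e-10)
})

test_that("POS distributions localize hole and electron as generated", {
  e <- make_ensemble(class_fractions = c(0.5, 0, 0, 0.5), n_frames = 60,
                     n_states_per_frame = 10, seed = 19,
                     ct_direction_prob = 1, mixing_noise = 0.05)
  desc <- analyze_records(e$records)
  # CT states: hole on guanine (fragment 2), electron on the PS (fragment 1)
  ct <- pos_distributions(desc, "charge_transfer")
  expect_false(ct$empty)
  expect_gt(sum(ct$pos_i$mass[ct$pos_i$lo >= 1.8]), 0.9)
  expect_gt(sum(ct$pos_f$mass[ct$pos_f$hi <= 1.2]), 0.9)
  # monomer states peak on fragment 1 for both carriers
  mono <- pos_distributions(desc, "monomer")
  expect_gt(sum(mono$pos_i$mass[mono$pos_i$hi <= 1.2]), 0.9)
  expect_gt(sum(mono$pos_f$mass[mono$pos_f$hi <= 1.2]), 0.9)
  expect_equal(sum(ct$pos_i$mass), 1, tolerance = 1e-12)
  # an empty class is flagged, with zero-mass histograms
  exc <- pos_distributions(desc, "exciton")
  expect_true(exc$empty)
  expect_equal(sum(exc$pos_i$mass), 0)
})

test_that("nearest-ion distance matches a brute-force minimum", {
  d <- make_stacked_dimer(20, ion_positions = rbind(c(50, 0, 0)))
  com <- center_of_mass(d$structure, d$fm$qm_region)
  d1 <- make_stacked_dimer(20, ion_positions = rbind(com + c(3, 0, 0)))
  expect_equal(nearest_ion_distance(d1$structure, d1$fm), 3, tolerance = 1e-10)

  d2 <- make_stacked_dimer(20, ion_positions = rbind(com + c(0, 5, 0),
                                                     com + c(0, 0, 2)))
  expect_equal(nearest_ion_distance(d2$structure, d2$fm), 2, tolerance = 1e-10)

  set.seed(20)
  for (k in 1:10) {
    ions <- matrix(rnorm(15, sd = 10), 5, 3)
    dk <- make_stacked_dimer(20, ion_positions = ions)
    comk <- center_of_mass(dk$structure, dk$fm$qm_region)
    brute <- min(apply(ions, 1, function(p) sqrt(sum((p - comk)^2))))
    expect_equal(nearest_ion_distance(dk$structure, dk$fm), brute,
                 tolerance = 1e-10)
  }
  d3 <- make_stacked_dimer(20)
  expect_error(nearest_ion_distance(d3$structure, d3$fm), "no ions")
})

test_that("binned trends equal a direct group-by mean", {
  bt <- binned_trend(c(0.5, 1.5, 2.5), rep(0.4, 3), bin_edges = 0:3)
  expect_equal(bt$mean, rep(0.4, 3))

  x <- seq(0.5, 9.5, by = 1)
  bt2 <- binned_trend(x, x, bin_edges = 0:10)
  expect_equal(bt2$mean, x)
  expect_equal(bt2$count, rep(1L, 10))

  set.seed(22)
  xr <- runif(300, 0, 20)
  yr <- runif(300)
  btr <- binned_trend(xr, yr)
  grp <- findInterval(xr, 0:20, rightmost.closed = TRUE)
  for (b in unique(grp))
    expect_equal(btr$mean[b], mean(yr[grp == b]), tolerance = 1e-12)
  expect_equal(sum(btr$count), 300)

  expect_error(binned_trend(1:3, 1:2), "equal length")
})

test_that("model comparison aligns class fractions and reports differences", {
  e1 <- make_ensemble(c(0.4, 0.05, 0.25, 0.3), n_frames = 80,
                      n_states_per_frame = 10, seed = 23)
  e2 <- make_ensemble(c(0.6, 0.05, 0.25, 0.1), n_frames = 80,
                      n_states_per_frame = 10, seed = 24)
  d1 <- analyze_records(e1$records)
  d2 <- analyze_records(e2$records)

  same <- compare_models(list(full = d1, strand = d1))
  expect_equal(unname(same$differences[2, ]), rep(0, 4))

  cmp <- compare_models(list(full = d1, vacuum = d2))
  expect_lt(cmp$differences["vacuum", "charge_transfer"], 0)
  expect_equal(unname(rowSums(cmp$fractions)), c(100, 100))

  three <- compare_models(list(a = d1, b = d2, c = d1))
  expect_equal(dim(three$fractions), c(3, 4))
  expect_equal(unname(rowSums(three$fractions)), rep(100, 3))

  expect_error(compare_models(list(d1)), "at least 2")
})
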