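test_that("Omega normalization divides by the element sum and is idempotent", {
  om <- normalize_omega(matrix(c(2, 0, 0, 0), 2, 2))
  expect_equal(unclass(om)[1:4], c(1, 0, 0, 0))
  expect_equal(attr(om, "raw_norm"), 2)

  already <- matrix(c(0.3, 0.1, 0.2, 0.4), 2, 2)  # column-major: sums to 1
  om2 <- normalize_omega(already)
  expect_equal(as.vector(om2), as.vector(already))
  expect_equal(attr(om2, "raw_norm"), 1)

  expect_error(normalize_omega(matrix(0, 2, 2)), "all zero")
  expect_error(normalize_omega(matrix(c(-1, 1, 1, 1), 2, 2)), "nonnegative")
})

test_that("hole/electron populations are the Omega row and column sums", {
  loc <- normalize_omega(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(hole_populations(loc), c(1, 0))
  expect_equal(electron_populations(loc), c(1, 0))

  ct <- normalize_omega(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(hole_populations(ct), c(1, 0))
  expect_equal(electron_populations(ct), c(0, 1))

  mixed <- normalize_omega(matrix(c(0.3, 0.2, 0.1, 0.4), 2, 2, byrow = TRUE))
  expect_equal(hole_populations(mixed), c(0.5, 0.5))
  expect_equal(electron_populations(mixed), c(0.4, 0.6))
})

test_that("participation ratio, DL_av, CTN and POS match their closed forms", {
  expect_equal(participation_ratio(c(1, 0)), 1)
  expect_equal(participation_ratio(c(0.5, 0.5)), 2)
  expect_equal(participation_ratio(c(0.8, 0.2)), 1 / 0.68)
  expect_error(participation_ratio(c(0.5, 0.4)), "sum to 1")

  mono <- normalize_omega(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
  exc <- normalize_omega(diag(c(0.5, 0.5)))
  mixed <- normalize_omega(matrix(c(0.3, 0.2, 0.1, 0.4), 2, 2, byrow = TRUE))
  expect_equal(dl_av(mono), 1)
  expect_equal(dl_av(exc), 2)
  expect_equal(dl_av(mixed), (2 + 1 / 0.52) / 2)

  ctmat <- normalize_omega(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(ctn(exc), 0)
  expect_equal(ctn(ctmat), 1)
  expect_equal(ctn(mixed), 0.3)

  expect_equal(pos(c(0, 1)), 2)
  expect_equal(pos(c(0.5, 0.5)), 1.5)
  expect_equal(pos(c(0.9, 0.1)), 1.1)
})

test_that("classification follows the DL_av/CTN thresholds with CT precedence", {
  expect_equal(classify_state(1.0, 0.0), "monomer")
  expect_equal(classify_state(1.5, 0.5), "excimer")
  expect_equal(classify_state(1.05, 0.95), "charge_transfer")
  expect_equal(classify_state(1.5, 0.05), "exciton")
  # boundary conventions
  expect_equal(classify_state(1.25, 0.1), "exciton")    # strict < for monomer
  expect_equal(classify_state(1.1, 0.2), "excimer")     # 0.2 inclusive
  expect_equal(classify_state(1.9, 0.8), "excimer")     # 0.8 inclusive
  expect_equal(classify_state(1.1, 0.5), "excimer")     # low-DL, mid-CTN corner
  expect_error(classify_state(0.5, 0.1), "out of range")
  expect_error(classify_state(1.5, 1.2), "out of range")
})

test_that("classification truth table is total over the descriptor domain", {
  grid <- expand.grid(dl = seq(1, 2, by = 0.01), ct = seq(0, 1, by = 0.01))
  lab <- classify_state(grid$dl, grid$ct)
  expect_true(all(lab %in% state_classes()))
  expect_false(anyNA(lab))
})

test_that("descriptors match the brute-force oracle on random Omega matrices", {
  set.seed(12)
  for (k in 1:200) {
    N <- sample(2:3, 1)
    raw <- matrix(runif(N * N), N, N)
    om <- normalize_omega(raw)
    o <- oracle_descriptors(raw)
    expect_equal(unname(hole_populations(om)), o$hole, tolerance = 1e-12)
    expect_equal(unname(electron_populations(om)), o$elec,
                 tolerance = 1e-12)
    expect_equal(dl_av(om), o$dl, tolerance = 1e-12)
    expect_equal(ctn(om), o$ctn, tolerance = 1e-12)
    expect_equal(pos(hole_populations(om)), o$pos_i, tolerance = 1e-12)
    expect_equal(pos(electron_populations(om)), o$pos_f, tolerance = 1e-12)
  }
})

test_that("fragment permutation leaves DL_av/CTN invariant, permutes POS", {
  set.seed(13)
  for (k in 1:20) {
    raw <- matrix(runif(4), 2, 2)
    om <- normalize_omega(raw)
    perm <- normalize_omega(raw[2:1, 2:1])
    expect_equal(dl_av(perm), dl_av(om), tolerance = 1e-12)
    expect_equal(ctn(perm), ctn(om), tolerance = 1e-12)
    expect_equal(unname(hole_populations(perm)),
                 unname(hole_populations(om))[2:1], tolerance = 1e-12)
    expect_equal(pos(hole_populations(perm)),
                 3 - pos(hole_populations(om)), tolerance = 1e-12)
  }
})

test_that("ensemble characterization keeps identifiers and flags bad rows", {
  e <- make_ensemble(n_frames = 20, n_states_per_frame = 10, seed = 14,
                     mixing_noise = 0)
  desc <- analyze_records(e$records)
  expect_equal(nrow(desc), 200)
  expect_true(all(desc$status == "ok"))
  # zero-noise archetypes classify exactly as their generating labels
  expect_equal(desc$class, e$truth$class)

  bad <- e$records
  bad[3, grep("^om_", names(bad))] <- 0
  desc_bad <- analyze_records(bad)
  expect_equal(nrow(desc_bad), 200)
  expect_match(desc_bad$status[3], "zero")
  expect_true(is.na(desc_bad$dl_av[3]))
  expect_equal(sum(desc_bad$status == "ok"), 199)

  empty <- e$records[0, ]
  expect_equal(nrow(analyze_records(empty)), 0)
})

test_that("state tables round-trip through the TSV dialect", {
  e <- make_ensemble(n_frames = 5, n_states_per_frame = 4, seed = 15,
                     model = "full")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_state_table(e$records, path)
  back <- read_state_table(path)
  expect_equal(back$energy_ev, e$records$energy_ev, tolerance = 1e-12)
  expect_equal(back$om_2_1, e$records$om_2_1, tolerance = 1e-12)
  expect_equal(back$model, e$records$model)

  # header-only file parses to an empty ensemble
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("frame\tstate\tenergy_ev\tosc\tom_1_1\tom_1_2\tom_2_1\tom_2_2",
             path2)
  expect_equal(nrow(read_state_table(path2)), 0)

  # malformed rows are reported with their line number
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("frame\tstate\tenergy_ev\tosc\tom_1_1\tom_1_2\tom_2_1\tom_2_2",
               "0\t1\t4.0\t0.1\t1\t0\t0\t0",
               "0\t2\t4.1\tx\t1\t0\t0\t0"), path3)
  expect_error(read_state_table(path3), "line 3")
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("frame\tstate\tenergy_ev\tosc\tom_1_1\tom_1_2\tom_2_1\tom_2_2",
               "0\t1\t4.0\t0.1\t1\t0\t-0.2\t0"), path4)
  expect_error(read_state_table(path4), "negative Omega")
})

test_that("descriptor bounds and conservation hold on random states", {
  set.seed(16)
  for (k in 1:500) {
    N <- sample(2:3, 1)
    om <- normalize_omega(matrix(runif(N * N), N, N))
    hp <- hole_populations(om)
    ep <- electron_populations(om)
    expect_equal(sum(hp), 1, tolerance = 1e-10)
    expect_equal(sum(ep), 1, tolerance = 1e-10)
    expect_true(participation_ratio(hp) >= 1 - 1e-12 &&
                  participation_ratio(hp) <= N + 1e-12)
    expect_true(ctn(om) >= -1e-12 && ctn(om) <= 1 + 1e-12)
    expect_true(pos(hp) >= 1 - 1e-12 && pos(hp) <= N + 1e-12)
  }
})
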