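test_that("make_dilution_series spans printed endpoints with constant ratio", {
  d <- make_dilution_series(2.0, 0.0156, 32)
  expect_length(d$values, 32)
  expect_equal(d$values[1], 2.0)
  expect_equal(d$values[32], 0.0156)
  ratios <- d$values[-1] / d$values[-32]
  expect_equal(ratios, rep((0.0156 / 2)^(1 / 31), 31), tolerance = 1e-9)
  expect_true(all(diff(d$values) < 0))

  expect_equal(make_dilution_series(8, 1, 4)$values, c(8, 4, 2, 1))
  expect_error(make_dilution_series(1, 1, 2), class = "qpid_invalid_argument")
  expect_error(make_dilution_series(-1, -2, 4), class = "qpid_invalid_argument")
  expect_error(make_dilution_series(2, 1, 1), class = "qpid_invalid_argument")
})

test_that("solve_equilibrium closed form matches hand cases and bisection", {
  expect_equal(solve_equilibrium(2, 0, 1)$bound, 0)
  expect_equal(solve_equilibrium(2, 0, 1)$free, 2)
  expect_equal(solve_equilibrium(1, 1, 1)$bound, (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  # stoichiometric limit kd -> 0
  eq <- solve_equilibrium(1, 1, 1e-12)
  expect_equal(eq$bound, 1, tolerance = 1e-5)
  expect_error(solve_equilibrium(-1, 1, 1), class = "qpid_invalid_argument")
  expect_error(solve_equilibrium(1, 1, 0), class = "qpid_invalid_argument")

  grid <- expand.grid(D = c(0.01, 0.1, 1, 10), P = c(0.01, 0.1, 1, 10),
                      K = c(1e-3, 0.05, 1, 10, 100))
  for (i in seq_len(nrow(grid))) {
    eq <- solve_equilibrium(grid$D[i], grid$P[i], grid$K[i])
    or <- bisect_equilibrium(grid$D[i], grid$P[i], grid$K[i])
    expect_equal(eq$bound, or$bound, tolerance = 1e-10)
    # mass conservation and the mass-action relation itself
    expect_equal(eq$bound + eq$free, grid$D[i], tolerance = 1e-12)
    expect_equal(eq$bound * grid$K[i],
                 eq$free * (grid$P[i] - eq$bound), tolerance = 1e-9)
  }
})

test_that("occupancy is monotone in total DNA at fixed kd", {
  d <- seq(0.01, 10, length.out = 50)
  for (kd in c(0.01, 1, 50)) {
    eq <- solve_equilibrium(d, 0.1, kd)
    expect_true(all(diff(eq$bound) > -1e-12))
    expect_true(all(diff(eq$free) > 0))
  }
})

test_that("chip layouts satisfy the coverage invariants", {
  ly <- chip_layout("four-section")
  cm <- ly$cell_map
  expect_equal(nrow(cm), 4096)
  expect_equal(sort(unique(cm$section)), 1:4)
  for (s in 1:4) {
    sec <- cm[cm$section == s, ]
    expect_equal(nrow(sec), 1024)
    expect_equal(length(unique(sec$protein)), 1L)
    # each (oligo, dilution) pair exactly once per section
    expect_equal(anyDuplicated(paste(sec$oligo, sec$dilution)), 0L)
    expect_equal(length(unique(sec$oligo)), 32L)
    expect_equal(length(unique(sec$dilution)), 32L)
  }

  wc <- chip_layout("whole-chip")$cell_map
  expect_equal(nrow(wc), 4096)
  expect_equal(anyDuplicated(paste(wc$oligo, wc$dilution)), 0L)
  expect_equal(length(unique(wc$oligo)), 128L)
  expect_equal(anyDuplicated(paste(wc$row, wc$col)), 0L)
})

test_that("simulate_chip is deterministic and validates truths", {
  ly <- chip_layout(proteins = paste0("P", 1:4), oligos = paste0("o", 1:32))
  truths <- expand.grid(protein = paste0("P", 1:4), oligo = paste0("o", 1:32),
                        stringsAsFactors = FALSE)
  truths$kd_uM <- 1
  s1 <- simulate_chip(ly, truths, noise = noise_spec(seed = 11))
  s2 <- simulate_chip(ly, truths, noise = noise_spec(seed = 11))
  expect_identical(s1, s2)
  s3 <- simulate_chip(ly, truths, noise = noise_spec(seed = 12))
  expect_false(identical(s1, s3))
  expect_true(all(s1$chamber_dna >= 0 & s1$button_dna >= 0 &
                    s1$button_protein >= 0))

  expect_error(simulate_chip(ly, truths[-1, ], noise = noise_spec(seed = 1)),
               class = "qpid_configuration")
})

test_that("noiseless chip round-trips the planted kd through the full fit", {
  ly <- chip_layout(proteins = paste0("P", 1:4), oligos = paste0("o", 1:32))
  truths <- expand.grid(protein = paste0("P", 1:4), oligo = paste0("o", 1:32),
                        stringsAsFactors = FALSE)
  truths$kd_uM <- rep(c(0.05, 0.5, 5, 20), length.out = nrow(truths))
  quiet <- noise_spec(protein_cv_range = c(0, 0), snr = Inf,
                      intensity_cv = 0, seed = 1)
  scan <- simulate_chip(ly, truths, noise = quiet)
  curve <- fit_calibration(
    simulate_calibration_series(calibration_curve(35579, 0), cv = 0, seed = 1))
  occ <- quantify_scan(scan, curve)
  agg <- aggregate_replicates(occ)
  kd <- fit_all_kd(assemble_series(agg))
  m <- merge(kd, truths, by = c("protein", "oligo"))
  expect_true(all(m$status == "quantitative"))
  expect_equal(m$kd_uM.x, m$kd_uM.y, tolerance = 1e-5)
})

test_that("mass conservation holds inside the simulator", {
  # with spotting noise but clean channels, chamber + button DNA signals
  # recover the perturbed totals: (free + bound) * slope = D_total * slope
  ly <- chip_layout(proteins = paste0("P", 1:4), oligos = paste0("o", 1:32))
  truths <- expand.grid(protein = paste0("P", 1:4), oligo = paste0("o", 1:32),
                        stringsAsFactors = FALSE)
  truths$kd_uM <- 0.3
  ns <- noise_spec(protein_cv_range = c(0, 0), snr = Inf, intensity_cv = 0.2,
                   seed = 5)
  scan <- simulate_chip(ly, truths, noise = ns)
  total <- (scan$chamber_dna + scan$button_dna) / 35579
  expect_true(all(total > 0))
  # totals deviate from the nominal series only by the multiplicative noise
  nominal <- make_dilution_series()$values[scan$dilution]
  expect_true(all(abs(total / nominal - 1) < 5 * 0.2 + 1e-9))
})

test_that("calibration series simulation is seeded and on the line", {
  p1 <- simulate_calibration_series(seed = 3)
  p2 <- simulate_calibration_series(seed = 3)
  expect_identical(p1, p2)
  exact <- simulate_calibration_series(cv = 0, seed = 1)
  expect_equal(exact$intensity, 35579 * exact$conc_uM - 1471, tolerance = 1e-12)
  expect_equal(nrow(exact), 128L)
  expect_true(all(exact$conc_uM >= 0.005 - 1e-12 & exact$conc_uM <= 1 + 1e-12))
})
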