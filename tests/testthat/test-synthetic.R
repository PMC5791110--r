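test_that("water boxes are seed-deterministic with no close oxygen pairs", {
  expect_identical(make_water_box(0, 20), list())
  ws <- make_water_box(100, 30, seed = 4)
  ws2 <- make_water_box(100, 30, seed = 4)
  expect_equal(length(ws), 100)
  expect_identical(lapply(ws, coords), lapply(ws2, coords))
  O <- t(vapply(ws, function(w) coords(w)[1, ], numeric(3)))
  D <- hydrosieve:::.pbc_cdist(O, O, rep(30, 3))
  diag(D) <- Inf
  expect_gte(min(D), 2.4)
  # internal geometry is rigid
  for (w in ws[1:5]) {
    expect_equal(dist(coords(w))[1], 0.9572, tolerance = 1e-6)
  }
  expect_error(make_water_box(1e6, 10), "infeasible")
})

test_that("noiseless designs reproduce the generating model exactly", {
  pts <- doe_design_table()[, c("coded_A", "coded_B")]
  b <- c(98.6, 2.66, 2.53, -2.70)
  d0 <- make_noisy_design(b, pts, noise_sd = 0, seed = 1)
  hand <- b[1] + b[2] * pts$coded_A + b[3] * pts$coded_B +
    b[4] * pts$coded_A * pts$coded_B
  expect_equal(d0$response, hand, tolerance = 1e-12)
  fit <- fit_interaction_model(d0)
  expect_equal(unname(fit$coefficients), b, tolerance = 1e-9)
  expect_equal(fit$r_squared, 100, tolerance = 1e-9)
  # determinism and error paths
  d1 <- make_noisy_design(b, pts, noise_sd = 1, seed = 7)
  d2 <- make_noisy_design(b, pts, noise_sd = 1, seed = 7)
  expect_identical(d1$response, d2$response)
  expect_error(make_noisy_design(b, pts, noise_sd = -1), "non-negative")
  expect_error(make_noisy_design(b, pts[1:3, ], 0), "at least 5")
})

test_that("planted trajectories are recovered exactly by the analyzers", {
  gel <- build_pva_chain(6, tacticity_seed = 2)
  traj <- make_planted_trajectory(
    gel, n_frames = 4, n_dmt = 5,
    capture_schedule = c(0, 40, 80, 100),
    water_schedule = c(0L, 3L, 7L, 2L),
    hbond_schedule = c(0L, 1L, 2L, 0L),
    n_far_waters = 4L, box = 60, com_radius = 12, seed = 9)
  res <- analyze_trajectory(traj,
                            observables = c("capture", "waters",
                                            "hbonds"),
                            params = list(com_radius = 12))
  cap <- res$value[res$observable == "capture"]
  expect_equal(cap, c(0, 40, 80, 100))
  expect_equal(res$value[res$observable == "waters"], c(0, 3, 7, 2))
  expect_equal(res$value[res$observable == "hbonds"], c(0, 1, 2, 0))
  expect_equal(attr(res, "first_full_capture_ns"), traj$times[4])
  # all-zero schedule stays at zero
  t0 <- make_planted_trajectory(gel, n_frames = 2, n_dmt = 5,
                                box = 60, seed = 2)
  r0 <- analyze_trajectory(t0, observables = "capture")
  expect_equal(r0$value, c(0, 0))
  expect_true(is.na(attr(r0, "first_full_capture_ns")))
})

test_that("a planted capture ramp is recovered frame-exactly", {
  gel <- build_pva_chain(4, tacticity_seed = 1)
  ramp <- seq(0, 100, by = 20)
  traj <- make_planted_trajectory(gel, n_frames = length(ramp),
                                  n_dmt = 10, capture_schedule = ramp,
                                  box = 70, seed = 13)
  res <- analyze_trajectory(traj, observables = "capture")
  expect_equal(res$value[res$observable == "capture"], ramp)
  expect_equal(attr(res, "first_full_capture_ns"),
               traj$times[which(ramp == 100)[1]])
})

test_that("a dozen planted hydrogen bonds are all found", {
  gel <- build_pva_chain(40, tacticity_seed = 5, conformation = "coil")
  traj <- make_planted_trajectory(gel, n_frames = 1, n_dmt = 14,
                                  capture_schedule = 100,
                                  hbond_schedule = 12L,
                                  box = 110, seed = 3)
  res <- analyze_trajectory(traj, observables = "hbonds")
  expect_equal(res$value, 12)
})

test_that("generators are deterministic and emit re-parseable files", {
  gel <- build_pva_chain(4, tacticity_seed = 1)
  t1 <- make_planted_trajectory(gel, n_frames = 3, n_dmt = 4,
                                capture_schedule = c(0, 50, 100),
                                box = 60, seed = 21)
  t2 <- make_planted_trajectory(gel, n_frames = 3, n_dmt = 4,
                                capture_schedule = c(0, 50, 100),
                                box = 60, seed = 21)
  expect_identical(t1$frames, t2$frames)

  withr::with_tempdir({
    write_trajectory(t1, "traj.pdb", "topo.json")
    back <- read_trajectory("traj.pdb", "topo.json")
    expect_equal(length(back$frames), 3)
    expect_equal(back$topology$role, t1$topology$role)
    expect_equal(back$frames[[2]], t1$frames[[2]], tolerance = 1e-3,
                 ignore_attr = TRUE)
    # the round-tripped trajectory yields the same planted observables
    res <- analyze_trajectory(back, observables = "capture")
    expect_equal(res$value, c(0, 50, 100))
  })
})

test_that("schedule validation catches impossible requests", {
  gel <- build_pva_chain(4, tacticity_seed = 1)
  expect_error(make_planted_trajectory(gel, n_frames = 1, n_dmt = 3,
                                       capture_schedule = 50, box = 60),
               "multiples")
  expect_error(make_planted_trajectory(gel, n_frames = 1, n_dmt = 4,
                                       capture_schedule = 25,
                                       hbond_schedule = 2L, box = 60),
               "exceed")
})
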