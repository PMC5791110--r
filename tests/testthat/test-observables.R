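test_that("SASA matches the isolated-sphere closed form within 1%", {
  o <- one_atom("O")
  a <- sasa(o, probe_radius = 1.4, n_points = 960)
  expect_lt(abs(a - 4 * pi * (1.52 + 1.4)^2) / (4 * pi * 2.92^2), 0.01)
})

test_that("SASA is additive for well-separated atoms", {
  pair <- toy_molecule(c("O", "O"), c(0, 0, 0, 50, 0, 0))
  both <- sasa(pair)
  each <- sasa(one_atom("O"))
  expect_equal(both, 2 * each, tolerance = 1e-9)
})

test_that("overlapping spheres match a dense-sampling oracle within 2%", {
  for (d in c(1.0, 2.0, 3.0)) {
    pair <- toy_molecule(c("C", "C"), c(0, 0, 0, d, 0, 0))
    coarse <- sasa(pair, n_points = 960)
    dense <- sasa(pair, n_points = 10000)
    expect_lt(abs(coarse - dense) / dense, 0.02)
  }
})

test_that("radius of gyration matches closed forms and brute force", {
  expect_equal(rgyr(one_atom("C")), 0)
  two <- toy_molecule(c("C", "C"), c(0, 0, 0, 10, 0, 0))
  expect_equal(rgyr(two), 5, tolerance = 1e-12)
  with_seed(3, {
    cloud <- toy_molecule(sample(c("C", "O", "N", "H"), 100,
                                 replace = TRUE),
                          stats::rnorm(300, sd = 6))
    m <- atomic_mass(cloud$atoms$element)
    com <- colSums(coords(cloud) * m) / sum(m)
    oracle <- sqrt(sum(m * rowSums(sweep(coords(cloud), 2, com)^2)) /
                     sum(m))
    expect_equal(rgyr(cloud), oracle, tolerance = 1e-12)
  })
  expect_error(rgyr(one_atom("C"), selection = integer(0)), "empty")
})

test_that("water-shell counting implements the union criterion", {
  # hydrogel: one C at the origin; waters planted per criterion
  fr <- toy_frame(
    elements = c("C", "O", "O", "O", "O"),
    xyz = c(0, 0, 0,       # hydrogel
            2.5, 0, 0,     # within 3.0 of backbone
            0, 8, 0,       # inside the com sphere (r = 10)
            0, 0, 25,      # outside both
            3.4, 0, 0),    # outside 3.0, inside com sphere
    roles = c("hydrogel", "water", "water", "water", "water"),
    mol_ids = 1:5)
  expect_equal(water_shell_count(fr, backbone_cutoff = 3,
                                 com_radius = 10), 3)
  expect_equal(water_shell_count(fr, backbone_cutoff = 3,
                                 com_radius = 2), 1)
  expect_error(water_shell_count(fr, com_radius = 0), "positive")
  # no waters at all
  solo <- toy_frame("C", c(0, 0, 0), "hydrogel", 1)
  expect_equal(water_shell_count(solo, com_radius = 5), 0L)
})

test_that("capture fraction counts molecules, not atoms, and is monotone in cutoff", {
  # 3 DMT molecules of 2 atoms each: two near (both atoms in range for
  # one; one atom only for the other), one far
  fr <- toy_frame(
    elements = c("C", "C", "C", "C", "C", "C", "C"),
    xyz = c(0, 0, 0,
            3, 0, 0, 4, 0, 0,      # mol 2: captured
            4.2, 0, 0, 9, 0, 0,    # mol 3: captured via one atom
            30, 0, 0, 31, 0, 0),   # mol 4: free
    roles = c("hydrogel", rep("DMT", 6)),
    mol_ids = c(1, 2, 2, 3, 3, 4, 4))
  expect_equal(capture_fraction(fr, cutoff = 4.5), 100 * 2 / 3)
  expect_equal(capture_fraction(fr, cutoff = 2.0), 0)
  expect_equal(capture_fraction(fr, cutoff = 50), 100)
  cuts <- c(1, 2, 3, 4, 5, 10, 29, 35)
  vals <- vapply(cuts, function(cc) capture_fraction(fr, cc), numeric(1))
  expect_true(all(diff(vals) >= 0))
  nofr <- toy_frame("C", c(0, 0, 0), "hydrogel", 1)
  expect_error(capture_fraction(nofr), "no DMT")
})

test_that("hydrogen-bond detection follows the distance-angle rule", {
  mk <- function(o_a, ang_deg = 0, d_oa = 2.8, acc_el = "O") {
    # donor O at origin, H along +x; acceptor at distance d_oa from the
    # donor, rotated ang_deg off the O-H axis
    th <- ang_deg * pi / 180
    acc <- d_oa * c(cos(th), sin(th), 0)
    toy_frame(
      elements = c("O", "H", acc_el),
      xyz = c(0, 0, 0, 0.96, 0, 0, acc),
      roles = c("hydrogel", "hydrogel", "DMT"),
      mol_ids = c(1, 1, 2),
      is_donor = c(TRUE, FALSE, FALSE),
      is_acceptor = c(TRUE, FALSE, TRUE),
      h_parent = c(NA, 1L, NA))
  }
  expect_equal(hbond_count(mk(ang_deg = 0, d_oa = 2.8)), 1)
  expect_equal(hbond_count(mk(ang_deg = 0, d_oa = 4.0)), 0)
  # 45 degrees off the donor axis at 2.8 A: deviation beyond the cone
  expect_equal(hbond_count(mk(ang_deg = 45, d_oa = 2.8)), 0)
  # sulfur acceptors get the extended cutoff
  expect_equal(hbond_count(mk(d_oa = 3.3, acc_el = "S")), 1)
  expect_equal(hbond_count(mk(d_oa = 3.3, acc_el = "O")), 0)
  # geometry sweep vs direct rule evaluation
  for (ang in c(5, 15, 25, 35, 55)) {
    for (d in c(2.4, 2.9, 3.2)) {
      fr <- mk(ang_deg = ang, d_oa = d)
      # the deviation from linearity at H, computed independently
      hpos <- fr$xyz[2, ]; apos <- fr$xyz[3, ]; dpos <- fr$xyz[1, ]
      v1 <- dpos - hpos; v2 <- apos - hpos
      dev <- 180 - acos(sum(v1 * v2) /
                          sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      expected <- as.integer(d <= 3.0 && dev <= 30)
      expect_equal(hbond_count(fr), expected,
                   label = sprintf("ang=%d d=%.1f", ang, d))
    }
  }
})

test_that("donors without hydrogens raise a topology error", {
  fr <- toy_frame(
    elements = c("O", "O"),
    xyz = c(0, 0, 0, 2.8, 0, 0),
    roles = c("hydrogel", "DMT"), mol_ids = 1:2,
    is_donor = c(TRUE, FALSE), is_acceptor = c(TRUE, TRUE))
  expect_error(hbond_count(fr), "topology error")
})

test_that("observables are invariant under rigid motion of a frame", {
  with_seed(12, {
    els <- sample(c("C", "O", "N", "H"), 60, replace = TRUE)
    xyz <- matrix(stats::rnorm(180, sd = 4), ncol = 3)
    roles <- rep(c("hydrogel", "DMT", "water"), each = 20)
    mols <- c(rep(1, 20), rep(2:5, each = 5), 21:40)
    mk <- function(X) {
      f <- toy_frame(els, t(X), roles, mols)
      f$xyz <- X
      f
    }
    f1 <- mk(xyz)
    R <- zyz_to_matrix(c(0.4, 1.2, -0.8))
    f2 <- mk(sweep(xyz %*% t(R), 2, c(5, -3, 8), "+"))
    gel <- which(roles == "hydrogel")
    expect_equal(sasa(f1, gel), sasa(f2, gel), tolerance = 1e-6)
    expect_equal(rgyr(f1, gel), rgyr(f2, gel), tolerance = 1e-6)
    expect_equal(capture_fraction(f1), capture_fraction(f2))
    expect_equal(water_shell_count(f1, com_radius = 6),
                 water_shell_count(f2, com_radius = 6))
  })
})

test_that("small-frame observables equal their brute-force oracles", {
  with_seed(21, {
    for (rep in 1:5) {
      n_gel <- 15; n_dmt_mol <- 4; n_wat <- 10
      els <- c(sample(c("C", "O"), n_gel, TRUE),
               rep("C", n_dmt_mol * 3),
               rep(c("O", "H", "H"), n_wat))
      roles <- c(rep("hydrogel", n_gel), rep("DMT", n_dmt_mol * 3),
                 rep("water", n_wat * 3))
      mols <- c(rep(1, n_gel), rep(1 + seq_len(n_dmt_mol), each = 3),
                rep(1 + n_dmt_mol + seq_len(n_wat), each = 3))
      box <- 30
      xyz <- matrix(stats::runif(length(els) * 3, 0, box), ncol = 3)
      fr <- toy_frame(els, t(xyz), roles, mols, box = box)
      fr$xyz <- xyz

      # capture oracle: all-pairs loop
      gel <- which(roles == "hydrogel" & els != "H")
      capt <- 0
      for (mid in unique(mols[roles == "DMT"])) {
        rows <- which(mols == mid & roles == "DMT")
        got <- FALSE
        for (i in rows) for (j in gel) {
          d <- xyz[i, ] - xyz[j, ]
          d <- d - box * round(d / box)
          if (sqrt(sum(d^2)) <= 4.5) got <- TRUE
        }
        capt <- capt + got
      }
      expect_equal(capture_fraction(fr), 100 * capt / n_dmt_mol)

      # water-shell oracle: double loop with the union rule
      m <- atomic_mass(els[roles == "hydrogel"])
      com <- colSums(xyz[roles == "hydrogel", , drop = FALSE] * m) / sum(m)
      cnt <- 0
      for (w in which(roles == "water" & els == "O")) {
        near <- FALSE
        for (j in gel) {
          d <- xyz[w, ] - xyz[j, ]
          d <- d - box * round(d / box)
          if (sqrt(sum(d^2)) <= 3.0) near <- TRUE
        }
        d <- xyz[w, ] - com
        d <- d - box * round(d / box)
        if (near || sqrt(sum(d^2)) <= 9) cnt <- cnt + 1
      }
      expect_equal(water_shell_count(fr, com_radius = 9), cnt)
    }
  })
})
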