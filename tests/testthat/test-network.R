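test_that("composition arithmetic follows the floor rule", {
  expect_equal(composition_to_links(625, "10:2"), 125L)
  expect_equal(composition_to_links(625, "10:4"), 250L)
  expect_equal(composition_to_links(625, "10:6"), 375L)
  expect_equal(composition_to_links(10, c(10, 2)), 2L)
  expect_equal(composition_to_links(7, c(2, 1)), 3L)
  expect_error(composition_to_links(-5, "10:2"), "positive")
  expect_error(composition_to_links(625, "10:0"), "positive")
  expect_equal(network_label(625, 125), "CLPH-MA20")
  expect_equal(network_label(625, 375), "CLPH-MA60")
})

test_that("single-chain packing is trivial and multi-chain packing respects min_sep", {
  one <- pack_chains(1, 5, box = 30, min_sep = 5, seed = 1)
  expect_equal(one$n_monomers, 5)
  expect_identical(min_interchain_distance(one), Inf)

  sys <- toy_system(n_chains = 3, monomers = 8, box = 32, min_sep = 4.5,
                    seed = 2)
  expect_equal(sys$n_monomers, 24)
  expect_gte(min_interchain_distance(sys), 4.5)
  # determinism
  sys2 <- toy_system(n_chains = 3, monomers = 8, box = 32, min_sep = 4.5,
                     seed = 2)
  expect_identical(coords(sys$mol), coords(sys2$mol))
  # an impossible density fails up front
  expect_error(pack_chains(80, 25, box = 20, min_sep = 5, seed = 1),
               "infeasible")
})

test_that("minimum-image distances agree with a 27-image brute force", {
  with_seed(6, {
    box <- c(11, 14, 9)
    A <- matrix(stats::runif(30, -20, 40), ncol = 3)
    B <- matrix(stats::runif(24, -20, 40), ncol = 3)
    d_mi <- hydrosieve:::.pbc_dist2(A, B, box)
    d_br <- hydrosieve:::.pbc_dist2_brute(
      hydrosieve:::.pbc_wrap(A, box), hydrosieve:::.pbc_wrap(B, box), box)
    expect_equal(d_mi, d_br, tolerance = 1e-9)
  })
})

test_that("crosslink pair selection honours its constraints and uniformity", {
  # far-apart chains in a huge box: nothing within 10 A
  far <- pack_chains(2, 3, box = 200, min_sep = 60, seed = 5)
  expect_null(with_seed(1, select_crosslink_pair(far, max_dist = 10)))

  sys <- toy_system()
  draws <- with_seed(8, replicate(300, {
    p <- select_crosslink_pair(sys, max_dist = 12)
    c(p$i, p$j, p$distance)
  }))
  s <- sys$sites
  expect_true(all(s$chain[draws[1, ]] != s$chain[draws[2, ]]))
  expect_true(all(draws[3, ] <= 12))

  # empirical selection frequencies are uniform over the eligible set
  at <- sys$mol$atoms
  O <- as.matrix(at[match(s$o_id, at$atom_id), c("x", "y", "z")])
  D <- hydrosieve:::.pbc_cdist(O, O, sys$box)
  elig <- which(upper.tri(D) & D <= 12 &
                  outer(s$chain, s$chain, "!="), arr.ind = TRUE)
  n_elig <- nrow(elig)
  keys <- paste(pmin(draws[1, ], draws[2, ]),
                pmax(draws[1, ], draws[2, ]))
  all_keys <- paste(elig[, 1], elig[, 2])
  counts <- table(factor(keys, levels = all_keys))
  expect_equal(sort(unique(keys)), sort(all_keys))
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("ester formation keeps exact atom, bond and charge books", {
  sys <- toy_system()
  pair <- with_seed(3, select_crosslink_pair(sys, max_dist = 20))
  n0 <- natoms(sys$mol)
  q0 <- net_charge(sys$mol)
  linker_n <- natoms(load_template("malic"))
  sys2 <- form_ester_link(sys, pair$i, pair$j, "malic")
  # condensation: the diacid enters minus one O and one chain H per ester
  expect_equal(natoms(sys2$mol), n0 + linker_n - 4)
  expect_equal(net_charge(sys2$mol), q0, tolerance = 1e-9)
  expect_true(all(sys2$sites$used[c(pair$i, pair$j)]))
  # a used site cannot react again
  expect_error(form_ester_link(sys2, pair$i, pair$j, "malic"),
               "already used")
  # same-chain pairs are refused
  same <- which(sys2$sites$chain == 1 & !sys2$sites$used)[1:2]
  expect_error(form_ester_link(sys2, same[1], same[2], "malic"),
               "different chains")
})

test_that("toy network builds pass the exhaustive post-hoc audit", {
  sys <- toy_system()
  net <- build_network(sys, "malic", target_links = 2, seed = 5,
                       max_dist = 20)
  expect_equal(net$n_links, 2)
  expect_equal(nrow(net$links), 2)
  expect_true(all(net$links$chain_i != net$links$chain_j))
  expect_true(all(net$links$distance_A <= 20))
  # inserted diacid residues equal the link count at all times
  expect_equal(sum(net$system$mol$atoms$label == "linker") /
                 (natoms(load_template("malic")) - 2), 2)
  # no site used twice
  expect_equal(sum(net$system$sites$used), 4)
  # target 0 leaves the system untouched
  net0 <- build_network(sys, "malic", target_links = 0, seed = 5)
  expect_identical(coords(net0$system$mol), coords(sys$mol))
  expect_equal(net0$n_links, 0)
})

test_that("link lists are incremental: smaller targets are prefixes", {
  sys <- toy_system()
  n1 <- build_network(sys, "malic", target_links = 1, seed = 5,
                      max_dist = 20, relax_steps = 2)
  n3 <- build_network(sys, "malic", target_links = 3, seed = 5,
                      max_dist = 20, relax_steps = 2)
  expect_identical(n1$links, n3$links[1, ])
})

test_that("a sparse system saturates with an informative error", {
  sys <- toy_system()
  expect_error(build_network(sys, "malic", target_links = 50, seed = 5,
                             max_dist = 20),
               "saturated")
})

test_that("relaxation descends monotonically and resolves overlaps", {
  # a dimer at its pair-potential minimum is a fixed point
  dmin <- lj_params("C")$sigma * 2^(1 / 6)
  apart <- toy_molecule(c("C", "C"), c(0, 0, 0, dmin, 0, 0))
  r0 <- relax(apart, max_steps = 50, force_tol = 1e-3)
  expect_lt(max(abs(coords(r0) - coords(apart))), 1e-6)

  # overlapping pair: pushed out to at least the LJ diameter
  close <- toy_molecule(c("C", "C"), c(0, 0, 0, 1.0, 0, 0))
  r1 <- relax(close, max_steps = 500, force_tol = 0.05)
  sep <- dist(coords(r1))[1]
  sigma <- lj_params("C")$sigma
  expect_gte(sep, sigma * 0.95)
  tr <- attr(r1, "energy_trace")
  expect_true(all(diff(tr) <= 1e-9))

  # a stretched bond relaxes toward its reference length
  bonded <- toy_molecule(c("C", "C"), c(0, 0, 0, 2.4, 0, 0),
                         bonds = data.frame(from = 1, to = 2,
                                            order = "1", r0 = 1.54))
  r2 <- relax(bonded, max_steps = 300, force_tol = 0.05)
  expect_lt(abs(dist(coords(r2))[1] - 1.54), 0.1)

  # non-finite entry geometry is rejected
  bad <- toy_molecule(c("C", "C"), c(0, 0, 0, 0, 0, 0))
  expect_error(relax(bad, max_steps = 5), NA)  # coincident is clamped
})
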