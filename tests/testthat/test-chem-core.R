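test_that("template library covers the 17 molecules with correct identities", {
  ids <- template_ids()
  expect_length(ids, 17)
  expect_length(diacid_ids(), 14)
  expect_error(load_template("citric"), "template not found")

  dmt <- load_template("dimethoate")
  expect_equal(chem_formula(dmt), "C5H12NO3PS2")
  expect_lt(abs(molar_mass(dmt) - 229.26), 0.05)
  expect_equal(net_charge(dmt), 0, tolerance = 1e-9)

  ma <- load_template("malic")
  expect_equal(net_charge(ma), -2, tolerance = 1e-9)
  wat <- load_template("water")
  expect_equal(chem_formula(wat), "H2O")
})

test_that("every template's net charge equals the sum of its partial charges", {
  for (id in template_ids()) {
    m <- load_template(id)
    expect_equal(net_charge(m), sum(m$atoms$charge))
    expect_true(all(m$atoms$vdw > 0))
    expect_true(all(is.finite(as.matrix(m$atoms[, c("x", "y", "z")]))))
  }
})

test_that("PVA chains have the documented monomer anatomy", {
  for (n in c(1, 3, 5, 12)) {
    ch <- build_pva_chain(n, tacticity_seed = 2)
    expect_equal(nrow(ch$sites), n)
    expect_equal(sum(ch$atoms$element == "C" &
                       ch$atoms$atom_id %in% ch$backbone_c), 2 * n + 1)
    expect_equal(net_charge(ch), 0, tolerance = 1e-12)
    expect_equal(chem_formula(ch),
                 paste0("C", 2 * n + 1, "H", 2 * (2 * n + 1) + 2,
                        "O", if (n > 1) n else ""))
  }
  expect_error(build_pva_chain(0), "positive")
})

test_that("a 5-monomer chain spans close to the 10 Angstrom design length", {
  ch <- build_pva_chain(5, tacticity_seed = 1)
  expect_lt(abs(chain_end_to_end(ch) - 10) / 10, 0.15)
})

test_that("chain building is deterministic per seed and varies across seeds", {
  a <- build_pva_chain(25, tacticity_seed = 9)
  b <- build_pva_chain(25, tacticity_seed = 9)
  c <- build_pva_chain(25, tacticity_seed = 10)
  expect_identical(coords(a), coords(b))
  expect_false(identical(coords(a), coords(c)))
  k1 <- build_pva_chain(25, tacticity_seed = 9, conformation = "coil")
  k2 <- build_pva_chain(25, tacticity_seed = 9, conformation = "coil")
  expect_identical(coords(k1), coords(k2))
})

test_that("protonation follows pKa vs pH and is idempotent", {
  ma <- load_template("malic")
  # at pH 2 both carboxylates pick up protons (net 0)
  low <- assign_protonation(ma, 2.0)
  expect_equal(net_charge(low), 0, tolerance = 1e-9)
  expect_equal(chem_formula(low), "C4H6O5")
  # back at pH 5.5 they deprotonate again (net -2)
  mid <- assign_protonation(low, 5.5)
  expect_equal(net_charge(mid), -2, tolerance = 1e-9)
  expect_identical(assign_protonation(mid, 5.5)$atoms, mid$atoms)
  # PVA hydroxyls stay protonated at pH 5.5
  ch <- build_pva_chain(3)
  ch2 <- assign_protonation(ch, 5.5)
  expect_equal(natoms(ch2), natoms(ch))
  expect_equal(net_charge(ch2), 0, tolerance = 1e-9)
  # and lose their protons only in strongly basic conditions
  ch3 <- assign_protonation(ch, 12)
  expect_equal(net_charge(ch3), -3, tolerance = 1e-9)
  # no ionizable groups -> identity
  ar <- one_atom("C")
  expect_identical(assign_protonation(ar, 5.5)$atoms, ar$atoms)
})

test_that("center of mass matches the direct-summation oracle", {
  expect_equal(center_of_mass(one_atom("C", c(1, 2, 3))), c(1, 2, 3))
  two <- toy_molecule(c("O", "O"), c(0, 0, 0, 2, 0, 0))
  expect_equal(center_of_mass(two), c(1, 0, 0))
  dmt <- load_template("dimethoate")
  m <- atomic_mass(dmt$atoms$element)
  oracle <- colSums(coords(dmt) * m) / sum(m)
  expect_equal(center_of_mass(dmt), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(center_of_mass(molecule(
    data.frame(atom_id = integer(), element = character(), x = numeric(),
               y = numeric(), z = numeric(), charge = numeric()))),
    "empty")
})

test_that("structure files round-trip per format capability", {
  dmt <- load_template("dimethoate")
  withr::with_tempdir({
    # MOL2 is lossless: coordinates, elements, bonds, charges
    write_structure(dmt, "m.mol2")
    m <- read_structure("m.mol2")
    expect_equal(chem_formula(m), chem_formula(dmt))
    expect_equal(nrow(m$bonds), nrow(dmt$bonds))
    expect_equal(coords(m), coords(dmt), tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_equal(m$atoms$charge, dmt$atoms$charge, tolerance = 1e-6)
    # extended XYZ keeps coordinates, elements and charges
    write_structure(dmt, "m.xyz")
    x <- read_structure("m.xyz")
    expect_equal(x$atoms$element, dmt$atoms$element)
    expect_equal(coords(x), coords(dmt), tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_equal(x$atoms$charge, dmt$atoms$charge, tolerance = 1e-6)
    # PDB keeps coordinates and elements
    write_structure(dmt, "m.pdb")
    p <- read_structure("m.pdb")
    expect_equal(p$atoms$element, dmt$atoms$element)
    expect_equal(coords(p), coords(dmt), tolerance = 1e-3,
                 ignore_attr = TRUE)
  })
})

test_that("every template survives a write-read cycle in all three formats", {
  withr::with_tempdir({
    for (id in c("oxalic", "malic", "azelaic", "dimethoate", "water")) {
      m0 <- load_template(id)
      for (fmt in c("mol2", "xyz", "pdb")) {
        f <- paste0(id, ".", fmt)
        write_structure(m0, f)
        m1 <- read_structure(f)
        expect_equal(chem_formula(m1), chem_formula(m0),
                     label = paste(id, fmt))
      }
    }
  })
})

test_that("malformed structure files raise parse errors", {
  withr::with_tempdir({
    writeLines(c("24", "truncated xyz", "C 0 0 0"), "bad.xyz")
    expect_error(read_structure("bad.xyz"), "truncated")
    writeLines("not a pdb at all", "bad.pdb")
    expect_error(read_structure("bad.pdb"), "parse|ATOM")
    writeLines(c("3", "no charges", "O 0 0 0", "H 1 0 0", "H 0 1 0"),
               "plain.xyz")
    expect_warning(m <- read_structure("plain.xyz"), "charge")
    expect_equal(m$atoms$charge, rep(0, 3))
    expect_error(read_structure("bad.cif"), "unsupported")
  })
})
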