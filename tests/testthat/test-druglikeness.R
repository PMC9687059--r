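test_that("formula parsing and pinned atomic weights reproduce printed MWs", {
  expect_equal(parse_formula("C15H24O"), c(C = 15L, H = 24L, O = 1L))
  expect_equal(molecular_weight("C15H24"), 204.35, tolerance = 0.01)
  expect_equal(molecular_weight("C15H24O"), 220.35, tolerance = 0.01)
  expect_equal(molecular_weight("C15H22"), 202.34, tolerance = 0.01)
  expect_equal(molecular_weight("H2O"), 18.02, tolerance = 0.01)
  expect_error(molecular_weight("C2Xx3"), "Xx")

  # additivity over a disjoint formula union
  set.seed(3)
  for (i in 1:10) {
    a <- c(C = sample(1:20, 1), H = sample(1:30, 1))
    b <- c(N = sample(1:5, 1), O = sample(1:5, 1))
    expect_equal(molecular_weight(c(a, b)),
                 molecular_weight(a) + molecular_weight(b),
                 tolerance = 1e-9)
  }
})

test_that("H-bond acceptor and donor counts follow the Lipinski convention", {
  cmp <- load_hit_compounds()
  expect_equal(count_hb_acceptors(cmp[["Caryophyllene oxide"]]), 1L)
  expect_equal(count_hb_acceptors(cmp[["Caryophyllene"]]), 0L)
  expect_equal(count_hb_acceptors("C2H6O"), 1L)  # ethanol, from formula

  expect_equal(count_hb_donors(cmp[["14-Hydroxy-9-epi-(E)-caryophyllene"]]), 1L)
  expect_equal(count_hb_donors(cmp[["Caryophyllene oxide"]]), 0L)
  expect_equal(count_hb_donors(cmp[["Caryophyllene"]]), 0L)

  water <- new_compound("water",
                        atoms = data.frame(element = c("O", "H", "H"),
                                           x = c(0, 0.96, -0.24),
                                           y = c(0, 0, 0.93), z = 0),
                        bonds = data.frame(a1 = c(1, 1), a2 = c(2, 3),
                                           order = 1L))
  expect_equal(count_hb_donors(water), 1L)  # one heteroatom with >= 1 H

  expect_error(count_hb_donors(new_compound("x", formula = "C2H6O")),
               "needs a structure")

  # counts invariant under atom reordering
  ox <- cmp[["Caryophyllene oxide"]]
  perm <- sample(nrow(ox$atoms))
  inv <- order(perm)
  reord <- new_compound(ox$name, atoms = ox$atoms[perm, ],
                        bonds = data.frame(a1 = inv[ox$bonds$a1],
                                           a2 = inv[ox$bonds$a2],
                                           order = ox$bonds$order))
  expect_equal(count_hb_donors(reord), count_hb_donors(ox))
  expect_equal(count_hb_acceptors(reord), count_hb_acceptors(ox))
})

test_that("Moriguchi MLOGP reproduces reference lipophilicities", {
  cmp <- load_hit_compounds()
  expect_equal(mlogp(cmp[["Caryophyllene"]]), 4.63, tolerance = 0.005)
  expect_equal(mlogp(cmp[["Humulene"]]), 4.53, tolerance = 0.005)
  expect_equal(mlogp(cmp[["Caryophyllene oxide"]]), 3.67, tolerance = 0.12)
  expect_equal(mlogp(cmp[["14-Hydroxy-9-epi-(E)-caryophyllene"]]), 3.56,
               tolerance = 0.12)
  for (nm in c("Caryophyllene", "Humulene", "Calamenene"))
    expect_gt(mlogp(cmp[[nm]]), 4.15)
  for (nm in c("Caryophyllene oxide", "14-Hydroxy-9-epi-(E)-caryophyllene"))
    expect_lt(mlogp(cmp[[nm]]), 4.15)
})

test_that("MLOGP descriptors match hand-evaluated regression terms", {
  methane <- new_compound("methane",
                          atoms = data.frame(element = c("C", rep("H", 4)),
                                             x = c(0, 1, -1, 0, 0),
                                             y = c(0, 0, 0, 1, -1), z = 0),
                          bonds = data.frame(a1 = 1, a2 = 2:5, order = 1L))
  # hand evaluation: CX = 1, ALK = 1, every other descriptor 0
  expect_equal(mlogp(methane), 1.244 * 1 + 0.912 - 1.041, tolerance = 1e-9)

  benz <- new_compound("benzene",
                       atoms = data.frame(element = rep("C", 6),
                                          x = cos(2 * pi * (0:5) / 6),
                                          y = sin(2 * pi * (0:5) / 6), z = 0),
                       bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1),
                                          order = c(2, 1, 2, 1, 2, 1)))
  d <- mlogp_descriptors(benz)
  expect_equal(d[["UB"]], 3)    # kekulized aromatic ring
  expect_equal(d[["RNG"]], 0)   # benzene itself is excluded from RNG
  expect_equal(d[["ALK"]], 0)
  expect_equal(mlogp(benz), 1.244 * 6^0.6 - 0.145 * 3^0.8 - 1.041,
               tolerance = 1e-9)

  cmp <- load_hit_compounds()
  d_car <- mlogp_descriptors(cmp[["Caryophyllene"]])
  expect_equal(d_car[["CX"]], 15)
  expect_equal(d_car[["UB"]], 2)
  expect_equal(d_car[["RNG"]], 1)
  expect_equal(d_car[["ALK"]], 0)  # two double bonds: not a mono-ene
  d_cal <- mlogp_descriptors(cmp[["Calamenene"]])
  expect_equal(d_cal[["UB"]], 3)   # aromatic ring, kekulized
  expect_equal(d_cal[["RNG"]], 1)  # the fused saturated ring

  glycol <- new_compound("ethylene glycol",
                         atoms = data.frame(element = c("O", "C", "C", "O"),
                                            x = 0:3, y = 0, z = 0),
                         bonds = data.frame(a1 = 1:3, a2 = 2:4, order = 1L))
  expect_equal(mlogp_descriptors(glycol)[["PRX"]], 0)  # O...O 3 bonds apart
  methoxy <- new_compound("methanediol",
                          atoms = data.frame(element = c("O", "C", "O"),
                                             x = 0:2, y = 0, z = 0),
                          bonds = data.frame(a1 = 1:2, a2 = 2:3, order = 1L))
  expect_equal(mlogp_descriptors(methoxy)[["PRX"]], 1)  # X-A-Y proximity

  arsenic <- new_compound("uncovered",
                          atoms = data.frame(element = c("C", "Se"),
                                             x = 0:1, y = 0, z = 0),
                          bonds = data.frame(a1 = 1, a2 = 2, order = 1L))
  expect_error(mlogp(arsenic), "coverage")
})

test_that("rule-of-five verdicts reproduce the reference druglikeness column", {
  tab <- adme_table(load_hit_compounds())
  verdicts <- setNames(tab$verdict, tab$name)
  expect_equal(verdicts[["Caryophyllene"]], "Yes; 1 violation: MLOGP > 4.15")
  expect_equal(verdicts[["Caryophyllene oxide"]], "Yes; 0 violation")
  expect_equal(verdicts[["Humulene"]], "Yes; 1 violation: MLOGP > 4.15")
  expect_equal(verdicts[["14-Hydroxy-9-epi-(E)-caryophyllene"]],
               "Yes; 0 violation")
  expect_equal(verdicts[["Calamenene"]], "Yes; 1 violation: MLOGP > 4.15")
  expect_true(all(tab$druglike))
  # molar refractivity is informational: plausible sesquiterpene range
  expect_true(all(tab$molar_refractivity > 55 & tab$molar_refractivity < 80))

  hypo <- lipinski_assess(mw = 600, mlogp = 6, hba = 12, hbd = 6)
  expect_equal(length(hypo$violations), 4L)
  expect_false(hypo$druglike)
  expect_match(hypo$verdict, "^No; 4 violations")
  expect_true(all(hypo$violations %in%
                    c("MW > 500", "MLOGP > 4.15", "HBA > 10", "HBD > 5")))
})
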