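test_that("the bundled contact table is symmetric with sensible signs", {
  ct <- contact_potential()
  expect_equal(dim(ct), c(20L, 20L))
  expect_equal(ct, t(ct))
  expect_lt(ct["F", "F"], ct["K", "K"])   # hydrophobic pairs more attractive
  expect_lt(ct["C", "C"], 0)
})

test_that("contact energy sums table entries over non-bonded contacts", {
  params <- energy_params()
  s <- stretched_peptide("ACDEFGHIKL")
  expect_equal(unname(contact_energy(s, params)["E_AA"]), 0)

  u <- uturn_4mer()        # single non-bonded contact: residues 1 and 4
  e <- contact_energy(u, params)
  expect_equal(unname(e["E_AA"]), params$contact_table["A", "W"])

  u$tags[1L] <- "ref"      # tagging a partner removes the interaction
  expect_equal(unname(contact_energy(u, params)["E_AA"]), 0)
})

test_that("solvent term counts exposed neighbour vertices", {
  solv <- stats::setNames(rep(0.5, 20L),
                          rownames(contact_potential()))
  params <- energy_params(solvent = solv)
  u <- uturn_4mer()
  # exposure: 8 - chain neighbours - residue contacts, per untagged residue
  exposed <- c(8 - 1 - 1, 8 - 2, 8 - 2, 8 - 1 - 1)
  expect_equal(unname(contact_energy(u, params)["E_sol"]),
               sum(0.5 * exposed))
})

test_that("secondary-structure bonuses require the native annotation", {
  params <- energy_params()
  coil <- stretched_peptide("AAAAAAA")
  expect_equal(secondary_structure_energy(coil, params), 0)

  helix <- lattice_structure(rep("A", 5L), lattice_helix(5L),
                             native_ss = rep("H", 5L))
  expect_equal(secondary_structure_energy(helix, params), -25)
  helix$tags[1L] <- "C"    # tagged residues lose the bonus
  expect_equal(secondary_structure_energy(helix, params), 0)
  # a native helix not re-formed on the lattice earns nothing
  flat <- stretched_peptide("AAAAA")
  flat$native_ss <- rep("H", 5L)
  expect_equal(secondary_structure_energy(flat, params), 0)

  sheet <- uturn_4mer()
  sheet$native_ss <- c("E", "C", "C", "E")
  expect_equal(secondary_structure_energy(sheet, params), -50)
})

test_that("disulfide bonus uses a maximum matching, one bond per cysteine", {
  params <- energy_params()
  expect_equal(disulfide_energy(stretched_peptide("AAAA"), params), 0)
  pair <- uturn_4mer(c("C", "G", "G", "C"))
  expect_equal(disulfide_energy(pair, params), -50)
  # star of three cysteines (1-4, 1-6 in contact): only one bridge forms
  expect_equal(disulfide_energy(cys_star_6mer(), params), -50)
  tagged <- pair
  tagged$tags[1L] <- "C"
  expect_equal(disulfide_energy(tagged, params), 0)
})

test_that("tag energy is the penalty times the minimal blocker count", {
  params <- energy_params()
  s <- label_structure(stretched_peptide("KAAAAAAAAC"),
                       default_scheme("C"))
  expect_equal(tag_energy(s, params), 0)
  cage <- caged_tag()
  expect_equal(tag_energy(cage, params),
               100 * clearance_blockers(cage, 1L))
})

test_that("reorganization penalty is thresholded-linear in displacement", {
  params <- energy_params(reg_weight = 2, reg_threshold = 4)
  s <- random_saw(10L, seed = 21)
  expect_equal(regularization_energy(s, s$coords, params), 0)
  expect_equal(regularization_energy(s, NULL, params), 0)
  prop <- propose_move(s, kind = "corner_flip", index = 5L)
  if (prop$valid) {
    s2 <- apply_move(s, prop)
    d <- sqrt(sum((s2$coords[5L, ] - s$coords[5L, ])^2))
    expect_equal(regularization_energy(s2, s$coords, params),
                 2 * max(0, d - 4))
  }
  # a large branch rotation is penalized more than a small one
  big <- propose_move(s, kind = "branch_rotation", index = 2L,
                      rotation = lattice_rotations()[[10L]])
  small <- propose_move(s, kind = "branch_rotation", index = 9L,
                        rotation = lattice_rotations()[[10L]])
  sb <- s; sb$coords <- big$new_coords
  ss <- s; ss$coords <- small$new_coords
  expect_gte(regularization_energy(sb, s$coords, params),
             regularization_energy(ss, s$coords, params))
})

test_that("the total is the exact sum of the six terms", {
  params <- energy_params()
  s <- label_structure(stretched_peptide("KCDEFGHICL"),
                       default_scheme("C"))
  e <- total_energy(s, NULL, params)
  expect_equal(e$E_tot,
               e$E_AA + e$E_sol + e$E_ss + e$E_dsb + e$E_tag + e$E_reg)
  # stretched untagged chain: all terms zero except solvent
  u <- stretched_peptide("ACDEFGHIKL")
  eu <- total_energy(u, NULL, params)
  expect_equal(eu$E_AA, 0)
  expect_equal(eu$E_ss, 0)
  expect_equal(eu$E_dsb, 0)
  expect_equal(eu$E_tag, 0)
  expect_equal(eu$E_reg, 0)
  expect_equal(eu$E_tot, eu$E_sol)
})

test_that("cached chain energies agree with fresh recomputation (property)", {
  params <- energy_params()
  s <- label_structure(random_saw(12L, seed = 31,
                                  sequence = strsplit("KCAFLGSWIKAG",
                                                      "")[[1]]),
                       default_scheme(c("C", "K")))
  e_cur <- total_energy(s, NULL, params)
  set.seed(77)
  for (i in 1:300) {
    prop <- propose_move(s)
    if (!prop$valid) next
    cand <- s
    cand$coords <- prop$new_coords
    e_new <- total_energy(cand, s$coords, params)
    if (metropolis_accept(e_new$E_tot - e_cur$E_tot, 0.01)) {
      s <- cand
      e_cur <- total_energy(s, NULL, params)   # cached going forward
    }
  }
  fresh <- total_energy(s, NULL, params)
  expect_equal(e_cur$E_tot, fresh$E_tot)
  expect_equal(unclass(e_cur)[1:6], unclass(fresh)[1:6])
})

test_that("inert residue types contribute no contact energy", {
  params <- energy_params(inert_types = c("G", "S"))
  u <- uturn_4mer(c("G", "A", "A", "S"))
  expect_equal(unname(contact_energy(u, params)["E_AA"]), 0)
  u2 <- uturn_4mer(c("F", "A", "A", "W"))
  expect_lt(unname(contact_energy(u2, params)["E_AA"]), 0)
})
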