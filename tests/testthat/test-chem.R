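test_that("peptide masses follow residue-table arithmetic", {
  # single glycine, free termini: residue + water
  expect_equal(peptide_mass("G", "average"), 75.07, tolerance = 0.01)
  # additivity: GG - G is one glycine residue
  expect_equal(peptide_mass("GG", "average") - peptide_mass("G", "average"),
               57.05, tolerance = 0.01)
  # concatenation: masses add minus one water (random sequences)
  withr::with_seed(13, {
    aa <- c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E","M",
            "H","F","R","Y","W")
    for (i in 1:10) {
      a <- paste(sample(aa, 8, TRUE), collapse = "")
      b <- paste(sample(aa, 5, TRUE), collapse = "")
      water <- 18.015
      expect_equal(peptide_mass(paste0(a, b)),
                   peptide_mass(a) + peptide_mass(b) - water,
                   tolerance = 0.01)
    }
  })
})

test_that("the assembled single-epitope design matches an independent mass computation", {
  # frozen values from an independent residue-table computation
  # (Ac-VQHTLTPGDLRDLGGC, free acid): average 1723.9074, monoisotopic 1722.8360
  des <- iris_design("mIRIS1")
  expect_equal(peptide_mass(des, "average"), 1723.9074, tolerance = 0.05)
  expect_equal(peptide_mass(des, "monoisotopic"), 1722.8360, tolerance = 0.02)
  # tandem design adds exactly one (epitope + linker) block
  des2 <- iris_design("mIRIS2")
  block <- peptide_mass("VQHTLTPGDLRDLGG") - 18.015  # residue-chain mass
  expect_equal(peptide_mass(des2, "average") - peptide_mass(des, "average"),
               block, tolerance = 0.02)
  expect_error(peptide_design("VQXHT"), "invalid residue")
})

test_that("ladder spacing is the peptide mass plus the crosslinker remnant", {
  des <- iris_design("mIRIS1")
  bare <- conjugation_chemistry(0, 0, 20)
  expect_equal(ladder_spacing(des, bare), peptide_mass(des))
  # SBAP remnant from independent formula arithmetic: the
  # 3-(bromoacetamido)propionyl group after NHS and HBr loss, C5H6NO2
  el <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999)
  remnant <- 5 * el["C"] + 6 * el["H"] + el["N"] + 2 * el["O"]
  chem <- sbap_chemistry(20)
  expect_equal(chem$linker_remnant_mass, unname(remnant), tolerance = 1e-6)
  expect_equal(ladder_spacing(des, chem), peptide_mass(des) + unname(remnant),
               tolerance = 1e-6)
  # one extra repeat shifts delta by one block mass
  des2 <- iris_design("mIRIS2")
  expect_equal(ladder_spacing(des2, chem) - ladder_spacing(des, chem),
               peptide_mass("VQHTLTPGDLRDLGG") - 18.015, tolerance = 0.02)
})

test_that("strict identity matches hand counts on the epitope homologs", {
  seqs <- iris_sequences()
  expect_equal(percent_identity(seqs["mIRIS"], seqs["bIRIS"]), 100 * 12 / 13)
  expect_equal(round(percent_identity(seqs["mIRIS"], seqs["bIRIS"]), 1), 92.3)
  # human homolog: 9 of 13 positions identical to bovine by hand count
  expect_equal(percent_identity(seqs["hIRIS"], seqs["bIRIS"]), 100 * 9 / 13)
  # symmetry, self-identity, length guard
  expect_equal(percent_identity(seqs["bIRIS"], seqs["mIRIS"]),
               percent_identity(seqs["mIRIS"], seqs["bIRIS"]))
  expect_equal(percent_identity("PGDL", "PGDL"), 100)
  expect_lt(percent_identity("PGDL", "PGDI"), 100)
  expect_error(percent_identity("PG", "PGD"), "equal length")
})

test_that("species mass ladder is affine in the load", {
  des <- iris_design("mIRIS1")
  bare <- conjugation_chemistry(0, 0, 20)
  delta <- ladder_spacing(des, bare)
  sm <- predict_species_masses(58408, des, bare, c(0, 2))
  expect_equal(sm$mass, 58408 + (0:2) * delta)
  # with capping, the slope is delta minus one capping adduct
  chem <- sbap_chemistry(20)
  smc <- predict_species_masses(58408, des, chem, c(0, 6))
  expect_equal(diff(smc$mass),
               rep(ladder_spacing(des, chem) - chem$capping_adduct_mass, 6),
               tolerance = 1e-9)
  expect_equal(smc$mass[1], 58408 + 20 * chem$capping_adduct_mass)
  expect_error(predict_species_masses(58408, des, chem, c(0, 25)),
               "activatable")
})

test_that("design_ladder bridges chemistry to fit-ready ladder parameters", {
  des <- iris_design("mIRIS1")
  chem <- sbap_chemistry(20)
  lad <- design_ladder(58408, des, chem, z = 2, n_range = c(0, 10))
  sm <- predict_species_masses(58408, des, chem, c(0, 10))
  expect_equal(lad$M0, sm$mass[1])
  expect_equal(lad$delta, sm$mass[2] - sm$mass[1])
  pr <- predict_ladder(lad)
  expect_equal(pr$center, (sm$mass + 2 * 1.007276) / 2, tolerance = 1e-9)
})

test_that("FASTA sequences round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">mIRIS", "VQHTLTPGDLRDL", ">bIRIS", "VRHTLTPGDLRDL"), f)
  seqs <- read_sequences_fasta(f)
  expect_equal(unname(seqs), c("VQHTLTPGDLRDL", "VRHTLTPGDLRDL"))
  expect_equal(names(seqs), c("mIRIS", "bIRIS"))
})
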