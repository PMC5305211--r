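test_that("residue masses agree with elemental compositions and stated mod deltas", {
  tab <- residue_table()
  elements <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
  recomputed <- as.matrix(tab$residues[, c("C", "H", "N", "O", "S")]) %*% elements
  expect_true(all(abs(tab$residues$mass - recomputed) < 1e-5))

  mods <- tab$modifications
  expect_equal(mods$delta[mods$name == "ox"], 15.9949, tolerance = 1e-4)
  expect_equal(mods$delta[mods$name == "cam"], 57.0215, tolerance = 1e-4)
  # Bpa = Phe + C7H4O; labeled Cys = Cys + C17H11NO3
  res <- tab$residues
  m <- function(r) res$mass[res$residue == r]
  expect_equal(m("B") - m("F"), 104.0262, tolerance = 1e-4)
  expect_equal(m("X") - m("C"), 277.0739, tolerance = 1e-4)
})

test_that("peptide_mass matches independent summation and handles errors", {
  expect_equal(peptide_mass("GRPK"), 456.2809, tolerance = 1e-4)
  expect_equal(peptide_mass("G"), 75.0320, tolerance = 1e-4)
  expect_error(peptide(""), "empty")
  expect_error(peptide("GZR"), "position 2")
  # illegal modification placement names the position
  expect_error(peptide("GAR", mods = c(`2` = "ox")), "position 2")
  expect_error(peptide("GMR", mods = c(`2` = "ox", `2` = "cam")),
               "one modification per position")
})

test_that("composition and residue-summation mass paths agree", {
  seqs <- c("GRPK", "LDGQTPBEDRNR", "QTEIFTHFM[ox]TNSAK", "XGR",
            "VLDILEDYCMWR", "GXGK", "M[ox]VIQGGR")
  for (s in seqs) {
    p <- peptide(s)
    expect_equal(peptide_mass(p, "composition"), peptide_mass(p, "residue"),
                 tolerance = 1e-4 / peptide_mass(p))
  }
})

test_that("crosslink mass is exactly additive with zero linker delta", {
  xl <- crosslink_mass(peptide("LDGQTPBEDRNR"), peptide("SPTKPK"))
  expect_equal(xl$mass, 2207.0971, tolerance = 1e-4)
  expect_lt(abs(ppm_error(2207.0968, xl$mass)), 10)

  xl2 <- crosslink_mass(peptide("LDGQTPBEDR"), peptide("GRPK"))
  expect_equal(xl2$mass, 1736.8482, tolerance = 1e-4)
  expect_equal(abs(ppm_error(1736.8594, xl2$mass)), 6.5, tolerance = 0.1)

  expect_error(crosslink_mass(peptide("GRPK"), peptide("SPTKPK")),
               "photo-reactive")
  expect_error(crosslink_mass(peptide("BGRB"), peptide("SPTKPK")),
               "photo-reactive")

  # additivity over generated pairs
  set.seed(11)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    a <- peptide(paste(c(sample(aas, sample(3:12, 1), TRUE), "B",
                         sample(aas, 2, TRUE)), collapse = ""))
    b <- peptide(paste(sample(aas, sample(2:15, 1), TRUE), collapse = ""))
    xl <- crosslink_mass(a, b)
    expect_identical(xl$mass, peptide_mass(a) + peptide_mass(b))
  }
})

test_that("ppm error follows the (obs - theo)/theo convention", {
  expect_equal(ppm_error(2000, 2000), 0)
  expect_equal(ppm_error(2000.02, 2000.00), 10, tolerance = 1e-6)
  xl1 <- crosslink_mass(peptide("LDGQTPBEDRNR"), peptide("QTEIFTHFM[ox]TNSAK"))
  expect_equal(abs(ppm_error(3220.4946, xl1$mass)), 1.9, tolerance = 0.15)
  expect_error(ppm_error(-1, 100), "positive")
})

test_that("m/z conversion round-trips and validates charge", {
  expect_equal(mass_to_mz(2000, 2), 1001.00728, tolerance = 1e-5)
  expect_equal(mass_to_mz(3220.4884, 3), 1074.5035, tolerance = 1e-4)
  expect_equal(mz_to_mass(mass_to_mz(1536.7, 4), 4), 1536.7)
  expect_error(mass_to_mz(2000, 0), "charge")
})

test_that("isotope patterns are normalized, non-negative and truncation-stable", {
  g <- isotope_pattern(peptide("G"), 5)
  expect_equal(sum(g$abundance), 1, tolerance = 1e-6)
  expect_true(all(g$abundance >= 0))
  expect_equal(which.max(g$abundance), 1L)  # small molecule: mono peak dominates
  expect_equal(diff(g$mass), rep(1.0033548, 4), tolerance = 1e-6)

  # ~3.2 kDa crosslinked peptide: most abundant isotopologue is not the mono peak
  xl1 <- crosslink_mass(peptide("LDGQTPBEDRNR"), peptide("QTEIFTHFM[ox]TNSAK"))
  ip <- isotope_pattern(xl1, 10)
  expect_equal(ip$mass[1], xl1$mass)
  expect_gte(which.max(ip$abundance), 2L)

  # monotone truncation: adding peaks rescales but never reorders earlier peaks
  short <- isotope_pattern(xl1, 4)
  long <- isotope_pattern(xl1, 8)
  expect_equal(short$abundance / short$abundance[1],
               long$abundance[1:4] / long$abundance[1], tolerance = 1e-9)
})
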