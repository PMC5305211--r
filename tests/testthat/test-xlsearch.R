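test_that("candidate enumeration counts pairs and oxidation variants", {
  cand <- enumerate_candidates("AGBGK", c("GRPK", "SPTKPK", "IVER"),
                               max_ox = 0)
  expect_equal(nrow(cand), 3L)

  cand_ox <- enumerate_candidates("AGBGK", "QTEIFTHFMTNSAK", max_ox = 1)
  expect_equal(nrow(cand_ox), 2L)
  expect_equal(abs(diff(sort(cand_ox$mass))), 15.9949, tolerance = 1e-4)

  expect_error(enumerate_candidates("AGGGK", "GRPK"), "B/X")
})

test_that("MS1 matching equals brute force and is monotone in the window", {
  set.seed(7)
  cand_masses <- runif(200, 800, 4000)
  candidates <- data.frame(candidate_id = sprintf("C%03d", 1:200),
                           mass = cand_masses)
  # half the features near real candidates, half random
  feats <- data.frame(mass = c(
    cand_masses[1:25] * (1 + rnorm(25, 0, 5e-6)),
    runif(25, 800, 4000)))
  got <- match_ms1(feats, candidates, window_ppm = 10)
  want <- brute_force_ms1(feats$mass, cand_masses, 10)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$feature, got$candidate_id),
                  paste(want$feature, sprintf("C%03d", want$cand)))
  expect_equal(sort(got$ppm), sort(want$ppm), tolerance = 1e-9)

  wide <- match_ms1(feats, candidates, window_ppm = 25)
  expect_true(all(paste(got$feature, got$candidate_id) %in%
                    paste(wide$feature, wide$candidate_id)))
})

test_that("MS1 matching accepts m/z + charge features", {
  candidates <- data.frame(candidate_id = "C001", mass = 2207.0971)
  feats <- data.frame(mz = mass_to_mz(2207.0968, 3), charge = 3)
  expect_equal(nrow(match_ms1(feats, candidates)), 1L)
  expect_equal(nrow(match_ms1(data.frame(mass = 2300), candidates)), 0L)
})

test_that("fragment ions count 2(n-1), include y1 of R, and shift across the link", {
  xl <- crosslink_mass(peptide("BGRK"), peptide("GRPK"))
  fa <- fragment_ions(xl, "alpha")
  expect_equal(nrow(fa), 6L)  # b1..b3, y1..y3
  fb <- fragment_ions(xl, "beta", link_site = 2)
  # beta fragments containing residue 2 carry the alpha mass
  alpha_m <- peptide_mass(xl$alpha)
  b1 <- fb$neutral_mass[fb$ion == "b1"]
  b2 <- fb$neutral_mass[fb$ion == "b2"]
  expect_equal(b2 - b1 - alpha_m, peptide_mass("R") - 18.010565,
               tolerance = 1e-5)
  y3 <- fb$neutral_mass[fb$ion == "y3"]  # spans residues 2..4: shifted
  y2 <- fb$neutral_mass[fb$ion == "y2"]  # residues 3..4: unshifted
  expect_gt(y3 - y2, alpha_m)
})

test_that("y1 fragment of a peptide ending in R is 175.1190 at z = 1", {
  xl <- crosslink_mass(peptide("BGK"), peptide("GPGR"))
  fb <- fragment_ions(xl, "beta", link_site = 1)
  y1 <- fb$neutral_mass[fb$ion == "y1"]
  expect_equal(mass_to_mz(y1, 1), 175.1190, tolerance = 1e-3)
})

test_that("MS2 scoring finds a complete ladder and rejects a shifted one", {
  xl <- crosslink_mass(peptide("LDGQTPBEDR"), peptide("SPTKPK"))
  z <- 4L
  frags <- rbind(fragment_ions(xl, "alpha"),
                 fragment_ions(xl, "beta", link_site = 3))
  mz <- unlist(lapply(1:2, function(zz) mass_to_mz(frags$neutral_mass, zz)))
  sp <- list(precursor_mz = mass_to_mz(xl$mass, z), precursor_z = z,
             peaks = data.frame(mz = sort(mz), intensity = 1000))
  rep <- score_ms2(sp, xl, window_ppm = 15)
  expect_equal(rep$matched_alpha, rep$total_alpha)
  expect_equal(rep$matched_beta, rep$total_beta)
  expect_equal(rep$intensity_explained, 1)

  sp_shift <- sp
  sp_shift$peaks$mz <- sp_shift$peaks$mz * (1 + 50e-6)
  rep2 <- score_ms2(sp_shift, xl, window_ppm = 15)
  expect_equal(rep2$matched_alpha + rep2$matched_beta, 0L)
  expect_equal(rep2$intensity_explained, 0)
})

test_that("planted-fragment recovery matches generator bookkeeping", {
  sim <- simulate_xl_ms(xlms_recipe(seed = 19, decoy_density = 0,
                                    ladder_completeness = 0.6))
  for (i in seq_along(sim$spectra)) {
    sp <- sim$spectra[[i]]
    xl <- crosslink_mass(peptide(sim$truth$alpha[i]),
                         peptide(sim$truth$beta[i]))
    rep <- score_ms2(sp, xl, window_ppm = 15)
    planted <- length(sp$planted_ions)
    expect_gte(rep$matched_alpha + rep$matched_beta, planted)
  }
})

test_that("site localization returns single sites, ranges, and full peptides", {
  xl <- crosslink_mass(peptide("BGRK", start = 100),
                       peptide("GAGAGR", start = 200))
  true_site <- 3L
  frags <- rbind(fragment_ions(xl, "alpha"),
                 fragment_ions(xl, "beta", link_site = true_site))
  full <- list(precursor_mz = mass_to_mz(xl$mass, 4), precursor_z = 4L,
               peaks = data.frame(mz = sort(mass_to_mz(frags$neutral_mass, 1)),
                                  intensity = 1))
  loc <- localize_sites(score_ms2(full, xl))
  beta <- loc[loc$chain == "beta", ]
  expect_equal(beta$site_min, true_site)
  expect_equal(beta$site_max, true_site)
  expect_equal(beta$parent_min, 200 + true_site - 1L)
  alpha <- loc[loc$chain == "alpha", ]
  expect_equal(alpha$parent_min, 100)  # the Bpa position

  # remove the beta ions discriminating sites 3..5 -> interval 3..5
  fb <- fragment_ions(xl, "beta", link_site = true_site)
  keep <- !(fb$type == "b" & fb$index %in% 3:4) &
    !(fb$type == "y" & (6 - fb$index + 1) %in% 4:5)
  frags2 <- rbind(fragment_ions(xl, "alpha"), fb[keep, ])
  sp2 <- list(precursor_mz = mass_to_mz(xl$mass, 4), precursor_z = 4L,
              peaks = data.frame(mz = sort(mass_to_mz(frags2$neutral_mass, 1)),
                                 intensity = 1))
  loc2 <- localize_sites(score_ms2(sp2, xl))
  beta2 <- loc2[loc2$chain == "beta", ]
  expect_lte(beta2$site_min, true_site)
  expect_gte(beta2$site_max, true_site)
  expect_gt(beta2$site_max - beta2$site_min, 0)

  # no discriminating evidence at all -> full-peptide interval
  sp3 <- list(precursor_mz = mass_to_mz(xl$mass, 4), precursor_z = 4L,
              peaks = data.frame(mz = 123.456, intensity = 1))
  loc3 <- localize_sites(score_ms2(sp3, xl))
  beta3 <- loc3[loc3$chain == "beta", ]
  expect_equal(c(beta3$site_min, beta3$site_max), c(1L, 6L))
})

test_that("UV dependence flags enrichment and floors the -UV signal", {
  plus <- data.frame(mass = 2000, intensity = 1e6)
  minus0 <- data.frame(mass = 3000, intensity = 1e6)  # species absent in -UV
  uv <- uv_dependence(plus, minus0, 2000)
  expect_equal(uv$ratio, 100)  # floored at 1% of +UV
  expect_true(uv$flagged)

  uv_eq <- uv_dependence(plus, plus, 2000)
  expect_equal(uv_eq$ratio, 1)
  expect_false(uv_eq$flagged)

  expect_error(uv_dependence(minus0, minus0, 2000), "absent")

  sim <- simulate_xl_ms(xlms_recipe(seed = 5, uv_enrichment = 20))
  for (m in sim$truth$mass)
    expect_true(uv_dependence(sim$ms1_plus, sim$ms1_minus, m)$flagged)
})

test_that("reliability rubric tiers matches deterministically", {
  m <- data.frame(matched_alpha = c(5, 5, 1, 5),
                  matched_beta = c(4, 0, 1, 4),
                  uv_flagged = c(TRUE, TRUE, TRUE, FALSE),
                  ppm = c(2, 2, 2, 2))
  tiers <- tier_matches(m)$reliability
  expect_equal(tiers, c("high", "medium", "low", "medium"))
  # high also requires tight MS1 error
  m2 <- m[1, ]; m2$ppm <- 8
  expect_equal(tier_matches(m2)$reliability, "medium")
})

test_that("confident identifications are planted pairs and recall is high", {
  n_true <- 0; n_found <- 0; n_false <- 0
  for (seed in 1:10) {
    sim <- simulate_xl_ms(xlms_recipe(seed = seed))
    xls <- search_crosslinks(sim$proteins["bait"], sim$proteins["prey"],
                             sim$ms1_plus, sim$ms1_minus, sim$spectra)
    conf <- xls[xls$reliability != "low", ]
    planted_keys <- paste(sim$truth$alpha, sim$truth$beta)
    got_keys <- paste(gsub("\\[ox\\]", "", conf$alpha_seq),
                      gsub("\\[ox\\]", "", conf$beta_seq))
    n_false <- n_false + sum(!got_keys %in% planted_keys)
    n_true <- n_true + length(planted_keys)
    n_found <- n_found + sum(planted_keys %in% got_keys)
  }
  expect_equal(n_false, 0L)
  expect_gte(n_found / n_true, 0.95)
})

test_that("shuffled-prey decoy search yields far fewer matches", {
  n_real <- 0; n_decoy <- 0
  for (seed in 1:5) {
    sim <- simulate_xl_ms(xlms_recipe(seed = seed))
    real <- search_crosslinks(sim$proteins["bait"], sim$proteins["prey"],
                              sim$ms1_plus, sim$ms1_minus, sim$spectra)
    set.seed(seed + 1000)
    shuffled <- paste(sample(strsplit(sim$proteins[["prey"]], "")[[1]]),
                      collapse = "")
    decoy <- search_crosslinks(sim$proteins["bait"], shuffled,
                               sim$ms1_plus, sim$ms1_minus, sim$spectra)
    # compare confident identifications; chance MS1-only hits rank low
    n_real <- n_real + sum(real$reliability != "low")
    n_decoy <- n_decoy + sum(decoy$reliability != "low")
  }
  expect_gte(n_real, 10 * max(n_decoy, 1))
})
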