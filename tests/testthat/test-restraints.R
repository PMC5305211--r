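test_that("high-reliability H4 crosslinks collapse to three unique linkages", {
  h4 <- reference_crosslinks("h4")
  hi <- h4[h4$reliability == "high", ]
  expect_equal(nrow(hi), 5L)
  r <- restraints_from_crosslinks(data.frame(
    alpha_chain = "H4", alpha_site = hi$alpha_site,
    beta_chain = "ISWI", beta_site = hi$beta_site))
  expect_equal(nrow(r), 3L)
  expect_true(all(r$bound == 20))
})

test_that("ambiguous site ranges parse, including truncated upper bounds", {
  m <- data.frame(alpha_chain = "P", alpha_site = "1",
                  beta_chain = "R", beta_site = "519-522")
  r <- restraints_from_crosslinks(m)
  expect_equal(r$res_b[[1]], 519:522)
  # published shorthand "519-22"
  m2 <- data.frame(alpha_chain = "P", alpha_site = "1",
                   beta_chain = "R", beta_site = "519-22")
  expect_equal(restraints_from_crosslinks(m2)$res_b[[1]], 519:522)
  expect_error(restraints_from_crosslinks(
    data.frame(alpha_chain = "P", alpha_site = NA,
               beta_chain = "R", beta_site = "5")), "localized")
})

test_that("filtering retains exactly the constructed-satisfying models", {
  sim <- simulate_ensemble(ensemble_recipe(seed = 21, n_models = 10,
                                           f_pocket = 0.4))
  pocket <- sim$truth$pocket_residues
  r <- restraints_from_crosslinks(data.frame(
    alpha_chain = "P", alpha_site = c("1", "4"),
    beta_chain = "R",
    beta_site = c(as.character(pocket[1]),
                  sprintf("%d-%d", pocket[2], pocket[3]))))
  f <- filter_ensemble(sim$ensemble, r)
  expect_equal(attr(f, "kept"), which(sim$truth$in_pocket))
  expect_equal(attr(f, "kept"), brute_force_filter(sim$ensemble, r))

  # f = 1 retains everything
  sim1 <- simulate_ensemble(ensemble_recipe(seed = 22, n_models = 6,
                                            f_pocket = 1))
  f1 <- filter_ensemble(sim1$ensemble, r)
  expect_equal(length(attr(f1, "kept")), 6L)

  # empty restraint set: vacuous satisfaction
  f0 <- filter_ensemble(sim$ensemble, r[0, ])
  expect_equal(length(attr(f0, "kept")), 10L)

  # bound 0 excludes every model
  r0 <- r; r0$bound <- 0
  expect_equal(length(attr(filter_ensemble(sim$ensemble, r0), "kept")), 0L)

  expect_error(filter_ensemble(sim$ensemble, restraints_from_crosslinks(
    data.frame(alpha_chain = "P", alpha_site = "1",
               beta_chain = "R", beta_site = "999"))), "missing")
})

test_that("filtering is idempotent and monotone", {
  sim <- simulate_ensemble(ensemble_recipe(seed = 33, n_models = 12,
                                           f_pocket = 0.5))
  pocket <- sim$truth$pocket_residues
  r <- restraints_from_crosslinks(data.frame(
    alpha_chain = "P", alpha_site = "1", beta_chain = "R",
    beta_site = as.character(pocket[1:2])))
  f1 <- filter_ensemble(sim$ensemble, r)
  f2 <- filter_ensemble(f1, r)
  expect_equal(f2$xyz, f1$xyz)

  # larger bound never removes models
  r_wide <- r; r_wide$bound <- 35
  kept_wide <- attr(filter_ensemble(sim$ensemble, r_wide), "kept")
  expect_true(all(attr(f1, "kept") %in% kept_wide))

  # extra restraints never add models
  r_more <- restraints_from_crosslinks(data.frame(
    alpha_chain = "P", alpha_site = c("1", "1", "8"), beta_chain = "R",
    beta_site = as.character(pocket[1:3])))
  kept_more <- attr(filter_ensemble(sim$ensemble, r_more), "kept")
  expect_true(all(kept_more %in% attr(f1, "kept")))
})

test_that("contact probabilities are counts over models with correct marginals", {
  sim <- simulate_ensemble(ensemble_recipe(seed = 8, n_models = 1))
  s1 <- contact_surface(sim$ensemble, "P", "R")
  expect_true(all(s1$pairwise %in% c(0, 1)))
  expect_true(all(s1$marginal %in% c(0, 1)))

  sim2 <- simulate_ensemble(ensemble_recipe(seed = 8, n_models = 2,
                                            f_pocket = 0.5))
  s2 <- contact_surface(sim2$ensemble, "P", "R")
  expect_true(any(abs(s2$marginal - 0.5) < 1e-9))
  expect_error(contact_surface(sim2$ensemble, "Z", "R"), "unknown chain")

  # union bound: max pairwise <= marginal <= sum pairwise
  sim3 <- simulate_ensemble(ensemble_recipe(seed = 9, n_models = 15,
                                            f_pocket = 0.6, jitter = 1.5))
  s3 <- contact_surface(sim3$ensemble, "P", "R")
  pmax_col <- apply(s3$pairwise, 2, max)
  psum_col <- colSums(s3$pairwise)
  expect_true(all(s3$marginal >= pmax_col - 1e-12))
  expect_true(all(s3$marginal <= psum_col + 1e-12))
})

test_that("pocket marginals track the planted pocket fraction", {
  sim <- simulate_ensemble(ensemble_recipe(seed = 14, n_models = 40,
                                           f_pocket = 0.7))
  s <- contact_surface(sim$ensemble, "P", "R")
  core <- sim$truth$pocket_residues
  marg <- s$marginal[as.character(core)]
  # binomial error around f for residues in solid contact
  expect_gt(mean(marg), 0.7 - 2 * sqrt(0.7 * 0.3 / 40) - 0.1)
  expect_lte(max(marg), 0.7 + 1e-9)
})

test_that("surface B-factors round-trip through a PDB reader", {
  sim <- simulate_ensemble(ensemble_recipe(seed = 4, n_models = 5,
                                           f_pocket = 1))
  s <- contact_surface(sim$ensemble, "P", "R")
  tf <- tempfile(fileext = ".pdb")
  write_surface_pdb(sim$ensemble, s, tf)
  back <- bio3d::read.pdb(tf)
  sel <- back$atom$chain == "R"
  got <- back$atom$b[sel] / 100
  want <- as.numeric(s$marginal[as.character(back$atom$resno[sel])])
  expect_true(all(abs(got - want) <= 0.01))
  expect_true(any(got == 1))   # fully conserved contact writes B = 100
})

test_that("multi-model PDB files and model directories read back identically", {
  sim <- simulate_ensemble(ensemble_recipe(seed = 6, n_models = 4))
  tf <- tempfile(fileext = ".pdb")
  xlmap:::.write_multimodel_pdb(sim$ensemble, tf)
  e <- read_ensemble(tf)
  expect_equal(nrow(e$xyz), 4L)
  expect_equal(as.numeric(e$xyz[2, ]),
               as.numeric(sim$ensemble$xyz[2, ]), tolerance = 1e-3)

  dir <- tempfile(); dir.create(dir)
  for (m in 1:4) {
    single <- sim$ensemble
    single$xyz <- bio3d::as.xyz(matrix(sim$ensemble$xyz[m, ], nrow = 1))
    xlmap:::.write_multimodel_pdb(single, file.path(dir, sprintf("m%02d.pdb", m)))
  }
  ed <- read_ensemble(dir)
  expect_equal(nrow(ed$xyz), 4L)
  expect_equal(as.numeric(ed$xyz), as.numeric(e$xyz), tolerance = 1e-3)
})
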