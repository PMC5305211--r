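# Seeded generators for every input the pipeline consumes: crosslink MS
# runs (FASTA + MS1 feature lists +/-UV + MGF spectra + truth), docked
# model ensembles with a planted binding pocket, and kinetic traces.
# A fixed seed makes every generator bit-reproducible, and each emits the
# planted truth alongside the data so downstream stages can be scored.

#' Recipe for a simulated crosslinking-MS experiment
#'
#' @param seed Integer seed fixing all randomness.
#' @param bait Bait protein sequence containing photo-reactive residue(s)
#'   (`B`/`X`). The default is a short construct with one Bpa site.
#' @param prey Prey protein sequence.
#' @param planted data.frame with columns `alpha` and `beta`: tryptic
#'   peptide sequences of bait and prey forming the planted crosslinks.
#'   `NULL` plants every bait peptide containing the photo residue against
#'   the first three prey peptides.
#' @param sigma_ppm Gaussian MS1/MS2 mass error, ppm (default 3).
#' @param uv_enrichment Fold intensity enrichment of crosslink features in
#'   the +UV condition (default 20).
#' @param ladder_completeness Fraction of theoretical b/y fragments present
#'   in each MS2 spectrum (default 0.8).
#' @param decoy_density Decoy MS1 features per Da of the scanned mass range
#'   (default 0.05) and expected noise peaks per MS2 spectrum scale.
#' @param precursor_z Precursor charge assigned to the spectra (default 4).
#' @return list of class `xlms_recipe`.
#' @export
xlms_recipe <- function(seed = 1L,
                        bait = "MKVSAEHALDGQTPBEDRNRQSTLK",
                        prey = "MSPTKPKGRAEILTHFMTNSAKDDIKQWER",
                        planted = NULL,
                        sigma_ppm = 3,
                        uv_enrichment = 20,
                        ladder_completeness = 0.8,
                        decoy_density = 0.05,
                        precursor_z = 4L) {
  structure(list(seed = as.integer(seed), bait = bait, prey = prey,
                 planted = planted, sigma_ppm = sigma_ppm,
                 uv_enrichment = uv_enrichment,
                 ladder_completeness = ladder_completeness,
                 decoy_density = decoy_density,
                 precursor_z = as.integer(precursor_z)),
            class = "xlms_recipe")
}

#' Simulate a crosslinking-MS experiment
#'
#' Digests the bait and prey in silico, plants crosslinked species, and
#' emits (a) MS1 feature lists for +UV and -UV conditions in which planted
#' masses carry Gaussian ppm error and are enriched in +UV, plus uniform
#' decoy features; (b) MS2 spectra holding a stated fraction of the
#' theoretical b/y ladder plus Poisson-many noise peaks; (c) a truth table.
#'
#' @param recipe An [xlms_recipe()].
#' @param out_dir Optional directory; when given, FASTA/TSV/MGF/TSV files
#'   are written there.
#' @return list with `proteins`, `ms1_plus`, `ms1_minus`, `spectra`,
#'   `truth` (data.frame: alpha, beta, mass, beta_link_site), and `paths`
#'   when files were written.
#' @export
simulate_xl_ms <- function(recipe = xlms_recipe(), out_dir = NULL) {
  stopifnot(inherits(recipe, "xlms_recipe"))
  set.seed(recipe$seed)
  spec <- digest_spec()
  bait_pep <- digest(recipe$bait, spec, parent = "bait")
  prey_pep <- digest(recipe$prey, spec, parent = "prey")
  bait_pep <- bait_pep[vapply(bait_pep$sequence,
                              function(s) length(photo_sites(s)) == 1L, TRUE), ]
  if (!nrow(bait_pep)) stop("inconsistent recipe: no bait peptide with one B/X")

  planted <- recipe$planted
  if (is.null(planted)) {
    # unmodified tryptic prey peptides, no missed cleavage, as link targets
    prey0 <- prey_pep[prey_pep$missed == 0L, ]
    alpha <- bait_pep$sequence[which.max(nchar(bait_pep$sequence))]
    planted <- data.frame(alpha = alpha,
                          beta = utils::head(prey0$sequence, 3L))
  }
  truth <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
    a <- planted$alpha[i]; b <- planted$beta[i]
    xl <- crosslink_mass(peptide(a), peptide(b))
    beta_site <- sample.int(nchar(b), 1L)
    data.frame(alpha = a, beta = b, mass = xl$mass, beta_link_site = beta_site)
  }))

  base_int <- 1e6
  perturb <- function(m) m * (1 + stats::rnorm(length(m), 0, recipe$sigma_ppm * 1e-6))
  mass_range <- range(truth$mass) + c(-200, 200)
  n_decoy <- stats::rpois(1, recipe$decoy_density * diff(mass_range))
  decoys <- function() data.frame(
    mass = stats::runif(n_decoy, mass_range[1], mass_range[2]),
    intensity = stats::rlnorm(n_decoy, log(base_int / 50), 0.5))
  ms1_plus <- rbind(
    data.frame(mass = perturb(truth$mass),
               intensity = base_int * stats::rlnorm(nrow(truth), 0, 0.1)),
    decoys())
  ms1_plus$condition <- "plusUV"
  ms1_minus <- rbind(
    data.frame(mass = perturb(truth$mass),
               intensity = base_int / recipe$uv_enrichment *
                 stats::rlnorm(nrow(truth), 0, 0.1)),
    decoys())
  ms1_minus$condition <- "minusUV"

  spectra <- lapply(seq_len(nrow(truth)), function(i) {
    xl <- crosslink_mass(peptide(truth$alpha[i]), peptide(truth$beta[i]))
    fa <- .fragment_mz(xl, "alpha", photo_sites(xl$alpha), 1:2)
    fb <- .fragment_mz(xl, "beta", truth$beta_link_site[i], 1:2)
    fr <- rbind(fa, fb)
    keep <- stats::runif(nrow(fr)) <= recipe$ladder_completeness
    mz <- perturb(fr$mz[keep])
    int <- stats::rlnorm(sum(keep), log(1e4), 0.4)
    n_noise <- stats::rpois(1, 100 * recipe$decoy_density / 0.05)
    if (recipe$decoy_density == 0) n_noise <- 0L
    if (n_noise > 0) {
      mz <- c(mz, stats::runif(n_noise, 150, mass_to_mz(xl$mass, 1)))
      int <- c(int, stats::rlnorm(n_noise, log(500), 0.5))
    }
    ord <- order(mz)
    list(title = sprintf("planted_%d", i),
         precursor_mz = mass_to_mz(truth$mass[i] *
                                     (1 + stats::rnorm(1, 0, recipe$sigma_ppm * 1e-6)),
                                   recipe$precursor_z),
         precursor_z = recipe$precursor_z,
         peaks = data.frame(mz = mz[ord], intensity = int[ord]),
         n_planted_fragments = sum(keep),
         planted_ions = unique(fr$ion[keep]))
  })

  out <- list(proteins = c(bait = recipe$bait, prey = recipe$prey),
              ms1_plus = ms1_plus, ms1_minus = ms1_minus,
              spectra = spectra, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "proteins.fasta"),
      ms1_plus = file.path(out_dir, "ms1_plusUV.tsv"),
      ms1_minus = file.path(out_dir, "ms1_minusUV.tsv"),
      mgf = file.path(out_dir, "spectra.mgf"),
      truth = file.path(out_dir, "truth.tsv"))
    write_fasta(out$proteins, paths$fasta)
    write_ms1(ms1_plus, paths$ms1_plus)
    write_ms1(ms1_minus, paths$ms1_minus)
    write_mgf(spectra, paths$mgf)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Recipe for a synthetic docked-model ensemble
#'
#' The receptor is a generated three-helix C-alpha bundle (chain `R`); the
#' docked peptide (chain `P`) is placed inside a designated pocket in a
#' stated fraction of the models and far outside it in the rest.
#'
#' @param seed Integer seed.
#' @param n_models Ensemble size.
#' @param f_pocket Fraction of models with the peptide in the pocket.
#' @param receptor_len Residues per receptor helix (3 helices).
#' @param peptide_len Docked peptide length.
#' @param jitter Coordinate noise (Angstrom s.d.) added to every atom.
#' @return list of class `ensemble_recipe`.
#' @export
ensemble_recipe <- function(seed = 1L, n_models = 20L, f_pocket = 0.5,
                            receptor_len = 20L, peptide_len = 8L,
                            jitter = 0.3) {
  if (f_pocket < 0 || f_pocket > 1) stop("f_pocket must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_models = as.integer(n_models),
                 f_pocket = f_pocket, receptor_len = as.integer(receptor_len),
                 peptide_len = as.integer(peptide_len), jitter = jitter),
            class = "ensemble_recipe")
}

# idealized C-alpha helix along +z: rise 1.5 A, radius 2.3 A, 100 deg/res
.helix_ca <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1L
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang) + origin[1], 2.3 * sin(ang) + origin[2],
        1.5 * i + origin[3])
}

#' Simulate a docked-model ensemble with a planted pocket
#'
#' Builds `n_models` copies of a rigid three-helix receptor bundle; in
#' `round(f_pocket * n_models)` of them the peptide sits in the central
#' groove of the bundle (the planted pocket), in the rest it is displaced
#' ~60 Angstrom away. By construction exactly the pocket-placed models
#' satisfy any crosslink restraint between the peptide and pocket residues
#' with the default 20 Angstrom bound.
#'
#' @param recipe An [ensemble_recipe()].
#' @param out_file Optional multi-model PDB path.
#' @return list with `ensemble` (bio3d `pdb`, multi-row `xyz`), `truth`
#'   (list: `in_pocket` logical vector, `pocket_residues` receptor residue
#'   numbers lining the pocket), and `path` if written.
#' @export
simulate_ensemble <- function(recipe = ensemble_recipe(), out_file = NULL) {
  stopifnot(inherits(recipe, "ensemble_recipe"))
  set.seed(recipe$seed)
  nr <- recipe$receptor_len
  # three parallel helices equidistant from the z-axis; the central groove
  # (the planted pocket) is threaded by the peptide
  rec <- rbind(.helix_ca(nr, c(6, 0, 0)),
               .helix_ca(nr, c(-3, 3 * sqrt(3), 0)),
               .helix_ca(nr, c(-3, -3 * sqrt(3), 0)))
  np <- recipe$peptide_len
  # extended peptide threading the central groove of the bundle
  pep0 <- cbind(0.5 * sin(seq_len(np)), 0.5 * cos(seq_len(np)),
                seq(5, by = 2.5, length.out = np))
  n_atoms <- nrow(rec) + np
  in_pocket <- rep(FALSE, recipe$n_models)
  if (recipe$n_models > 0)
    in_pocket[seq_len(round(recipe$f_pocket * recipe$n_models))] <- TRUE

  xyz <- matrix(NA_real_, recipe$n_models, 3 * n_atoms)
  for (m in seq_len(recipe$n_models)) {
    pep <- pep0
    if (!in_pocket[m]) pep <- sweep(pep, 2, c(60, 60, 30), `+`)
    coords <- rbind(rec, pep) +
      matrix(stats::rnorm(3 * n_atoms, 0, recipe$jitter), n_atoms, 3)
    xyz[m, ] <- as.vector(t(coords))
  }

  atom <- data.frame(
    type = "ATOM", eleno = seq_len(n_atoms), elety = "CA", alt = "",
    resid = "ALA", chain = c(rep("R", nrow(rec)), rep("P", np)),
    resno = c(seq_len(nrow(rec)), seq_len(np)), insert = "",
    x = xyz[1, seq(1, by = 3, length.out = n_atoms)],
    y = xyz[1, seq(2, by = 3, length.out = n_atoms)],
    z = xyz[1, seq(3, by = 3, length.out = n_atoms)],
    o = 1, b = 0, segid = "", elesy = "C", charge = "")
  ensemble <- structure(list(atom = atom, xyz = bio3d::as.xyz(xyz),
                             calpha = rep(TRUE, n_atoms)), class = "pdb")

  # planted pocket = receptor residues in contact (5 A, the default contact
  # cutoff) with the ideally placed peptide
  d <- sqrt(pmax(outer(rowSums(rec^2), rowSums(pep0^2), `+`) -
                   2 * tcrossprod(rec, pep0), 0))
  pocket_res <- which(apply(d, 1, min) <= 5)

  out <- list(ensemble = ensemble,
              truth = list(in_pocket = in_pocket,
                           pocket_residues = sort(unique(pocket_res))))
  if (!is.null(out_file)) {
    .write_multimodel_pdb(ensemble, out_file)
    out$path <- out_file
  }
  out
}

# bio3d::write.pdb writes single models; emit MODEL/ENDMDL blocks ourselves
.write_multimodel_pdb <- function(ensemble, path) {
  xyz <- .ensure_xyz_matrix(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  a <- ensemble$atom
  for (m in seq_len(nrow(xyz))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xs <- xyz[m, seq(1, by = 3, length.out = nrow(a))]
    ys <- xyz[m, seq(2, by = 3, length.out = nrow(a))]
    zs <- xyz[m, seq(3, by = 3, length.out = nrow(a))]
    writeLines(sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$eleno, paste0(" ", a$elety), "", a$resid, a$chain, a$resno, "",
      xs, ys, zs, a$o, a$b, a$elesy), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a model ensemble from PDB input
#'
#' Accepts a multi-model PDB file (MODEL/ENDMDL records) or a directory of
#' single-model files sharing one topology.
#'
#' @param path PDB file or directory.
#' @return bio3d `pdb` object with one `xyz` row per model.
#' @export
read_ensemble <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (!length(files)) stop("no PDB files in directory")
    pdbs <- lapply(files, bio3d::read.pdb, multi = FALSE)
    ref <- pdbs[[1]]
    xyz <- do.call(rbind, lapply(pdbs, function(p) {
      if (nrow(p$atom) != nrow(ref$atom))
        stop("models do not share one topology")
      as.vector(p$xyz)
    }))
    ref$xyz <- bio3d::as.xyz(xyz)
    return(ref)
  }
  bio3d::read.pdb(path, multi = TRUE)
}

#' Recipe for simulated kinetic traces
#'
#' @param seed Integer seed.
#' @param kind `"exponential"` (remodeling time course, signal approaching a
#'   plateau) or `"linear"` (NADH-depletion absorbance trace).
#' @param k Rate constant (s^-1) for exponential traces.
#' @param slope Slope (AU/s, negative) for linear traces.
#' @param y0,y_inf Start and plateau signal for exponential traces.
#' @param noise_sd Gaussian noise s.d.; for exponential traces interpreted
#'   as a fraction of the amplitude.
#' @param n_points Points per trace.
#' @param t_max Trace duration (s).
#' @param replicates Number of replicate traces.
#' @return list of class `kinetics_recipe`.
#' @export
kinetics_recipe <- function(seed = 1L, kind = c("exponential", "linear"),
                            k = 0.05, slope = -0.00622, y0 = 1, y_inf = 0,
                            noise_sd = 0.05, n_points = 40L, t_max = NULL,
                            replicates = 1L) {
  kind <- match.arg(kind)
  if (kind == "exponential" && k <= 0) stop("k must be positive")
  if (is.null(t_max)) t_max <- if (kind == "exponential") 4 / k else 120
  structure(list(seed = as.integer(seed), kind = kind, k = k, slope = slope,
                 y0 = y0, y_inf = y_inf, noise_sd = noise_sd,
                 n_points = as.integer(n_points), t_max = t_max,
                 replicates = as.integer(replicates)),
            class = "kinetics_recipe")
}

#' Simulate kinetic traces
#'
#' Exponential traces follow `y(t) = y_inf + (y0 - y_inf) exp(-k t)`; linear
#' traces follow `y(t) = y0 + slope * t`. Gaussian noise is added per point.
#'
#' @param recipe A [kinetics_recipe()].
#' @param out_file Optional CSV path.
#' @return list with `traces` (data.frame: time, signal, replicate) and
#'   `truth` (the generating parameters).
#' @export
simulate_kinetics <- function(recipe = kinetics_recipe(), out_file = NULL) {
  stopifnot(inherits(recipe, "kinetics_recipe"))
  set.seed(recipe$seed)
  t <- seq(0, recipe$t_max, length.out = recipe$n_points)
  traces <- do.call(rbind, lapply(seq_len(recipe$replicates), function(r) {
    y <- if (recipe$kind == "exponential") {
      amp <- recipe$y0 - recipe$y_inf
      recipe$y_inf + amp * exp(-recipe$k * t) +
        stats::rnorm(length(t), 0, recipe$noise_sd * abs(amp))
    } else {
      recipe$y0 + recipe$slope * t + stats::rnorm(length(t), 0, recipe$noise_sd)
    }
    data.frame(time = t, signal = y, replicate = r)
  }))
  out <- list(traces = traces,
              truth = recipe[c("kind", "k", "slope", "y0", "y_inf", "noise_sd")])
  if (!is.null(out_file)) {
    write_traces(traces, out_file)
    out$path <- out_file
  }
  out
}
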