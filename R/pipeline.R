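# End-to-end orchestration: crosslink search -> restraints -> ensemble
# filtering -> contact surface, with a serialized config and log so a run is
# reproducible from its output directory.

#' Default run configuration
#'
#' Every instrument- or method-level constant is a named, defaulted field:
#' MS1/MS2 error windows (10/15 ppm), precursor charges considered (3-5),
#' scanned m/z range (375-1600), restraint bound (20 Angstrom), contact
#' cutoff (5 Angstrom), UV-dependence threshold (5-fold) and the tier
#' rubric thresholds.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    ms1_window_ppm = 10,
    ms2_window_ppm = 15,
    precursor_charges = 3:5,
    mz_range = c(375, 1600),
    max_missed_cleavages = 2L,
    peptide_length = c(2L, 30L),
    max_ox = 1L,
    uv_threshold = 5,
    uv_floor_frac = 0.01,
    tier_min_frag = 3L,
    tier_high_ppm = 5,
    restraint_bound = 20,
    restraint_atom = "CA",
    contact_cutoff = 5,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Search crosslinked peptide pairs in MS data
#'
#' Runs the identification chain: tryptic digestion of bait (photo-labeled)
#' and prey proteins, candidate enumeration with variable Met oxidation,
#' MS1 precursor matching in the +UV run, MS2 fragment assignment and site
#' localization, UV-dependence quantification and reliability tiering.
#'
#' @param bait,prey Protein sequences (bait carries `B`/`X`).
#' @param ms1_plus,ms1_minus MS1 feature data.frames for the +UV and -UV
#'   conditions.
#' @param spectra List of MS2 spectra (see [read_mgf()]).
#' @param config A [run_config()].
#' @return data.frame: one row per identified crosslink with mass, ppm
#'   error, per-chain fragment counts, localized parent-coordinate sites,
#'   UV ratio and reliability tier.
#' @export
search_crosslinks <- function(bait, prey, ms1_plus, ms1_minus = NULL,
                              spectra = list(), config = run_config()) {
  dspec <- digest_spec(config$max_missed_cleavages,
                       config$peptide_length[1], config$peptide_length[2])
  bait_pep <- digest(bait, dspec, parent = "bait")
  prey_pep <- digest(prey, dspec, parent = "prey")
  bait_pep <- bait_pep[vapply(bait_pep$sequence,
                              function(s) length(photo_sites(s)) == 1L, TRUE), ,
                       drop = FALSE]
  candidates <- enumerate_candidates(bait_pep, prey_pep, max_ox = config$max_ox)
  ms1_hits <- match_ms1(ms1_plus, candidates, config$ms1_window_ppm)
  if (!nrow(ms1_hits)) return(.empty_match_table())

  # one row per candidate with MS1 support; best (lowest |ppm|) feature kept
  ms1_hits <- ms1_hits[order(abs(ms1_hits$ppm)), ]
  ms1_hits <- ms1_hits[!duplicated(ms1_hits$candidate_id), ]

  rows <- lapply(seq_len(nrow(ms1_hits)), function(i) {
    cid <- ms1_hits$candidate_id[i]
    xl <- candidates$species[[match(cid, candidates$candidate_id)]]
    # best-scoring spectrum within the MS1 window of this species
    best <- NULL
    for (sp in spectra) {
      if (is.na(sp$precursor_z) ||
          !sp$precursor_z %in% config$precursor_charges) next
      pmass <- mz_to_mass(sp$precursor_mz, sp$precursor_z)
      if (abs(ppm_error(pmass, xl$mass)) > config$ms1_window_ppm) next
      rep <- score_ms2(sp, xl, config$ms2_window_ppm)
      if (is.null(best) ||
          rep$matched_alpha + rep$matched_beta >
            best$matched_alpha + best$matched_beta) best <- rep
    }
    uv <- tryCatch(
      uv_dependence(ms1_plus, ms1_minus, xl$mass, config$ms1_window_ppm,
                    config$uv_threshold, config$uv_floor_frac),
      error = function(e) list(ratio = NA_real_, flagged = FALSE))
    loc <- if (!is.null(best)) localize_sites(best) else NULL
    site_str <- function(chain) {
      if (is.null(loc)) return(NA_character_)
      l <- loc[loc$chain == chain, ]
      lo <- if (!is.na(l$parent_min)) l$parent_min else l$site_min
      hi <- if (!is.na(l$parent_max)) l$parent_max else l$site_max
      if (lo == hi) as.character(lo) else sprintf("%d-%d", lo, hi)
    }
    data.frame(
      candidate_id = cid,
      alpha_seq = candidates$alpha_seq[match(cid, candidates$candidate_id)],
      beta_seq = candidates$beta_seq[match(cid, candidates$candidate_id)],
      mass_obs = ms1_hits$mass_obs[i], mass_theo = ms1_hits$mass_theo[i],
      ppm = ms1_hits$ppm[i],
      matched_alpha = if (!is.null(best)) best$matched_alpha else 0L,
      matched_beta = if (!is.null(best)) best$matched_beta else 0L,
      alpha_site = site_str("alpha"), beta_site = site_str("beta"),
      uv_ratio = uv$ratio, uv_flagged = uv$flagged)
  })
  tier_matches(do.call(rbind, rows), config$tier_min_frag,
               config$tier_high_ppm)
}

.empty_match_table <- function() {
  data.frame(candidate_id = character(0), alpha_seq = character(0),
             beta_seq = character(0), mass_obs = numeric(0),
             mass_theo = numeric(0), ppm = numeric(0),
             matched_alpha = integer(0), matched_beta = integer(0),
             alpha_site = character(0), beta_site = character(0),
             uv_ratio = numeric(0), uv_flagged = logical(0),
             reliability = character(0))
}

#' Run the full crosslink-to-surface mapping pipeline
#'
#' Stages, in order: crosslink search ([search_crosslinks()]), restraint
#' construction from the high-reliability matches
#' ([restraints_from_crosslinks()]), ensemble filtering
#' ([filter_ensemble()]), contact-probability surface ([contact_surface()]).
#' All stage outputs, the fully resolved config and a log are written under
#' `out_dir`; a rerun with the same inputs and config is byte-identical.
#'
#' @param inputs list with `bait`, `prey` (sequences), `ms1_plus`,
#'   `ms1_minus`, `spectra`, `ensemble` (bio3d `pdb`), `peptide_chain`,
#'   `receptor_chain`, and `site_map` — a function mapping a crosslink-table
#'   row to chain-level sites (defaults to using the localized sites with
#'   alpha on `peptide_chain`, beta on `receptor_chain`).
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return list with `crosslinks`, `restraints`, `filtered` (ensemble),
#'   `surface`, `report` (summary list).
#' @export
run_mapping <- function(inputs, config = run_config(), out_dir = NULL) {
  required <- c("bait", "prey", "ms1_plus", "spectra", "ensemble",
                "peptide_chain", "receptor_chain")
  missing <- setdiff(required, names(inputs))
  if (length(missing))
    stop("missing input(s): ", paste(missing, collapse = ", "))

  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message("[xlmap] ", msg)
  }

  say("stage search: digesting and matching")
  xls <- tryCatch(
    search_crosslinks(inputs$bait, inputs$prey, inputs$ms1_plus,
                      inputs$ms1_minus, inputs$spectra, config),
    error = function(e) stop("stage 'search' failed: ", conditionMessage(e)))
  say("stage search: %d crosslinks (%d high)", nrow(xls),
      sum(xls$reliability == "high"))

  hi <- xls[xls$reliability == "high", , drop = FALSE]
  if (!nrow(hi)) hi <- xls
  if (!is.null(inputs$site_map)) {
    mapped <- lapply(seq_len(nrow(hi)), function(i) inputs$site_map(hi[i, ]))
    m <- data.frame(alpha_chain = inputs$peptide_chain,
                    alpha_site = vapply(mapped, function(x)
                      as.character(x$alpha_site), ""),
                    beta_chain = inputs$receptor_chain,
                    beta_site = vapply(mapped, function(x)
                      as.character(x$beta_site), ""))
  } else {
    loc <- !is.na(hi$alpha_site) & !is.na(hi$beta_site)
    if (!all(loc)) say("stage restraints: dropping %d unlocalized match(es)",
                       sum(!loc))
    hi <- hi[loc, , drop = FALSE]
    m <- data.frame(alpha_chain = inputs$peptide_chain,
                    alpha_site = hi$alpha_site,
                    beta_chain = inputs$receptor_chain,
                    beta_site = hi$beta_site)
  }
  restraints <- tryCatch(
    restraints_from_crosslinks(m, config$restraint_bound,
                               config$restraint_atom),
    error = function(e) stop("stage 'restraints' failed: ", conditionMessage(e)))
  say("stage restraints: %d unique linkages from %d matches",
      nrow(restraints), nrow(hi))

  filtered <- tryCatch(filter_ensemble(inputs$ensemble, restraints),
                       error = function(e)
                         stop("stage 'filter' failed: ", conditionMessage(e)))
  n_in <- nrow(.ensure_xyz_matrix(inputs$ensemble))
  n_keep <- length(attr(filtered, "kept"))
  say("stage filter: retained %d of %d models", n_keep, n_in)
  if (n_keep == 0L) stop("stage 'filter' failed: no model satisfies the restraints")

  surface <- tryCatch(
    contact_surface(filtered, inputs$peptide_chain, inputs$receptor_chain,
                    config$contact_cutoff),
    error = function(e) stop("stage 'surface' failed: ", conditionMessage(e)))
  top <- sort(surface$marginal, decreasing = TRUE)
  top <- top[top > 0]
  say("stage surface: %d contact residues, top: %s", length(top),
      paste(utils::head(names(top), 5), collapse = ","))

  report <- list(n_crosslinks = nrow(xls),
                 n_high = sum(xls$reliability == "high"),
                 n_unique_linkages = nrow(restraints),
                 n_models_in = n_in, n_models_retained = n_keep,
                 top_contact_residues = as.integer(names(top)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_crosslink_table(xls, file.path(out_dir, "crosslinks.tsv"))
    utils::write.table(
      data.frame(chain_a = restraints$chain_a,
                 res_a = vapply(restraints$res_a, paste, "", collapse = ","),
                 chain_b = restraints$chain_b,
                 res_b = vapply(restraints$res_b, paste, "", collapse = ","),
                 bound = restraints$bound, atom = restraints$atom),
      file.path(out_dir, "restraints.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    .write_multimodel_pdb(filtered, file.path(out_dir, "filtered_models.pdb"))
    utils::write.table(
      data.frame(residue = as.integer(names(surface$marginal)),
                 contact_probability = as.numeric(surface$marginal)),
      file.path(out_dir, "contact_surface.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_surface_pdb(filtered, surface,
                      file.path(out_dir, "surface_bfactor.pdb"))
    write_config(config, file.path(out_dir, "config.yaml"))
    writeLines(log, file.path(out_dir, "run.log"))
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "report.json"))
  }
  list(crosslinks = xls, restraints = restraints, filtered = filtered,
       surface = surface, report = report)
}
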