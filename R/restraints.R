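# Crosslink-derived distance restraints, ensemble filtering and contact-
# probability surfaces.
#
# An ensemble is represented the bio3d way: a `pdb` object whose `xyz` is a
# matrix with one row per model (as returned by bio3d::read.pdb(multi=TRUE)).

#' Build distance restraints from localized crosslink matches
#'
#' One upper-bound restraint per crosslink. A localized site range (e.g.
#' 519-522) yields an ambiguous restraint satisfied when ANY residue in the
#' range lies within the bound — the photo-chemistry marks one unknown
#' residue of the range. Matches collapsing to the same residue linkage are
#' deduplicated.
#'
#' @param matches data.frame with columns `alpha_chain`, `alpha_site`,
#'   `beta_chain`, `beta_site`; sites are integers or `"a-b"` range strings.
#' @param bound Upper distance bound in Angstrom (default 20).
#' @param atom Atom used to measure the distance (default `"CA"`).
#' @return data.frame of class `xl_restraints` with list columns `res_a`,
#'   `res_b` (integer vectors of allowed residues) and columns `chain_a`,
#'   `chain_b`, `bound`, `atom`.
#' @export
#' @examples
#' m <- data.frame(alpha_chain = "P", alpha_site = "1",
#'                 beta_chain = "R", beta_site = c("482", "482", "519-522"))
#' restraints_from_crosslinks(m)
restraints_from_crosslinks <- function(matches, bound = 20, atom = "CA") {
  stopifnot(bound > 0, is.data.frame(matches),
            all(c("alpha_chain", "alpha_site", "beta_chain", "beta_site") %in%
                  names(matches)))
  if (any(is.na(matches$alpha_site)) || any(is.na(matches$beta_site)))
    stop("every match must carry localized sites")
  res_a <- lapply(matches$alpha_site, .parse_site_range)
  res_b <- lapply(matches$beta_site, .parse_site_range)
  key <- paste(matches$alpha_chain,
               vapply(res_a, paste, "", collapse = ","),
               matches$beta_chain,
               vapply(res_b, paste, "", collapse = ","))
  keep <- !duplicated(key)
  out <- data.frame(chain_a = matches$alpha_chain[keep],
                    chain_b = matches$beta_chain[keep],
                    bound = bound, atom = atom)
  out$res_a <- I(res_a[keep])
  out$res_b <- I(res_b[keep])
  class(out) <- c("xl_restraints", class(out))
  out
}

.parse_site_range <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- as.integer(strsplit(as.character(x), "[-–]")[[1]])
  if (anyNA(parts)) stop(sprintf("cannot parse site '%s'", x))
  if (length(parts) == 1L) return(parts)
  # ranges may be printed with a truncated upper bound ("519-22")
  if (parts[2] < parts[1])
    parts[2] <- parts[1] - parts[1] %% 10^nchar(as.character(parts[2])) + parts[2]
  seq.int(parts[1], parts[2])
}

# coordinates of the selected atoms of given residues, one model
.atom_xyz <- function(pdb, xyz_row, chain, resno, atom = NULL) {
  sel <- pdb$atom$chain == chain & pdb$atom$resno %in% resno &
    !grepl("^H", pdb$atom$elety)
  if (!is.null(atom)) sel <- sel & pdb$atom$elety == atom
  idx <- which(sel)
  if (!length(idx)) return(NULL)
  m <- matrix(xyz_row[as.vector(t(cbind(3 * idx - 2, 3 * idx - 1, 3 * idx)))],
              ncol = 3, byrow = TRUE)
  list(xyz = m, resno = pdb$atom$resno[idx])
}

.min_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Test restraint satisfaction for every model of an ensemble
#'
#' @param ensemble bio3d `pdb` object with multi-row `xyz`.
#' @param restraints An `xl_restraints` table.
#' @return Logical matrix, models x restraints.
#' @export
satisfaction_matrix <- function(ensemble, restraints) {
  xyz <- .ensure_xyz_matrix(ensemble)
  nmod <- nrow(xyz)
  sat <- matrix(TRUE, nmod, nrow(restraints))
  for (r in seq_len(nrow(restraints))) {
    atom <- restraints$atom[r]
    for (m in seq_len(nmod)) {
      a <- .atom_xyz(ensemble, xyz[m, ], restraints$chain_a[r],
                     restraints$res_a[[r]], atom)
      b <- .atom_xyz(ensemble, xyz[m, ], restraints$chain_b[r],
                     restraints$res_b[[r]], atom)
      if (is.null(a) || is.null(b))
        stop(sprintf("restraint %d references residues missing from the models", r))
      sat[m, r] <- .min_dist(a$xyz, b$xyz) <= restraints$bound[r]
    }
  }
  sat
}

.ensure_xyz_matrix <- function(ensemble) {
  xyz <- ensemble$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz
}

#' Filter an ensemble to restraint-satisfying models
#'
#' Keeps exactly the models in which every restraint is satisfied (ambiguous
#' restraints by any-of semantics), preserving order. Filtering is
#' idempotent and monotone: a larger bound never removes models and extra
#' restraints never add any.
#'
#' @inheritParams satisfaction_matrix
#' @return The ensemble with `xyz` reduced to the retained models; the
#'   retained indices are stored in `attr(, "kept")`.
#' @export
filter_ensemble <- function(ensemble, restraints) {
  xyz <- .ensure_xyz_matrix(ensemble)
  keep <- if (is.null(restraints) || nrow(restraints) == 0L)
    seq_len(nrow(xyz))
  else which(rowSums(!satisfaction_matrix(ensemble, restraints)) == 0L)
  out <- ensemble
  out$xyz <- bio3d::as.xyz(xyz[keep, , drop = FALSE])
  attr(out, "kept") <- keep
  out
}

#' Contact-probability surface across an ensemble
#'
#' A peptide residue i and receptor residue j are in contact in a model when
#' their minimum heavy-atom distance is at most `cutoff`. The pairwise
#' probability is the fraction of models with the contact; the per-receptor-
#' residue marginal is the fraction of models in which that residue contacts
#' ANY peptide residue.
#'
#' @param ensemble bio3d `pdb` with multi-row `xyz`.
#' @param peptide_chain,receptor_chain Chain identifiers.
#' @param cutoff Contact distance in Angstrom (default 5).
#' @return List of class `contact_surface`: `pairwise` (matrix peptide x
#'   receptor residues), `marginal` (named vector per receptor residue),
#'   `n_models`.
#' @export
contact_surface <- function(ensemble, peptide_chain, receptor_chain,
                            cutoff = 5) {
  xyz <- .ensure_xyz_matrix(ensemble)
  if (!peptide_chain %in% ensemble$atom$chain ||
      !receptor_chain %in% ensemble$atom$chain)
    stop("unknown chain identifier")
  pres <- sort(unique(ensemble$atom$resno[ensemble$atom$chain == peptide_chain]))
  rres <- sort(unique(ensemble$atom$resno[ensemble$atom$chain == receptor_chain]))
  nmod <- nrow(xyz)
  counts <- matrix(0L, length(pres), length(rres),
                   dimnames = list(pres, rres))
  marg_counts <- stats::setNames(integer(length(rres)), rres)
  for (m in seq_len(nmod)) {
    pa <- .atom_xyz(ensemble, xyz[m, ], peptide_chain, pres)
    ra <- .atom_xyz(ensemble, xyz[m, ], receptor_chain, rres)
    d2 <- outer(rowSums(pa$xyz^2), rowSums(ra$xyz^2), `+`) -
      2 * tcrossprod(pa$xyz, ra$xyz)
    contact <- sqrt(pmax(d2, 0)) <= cutoff
    pair <- t(rowsum(t(rowsum(contact + 0, pa$resno)), ra$resno)) > 0
    counts[rownames(pair), colnames(pair)] <-
      counts[rownames(pair), colnames(pair)] + pair
    marg_counts[colnames(pair)] <- marg_counts[colnames(pair)] +
      (colSums(pair) > 0)
  }
  structure(list(pairwise = counts / nmod, marginal = marg_counts / nmod,
                 n_models = nmod, peptide_chain = peptide_chain,
                 receptor_chain = receptor_chain, cutoff = cutoff),
            class = "contact_surface")
}

#' @export
print.contact_surface <- function(x, ...) {
  top <- sort(x$marginal, decreasing = TRUE)
  cat(sprintf("<contact_surface> %d models, %d x %d residues; top residues: %s\n",
              x$n_models, nrow(x$pairwise), ncol(x$pairwise),
              paste(sprintf("%s (%.2f)", names(top)[1:min(5, length(top))],
                            top[1:min(5, length(top))]), collapse = ", ")))
  invisible(x)
}

#' Write a contact surface onto a representative model as B-factors
#'
#' Per-residue marginal contact probabilities are scaled to 0-100 and stored
#' in the B-factor field of the receptor chain, so standard viewers can
#' color the surface. The file round-trips through any PDB reader.
#'
#' @param ensemble bio3d `pdb`; the first model is used.
#' @param surface A `contact_surface` computed on the same topology.
#' @param path Output PDB path.
#' @export
write_surface_pdb <- function(ensemble, surface, path) {
  stopifnot(inherits(surface, "contact_surface"))
  rres <- as.integer(names(surface$marginal))
  if (!all(rres %in% ensemble$atom$resno[ensemble$atom$chain ==
                                         surface$receptor_chain]))
    stop("surface topology does not match the ensemble")
  xyz <- .ensure_xyz_matrix(ensemble)
  b <- numeric(nrow(ensemble$atom))
  sel <- ensemble$atom$chain == surface$receptor_chain
  b[sel] <- round(100 * surface$marginal[as.character(ensemble$atom$resno[sel])], 2)
  bio3d::write.pdb(pdb = ensemble, xyz = xyz[1, ], b = b, file = path)
  invisible(path)
}
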