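# Monoisotopic mass calculus for modified and photo-crosslinked peptides.
#
# Two residue letters beyond the standard 20 are accepted, exactly as they
# appear in published crosslink tables:
#   B  p-benzoyl-phenylalanine (Bpa): Phe + C7H4O
#   X  4-maleimidobenzophenone-labeled cysteine: Cys + C17H11NO3
# Photo-insertion of the benzophenone into a C-H bond adds zero mass, so a
# crosslinked pair weighs exactly the sum of its two peptides.

# monoisotopic element masses (IUPAC)
.elements <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)

#' Physical constants used in the mass calculus
#'
#' Proton mass (Da), water monoisotopic mass (Da) and the average
#' isotopologue spacing (Da per extra neutron) used for isotope grids.
#' @name mass-constants
#' @keywords internal
NULL

.proton_mass  <- 1.00727646688
.water_mass   <- 2 * .elements[["H"]] + .elements[["O"]]
.neutron_step <- 1.0033548378

# residue elemental compositions (C, H, N, O, S), residue = amino acid - water
.residue_comp <- rbind(
  G = c(2, 3, 1, 1, 0),
  A = c(3, 5, 1, 1, 0),
  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),
  V = c(5, 9, 1, 1, 0),
  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),
  L = c(6, 11, 1, 1, 0),
  I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),
  D = c(4, 5, 1, 3, 0),
  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0),
  E = c(5, 7, 1, 3, 0),
  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),
  F = c(9, 9, 1, 1, 0),
  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),
  W = c(11, 10, 2, 1, 0),
  # Bpa = Phe + C7H4O
  B = c(16, 13, 1, 2, 0),
  # benzophenone-maleimide labeled Cys = Cys + C17H11NO3
  X = c(20, 16, 2, 4, 1)
)
colnames(.residue_comp) <- names(.elements)

# named modifications: elemental delta and the residue letter it may sit on
.modifications <- list(
  ox  = list(delta = c(C = 0, H = 0, N = 0, O = 1, S = 0), target = "M",
             name = "methionine oxidation"),
  cam = list(delta = c(C = 2, H = 3, N = 1, O = 1, S = 0), target = "C",
             name = "carbamidomethyl cysteine")
)

#' Residue and modification mass table
#'
#' Returns the table of residue elemental compositions and monoisotopic
#' masses used throughout the package, including the photo-reactive residues
#' `B` (Bpa, Phe + C7H4O) and `X` (benzophenone-labeled Cys, Cys + C17H11NO3),
#' and the named modification deltas (`ox` = +15.9949 Da on Met, `cam` =
#' +57.0215 Da on Cys).
#'
#' @return A list with elements `residues` (data.frame: residue, C, H, N, O,
#'   S, mass) and `modifications` (data.frame: name, target, delta).
#' @export
#' @examples
#' residue_table()$modifications
residue_table <- function() {
  mass <- as.vector(.residue_comp %*% .elements)
  residues <- data.frame(residue = rownames(.residue_comp), .residue_comp,
                         mass = mass, row.names = NULL)
  mods <- data.frame(
    name = names(.modifications),
    target = vapply(.modifications, `[[`, "", "target"),
    delta = vapply(.modifications, function(m) sum(m$delta * .elements), 0),
    row.names = NULL)
  list(residues = residues, modifications = mods)
}

#' Construct a peptide with positioned modifications
#'
#' A peptide is a protein subsequence with an optional map of positioned
#' modifications. Inline notation is accepted: `"QTEIFTHFM[ox]TNSAK"` marks
#' an oxidized methionine. By default every unlabeled cysteine carries a
#' fixed carbamidomethyl group (`cam`), the standard alkylation of in-gel
#' tryptic digests; the labeled residue `X` never does.
#'
#' @param sequence Peptide sequence, possibly with inline `[mod]` tags after
#'   the modified residue. Letters `B` (Bpa) and `X` (labeled Cys) allowed.
#' @param mods Named character vector: names are 1-based positions, values
#'   modification names (`"ox"`, `"cam"`). Merged with inline tags.
#' @param parent Optional parent protein identifier.
#' @param start 1-based start position in the parent (end is implied).
#' @param fixed_cam Apply carbamidomethyl to every unmodified `C`.
#' @return An object of class `xl_peptide`.
#' @export
#' @examples
#' p <- peptide("QTEIFTHFM[ox]TNSAK")
#' peptide_mass(p)
peptide <- function(sequence, mods = NULL, parent = NA_character_,
                    start = NA_integer_, fixed_cam = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single character string")
  parsed <- .parse_inline_mods(sequence)
  seq <- parsed$sequence
  if (nchar(seq) == 0L) stop("empty peptide sequence")
  aa <- strsplit(seq, "")[[1]]
  bad <- which(!aa %in% rownames(.residue_comp))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))

  allmods <- parsed$mods
  if (!is.null(mods) && length(mods)) {
    m <- as.character(mods)
    names(m) <- names(mods)
    allmods <- c(allmods, m)
  }
  if (anyDuplicated(names(allmods)))
    stop("at most one modification per position")
  if (isTRUE(fixed_cam)) {
    cys <- which(aa == "C")
    cys <- setdiff(cys, as.integer(names(allmods)))
    if (length(cys)) {
      camv <- rep("cam", length(cys))
      names(camv) <- cys
      allmods <- c(allmods, camv)
    }
  }
  # validate placement
  for (posc in names(allmods)) {
    pos <- as.integer(posc)
    mod <- allmods[[posc]]
    if (is.na(pos) || pos < 1L || pos > length(aa))
      stop(sprintf("modification position %s outside peptide", posc))
    if (!mod %in% names(.modifications))
      stop(sprintf("unknown modification '%s' at position %d", mod, pos))
    if (aa[pos] != .modifications[[mod]]$target)
      stop(sprintf("modification '%s' not allowed on residue '%s' at position %d",
                   mod, aa[pos], pos))
  }
  if (length(allmods)) allmods <- allmods[order(as.integer(names(allmods)))]
  structure(list(sequence = seq, mods = allmods, parent = parent,
                 start = as.integer(start),
                 end = if (is.na(start)) NA_integer_
                       else as.integer(start) + nchar(seq) - 1L),
            class = "xl_peptide")
}

.parse_inline_mods <- function(sequence) {
  mods <- character(0)
  out <- character(0)
  chars <- strsplit(sequence, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (!length(close)) stop("unterminated modification tag in sequence")
      tag <- paste(chars[(i + 1L):(close[1] - 1L)], collapse = "")
      if (!length(out)) stop("modification tag before first residue")
      m <- tag
      names(m) <- length(out)
      mods <- c(mods, m)
      i <- close[1] + 1L
    } else {
      out <- c(out, toupper(ch))
      i <- i + 1L
    }
  }
  list(sequence = paste(out, collapse = ""), mods = mods)
}

#' @export
print.xl_peptide <- function(x, ...) {
  modtxt <- if (length(x$mods))
    paste(sprintf("%s@%s", x$mods, names(x$mods)), collapse = ", ") else "none"
  cat(sprintf("<xl_peptide> %s  (mods: %s)  mass %.4f Da\n",
              x$sequence, modtxt, peptide_mass(x)))
  invisible(x)
}

.as_peptide <- function(x, ...) {
  if (inherits(x, "xl_peptide")) x else peptide(x, ...)
}

#' Elemental composition of a peptide or crosslinked species
#'
#' @param x An `xl_peptide`, `xl_species`, or sequence string.
#' @return Named integer vector of C, H, N, O, S counts (water included).
#' @export
peptide_composition <- function(x) {
  if (inherits(x, "xl_species"))
    return(peptide_composition(x$alpha) + peptide_composition(x$beta))
  p <- .as_peptide(x)
  aa <- strsplit(p$sequence, "")[[1]]
  comp <- colSums(.residue_comp[aa, , drop = FALSE])
  for (mod in p$mods) comp <- comp + .modifications[[mod]]$delta
  comp + c(C = 0, H = 2, N = 0, O = 1, S = 0)   # water
}

#' Neutral monoisotopic mass of a peptide
#'
#' Two independent code paths are provided: `"composition"` computes the mass
#' from summed element counts, `"residue"` sums per-residue monoisotopic
#' masses plus modification deltas plus water. They agree to < 1e-9 Da and
#' the duplication exists so each can audit the other.
#'
#' @param p An `xl_peptide` or sequence string.
#' @param method `"composition"` (default) or `"residue"`.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("GRPK")   # 456.2809
peptide_mass <- function(p, method = c("composition", "residue")) {
  method <- match.arg(method)
  p <- .as_peptide(p)
  if (method == "composition") {
    sum(peptide_composition(p) * .elements)
  } else {
    aa <- strsplit(p$sequence, "")[[1]]
    rmass <- .residue_comp %*% .elements
    deltas <- vapply(p$mods, function(m) sum(.modifications[[m]]$delta * .elements), 0)
    sum(rmass[aa, ]) + sum(deltas) + .water_mass
  }
}

#' Positions of photo-reactive residues (B or X) in a peptide
#' @param p An `xl_peptide` or sequence string.
#' @return Integer vector of positions.
#' @export
photo_sites <- function(p) {
  p <- .as_peptide(p)
  which(strsplit(p$sequence, "")[[1]] %in% c("B", "X"))
}

#' Crosslinked peptide pair
#'
#' Benzophenone photo-chemistry inserts into a C-H bond without gain or loss
#' of atoms, so the neutral mass of the crosslinked species is exactly the
#' sum of the two peptide masses (zero linker delta). The alpha peptide must
#' carry exactly one photo-reactive residue (`B` or `X`).
#'
#' @param alpha Peptide carrying the photo-reactive group.
#' @param beta Target peptide.
#' @return An object of class `xl_species` with fields `alpha`, `beta`,
#'   `mass`.
#' @export
#' @examples
#' xl <- crosslink_mass(peptide("LDGQTPBEDRNR"), peptide("SPTKPK"))
#' xl$mass   # 2207.097
crosslink_mass <- function(alpha, beta) {
  alpha <- .as_peptide(alpha)
  beta <- .as_peptide(beta)
  np <- length(photo_sites(alpha))
  if (np != 1L)
    stop(sprintf("alpha peptide must contain exactly one photo-reactive residue (B/X), found %d", np))
  structure(list(alpha = alpha, beta = beta,
                 mass = peptide_mass(alpha) + peptide_mass(beta)),
            class = "xl_species")
}

#' @export
print.xl_species <- function(x, ...) {
  cat(sprintf("<xl_species> %s -- %s  mass %.4f Da\n",
              x$alpha$sequence, x$beta$sequence, x$mass))
  invisible(x)
}

#' Relative mass error in parts per million
#'
#' Sign convention: `(observed - theoretical) / theoretical * 1e6`.
#'
#' @param observed,theoretical Neutral masses in Da, both > 0.
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(observed <= 0) || any(theoretical <= 0))
    stop("masses must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Convert neutral mass to m/z and back
#'
#' @param neutral_mass Neutral mass in Da.
#' @param z Positive integer charge.
#' @return `mass_to_mz`: m/z; `mz_to_mass`: neutral mass.
#' @export
mass_to_mz <- function(neutral_mass, z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L)) stop("charge must be a positive integer")
  (neutral_mass + z * .proton_mass) / z
}

#' @rdname mass_to_mz
#' @param mz Mass-to-charge ratio.
#' @export
mz_to_mass <- function(mz, z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L)) stop("charge must be a positive integer")
  mz * z - z * .proton_mass
}

# isotope abundance vectors per element, indexed by neutron offset 0,1,2,...
.isotope_dist <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99632, 0.00368),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9493, 0.0076, 0.0429, 0.0000, 0.0002)
)

# distribution of n iid copies of 'dist' by repeated squaring convolution
.convolve_power <- function(dist, n, maxlen) {
  res <- 1
  base <- dist
  while (n > 0) {
    if (n %% 2 == 1) {
      res <- convolve(res, rev(base), type = "open")
      if (length(res) > maxlen) res <- res[seq_len(maxlen)]
    }
    n <- n %/% 2
    if (n > 0) {
      base <- convolve(base, rev(base), type = "open")
      if (length(base) > maxlen) base <- base[seq_len(maxlen)]
    }
  }
  res
}

#' Isotope pattern from exact elemental composition
#'
#' Convolves per-element isotopologue distributions (no averagine
#' approximation) and reports the first `n_peaks` isotopologues. Abundances
#' are renormalized to sum to one over the returned peaks; the first peak is
#' the monoisotopic mass and successive peaks are spaced by one neutron
#' (~1.00335 Da).
#'
#' @param x An `xl_peptide`, `xl_species`, sequence string, or named
#'   composition vector (C,H,N,O,S).
#' @param n_peaks Number of isotopologue peaks to return.
#' @return data.frame with columns `mass`, `abundance`.
#' @export
#' @examples
#' isotope_pattern(peptide("G"), n_peaks = 3)
isotope_pattern <- function(x, n_peaks = 10L) {
  comp <- if (is.numeric(x)) {
    if (is.null(names(x)) || !all(names(.elements) %in% names(x)))
      stop("composition vector must be named with C,H,N,O,S")
    x[names(.elements)]
  } else peptide_composition(x)
  n_peaks <- max(1L, as.integer(n_peaks))
  maxlen <- n_peaks + 2L
  ab <- 1
  for (el in names(.elements)) {
    n <- comp[[el]]
    if (n > 0) {
      ab <- convolve(ab, rev(.convolve_power(.isotope_dist[[el]], n, maxlen)),
                     type = "open")
      if (length(ab) > maxlen) ab <- ab[seq_len(maxlen)]
    }
  }
  ab <- pmax(ab, 0)[seq_len(min(n_peaks, length(ab)))]
  mono <- sum(comp * .elements)
  data.frame(mass = mono + (seq_along(ab) - 1L) * .neutron_step,
             abundance = ab / sum(ab))
}
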