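# In-silico tryptic digestion.

#' Digestion rule
#'
#' Trypsin cleaves C-terminal of K or R, but not when the next residue is
#' proline. Defaults: up to 2 missed cleavages, peptide length 2-30.
#'
#' @param missed Maximum missed cleavages.
#' @param min_length,max_length Peptide length bounds (residues).
#' @return A list of class `digest_spec`.
#' @export
digest_spec <- function(missed = 2L, min_length = 2L, max_length = 30L) {
  stopifnot(missed >= 0, min_length >= 1, max_length >= min_length)
  structure(list(missed = as.integer(missed),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_spec")
}

# 0-based cut positions after each cleavable residue (K/R not before P)
.cut_sites <- function(aa) {
  n <- length(aa)
  k <- which(aa %in% c("K", "R"))
  k <- k[k < n & aa[pmin(k + 1L, n)] != "P"]
  k
}

#' Tryptic digest of a protein sequence
#'
#' Emits every peptide consistent with the cleavage rule and the missed-
#' cleavage and length bounds, ordered by start position then length.
#'
#' @param sequence Protein sequence over the 20 standard residues plus the
#'   photo-reactive letters `B` and `X`.
#' @param spec A [digest_spec()].
#' @param parent Parent protein id recorded on each peptide.
#' @return data.frame with columns `start`, `end`, `sequence`, `missed`.
#' @export
#' @examples
#' digest("SPTKPKGR", digest_spec(missed = 0))
digest <- function(sequence, spec = digest_spec(), parent = NA_character_) {
  stopifnot(inherits(spec, "digest_spec"))
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single string")
  if (nchar(sequence) == 0L)
    return(data.frame(parent = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      missed = integer(0)))
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% rownames(.residue_comp))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d", aa[bad[1]], bad[1]))

  bounds <- c(0L, .cut_sites(aa), length(aa))   # segment boundaries
  nseg <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + spec$missed)) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len >= spec$min_length && len <= spec$max_length)
        out[[length(out) + 1L]] <- data.frame(
          parent = parent, start = s, end = e,
          sequence = paste(aa[s:e], collapse = ""),
          missed = j - i)
    }
  }
  if (!length(out))
    return(data.frame(parent = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      missed = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$end - res$start), , drop = FALSE]
}
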