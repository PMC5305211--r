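# File formats: FASTA (via Biostrings), MGF centroid spectra, MS1 feature
# TSVs, kinetic trace CSVs and the crosslink result table.
#
# MGF is a line-oriented text format (BEGIN IONS / END IONS blocks with
# PEPMASS, CHARGE, TITLE headers and mz-intensity pairs); the reader below
# covers exactly that subset.

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Write protein sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read MS2 centroid spectra from an MGF file
#'
#' @param path MGF file.
#' @return List of spectra; each a list with `title`, `precursor_mz`,
#'   `precursor_z`, `peaks` (data.frame `mz`, `intensity`, sorted by mz).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  spectra <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[[`, "", 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    pk <- block[!hdr & nzchar(trimws(block))]
    mzint <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), as.numeric))
    peaks <- if (is.null(mzint))
      data.frame(mz = numeric(0), intensity = numeric(0))
    else data.frame(mz = mzint[, 1], intensity = mzint[, 2])
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    pepmass <- as.numeric(strsplit(vals[match("PEPMASS", keys)], "[ \t]+")[[1]][1])
    zraw <- vals[match("CHARGE", keys)]
    z <- if (is.na(zraw)) NA_integer_ else as.integer(gsub("[^0-9]", "", zraw))
    spectra[[i]] <- list(title = vals[match("TITLE", keys)],
                         precursor_mz = pepmass, precursor_z = z,
                         peaks = peaks)
  }
  spectra
}

#' Write MS2 centroid spectra to an MGF file
#' @param spectra List of spectra as returned by [read_mgf()].
#' @param path Output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$title) && !is.na(sp$title))
      writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", sp$precursor_z), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.4f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read / write MS1 feature lists
#'
#' Tab-separated with columns `mass` (neutral Da) or `mz` + `charge`, plus
#' `intensity` and `condition` (`plusUV` / `minusUV`).
#'
#' @param path TSV file.
#' @return data.frame of features.
#' @export
read_ms1 <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_ms1
#' @param features data.frame of features.
#' @export
write_ms1 <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write kinetic traces
#'
#' CSV with columns `time`, `signal` and optionally `replicate`.
#' @param path CSV file.
#' @return data.frame.
#' @export
read_traces <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_traces
#' @param traces data.frame of traces.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a crosslink result table
#'
#' Columns mirror published crosslink overview tables: id, observed and
#' theoretical mass, ppm error, sequences and localized sites of both
#' chains, UV ratio and reliability tier.
#'
#' @param table data.frame of crosslink matches.
#' @param path Output TSV.
#' @export
write_crosslink_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled reference crosslink tables
#'
#' Machine-readable versions of the two published crosslink overview tables
#' for the ISWI remodeler: `"ntr"` — crosslinks formed by Bpa at ISWI
#' position 483 to the N-terminal region; `"h4"` — crosslinks formed by
#' photo-reactive H4-tail probes (Bpa peptides and benzophenone-labeled
#' nucleosomal H4) to Lobe 2 of ISWI or SNF2H. Sequences use inline
#' notation (`B`, `X`, `M[ox]`); `inferred_ox` marks entries whose printed
#' mass requires a methionine oxidation not annotated in the published
#' sequence.
#'
#' @param which `"ntr"` or `"h4"`.
#' @return data.frame with columns `id`, `reliability` (h4 set only),
#'   `mass_obs`, `error_ppm`, `alpha_seq`, `alpha_site`, `beta_seq`,
#'   `beta_site`, `inferred_ox`.
#' @export
#' @examples
#' head(reference_crosslinks("h4"))
reference_crosslinks <- function(which = c("ntr", "h4")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("%s_crosslinks.tsv", which), package = "xlmap",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(alpha_site = "character",
                                   beta_site = "character"))
}
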