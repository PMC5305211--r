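# Identification of crosslinked peptide pairs from MS1 features and MS2
# spectra: candidate enumeration, precursor matching, fragment assignment,
# site localization, UV dependence and reliability tiering.

#' Enumerate candidate crosslinked species
#'
#' Forms the Cartesian product of bait peptides (each must carry exactly one
#' photo-reactive `B`/`X` residue; others are dropped) and prey peptides,
#' expanded over variable methionine oxidation on either chain. Duplicate
#' candidates (same sequences, same modifications, same mass) are collapsed.
#'
#' @param bait,prey data.frames as returned by [digest()] (columns `parent`,
#'   `start`, `sequence`), or character vectors of sequences.
#' @param max_ox Maximum number of oxidized methionines per peptide.
#' @return data.frame with columns `candidate_id`, `alpha_seq`, `beta_seq`
#'   (inline-modified notation), `mass`, and list column `species` holding
#'   the `xl_species` objects.
#' @export
enumerate_candidates <- function(bait, prey, max_ox = 1L) {
  bait <- .as_peptide_frame(bait)
  prey <- .as_peptide_frame(prey)
  if (!nrow(bait)) stop("bait peptide set is empty")
  keep <- vapply(seq_len(nrow(bait)), function(i)
    length(photo_sites(bait$sequence[i])) == 1L, TRUE)
  bait <- bait[keep, , drop = FALSE]
  if (!nrow(bait)) stop("no bait peptide carries exactly one B/X residue")

  alpha <- .expand_ox(bait, max_ox)
  beta <- .expand_ox(prey, max_ox)
  if (!nrow(beta))
    return(.empty_candidates())

  grid <- expand.grid(a = seq_len(nrow(alpha)), b = seq_len(nrow(beta)))
  species <- lapply(seq_len(nrow(grid)), function(k) {
    crosslink_mass(alpha$peptide[[grid$a[k]]], beta$peptide[[grid$b[k]]])
  })
  out <- data.frame(
    alpha_seq = alpha$label[grid$a],
    beta_seq = beta$label[grid$b],
    mass = vapply(species, `[[`, 0, "mass"))
  dup <- duplicated(paste(out$alpha_seq, out$beta_seq, signif(out$mass, 12)))
  out <- out[!dup, , drop = FALSE]
  species <- species[!dup]
  out$candidate_id <- sprintf("C%03d", seq_len(nrow(out)))
  out$species <- species
  rownames(out) <- NULL
  out[, c("candidate_id", "alpha_seq", "beta_seq", "mass", "species")]
}

.empty_candidates <- function() {
  data.frame(candidate_id = character(0), alpha_seq = character(0),
             beta_seq = character(0), mass = numeric(0))
}

.as_peptide_frame <- function(x) {
  if (is.character(x))
    x <- data.frame(parent = NA_character_, start = NA_integer_, sequence = x)
  stopifnot(is.data.frame(x), "sequence" %in% names(x))
  if (is.null(x$parent)) x$parent <- NA_character_
  if (is.null(x$start)) x$start <- NA_integer_
  x
}

# expand each peptide over 0..max_ox methionine oxidations
.expand_ox <- function(df, max_ox) {
  rows <- list()
  for (i in seq_len(nrow(df))) {
    base <- peptide(df$sequence[i], parent = df$parent[i], start = df$start[i])
    rows[[length(rows) + 1L]] <- list(peptide = base,
                                      label = .peptide_label(base))
    if (max_ox >= 1L) {
      mets <- which(strsplit(base$sequence, "")[[1]] == "M")
      mets <- setdiff(mets, as.integer(names(base$mods)))
      for (m in mets) {
        oxv <- "ox"; names(oxv) <- m
        p <- peptide(base$sequence, mods = oxv, parent = df$parent[i],
                     start = df$start[i])
        rows[[length(rows) + 1L]] <- list(peptide = p, label = .peptide_label(p))
      }
    }
  }
  data.frame(label = vapply(rows, `[[`, "", "label"),
             peptide = I(lapply(rows, `[[`, "peptide")))
}

# inline-notation label; fixed cam is implicit and not printed
.peptide_label <- function(p) {
  aa <- strsplit(p$sequence, "")[[1]]
  shown <- p$mods[p$mods != "cam"]
  if (length(shown))
    aa[as.integer(names(shown))] <-
      paste0(aa[as.integer(names(shown))], "[", shown, "]")
  paste(aa, collapse = "")
}

#' Match MS1 features against candidate crosslink masses
#'
#' A feature matches a candidate when the relative mass error is within
#' `window_ppm`. Features may carry a neutral `mass` or an `mz` plus
#' `charge`, in which case the neutral mass is derived first.
#'
#' @param features data.frame with `mass` (neutral, Da) or `mz` + `charge`,
#'   and optionally `intensity`, `condition`.
#' @param candidates data.frame from [enumerate_candidates()].
#' @param window_ppm MS1 error window (default 10 ppm).
#' @return data.frame with one row per (feature, candidate) match: columns
#'   `feature`, `candidate_id`, `mass_obs`, `mass_theo`, `ppm`.
#' @export
match_ms1 <- function(features, candidates, window_ppm = 10) {
  stopifnot(window_ppm > 0, is.data.frame(features))
  if (is.null(features$mass)) {
    if (is.null(features$mz) || is.null(features$charge))
      stop("features need a 'mass' column or 'mz' + 'charge'")
    features$mass <- mz_to_mass(features$mz, features$charge)
  }
  if (!nrow(features) || !nrow(candidates))
    return(data.frame(feature = integer(0), candidate_id = character(0),
                      mass_obs = numeric(0), mass_theo = numeric(0),
                      ppm = numeric(0)))
  ppm <- outer(features$mass, candidates$mass,
               function(o, t) (o - t) / t * 1e6)
  hit <- which(abs(ppm) <= window_ppm, arr.ind = TRUE)
  out <- data.frame(feature = hit[, 1],
                    candidate_id = candidates$candidate_id[hit[, 2]],
                    mass_obs = features$mass[hit[, 1]],
                    mass_theo = candidates$mass[hit[, 2]],
                    ppm = ppm[hit])
  out[order(out$feature, out$candidate_id), , drop = FALSE]
}

#' Theoretical b/y fragment ions of one chain of a crosslinked species
#'
#' For a chain of length n, the 2(n-1) singly-described b and y fragments are
#' produced. Any fragment containing the linked residue carries the full
#' neutral mass of the partner peptide as a rigid added mass.
#'
#' @param xl An `xl_species`.
#' @param chain `"alpha"` or `"beta"`.
#' @param link_site 1-based linked-residue position on this chain. Defaults
#'   to the photo-reactive residue for the alpha chain; required for beta.
#' @return data.frame with `ion`, `type`, `index`, `neutral_mass`.
#' @export
fragment_ions <- function(xl, chain = c("alpha", "beta"), link_site = NULL) {
  chain <- match.arg(chain)
  stopifnot(inherits(xl, "xl_species"))
  p <- xl[[chain]]
  partner <- if (chain == "alpha") xl$beta else xl$alpha
  n <- nchar(p$sequence)
  if (is.null(link_site)) {
    if (chain == "alpha") link_site <- photo_sites(p)
    else stop("link_site must be given for the beta chain")
  }
  stopifnot(length(link_site) == 1L, link_site >= 1L, link_site <= n)
  if (n < 2L)
    return(data.frame(ion = character(0), type = character(0),
                      index = integer(0), neutral_mass = numeric(0)))
  aa <- strsplit(p$sequence, "")[[1]]
  rmass <- as.vector(.residue_comp %*% .elements)[match(aa, rownames(.residue_comp))]
  modm <- numeric(n)
  for (posc in names(p$mods))
    modm[as.integer(posc)] <- sum(.modifications[[p$mods[[posc]]]]$delta * .elements)
  res <- rmass + modm
  pm <- peptide_mass(partner)
  idx <- seq_len(n - 1L)
  b <- cumsum(res)[idx] + ifelse(idx >= link_site, pm, 0)
  y <- rev(cumsum(rev(res)))[idx + 1L] + .water_mass +
    ifelse(idx + 1L <= link_site, pm, 0)
  data.frame(
    ion = c(sprintf("b%d", idx), sprintf("y%d", n - idx)),
    type = rep(c("b", "y"), each = n - 1L),
    index = c(idx, n - idx),
    neutral_mass = c(b, y))
}

# fragment m/z table over charges, for one chain under one site hypothesis
.fragment_mz <- function(xl, chain, link_site, charges) {
  fr <- fragment_ions(xl, chain, link_site)
  do.call(rbind, lapply(charges, function(z) {
    f <- fr
    f$z <- z
    f$mz <- mass_to_mz(f$neutral_mass, z)
    f
  }))
}

#' Match MS2 fragments of a crosslinked species against a spectrum
#'
#' Matches theoretical b/y ions of both chains (fragment charges 1 to
#' precursor charge minus 1) against centroid peaks within `window_ppm`.
#' The beta-chain link site is unknown a priori, so fragments are generated
#' under every site hypothesis and a peak counts as matched if it matches
#' under any of them.
#'
#' @param spectrum list with `precursor_mz`, `precursor_z` and `peaks`
#'   (data.frame `mz`, `intensity`, sorted by mz).
#' @param xl An `xl_species`.
#' @param window_ppm MS2 error window (default 15 ppm).
#' @return list of class `ms2_report`: per-chain matched/total fragment
#'   counts, fraction of total peak intensity explained, matched-peak table,
#'   and the per-site consistency matrix used for localization.
#' @export
score_ms2 <- function(spectrum, xl, window_ppm = 15) {
  stopifnot(is.list(spectrum), nrow(spectrum$peaks) > 0)
  peaks <- spectrum$peaks
  z <- spectrum$precursor_z
  charges <- seq_len(max(1L, z - 1L))
  res <- list()
  for (chain in c("alpha", "beta")) {
    p <- xl[[chain]]
    n <- nchar(p$sequence)
    sites <- if (chain == "alpha") photo_sites(p) else seq_len(n)
    # per-site: logical matrix peaks x fragments collapsed to matched ion set
    matched_by_site <- list()
    for (s in sites) {
      fr <- .fragment_mz(xl, chain, s, charges)
      dmat <- outer(peaks$mz, fr$mz, function(o, t) abs(o - t) / t * 1e6)
      hit <- dmat <= window_ppm
      matched_by_site[[as.character(s)]] <- list(
        peak_matched = rowSums(hit) > 0,
        frag_matched = unique(paste0(fr$ion[colSums(hit) > 0])))
    }
    union_peaks <- Reduce(`|`, lapply(matched_by_site, `[[`, "peak_matched"))
    union_frags <- unique(unlist(lapply(matched_by_site, `[[`, "frag_matched")))
    res[[chain]] <- list(sites = sites, by_site = matched_by_site,
                         union_peaks = union_peaks,
                         matched = length(union_frags),
                         total = 2L * (n - 1L),
                         matched_ions = union_frags)
  }
  any_matched <- res$alpha$union_peaks | res$beta$union_peaks
  structure(list(
    alpha = res$alpha, beta = res$beta,
    matched_alpha = res$alpha$matched, total_alpha = res$alpha$total,
    matched_beta = res$beta$matched, total_beta = res$beta$total,
    intensity_explained = sum(peaks$intensity[any_matched]) /
      max(sum(peaks$intensity), .Machine$double.eps),
    window_ppm = window_ppm, xl = xl), class = "ms2_report")
}

#' @export
print.ms2_report <- function(x, ...) {
  cat(sprintf("<ms2_report> alpha %d/%d, beta %d/%d fragments; %.1f%% intensity explained\n",
              x$matched_alpha, x$total_alpha, x$matched_beta, x$total_beta,
              100 * x$intensity_explained))
  invisible(x)
}

#' Localize crosslink sites from matched fragments
#'
#' For each chain, a candidate link site is consistent when every spectrum
#' peak matched for that chain under the union of site hypotheses is also
#' matched under that single site. The reported site is the smallest
#' contiguous residue interval covering all consistent sites; when no
#' fragment discriminates, this is the full peptide. Positions are mapped to
#' parent-protein coordinates when the peptide carries a `start`.
#'
#' @param report An `ms2_report` from [score_ms2()].
#' @return data.frame with one row per chain: `chain`, `site_min`,
#'   `site_max` (peptide coordinates), `parent_min`, `parent_max`.
#' @export
localize_sites <- function(report) {
  stopifnot(inherits(report, "ms2_report"))
  out <- lapply(c("alpha", "beta"), function(chain) {
    r <- report[[chain]]
    p <- report$xl[[chain]]
    union_pk <- r$union_peaks
    # a site is consistent when it explains every peak any site hypothesis
    # explains for this chain
    consistent <- vapply(r$by_site, function(bs)
      all(bs$peak_matched[union_pk]), TRUE)
    sites <- r$sites[consistent]
    if (!length(sites)) sites <- r$sites   # nothing discriminates
    smin <- min(sites); smax <- max(sites)
    data.frame(chain = chain, site_min = smin, site_max = smax,
               parent_min = if (!is.na(p$start)) p$start + smin - 1L else NA_integer_,
               parent_max = if (!is.na(p$start)) p$start + smax - 1L else NA_integer_)
  })
  do.call(rbind, out)
}

#' UV dependence of a crosslinked species
#'
#' Sums feature intensities matching the species mass in the +UV and -UV
#' runs and reports their ratio. To avoid division by zero the -UV signal is
#' floored at `floor_frac` of the +UV signal; a species is flagged
#' UV-dependent when the ratio reaches `threshold`.
#'
#' @param plus_uv,minus_uv MS1 feature data.frames (`mass` or `mz`+`charge`,
#'   `intensity`).
#' @param species_mass Neutral mass of the species (Da).
#' @param window_ppm Matching window.
#' @param threshold Fold-enrichment required to flag UV dependence.
#' @param floor_frac Floor on the -UV signal, as a fraction of +UV.
#' @return list with `ratio`, `flagged`, `intensity_plus`, `intensity_minus`.
#' @export
uv_dependence <- function(plus_uv, minus_uv, species_mass, window_ppm = 10,
                          threshold = 5, floor_frac = 0.01) {
  sum_int <- function(df) {
    if (is.null(df) || !nrow(df)) return(0)
    if (is.null(df$mass)) df$mass <- mz_to_mass(df$mz, df$charge)
    if (is.null(df$intensity)) df$intensity <- 1
    sel <- abs((df$mass - species_mass) / species_mass * 1e6) <= window_ppm
    sum(df$intensity[sel])
  }
  ip <- sum_int(plus_uv)
  im <- sum_int(minus_uv)
  if (ip == 0 && im == 0)
    stop("species absent from both conditions")
  ratio <- ip / max(im, floor_frac * ip)
  list(ratio = ratio, flagged = ratio >= threshold,
       intensity_plus = ip, intensity_minus = im)
}

#' Assign reliability tiers to scored crosslink matches
#'
#' Codifies the manual high/medium/low confidence rating as a deterministic
#' rubric: `high` requires at least `min_frag` matched fragments on each
#' chain, a UV-dependent precursor, and an MS1 error within `high_ppm`;
#' `medium` requires `min_frag` matched fragments on at least one chain;
#' everything else is `low`.
#'
#' @param matches data.frame with columns `matched_alpha`, `matched_beta`,
#'   `uv_flagged` (logical), `ppm`.
#' @param min_frag Fragments per chain required (default 3).
#' @param high_ppm MS1 ppm bound for the high tier (default 5).
#' @return `matches` with an added `reliability` column.
#' @export
tier_matches <- function(matches, min_frag = 3L, high_ppm = 5) {
  stopifnot(all(c("matched_alpha", "matched_beta", "uv_flagged", "ppm") %in%
                  names(matches)))
  both <- matches$matched_alpha >= min_frag & matches$matched_beta >= min_frag
  one <- matches$matched_alpha >= min_frag | matches$matched_beta >= min_frag
  tier <- ifelse(both & matches$uv_flagged & abs(matches$ppm) <= high_ppm,
                 "high", ifelse(one, "medium", "low"))
  matches$reliability <- tier
  matches
}
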