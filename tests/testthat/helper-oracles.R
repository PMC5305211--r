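# Independent brute-force oracles used to validate the fast implementations.

# Tryptic digest by exhaustive substring enumeration: a substring is a valid
# peptide iff both ends sit on cleavage boundaries and it contains no more
# than `missed` internal cleavage sites. Formulated independently of the
# boundary-walk in digest().
brute_force_digest <- function(sequence, missed = 2L, min_length = 2L,
                               max_length = 30L) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cleavable <- function(i) i >= 1 && i < n && aa[i] %in% c("K", "R") &&
    aa[i + 1] != "P"
  out <- list()
  for (s in seq_len(n)) {
    if (!(s == 1 || cleavable(s - 1))) next
    for (e in s:n) {
      if (!(e == n || cleavable(e))) next
      len <- e - s + 1
      if (len < min_length || len > max_length) next
      internal <- if (e > s) sum(vapply(s:(e - 1), cleavable, TRUE)) else 0L
      if (internal > missed) next
      out[[length(out) + 1]] <- data.frame(
        start = s, end = e, sequence = paste(aa[s:e], collapse = ""),
        missed = internal)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      sequence = character(0),
                                      missed = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$end - res$start), , drop = FALSE]
}

# all-pairs ppm comparison, the oracle for match_ms1()
brute_force_ms1 <- function(masses, cand_masses, window_ppm) {
  hits <- list()
  for (i in seq_along(masses)) {
    for (j in seq_along(cand_masses)) {
      ppm <- (masses[i] - cand_masses[j]) / cand_masses[j] * 1e6
      if (abs(ppm) <= window_ppm)
        hits[[length(hits) + 1]] <- data.frame(feature = i, cand = j,
                                               ppm = ppm)
    }
  }
  if (!length(hits)) return(data.frame(feature = integer(0),
                                       cand = integer(0), ppm = numeric(0)))
  do.call(rbind, hits)
}

# per-model brute-force restraint check, the oracle for filter_ensemble()
brute_force_filter <- function(ensemble, restraints) {
  xyz <- ensemble$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  keep <- logical(nrow(xyz))
  for (m in seq_len(nrow(xyz))) {
    ok <- TRUE
    for (r in seq_len(nrow(restraints))) {
      dmin <- Inf
      for (ra in restraints$res_a[[r]]) for (rb in restraints$res_b[[r]]) {
        ia <- which(ensemble$atom$chain == restraints$chain_a[r] &
                      ensemble$atom$resno == ra &
                      ensemble$atom$elety == restraints$atom[r])
        ib <- which(ensemble$atom$chain == restraints$chain_b[r] &
                      ensemble$atom$resno == rb &
                      ensemble$atom$elety == restraints$atom[r])
        for (a in ia) for (b in ib) {
          pa <- xyz[m, (3 * a - 2):(3 * a)]
          pb <- xyz[m, (3 * b - 2):(3 * b)]
          dmin <- min(dmin, sqrt(sum((pa - pb)^2)))
        }
      }
      if (dmin > restraints$bound[r]) { ok <- FALSE; break }
    }
    keep[m] <- ok
  }
  which(keep)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
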