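# Identification of formaldehyde cross-linked peptide pairs in MS2 spectra:
# search database with decoys, candidate enumeration by precursor mass,
# fragment matching at ppm tolerance, confidence classification and
# cross-linking site assignment.

#' Build a restricted target-decoy search database
#'
#' Retains the `n_top` most abundant proteins (by the supplied ranking
#' value, typically the mean iBAQ over replicates) and appends one decoy
#' per target, generated by full sequence reversal and prefixed `REV_`.
#'
#' @param sequences Named character vector of protein sequences.
#' @param abundance Numeric abundance used for ranking (same order as
#'   `sequences`); higher is more abundant. If `NULL` the input order is
#'   taken as already ranked.
#' @param n_top Number of targets to keep (default 800).
#' @return Named character vector of `2 * n_top` sequences; decoys carry
#'   the `REV_` accession prefix. Attribute `is_decoy` flags them.
#' @export
build_search_database <- function(sequences, abundance = NULL, n_top = 800L) {
  if (n_top < 1L) stop("n_top must be >= 1 (empty database)")
  if (!is.null(abundance)) {
    stopifnot(length(abundance) == length(sequences))
    sequences <- sequences[order(abundance, decreasing = TRUE)]
  }
  if (length(sequences) < n_top) {
    warning(sprintf("only %d proteins available; using all", length(sequences)))
    n_top <- length(sequences)
  }
  targets <- sequences[seq_len(n_top)]
  decoys <- vapply(targets, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), "")
  names(decoys) <- paste0("REV_", names(targets))
  db <- c(targets, decoys)
  attr(db, "is_decoy") <- c(rep(FALSE, n_top), rep(TRUE, n_top))
  db
}

#' Digest a search database into a mass-sorted peptide index
#'
#' @param db Database from [build_search_database()] (or any named sequence
#'   vector; accessions prefixed `REV_` are treated as decoys unless the
#'   `is_decoy` attribute is present).
#' @param max_missed Maximum missed cleavages (default 4, the cross-link
#'   search setting).
#' @param length_range Peptide length window.
#' @param constants Mass constants.
#' @return Data frame sorted by `mass` with peptide columns plus `mass`.
#' @export
peptide_index <- function(db, max_missed = 4L, length_range = c(5L, 60L),
                          constants = mass_constants()) {
  decoy <- attr(db, "is_decoy")
  if (is.null(decoy)) decoy <- startsWith(names(db), "REV_")
  peps <- do.call(rbind, lapply(seq_along(db), function(i)
    digest(db[[i]], protein_id = names(db)[i], max_missed = max_missed,
           length_range = length_range, is_decoy = decoy[i])))
  peps <- unique(peps)
  peps$mass <- peptide_mass_vec(peps$sequence, constants)
  peps <- peps[order(peps$mass), ]
  rownames(peps) <- NULL
  peps
}

precursor_neutral_mass <- function(precursor_mz, charge,
                                   constants = mass_constants()) {
  charge * precursor_mz - charge * constants$proton
}

#' Enumerate candidate peptide pairs for a spectrum
#'
#' A pair (A, B) with `linker_count` methylene bridges is a candidate when
#' the precursor neutral mass matches `mass_A + mass_B + linker_count * 12`
#' within the MS1 ppm tolerance (boundary inclusive). Pairs are unordered.
#'
#' @param spectrum Spectrum record (see [read_mgf()]).
#' @param index Peptide index from [peptide_index()].
#' @param ms1_tol_ppm MS1 tolerance in ppm (default 6).
#' @param charge_window Accepted precursor charges; spectra outside are
#'   skipped (empty candidate list).
#' @param constants Mass constants.
#' @return Data frame with columns `idx_a`, `idx_b` (rows of `index`) and
#'   `linker_count`.
#' @export
enumerate_candidates <- function(spectrum, index, ms1_tol_ppm = 6,
                                 charge_window = 4:7,
                                 constants = mass_constants()) {
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      linker_count = integer())
  if (!(spectrum$precursor_charge %in% charge_window)) return(empty)
  M <- precursor_neutral_mass(spectrum$precursor_mz,
                              spectrum$precursor_charge, constants)
  masses <- index$mass
  res <- list()
  for (lc in c(1L, 2L)) {
    target <- M - lc * constants$linker_single
    w <- ms1_tol_ppm * 1e-6 * M * 1.01  # loose pre-window; exact check below
    # for each i, partner mass must lie in [target - m_i - w, target - m_i + w]
    i_max <- findInterval(target / 2 + w, masses)
    if (i_max < 1L) next
    i_all <- seq_len(i_max)
    j1 <- pmax(findInterval(target - masses[i_all] - w, masses) + 1L, i_all)
    j2 <- findInterval(target - masses[i_all] + w, masses)
    n_j <- pmax(j2 - j1 + 1L, 0L)
    keep <- n_j > 0L
    if (!any(keep)) next
    idx_a <- rep.int(i_all[keep], n_j[keep])
    idx_b <- sequence(n_j[keep], from = j1[keep])
    theo <- masses[idx_a] + masses[idx_b] + lc * constants$linker_single
    ok <- abs(ppm_delta(M, theo)) <= ms1_tol_ppm
    if (any(ok))
      res[[length(res) + 1L]] <- data.frame(
        idx_a = idx_a[ok], idx_b = idx_b[ok], linker_count = lc)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Memo for theoretical ion vectors, keyed by sequence and charge ceiling;
# scoped per xl_search() call (candidate peptides recur across spectra).
theo_cache <- new.env(parent = emptyenv())

# Flat-vector theoretical ion generator (a/b/y, shifted twins, several
# charges); avoids data-frame construction in the scoring hot path.
theo_ions_fast <- function(sequence, zmax, constants) {
  key <- paste0(sequence, "#", zmax, "#",
                sum(constants$fixed_mods), "#", constants$linker_single)
  hit <- theo_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- theo_ions_build(sequence, zmax, constants)
  theo_cache[[key]] <- out
  out
}

theo_ions_build <- function(sequence, zmax, constants) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  res <- constants$residue_monoisotopic[chars]
  for (mod in names(constants$fixed_mods))
    res[chars == mod] <- res[chars == mod] + constants$fixed_mods[[mod]]
  prefix <- cumsum(res)
  suffix <- rev(cumsum(rev(res)))
  idx <- seq_len(n - 1L)
  neutral <- c(unname(prefix[idx]) - constants$co,       # a
               unname(prefix[idx]),                      # b
               unname(suffix[n + 1L - idx]) + constants$water)  # y
  nz <- length(neutral)
  link <- constants$linker_single
  mz <- unlist(lapply(seq_len(zmax), function(z)
    c((neutral + z * constants$proton) / z,
      (neutral + link + z * constants$proton) / z)), use.names = FALSE)
  list(series = rep.int(rep(c("a", "b", "y"), each = n - 1L), 2L * zmax),
       index = rep.int(idx, 6L * zmax),
       charge = rep(seq_len(zmax), each = 2L * nz),
       shifted = rep.int(rep(c(FALSE, TRUE), each = nz), zmax),
       mz = mz)
}

# Count distinct theoretical ions of one peptide matched by >= 1 peak
# within tolerance; returns the count and the matched-ion annotation.
match_fragments <- function(sequence, peaks_mz, max_charge, ms2_tol_ppm,
                            constants) {
  ions <- theo_ions_fast(sequence, max(1L, max_charge), constants)
  if (!length(peaks_mz)) {
    matched <- logical(length(ions$mz))
  } else {
    pos <- findInterval(ions$mz, peaks_mz)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(peaks_mz))
    nearest <- pmin(abs(peaks_mz[lo] - ions$mz), abs(peaks_mz[hi] - ions$mz))
    matched <- (1e6 * nearest / ions$mz) <= ms2_tol_ppm
  }
  list(series = ions$series[matched], index = ions$index[matched],
       charge = ions$charge[matched], shifted = ions$shifted[matched],
       mz = ions$mz[matched], n = sum(matched))
}

#' Score a candidate peptide pair against a spectrum
#'
#' Counts, for each peptide, the distinct theoretical ions (series a/b/y,
#' shifted and unshifted, charges 1 to precursor charge minus 1) matched by
#' at least one peak within the MS2 ppm tolerance. One observed peak may
#' support several theoretical ions.
#'
#' @param spectrum Spectrum record.
#' @param peptide_a,peptide_b One-row data frames (rows of a peptide
#'   index) with at least `sequence`, `protein_id`, `start`, `is_decoy`.
#' @param linker_count 1 or 2 bridges.
#' @param ms2_tol_ppm MS2 tolerance in ppm (default 8).
#' @param constants Mass constants.
#' @return A `CrossLinkHit` list: ids, peptides, counts, `ratio`,
#'   matched-ion annotations, `contains_decoy`; `confidence` unset.
#' @export
score_candidate <- function(spectrum, peptide_a, peptide_b, linker_count,
                            ms2_tol_ppm = 8, constants = mass_constants()) {
  zmax <- max(1L, spectrum$precursor_charge - 1L)
  mz <- spectrum$peaks[, 1]
  ann_a <- match_fragments(peptide_a$sequence, mz, zmax, ms2_tol_ppm, constants)
  ann_b <- match_fragments(peptide_b$sequence, mz, zmax, ms2_tol_ppm, constants)
  ma <- ann_a$n
  mb <- ann_b$n
  la <- nchar(peptide_a$sequence)
  lb <- nchar(peptide_b$sequence)
  structure(list(
    spectrum_id = spectrum$spectrum_id,
    condition = spectrum$condition,
    replicate_id = spectrum$replicate_id,
    peptide_a = peptide_a, peptide_b = peptide_b,
    linker_count = as.integer(linker_count),
    matched_fragments_a = ma, matched_fragments_b = mb,
    ratio = (ma + mb) / (la + lb),
    annotation_a = ann_a,
    annotation_b = ann_b,
    contains_decoy = isTRUE(peptide_a$is_decoy) || isTRUE(peptide_b$is_decoy),
    confidence = NA_character_
  ), class = "CrossLinkHit")
}

#' Classify a hit's confidence
#'
#' High confidence requires a fragments-per-residue ratio
#' `(matched_a + matched_b) / (len_a + len_b) > 1.5` and more than 18
#' matched fragments for each peptide. Failing that, more than 15 matched
#' fragments for each peptide gives intermediate confidence; anything else
#' is rejected.
#'
#' @param hit A `CrossLinkHit` (or anything with the count fields), or the
#'   counts/lengths given directly.
#' @param ratio_min High-confidence ratio threshold (default 1.5, strict >).
#' @param high_floor,intermediate_floor Per-peptide matched-fragment floors
#'   (strict >; defaults 18 and 15).
#' @return One of `"high"`, `"intermediate"`, `"rejected"`.
#' @export
classify_confidence <- function(hit, ratio_min = 1.5, high_floor = 18L,
                                intermediate_floor = 15L) {
  ma <- hit$matched_fragments_a
  mb <- hit$matched_fragments_b
  if (min(ma, mb) > high_floor && hit$ratio > ratio_min) "high"
  else if (min(ma, mb) > intermediate_floor) "intermediate"
  else "rejected"
}

# Interval of peptide positions consistent with matched shifted/unshifted
# ion evidence. y_k covers the last k residues, b_k/a_k the first k. A
# shifted ion places the linker inside its covered span, an unshifted ion
# outside it. Conflicting evidence collapses to the full peptide.
site_interval <- function(n, annotation) {
  lo <- 1L; hi <- n
  n_ann <- if (is.null(annotation)) 0L
           else if (is.data.frame(annotation)) nrow(annotation)
           else length(annotation$index)
  if (n_ann) {
    for (r in seq_len(n_ann)) {
      k <- annotation$index[r]
      if (annotation$series[r] == "y") {
        if (annotation$shifted[r]) lo <- max(lo, n - k + 1L)
        else hi <- min(hi, n - k)
      } else {  # a/b share prefix coverage
        if (annotation$shifted[r]) hi <- min(hi, k)
        else lo <- max(lo, k + 1L)
      }
    }
    if (lo > hi) { lo <- 1L; hi <- n }
  }
  c(lo, hi)
}

middle_of <- function(lo, hi) lo + (hi - lo) %/% 2L

#' Assign the cross-linking site within each peptide
#'
#' Formaldehyde bridges are cleaved during fragmentation, so the exact
#' linked residue is usually ambiguous; the default site is the middle
#' residue of the peptide (the N-terminal one of the two central residues
#' for even lengths). When matched shifted/unshifted fragment evidence
#' brackets the linker to a sub-interval, the site is the middle of that
#' interval and the interval is reported. A note is attached when a
#' lysine or arginine (the preferentially reactive residues) lies in the
#' interval.
#'
#' @param hit A scored `CrossLinkHit`.
#' @return The hit with `site_a`, `site_b` (1-based within each peptide),
#'   `interval_a`, `interval_b` and `site_note_a`/`_b` filled in.
#' @export
assign_site <- function(hit) {
  for (side in c("a", "b")) {
    pep <- hit[[paste0("peptide_", side)]]
    n <- nchar(pep$sequence)
    iv <- site_interval(n, hit[[paste0("annotation_", side)]])
    site <- middle_of(iv[1], iv[2])
    chars <- strsplit(pep$sequence, "", fixed = TRUE)[[1]]
    kr <- any(chars[iv[1]:iv[2]] %in% c("K", "R"))
    hit[[paste0("site_", side)]] <- site
    hit[[paste0("interval_", side)]] <- iv
    hit[[paste0("site_note_", side)]] <-
      if (kr) "K/R in interval" else "no K/R in interval"
  }
  hit
}

hit_rank_key <- function(hit) {
  conf_rank <- match(hit$confidence, c("high", "intermediate", "rejected"))
  c(conf_rank, -hit$ratio,
    -min(hit$matched_fragments_a, hit$matched_fragments_b))
}

# TRUE when (key, acc) ranks strictly before (best_key, best_acc):
# lexicographic on the numeric key, accession string as final tie-break.
hit_outranks <- function(key, acc, best_key, best_acc) {
  d <- key - best_key
  nz <- which(d != 0)
  if (length(nz)) return(d[nz[1]] < 0)
  acc < best_acc
}

#' Search spectra for cross-linked peptide pairs
#'
#' Runs candidate enumeration, fragment scoring, confidence classification
#' and site assignment for each spectrum, keeping the best hit per spectrum
#' (ties broken by higher ratio, then higher minimum fragment count, then
#' lexicographic accession pair).
#'
#' @param spectra List of spectrum records.
#' @param index Peptide index from [peptide_index()].
#' @param ms1_tol_ppm,ms2_tol_ppm Tolerances in ppm (defaults 6 and 8).
#' @param charge_window Accepted precursor charges (default 4 to 7).
#' @param keep Confidence levels retained in the result (default high and
#'   intermediate).
#' @param constants Mass constants.
#' @return Data frame of accepted hits, one row per spectrum, with peptide
#'   sequences, accessions, protein-coordinate sites, counts, ratio,
#'   confidence and decoy flag. The full hit objects are attached as the
#'   `hits` attribute.
#' @export
xl_search <- function(spectra, index, ms1_tol_ppm = 6, ms2_tol_ppm = 8,
                      charge_window = 4:7,
                      keep = c("high", "intermediate"),
                      constants = mass_constants()) {
  rm(list = ls(theo_cache), envir = theo_cache)  # bound memory per run
  # plain-vector view of the index: row extraction from a data frame is
  # too slow for the per-candidate loop
  pep_row <- function(i) list(sequence = index$sequence[i],
                              protein_id = index$protein_id[i],
                              start = index$start[i],
                              missed_cleavages = index$missed_cleavages[i],
                              is_decoy = index$is_decoy[i])
  best_hits <- list()
  for (s in spectra) {
    cand <- enumerate_candidates(s, index, ms1_tol_ppm, charge_window,
                                 constants)
    if (!nrow(cand)) next
    best <- NULL
    best_key <- NULL
    best_acc <- NULL
    for (r in seq_len(nrow(cand))) {
      hit <- score_candidate(s, pep_row(cand$idx_a[r]), pep_row(cand$idx_b[r]),
                             cand$linker_count[r], ms2_tol_ppm, constants)
      hit$confidence <- classify_confidence(hit)
      key <- hit_rank_key(hit)
      acc <- paste(sort(c(hit$peptide_a$protein_id,
                          hit$peptide_b$protein_id)), collapse = "|")
      if (is.null(best) || hit_outranks(key, acc, best_key, best_acc)) {
        best <- hit
        best_key <- key
        best_acc <- acc
      }
    }
    if (is.null(best) || !(best$confidence %in% keep)) next
    best <- assign_site(best)
    best_hits[[length(best_hits) + 1L]] <- best
  }
  hits_to_frame(best_hits)
}

hits_to_frame <- function(hits) {
  if (!length(hits)) {
    out <- data.frame(
      spectrum_id = character(), condition = character(),
      replicate_id = character(), protein_a = character(),
      protein_b = character(), peptide_a = character(),
      peptide_b = character(), start_a = integer(), start_b = integer(),
      linker_count = integer(), matched_a = integer(), matched_b = integer(),
      ratio = numeric(), confidence = character(),
      site_a = integer(), site_b = integer(),
      protein_site_a = integer(), protein_site_b = integer(),
      interval_a_lo = integer(), interval_a_hi = integer(),
      interval_b_lo = integer(), interval_b_hi = integer(),
      contains_decoy = logical())
    attr(out, "hits") <- hits
    return(out)
  }
  out <- do.call(rbind, lapply(hits, function(h) data.frame(
    spectrum_id = h$spectrum_id,
    condition = if (is.null(h$condition)) NA_character_ else h$condition,
    replicate_id = if (is.null(h$replicate_id)) NA_character_ else h$replicate_id,
    protein_a = h$peptide_a$protein_id,
    protein_b = h$peptide_b$protein_id,
    peptide_a = h$peptide_a$sequence,
    peptide_b = h$peptide_b$sequence,
    start_a = h$peptide_a$start,
    start_b = h$peptide_b$start,
    linker_count = h$linker_count,
    matched_a = h$matched_fragments_a,
    matched_b = h$matched_fragments_b,
    ratio = h$ratio,
    confidence = h$confidence,
    site_a = h$site_a,
    site_b = h$site_b,
    protein_site_a = h$peptide_a$start + h$site_a - 1L,
    protein_site_b = h$peptide_b$start + h$site_b - 1L,
    interval_a_lo = h$peptide_a$start + h$interval_a[1] - 1L,
    interval_a_hi = h$peptide_a$start + h$interval_a[2] - 1L,
    interval_b_lo = h$peptide_b$start + h$interval_b[1] - 1L,
    interval_b_hi = h$peptide_b$start + h$interval_b[2] - 1L,
    contains_decoy = h$contains_decoy,
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "hits") <- hits
  out
}

#' Decoy content of a set of accepted hits
#'
#' @param hits Hit data frame from [xl_search()].
#' @return Data frame per condition with accepted-hit count, decoy-containing
#'   count and decoy fraction.
#' @export
decoy_report <- function(hits) {
  cond <- if (nrow(hits)) ifelse(is.na(hits$condition), "all", hits$condition)
          else character()
  if (!nrow(hits))
    return(data.frame(condition = character(), n_hits = integer(),
                      n_decoy = integer(), decoy_fraction = numeric()))
  agg <- do.call(rbind, lapply(split(hits, cond), function(d) data.frame(
    condition = d$condition[1], n_hits = nrow(d),
    n_decoy = sum(d$contains_decoy),
    decoy_fraction = sum(d$contains_decoy) / nrow(d),
    stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg
}

#' Write a hit table to TSV
#'
#' @param hits Hit data frame.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
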