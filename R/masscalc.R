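# Deterministic peptide chemistry: tryptic digestion, monoisotopic masses,
# theoretical fragment ions (including formaldehyde +12 Da shifted series)
# and ppm comparison.

CANONICAL_AA <- c("G","A","S","P","V","T","C","L","I","N",
                  "D","Q","K","E","M","H","F","R","Y","W")

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty character scalar")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% CANONICAL_AA))
  if (length(bad))
    stop(sprintf("non-canonical residue '%s' at position %d", chars[bad[1]], bad[1]))
  chars
}

#' In silico tryptic digestion (trypsin/P)
#'
#' Cleaves C-terminal of every lysine or arginine, including when the next
#' residue is proline (trypsin/P convention), and enumerates peptides with
#' up to `max_missed` internal missed cleavage sites.
#'
#' @param protein_sequence Protein sequence (uppercase one-letter codes).
#' @param max_missed Maximum number of internal K/R sites retained.
#' @param length_range Length window `c(min, max)`; peptides outside are
#'   dropped. Default `c(5, 60)` suits cross-link searches; use `c(7, 30)`
#'   with `max_missed = 0` for iBAQ theoretical peptide counting.
#' @param protein_id Accession carried on each peptide.
#' @param is_decoy Decoy flag propagated to every peptide.
#' @return A data frame with columns `sequence`, `protein_id`, `start`
#'   (1-based in the parent), `missed_cleavages`, `is_decoy`.
#' @examples
#' digest("MKRAG", max_missed = 1, length_range = c(1, 50))
#' @export
digest <- function(protein_sequence, max_missed = 0L,
                   length_range = c(5L, 60L),
                   protein_id = NA_character_, is_decoy = FALSE) {
  protein_id <- as.character(protein_id)
  chars <- check_sequence(protein_sequence)
  stopifnot(max_missed >= 0, length(length_range) == 2L)
  n <- length(chars)
  # cleavage after every K/R (trypsin/P: no proline exception)
  cut_after <- which(chars %in% c("K", "R"))
  bounds <- unique(c(0L, cut_after, n))       # segment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends   <- bounds[-1]
  nseg <- length(starts)
  out <- vector("list", nseg * (max_missed + 1L))
  k <- 0L
  for (i in seq_len(nseg)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nseg) break
      len <- ends[j] - starts[i] + 1L
      if (len < length_range[1] || len > length_range[2]) next
      k <- k + 1L
      out[[k]] <- list(
        sequence = paste(chars[starts[i]:ends[j]], collapse = ""),
        protein_id = protein_id,
        start = starts[i],
        missed_cleavages = m
      )
    }
  }
  if (k == 0L)
    return(data.frame(sequence = character(), protein_id = character(),
                      start = integer(), missed_cleavages = integer(),
                      is_decoy = logical()))
  out <- out[seq_len(k)]
  data.frame(
    sequence = vapply(out, `[[`, "", "sequence"),
    protein_id = vapply(out, `[[`, "", "protein_id"),
    start = vapply(out, `[[`, 0L, "start"),
    missed_cleavages = vapply(out, `[[`, 0L, "missed_cleavages"),
    is_decoy = is_decoy,
    stringsAsFactors = FALSE
  )
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus water plus fixed modifications
#' (one per occurrence of each modified residue).
#'
#' @param sequence Peptide sequence.
#' @param constants Mass constants from [mass_constants()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")  # 75.032029
#' @export
peptide_mass <- function(sequence, constants = mass_constants()) {
  chars <- check_sequence(sequence)
  m <- sum(constants$residue_monoisotopic[chars]) + constants$water
  for (res in names(constants$fixed_mods))
    m <- m + constants$fixed_mods[[res]] * sum(chars == res)
  unname(m)
}

# Vectorised over many sequences; used by the search index.
peptide_mass_vec <- function(sequences, constants = mass_constants()) {
  vapply(sequences, peptide_mass, 0.0, constants = constants,
         USE.NAMES = FALSE)
}

#' Theoretical fragment ions with optional +12 Da linker-shifted twins
#'
#' Generates a/b/y fragment ions for a peptide over the requested charge
#' states. When `include_shifted` is `TRUE` every ion additionally gets a
#' twin carrying the formaldehyde linker remnant, offset by exactly
#' `linker_single / charge` Thomson.
#'
#' Neutral fragment masses: `b_i` is the sum of the first i residue masses
#' (plus fixed modifications), `y_j` adds water to the last j residues and
#' `a_i = b_i - CO`. The observed m/z is
#' `(neutral + shift + charge * proton) / charge`.
#'
#' @param sequence Peptide sequence of length >= 2.
#' @param series Character subset of `c("a","b","y")`.
#' @param charges Positive integer charge states.
#' @param include_shifted Emit +12 Da shifted twins for every ion.
#' @param constants Mass constants.
#' @return Data frame with columns `series`, `index`, `charge`, `shifted`,
#'   `mz`.
#' @export
fragment_ions <- function(sequence, series = c("b", "y"),
                          charges = 1L, include_shifted = FALSE,
                          constants = mass_constants()) {
  chars <- check_sequence(sequence)
  n <- length(chars)
  if (n < 2L) stop("peptide must have length >= 2 to fragment")
  series <- match.arg(series, c("a", "b", "y"), several.ok = TRUE)
  stopifnot(all(charges >= 1))
  res <- constants$residue_monoisotopic[chars]
  for (mod in names(constants$fixed_mods))
    res[chars == mod] <- res[chars == mod] + constants$fixed_mods[[mod]]
  prefix <- cumsum(res)                     # b_i neutral
  suffix <- rev(cumsum(rev(res)))           # y from position i to n
  idx <- seq_len(n - 1L)
  neutral <- list(
    b = unname(prefix[idx]),
    a = unname(prefix[idx]) - constants$co,
    y = unname(suffix[n + 1L - idx]) + constants$water
  )
  shifts <- if (include_shifted) c(0, constants$linker_single) else 0
  rows <- list()
  for (s in series) {
    for (z in charges) {
      for (sh in shifts) {
        rows[[length(rows) + 1L]] <- data.frame(
          series = s, index = idx, charge = as.integer(z),
          shifted = sh > 0,
          mz = (neutral[[s]] + sh + z * constants$proton) / z,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative mass deviation in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed_mz,theoretical_mz Positive m/z values (vectorised).
#' @return Signed ppm deviation.
#' @export
ppm_delta <- function(observed_mz, theoretical_mz) {
  if (any(observed_mz <= 0) || any(theoretical_mz <= 0))
    stop("m/z values must be positive")
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}

#' Tolerance check on a ppm deviation (boundary inclusive)
#'
#' @param observed_mz,theoretical_mz Positive m/z values.
#' @param tol_ppm Tolerance in ppm; a deviation of exactly `tol_ppm` matches.
#' @return Logical vector.
#' @export
ppm_match <- function(observed_mz, theoretical_mz, tol_ppm) {
  abs(ppm_delta(observed_mz, theoretical_mz)) <= tol_ppm
}

#' Read a FASTA file into a named character vector
#'
#' Accessions are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
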