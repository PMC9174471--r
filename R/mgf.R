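# Mascot generic format (MGF) reader/writer for MS2 peak lists.

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` and
#' `CHARGE` headers. `condition=<x>` and `replicate=<x>` tokens in the
#' title, if present, are carried onto the spectrum record.
#'
#' @param path MGF file path.
#' @return List of spectra; each a list with `spectrum_id`, `precursor_mz`,
#'   `precursor_charge`, `peaks` (two-column matrix `mz`, `intensity`,
#'   sorted by m/z), `condition`, `replicate_id`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends   <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    is_hdr <- grepl("^[A-Z]+=", block)
    hdr <- block[is_hdr]
    get <- function(key) {
      v <- hdr[startsWith(hdr, paste0(key, "="))]
      if (!length(v)) return(NA_character_)
      sub(paste0("^", key, "="), "", v[1])
    }
    title <- get("TITLE")
    charge <- get("CHARGE")
    charge <- if (is.na(charge)) NA_integer_ else
      as.integer(sub("\\+$", "", charge))
    pepmass <- as.numeric(strsplit(get("PEPMASS"), "\\s+")[[1]][1])
    peak_lines <- block[!is_hdr & nzchar(trimws(block))]
    peaks <- if (length(peak_lines)) {
      m <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "\\s+"),
                                 function(x) as.numeric(x[1:2])))
      colnames(m) <- c("mz", "intensity")
      m[order(m[, 1]), , drop = FALSE]
    } else {
      matrix(numeric(), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
    }
    tag <- function(key) {
      m <- regmatches(title, regexec(paste0(key, "=([^ ]+)"), title))[[1]]
      if (length(m) == 2L) m[2] else NA_character_
    }
    list(
      spectrum_id = if (is.na(title)) sprintf("spectrum_%d", i) else
        strsplit(title, "\\s+")[[1]][1],
      precursor_mz = pepmass,
      precursor_charge = charge,
      peaks = peaks,
      condition = tag("condition"),
      replicate_id = tag("replicate")
    )
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra List of spectrum records as produced by [read_mgf()].
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    title <- s$spectrum_id
    if (!is.null(s$condition) && !is.na(s$condition))
      title <- paste0(title, " condition=", s$condition)
    if (!is.null(s$replicate_id) && !is.na(s$replicate_id))
      title <- paste0(title, " replicate=", s$replicate_id)
    writeLines(paste0("TITLE=", title), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    if (nrow(s$peaks))
      writeLines(sprintf("%.6f %.2f", s$peaks[, 1], s$peaks[, 2]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
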