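# Mapping consensus cross-links onto high-resolution structures and
# classifying Calpha-Calpha distances against the 30 Angstrom restraint.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Load a structure model (mmCIF or legacy PDB) as Calpha traces
#'
#' Reads the polymer chains of a structure file and keeps one Calpha per
#' observed residue with its author residue number. mmCIF is preferred for
#' large assemblies that exceed legacy PDB format limits.
#'
#' @param path Path to a `.cif`/`.mmcif` or `.pdb` file.
#' @return A `StructureModel` list: `structure_id` and `chains`, a named
#'   list per chain with `sequence` (one-letter, observed residues in
#'   order), `resno` (author numbering) and `xyz` (N x 3 coordinate
#'   matrix, Angstrom).
#' @export
read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA" & atoms$resid %in% names(AA3TO1), ,
              drop = FALSE]
  chains <- lapply(split(ca, ca$chain), function(d) {
    d <- d[!duplicated(d$resno), , drop = FALSE]
    d <- d[order(d$resno), , drop = FALSE]
    list(sequence = paste(AA3TO1[d$resid], collapse = ""),
         resno = d$resno,
         xyz = as.matrix(d[, c("x", "y", "z")]))
  })
  structure(list(
    structure_id = sub("\\.[^.]*$", "", basename(path)),
    chains = chains
  ), class = "StructureModel")
}

#' Map a protein sequence onto structure chains
#'
#' Ungapped sliding alignment of each chain's observed-residue sequence
#' against the protein; chains whose best window identity reaches
#' `min_identity` are returned with the offset translating protein residue
#' numbering into chain residue positions.
#'
#' @param protein_sequence Full-length protein sequence.
#' @param model `StructureModel` from [read_structure()].
#' @param min_identity Minimum fractional identity over the aligned span
#'   (default 0.9).
#' @return Data frame with `chain_id`, `identity` and `offset`, where
#'   protein residue `i` corresponds to position `i - offset` in the
#'   chain's observed-residue vector. Empty when no chain qualifies.
#' @export
map_protein_to_chains <- function(protein_sequence, model,
                                  min_identity = 0.9) {
  p <- strsplit(protein_sequence, "", fixed = TRUE)[[1]]
  np <- length(p)
  rows <- list()
  for (cid in names(model$chains)) {
    s <- strsplit(model$chains[[cid]]$sequence, "", fixed = TRUE)[[1]]
    ns <- length(s)
    if (ns == 0L) next
    best_id <- -1; best_off <- NA_integer_
    # slide the chain along the protein (chain fully inside or overhanging)
    for (off in (-ns + 1L):(np - 1L)) {
      i <- seq_len(ns) + off          # protein positions facing chain 1..ns
      keep <- i >= 1L & i <= np
      span <- sum(keep)
      if (span < min(ns, np) * 0.5) next   # require a substantial overlap
      ident <- sum(p[i[keep]] == s[keep]) / span
      if (ident > best_id) { best_id <- ident; best_off <- off }
    }
    if (best_id >= min_identity)
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = cid, identity = best_id, offset = best_off,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chain_id = character(), identity = numeric(),
                      offset = integer()))
  do.call(rbind, rows)
}

# Calpha coordinates of protein residue `site` on a mapped chain, or NULL
# when the residue is not observed.
site_coords <- function(model, chain_id, offset, site) {
  ch <- model$chains[[chain_id]]
  pos <- site - offset
  if (is.na(pos) || pos < 1L || pos > nrow(ch$xyz)) return(NULL)
  ch$xyz[pos, ]
}

#' Minimal Calpha distance of a cross-link over all chain-copy pairs
#'
#' For homo-oligomeric assemblies every combination of chain copies is
#' considered and the minimum Euclidean Calpha-Calpha distance is reported.
#' For a link flagged as homo-multimeric (evidence of two protein copies)
#' the two sites must lie on distinct chains; otherwise an intra-protein
#' link may also be measured within a single chain.
#'
#' @param link One row of a consensus cross-link data frame (fields
#'   `protein_a`, `protein_b`, `site_a`, `site_b`, `link_type`,
#'   `homomultimer`).
#' @param model `StructureModel`.
#' @param assignments Named list of chain-assignment data frames (from
#'   [map_protein_to_chains()]) keyed by accession.
#' @param threshold Distance restraint in Angstrom (default 30); exactly 30
#'   counts as satisfied.
#' @return A `DistanceAssessment` data frame row: chains used, `ca_distance`
#'   and `verdict` in `satisfied`, `over_length`, `unmapped`.
#' @export
min_ca_distance <- function(link, model, assignments, threshold = 30) {
  asg_a <- assignments[[link$protein_a]]
  asg_b <- assignments[[link$protein_b]]
  unmapped <- function(reason) data.frame(
    protein_a = link$protein_a, protein_b = link$protein_b,
    site_a = link$site_a, site_b = link$site_b,
    chain_a = NA_character_, chain_b = NA_character_,
    ca_distance = NA_real_, verdict = "unmapped", reason = reason,
    stringsAsFactors = FALSE)
  if (is.null(asg_a) || !nrow(asg_a) || is.null(asg_b) || !nrow(asg_b))
    return(unmapped("no chain assignment"))
  require_distinct <- isTRUE(link$homomultimer)
  best <- NULL
  for (i in seq_len(nrow(asg_a))) {
    xa <- site_coords(model, asg_a$chain_id[i], asg_a$offset[i], link$site_a)
    if (is.null(xa)) next
    for (j in seq_len(nrow(asg_b))) {
      same_chain <- asg_a$chain_id[i] == asg_b$chain_id[j]
      if (require_distinct && same_chain) next
      xb <- site_coords(model, asg_b$chain_id[j], asg_b$offset[j],
                        link$site_b)
      if (is.null(xb)) next
      if (same_chain && link$site_a == link$site_b) next  # same physical atom
      d <- sqrt(sum((xa - xb)^2))
      if (is.null(best) || d < best$d)
        best <- list(d = d, ca = asg_a$chain_id[i], cb = asg_b$chain_id[j])
    }
  }
  if (is.null(best)) return(unmapped("site not observed"))
  data.frame(
    protein_a = link$protein_a, protein_b = link$protein_b,
    site_a = link$site_a, site_b = link$site_b,
    chain_a = best$ca, chain_b = best$cb,
    ca_distance = best$d,
    verdict = if (best$d > threshold) "over_length" else "satisfied",
    reason = NA_character_, stringsAsFactors = FALSE)
}

#' Assess all cross-links of a consensus table against a structure
#'
#' @param links Consensus cross-link data frame (accepted rows are used).
#' @param model `StructureModel`.
#' @param proteins Named character vector of protein sequences (for chain
#'   mapping).
#' @param threshold Restraint distance in Angstrom.
#' @param min_identity Chain-mapping identity threshold.
#' @return Data frame of per-link assessments.
#' @export
assess_links <- function(links, model, proteins, threshold = 30,
                         min_identity = 0.9) {
  links <- links[links$accepted, , drop = FALSE]
  accs <- unique(c(links$protein_a, links$protein_b))
  assignments <- lapply(accs, function(a) {
    if (is.na(proteins[a])) return(NULL)
    map_protein_to_chains(proteins[[a]], model, min_identity)
  })
  names(assignments) <- accs
  out <- do.call(rbind, lapply(seq_len(nrow(links)), function(r)
    cbind(min_ca_distance(links[r, ], model, assignments, threshold),
          condition = links$condition[r])))
  if (is.null(out))
    out <- data.frame(protein_a = character(), protein_b = character(),
                      site_a = integer(), site_b = integer(),
                      chain_a = character(), chain_b = character(),
                      ca_distance = numeric(), verdict = character(),
                      reason = character(), condition = character())
  rownames(out) <- NULL
  out
}

#' Tally restraint verdicts
#'
#' @param assessments Data frame from [assess_links()].
#' @return Data frame per condition with counts `satisfied`, `over_length`,
#'   `unmapped`; the over-length links are attached as attribute
#'   `over_length_links`.
#' @export
restraint_summary <- function(assessments) {
  if (!nrow(assessments))
    return(data.frame(condition = character(), satisfied = integer(),
                      over_length = integer(), unmapped = integer()))
  cond <- if ("condition" %in% names(assessments)) assessments$condition
          else "all"
  out <- do.call(rbind, lapply(split(assessments, cond), function(d)
    data.frame(condition = d$condition[1],
               satisfied = sum(d$verdict == "satisfied"),
               over_length = sum(d$verdict == "over_length"),
               unmapped = sum(d$verdict == "unmapped"),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "over_length_links") <-
    assessments[assessments$verdict == "over_length", , drop = FALSE]
  out
}
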