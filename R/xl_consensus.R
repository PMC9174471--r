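# Replicate-consensus aggregation of cross-link hits: the 1-7 evidence
# score, the score <= 4 acceptance rule, inter/intra classification,
# homo-multimer flagging and network export.

#' Consensus score from per-replicate evidence
#'
#' Maps the confidence pattern of a cross-link over the replicates of one
#' condition to the 1-7 score used for acceptance:
#'
#' | evidence                                         | score |
#' |--------------------------------------------------|-------|
#' | high in three replicates                         | 1     |
#' | high in two replicates                           | 2     |
#' | high in one replicate + intermediate in another  | 3     |
#' | intermediate in three replicates                 | 4     |
#' | intermediate in two replicates                   | 5     |
#' | high in one replicate only                       | 6     |
#' | intermediate in one replicate only               | 7     |
#'
#' With more than three replicates configured the table generalises by
#' category counts (three or more high gives 1, and so on).
#'
#' @param evidence Character vector over replicates, each `"high"`,
#'   `"intermediate"` or `"absent"`.
#' @return Integer score 1-7, or `NA` for no evidence at all.
#' @examples
#' consensus_score(c("high", "intermediate", "absent"))  # 3
#' @export
consensus_score <- function(evidence) {
  stopifnot(all(evidence %in% c("high", "intermediate", "absent")))
  h <- sum(evidence == "high")
  i <- sum(evidence == "intermediate")
  if (h >= 3) 1L
  else if (h == 2) 2L
  else if (h == 1 && i >= 1) 3L
  else if (i >= 3) 4L
  else if (i == 2) 5L
  else if (h == 1) 6L
  else if (i == 1) 7L
  else NA_integer_
}

#' Acceptance rule for a scored cross-link
#'
#' @param score Consensus score (1-7).
#' @param max_score Highest accepted score (default 4).
#' @return Logical.
#' @export
accept_link <- function(score, max_score = 4L) {
  !is.na(score) & score <= max_score
}

#' Flag a homo-multimeric intra-protein cross-link
#'
#' An intra-protein link whose supporting peptides overlap in protein
#' coordinates cannot come from one molecule (a residue cannot belong to
#' both peptides of a pair); overlapping peptide sequences imply two
#' copies of the protein. Intervals are closed; touching at a shared
#' residue counts as overlap.
#'
#' @param start_a,end_a,start_b,end_b Protein-coordinate spans of the two
#'   supporting peptides (vectorised).
#' @param intra Logical; inter-protein calls return `FALSE` with a warning.
#' @return Logical vector.
#' @export
flag_homomultimer <- function(start_a, end_a, start_b, end_b, intra = TRUE) {
  if (!all(intra)) {
    warning("homo-multimer flag requested for inter-protein link; FALSE")
  }
  intra & (start_a <= end_b) & (start_b <= end_a)
}

# Greedy single-pass clustering of hits (same condition + protein pair)
# whose site-uncertainty intervals overlap on both peptides; the cluster
# interval shrinks to the running intersection. Returns integer ids.
cluster_by_intervals <- function(g) {
  n <- nrow(g)
  ids <- integer(n)
  bounds <- list()  # per cluster: c(a_lo, a_hi, b_lo, b_hi)
  ord <- order(g$interval_a_lo, g$interval_b_lo)
  for (r in ord) {
    placed <- FALSE
    for (k in seq_along(bounds)) {
      b <- bounds[[k]]
      if (g$interval_a_lo[r] <= b[2] && b[1] <= g$interval_a_hi[r] &&
          g$interval_b_lo[r] <= b[4] && b[3] <= g$interval_b_hi[r]) {
        ids[r] <- k
        bounds[[k]] <- c(max(b[1], g$interval_a_lo[r]),
                         min(b[2], g$interval_a_hi[r]),
                         max(b[3], g$interval_b_lo[r]),
                         min(b[4], g$interval_b_hi[r]))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      bounds[[length(bounds) + 1L]] <- c(g$interval_a_lo[r],
                                         g$interval_a_hi[r],
                                         g$interval_b_lo[r],
                                         g$interval_b_hi[r])
      ids[r] <- length(bounds)
    }
  }
  ids
}

# Canonically order the two sides of a hit so (protein, site) pairs are
# comparable across replicates: sort by accession, then by site.
canonical_hits <- function(hits) {
  swap <- hits$protein_a > hits$protein_b |
    (hits$protein_a == hits$protein_b &
       hits$protein_site_a > hits$protein_site_b)
  for (cols in list(c("protein_a", "protein_b"),
                    c("peptide_a", "peptide_b"),
                    c("start_a", "start_b"),
                    c("site_a", "site_b"),
                    c("protein_site_a", "protein_site_b"),
                    c("interval_a_lo", "interval_b_lo"),
                    c("interval_a_hi", "interval_b_hi"),
                    c("matched_a", "matched_b"))) {
    tmp <- hits[[cols[1]]][swap]
    hits[[cols[1]]][swap] <- hits[[cols[2]]][swap]
    hits[[cols[2]]][swap] <- tmp
  }
  hits
}

#' Aggregate per-replicate hits into consensus cross-links
#'
#' Hits are grouped per condition by residue pair
#' `(protein_a, protein_b, site_a, site_b)` after canonical ordering
#' (optionally by peptide pair with `by_peptide = TRUE`); the best
#' confidence per replicate is taken as that replicate's evidence, the 1-7
#' score assigned, links with score <= `max_score` accepted, intra links
#' checked for homo-multimer peptide overlap.
#'
#' @param hits Hit data frame from [xl_search()].
#' @param replicates Character vector of all replicate ids per condition
#'   (default: those observed in `hits`); replicates without evidence count
#'   as absent.
#' @param max_score Acceptance threshold (default 4).
#' @param by_peptide Group by peptide pair instead of residue pair.
#' @return Data frame of consensus cross-links: proteins, sites, per-pattern
#'   evidence counts, `score`, `accepted`, `link_type`, `homomultimer`,
#'   `condition`, `n_spectra`.
#' @export
consensus_crosslinks <- function(hits, replicates = NULL, max_score = 4L,
                                 by_peptide = FALSE) {
  empty <- data.frame(
    condition = character(), protein_a = character(), protein_b = character(),
    site_a = integer(), site_b = integer(), n_high = integer(),
    n_intermediate = integer(), score = integer(), accepted = logical(),
    link_type = character(), homomultimer = logical(), n_spectra = integer(),
    contains_decoy = logical())
  if (!nrow(hits)) return(empty)
  hits <- canonical_hits(hits)
  hits$condition[is.na(hits$condition)] <- "all"
  hits$replicate_id[is.na(hits$replicate_id)] <- "r1"
  key <- if (by_peptide)
    paste(hits$condition, hits$protein_a, hits$protein_b,
          hits$peptide_a, hits$peptide_b, sep = "\r")
  else {
    # residue-pair identity: hits with overlapping site-uncertainty
    # intervals on both sides are the same physical cross-link even when
    # their assigned middle residues differ between replicates
    pair_key <- paste(hits$condition, hits$protein_a, hits$protein_b,
                      sep = "\r")
    cl <- character(nrow(hits))
    for (rows in split(seq_len(nrow(hits)), pair_key)) {
      ids <- cluster_by_intervals(hits[rows, , drop = FALSE])
      cl[rows] <- paste(pair_key[rows], ids, sep = "\r")
    }
    cl
  }
  groups <- split(hits, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    # consensus site: middle of the intersection of the supporting
    # intervals (they are guaranteed to overlap within a cluster)
    ia <- c(max(g$interval_a_lo), min(g$interval_a_hi))
    ib <- c(max(g$interval_b_lo), min(g$interval_b_hi))
    g$protein_site_a <- ia[1] + (max(ia[2], ia[1]) - ia[1]) %/% 2L
    g$protein_site_b <- ib[1] + (max(ib[2], ib[1]) - ib[1]) %/% 2L
    reps <- if (is.null(replicates)) unique(hits$replicate_id) else replicates
    ev <- vapply(reps, function(r) {
      conf <- g$confidence[g$replicate_id == r]
      if (!length(conf)) "absent"
      else if (any(conf == "high")) "high"
      else "intermediate"
    }, "")
    sc <- consensus_score(ev)
    data.frame(
      condition = g$condition[1],
      protein_a = g$protein_a[1], protein_b = g$protein_b[1],
      site_a = g$protein_site_a[1], site_b = g$protein_site_b[1],
      n_high = sum(ev == "high"), n_intermediate = sum(ev == "intermediate"),
      score = sc, accepted = accept_link(sc, max_score),
      link_type = if (g$protein_a[1] == g$protein_b[1]) "intra_protein"
                  else "inter_protein",
      homomultimer = g$protein_a[1] == g$protein_b[1] &&
        any(flag_homomultimer(g$start_a, g$start_a + nchar(g$peptide_a) - 1L,
                              g$start_b, g$start_b + nchar(g$peptide_b) - 1L)),
      n_spectra = nrow(g),
      contains_decoy = any(g$contains_decoy),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$protein_a, out$protein_b,
            out$site_a, out$site_b), , drop = FALSE]
}

#' Build a protein-interaction edge table from accepted cross-links
#'
#' One edge per unordered protein pair (or per residue pair with
#' `detailed = TRUE`), annotated with the conditions in which the edge was
#' observed and the number of supporting residue-pair links.
#'
#' @param links Consensus data frame from [consensus_crosslinks()]; only
#'   accepted rows are used.
#' @param detailed Keep residue-pair resolution.
#' @return Data frame with `source`, `target`, per-condition presence
#'   columns and `n_links`; attribute `tallies` holds inter/intra counts
#'   per condition.
#' @export
build_network <- function(links, detailed = FALSE) {
  links <- links[links$accepted, , drop = FALSE]
  conds <- sort(unique(links$condition))
  tallies <- do.call(rbind, lapply(conds, function(cc) {
    d <- links[links$condition == cc, ]
    data.frame(condition = cc,
               inter = sum(d$link_type == "inter_protein"),
               intra = sum(d$link_type == "intra_protein"),
               stringsAsFactors = FALSE)
  }))
  key <- if (detailed)
    paste(links$protein_a, links$protein_b, links$site_a, links$site_b,
          sep = "\r")
  else paste(links$protein_a, links$protein_b, sep = "\r")
  groups <- split(links, key)
  edges <- do.call(rbind, lapply(groups, function(g) {
    row <- data.frame(source = g$protein_a[1], target = g$protein_b[1],
                      stringsAsFactors = FALSE)
    if (detailed) { row$site_a <- g$site_a[1]; row$site_b <- g$site_b[1] }
    for (cc in conds) row[[paste0("in_", cc)]] <- cc %in% g$condition
    row$n_links <- length(unique(paste(g$site_a, g$site_b)))
    row$best_score <- min(g$score)
    row
  }))
  if (is.null(edges)) edges <- data.frame(source = character(),
                                          target = character())
  rownames(edges) <- NULL
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  attr(edges, "tallies") <- tallies
  edges
}

#' Write an edge table to TSV
#' @param edges Edge table from [build_network()].
#' @param path Output path.
#' @export
write_network_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
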