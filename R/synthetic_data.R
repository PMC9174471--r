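# Seeded synthetic-data generators. Each generator records machine-readable
# ground truth alongside its artefact so recovery properties can be checked
# without any external data. One master seed fans out to per-generator
# child seeds by a fixed affine derivation.

#' Derive a child seed from a master seed
#'
#' `(seed + 1000003 * stream) mod (2^31 - 1)`; documented so every fixture
#' is independently reproducible from the master seed and its stream index.
#'
#' @param seed Master seed (integer).
#' @param stream Stream index (0, 1, 2, ...).
#' @return Integer child seed.
#' @export
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * stream) %% 2147483647)
}

# Approximate human amino-acid frequencies; K+R ~ 11% so tryptic peptides
# have realistic lengths.
AA_FREQ <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1,
             G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7,
             P = 6.3, S = 8.3, T = 5.4, W = 1.2, Y = 2.7, V = 6.0)

COMPARTMENTS <- c("cytosol", "nucleus", "ER", "dense cytosol",
                  "mitochondrium", "plasma membrane", "lysosome",
                  "peroxisome", "golgi")

#' Generate a synthetic proteome with a subcellular localisation map
#'
#' Random sequences drawn at natural amino-acid frequencies (so K/R content
#' and hence tryptic peptide lengths are realistic); each protein is
#' assigned one main compartment from the nine-category localisation
#' scheme.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param mean_length Mean sequence length (lengths are drawn from a
#'   normal with 20% CV, floored at 60).
#' @param seed Seed.
#' @return List with `sequences` (named character, accessions `SYNP0001`
#'   ...) and `localisation` (named character protein -> compartment).
#' @export
gen_proteome <- function(n_proteins = 30L, mean_length = 300L, seed = 1L) {
  if (n_proteins < 1L) stop("n_proteins must be >= 1")
  set.seed(seed)
  lens <- pmax(60L, round(stats::rnorm(n_proteins, mean_length,
                                       0.2 * mean_length)))
  seqs <- vapply(lens, function(n)
    paste(sample(names(AA_FREQ), n, replace = TRUE, prob = AA_FREQ),
          collapse = ""), "")
  names(seqs) <- sprintf("SYNP%04d", seq_len(n_proteins))
  loc <- sample(COMPARTMENTS, n_proteins, replace = TRUE,
                prob = c(30, 25, 10, 8, 10, 8, 4, 2, 3))
  names(loc) <- names(seqs)
  list(sequences = seqs, localisation = loc)
}

# Sample a cross-linkable peptide (length window, with a site preferring
# K/R residues) from the tryptic peptides of one protein.
pick_peptide <- function(peps) {
  row <- peps[sample.int(nrow(peps), 1L), ]
  chars <- strsplit(row$sequence, "", fixed = TRUE)[[1]]
  kr <- which(chars %in% c("K", "R"))
  site <- if (length(kr) && stats::runif(1) < 0.8) kr[sample.int(length(kr), 1L)]
          else sample.int(length(chars), 1L)
  row$site <- site
  row
}

# Emit the fragment peaks of one linked peptide: y/b/a ladders in the
# physically consistent shift state (a fragment containing the linked
# residue carries the +12 Da remnant, one that does not is unshifted),
# each ion kept with probability `coverage` and jittered within the MS2
# tolerance.
emit_fragments <- function(sequence, site, coverage, ppm_sigma, ppm_cap,
                           constants) {
  n <- nchar(sequence)
  ions <- fragment_ions(sequence, series = c("a", "b", "y"), charges = 1L,
                        include_shifted = TRUE, constants = constants)
  contains <- ifelse(ions$series == "y", ions$index >= n - site + 1L,
                     ions$index >= site)
  ions <- ions[ions$shifted == contains, , drop = FALSE]
  keep <- stats::runif(nrow(ions)) < coverage
  ions <- ions[keep, , drop = FALSE]
  err <- pmax(pmin(stats::rnorm(nrow(ions), 0, ppm_sigma), ppm_cap), -ppm_cap)
  data.frame(mz = ions$mz * (1 + 1e-6 * err),
             intensity = stats::runif(nrow(ions), 100, 1000))
}

#' Generate cross-linked peptide-pair MS2 spectra with ground truth
#'
#' Plants `n_links` cross-links between tryptic peptides of the proteome
#' (sites preferring K/R, the preferentially reactive residues), then
#' emits one spectrum per link per replicate and condition: precursor mass
#' equal to the peptide-pair mass plus 12 Da (24 Da for a `frac_double`
#' fraction) with MS1 ppm jitter, a `coverage` fraction of the a/b/y and
#' linker-shifted fragment ions with MS2 jitter, and uniform noise peaks
#' whose intensities stay below the median true-fragment intensity.
#'
#' @param proteome List from [gen_proteome()].
#' @param n_links Number of planted cross-links.
#' @param coverage Fraction of theoretical fragment ions emitted (0, 1].
#' @param noise_peaks Noise peaks per spectrum.
#' @param ms1_ppm_sigma,ms2_ppm_sigma Gaussian ppm jitter SDs; MS1 jitter
#'   is capped at 5 ppm and MS2 at 7 ppm so planted peaks stay inside the
#'   6/8 ppm search tolerances.
#' @param frac_double Fraction of links carrying two bridges (+24 Da).
#' @param frac_intra Fraction of links within one protein.
#' @param charges Precursor charge states to sample from.
#' @param conditions,replicates Condition labels and replicates per
#'   condition.
#' @param peptide_length Length window for linkable peptides.
#' @param seed Seed.
#' @return List with `spectra` (flat list of spectrum records) and `truth`
#'   (data frame: link id, proteins, peptides, starts, sites in protein
#'   coordinates, linker count).
#' @export
gen_xl_spectra <- function(proteome, n_links = 40L, coverage = 0.85,
                           noise_peaks = 5L, ms1_ppm_sigma = 2,
                           ms2_ppm_sigma = 2, frac_double = 0.1,
                           frac_intra = 0.3, charges = 4:7,
                           conditions = "undiff", replicates = 3L,
                           peptide_length = c(9L, 13L), seed = 1L) {
  stopifnot(coverage > 0, coverage <= 1)
  constants <- mass_constants()
  set.seed(seed)
  pep_pool <- lapply(proteome$sequences, function(s)
    digest(s, max_missed = 2L, length_range = peptide_length))
  for (i in seq_along(pep_pool)) {
    if (nrow(pep_pool[[i]]))
      pep_pool[[i]]$protein_id <- names(pep_pool)[i]
  }
  usable <- names(pep_pool)[vapply(pep_pool, nrow, 0L) > 0L]
  if (length(usable) < 2L) stop("proteome yields too few linkable peptides")
  truth <- list()
  tries <- 0L
  while (length(truth) < n_links) {
    tries <- tries + 1L
    if (tries > 20L * n_links)
      stop("requested links exceed available residue pairs")
    intra <- stats::runif(1) < frac_intra
    if (intra) {
      pa <- sample(usable, 1L)
      pb <- pa
    } else {
      pr <- sample(usable, 2L)
      pa <- pr[1]; pb <- pr[2]
    }
    pep_a <- pick_peptide(pep_pool[[pa]])
    pep_b <- pick_peptide(pep_pool[[pb]])
    if (intra && pep_a$start == pep_b$start) next  # same peptide twice
    lc <- if (stats::runif(1) < frac_double) 2L else 1L
    truth[[length(truth) + 1L]] <- data.frame(
      link_id = sprintf("XL%03d", length(truth) + 1L),
      protein_a = pa, protein_b = pb,
      peptide_a = pep_a$sequence, peptide_b = pep_b$sequence,
      start_a = pep_a$start, start_b = pep_b$start,
      site_a = pep_a$site, site_b = pep_b$site,
      protein_site_a = pep_a$start + pep_a$site - 1L,
      protein_site_b = pep_b$start + pep_b$site - 1L,
      linker_count = lc, intra = intra, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  spectra <- list()
  for (cond in conditions) {
    for (rep_i in seq_len(replicates)) {
      for (l in seq_len(nrow(truth))) {
        tr <- truth[l, ]
        z <- sample(charges, 1L)
        m0 <- peptide_mass(tr$peptide_a, constants) +
              peptide_mass(tr$peptide_b, constants) +
              tr$linker_count * constants$linker_single
        e1 <- max(min(stats::rnorm(1, 0, ms1_ppm_sigma), 5), -5)
        mz <- (m0 * (1 + 1e-6 * e1) + z * constants$proton) / z
        fa <- emit_fragments(tr$peptide_a, tr$site_a, coverage,
                             ms2_ppm_sigma, 7, constants)
        fb <- emit_fragments(tr$peptide_b, tr$site_b, coverage,
                             ms2_ppm_sigma, 7, constants)
        med <- stats::median(c(fa$intensity, fb$intensity))
        if (!is.finite(med)) med <- 100
        noise <- data.frame(
          mz = stats::runif(noise_peaks, 200, 1600),
          intensity = stats::runif(noise_peaks, 1, max(1, 0.2 * med)))
        peaks <- rbind(fa[, c("mz", "intensity")],
                       fb[, c("mz", "intensity")], noise)
        peaks <- as.matrix(peaks[order(peaks$mz), ])
        colnames(peaks) <- c("mz", "intensity")
        spectra[[length(spectra) + 1L]] <- list(
          spectrum_id = sprintf("%s_r%d_%s", cond, rep_i, tr$link_id),
          precursor_mz = mz, precursor_charge = z, peaks = peaks,
          condition = cond, replicate_id = sprintf("r%d", rep_i),
          link_id = tr$link_id,
          n_emitted_a = nrow(fa), n_emitted_b = nrow(fb))
      }
    }
  }
  list(spectra = spectra, truth = truth)
}

#' Generate a synthetic protein abundance table with planted fold-changes
#'
#' Log-normal intensities for `n_proteins` over a multi-condition design
#' with biological replicates; `n_planted` proteins carry an additive
#' planted log2 effect (random sign) in `effect_condition`; values are
#' missing completely at random at `missing_rate`. An iBAQ companion
#' matrix is derived from per-protein theoretical peptide counts.
#'
#' @param n_proteins Number of proteins.
#' @param conditions Condition labels (first is the reference).
#' @param replicates Replicates per condition.
#' @param n_planted Number of proteins with a planted effect.
#' @param effect_log2 Absolute planted log2 fold-change.
#' @param sigma Residual SD on the log2 scale.
#' @param missing_rate Missing-completely-at-random rate.
#' @param effect_condition Condition carrying the planted effect (default
#'   the second condition).
#' @param peptide_counts Optional named counts; drawn uniformly 5..50 if
#'   absent.
#' @param seed Seed.
#' @return List with `intensity`, `ibaq` (protein x sample, `NA` =
#'   missing), `samples` (data frame: sample_id, condition, replicate) and
#'   `truth` (planted proteins with signed effects, peptide counts).
#' @export
gen_abundance <- function(n_proteins = 1000L,
                          conditions = c("undiff", "RA", "RA_PMA"),
                          replicates = 6L, n_planted = 50L,
                          effect_log2 = 1.5, sigma = 0.3,
                          missing_rate = 0.05,
                          effect_condition = conditions[2],
                          peptide_counts = NULL, seed = 1L) {
  set.seed(seed)
  prot <- sprintf("SYNQ%04d", seq_len(n_proteins))
  samples <- data.frame(
    sample_id = paste0(rep(conditions, each = replicates), "_",
                       rep(seq_len(replicates), length(conditions))),
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), length(conditions)),
    stringsAsFactors = FALSE)
  base <- stats::runif(n_proteins, 20, 28)
  planted <- sample(prot, n_planted)
  sign <- sample(c(-1, 1), n_planted, replace = TRUE)
  effect <- stats::setNames(rep(0, n_proteins), prot)
  effect[planted] <- sign * effect_log2
  log2_mat <- matrix(base, n_proteins, nrow(samples))
  is_eff <- samples$condition == effect_condition
  log2_mat[, is_eff] <- log2_mat[, is_eff] + effect
  log2_mat <- log2_mat + matrix(stats::rnorm(length(log2_mat), 0, sigma),
                                n_proteins)
  intensity <- 2^log2_mat
  miss <- matrix(stats::runif(length(intensity)) < missing_rate,
                 n_proteins)
  intensity[miss] <- NA
  dimnames(intensity) <- list(prot, samples$sample_id)
  if (is.null(peptide_counts)) {
    peptide_counts <- stats::setNames(sample(5:50, n_proteins,
                                             replace = TRUE), prot)
  }
  ibaq <- intensity / peptide_counts[prot]
  list(intensity = intensity, ibaq = ibaq, samples = samples,
       truth = list(planted = data.frame(protein = planted,
                                         effect = sign * rep(effect_log2,
                                                             n_planted),
                                         condition = rep(effect_condition,
                                                         n_planted),
                                         stringsAsFactors = FALSE),
                    peptide_counts = peptide_counts,
                    sigma = sigma, missing_rate = missing_rate))
}

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Generate a toy multi-chain structure with planted site-pair distances
#'
#' Each planted pair gets a fresh pair of chains, laid out as extended
#' Calpha traces (3.8 Angstrom spacing) and positioned so the two planted
#' sites sit at exactly the requested Calpha distance; chain pairs are
#' separated by 1000 Angstrom so distances never interfere across pairs.
#' Written as a minimal mmCIF with one Calpha atom per residue.
#'
#' @param proteins Named character vector of protein sequences.
#' @param pairs Data frame with `protein_a`, `site_a`, `protein_b`,
#'   `site_b`, `distance` (Angstrom, the planted Calpha-Calpha distance).
#' @param path Output mmCIF path.
#' @param structure_id Identifier written to the data block.
#' @return Invisibly, a list with `path` and `truth` (the input pairs with
#'   the chain ids used).
#' @export
gen_structure_toy <- function(proteins, pairs, path,
                              structure_id = "SYNTOY") {
  stopifnot(all(c("protein_a", "site_a", "protein_b", "site_b",
                  "distance") %in% names(pairs)))
  chain_ids <- c(LETTERS, letters)
  if (2L * nrow(pairs) > length(chain_ids))
    stop("too many planted pairs for available chain ids")
  lines <- c(paste0("data_", structure_id), "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
  atom_id <- 0L
  truth <- pairs
  truth$chain_a <- NA_character_; truth$chain_b <- NA_character_
  emit_chain <- function(seqn, cid, entity, origin) {
    chars <- strsplit(seqn, "", fixed = TRUE)[[1]]
    vapply(seq_along(chars), function(i) {
      atom_id <<- atom_id + 1L
      sprintf(paste0("ATOM %d C CA . %s %s %d %d ? %.3f %.3f %.3f ",
                     "1.00 0.00 ? %d %s %s CA 1"),
              atom_id, AA1TO3[chars[i]], cid, entity, i,
              origin[1] + 3.8 * i, origin[2], origin[3],
              i, AA1TO3[chars[i]], cid)
    }, "")
  }
  for (k in seq_len(nrow(pairs))) {
    pa <- pairs$protein_a[k]; pb <- pairs$protein_b[k]
    ca <- chain_ids[2L * k - 1L]; cb <- chain_ids[2L * k]
    z0 <- 1000 * (k - 1L)
    # chain B shifted along x so the planted sites face each other, and
    # along y by the target distance
    dx <- 3.8 * (pairs$site_a[k] - pairs$site_b[k])
    lines <- c(lines,
               emit_chain(proteins[[pa]], ca, 2L * k - 1L, c(0, 0, z0)),
               emit_chain(proteins[[pb]], cb, 2L * k,
                          c(dx, pairs$distance[k], z0)))
    truth$chain_a[k] <- ca; truth$chain_b[k] <- cb
  }
  lines <- c(lines, "#")
  writeLines(lines, path)
  invisible(list(path = path, truth = truth))
}

#' Generate a synthetic qPCR Ct table with planted ddCt effects
#'
#' Ct values are gene baseline + condition shift (the planted ddCt) +
#' sample plate offset + Gaussian noise; the reference gene shares each
#' sample's plate offset so normalisation cancels it. Technical replicates
#' add small extra noise.
#'
#' @param genes Character vector of target gene names.
#' @param planted Data frame `gene`, `condition`, `ddct` (planted shifts
#'   relative to the control condition; negative means induction).
#' @param conditions Condition labels (first is the control).
#' @param replicates Biological replicates per condition.
#' @param technical_reps Technical replicates per biological sample.
#' @param ct_sigma Biological Ct noise SD (cycles).
#' @param ref_gene Reference gene name.
#' @param seed Seed.
#' @return List with `ct` (long-format Ct table) and `truth` (`planted`).
#' @export
gen_ct <- function(genes, planted = NULL,
                   conditions = c("undiff", "RA", "RA_PMA"),
                   replicates = 6L, technical_reps = 2L, ct_sigma = 0.2,
                   ref_gene = "HPRT1", seed = 1L) {
  set.seed(seed)
  all_genes <- c(ref_gene, genes)
  base <- stats::setNames(stats::runif(length(all_genes), 18, 28), all_genes)
  rows <- list()
  for (cond in conditions) {
    for (r in seq_len(replicates)) {
      sid <- sprintf("%s_%d", cond, r)
      plate <- stats::rnorm(1, 0, 0.3)
      for (g in all_genes) {
        shift <- 0
        if (!is.null(planted) && g != ref_gene) {
          hit <- planted$gene == g & planted$condition == cond
          if (any(hit)) shift <- planted$ddct[hit][1]
        }
        mu <- base[g] + shift + plate + stats::rnorm(1, 0, ct_sigma)
        for (tr in seq_len(technical_reps)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, sample_id = sid, condition = cond, replicate = r,
            technical_rep = tr, ct = mu + stats::rnorm(1, 0, 0.1),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(ct = do.call(rbind, rows), truth = list(planted = planted))
}
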