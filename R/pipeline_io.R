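# Orchestration: generate or load inputs, run the full analysis
# (search -> consensus -> structures -> quant -> qPCR) from one declarative
# configuration, and write stage outputs with a JSON summary and manifest.

#' Default pipeline parameters
#'
#' The defaults are the reference analysis settings: 6/8 ppm MS1/MS2
#' tolerances, 4 missed cleavages, precursor charges 4-7, top-800 database,
#' high-confidence ratio 1.5 with per-peptide fragment floors 18/15,
#' consensus score <= 4, 30 Angstrom Calpha restraint, |log2FC| 0.8 and
#' adjusted p 0.05 volcano thresholds.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(ms1_tol_ppm = 6, ms2_tol_ppm = 8, max_missed = 4L,
       charge_window = 4:7, n_top = 800L, ratio_min = 1.5,
       high_floor = 18L, intermediate_floor = 15L, max_score = 4L,
       distance_threshold = 30, lfc = 0.8, alpha = 0.05, min_obs = 2L,
       peptide_length = c(5L, 60L), ibaq_length = c(7L, 30L))
}

#' Validate a pipeline configuration
#'
#' A config is a named list (or a YAML file path) with any of the input
#' slots `fasta`, `localisation`, `mgf` (named list condition ->
#' replicate file vector), `abundance` (protein-groups TSV), `design`
#' (sample annotation TSV), `structure` (mmCIF/PDB), `ct` (Ct TSV), plus
#' `out_dir` and an optional `params` list overriding [default_params()].
#' All referenced paths must exist.
#'
#' @param config List or YAML path.
#' @return The validated config with `params` filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  paths <- c(config$fasta, config$localisation, unlist(config$mgf),
             config$abundance, config$design, config$structure, config$ct)
  missing <- if (length(paths)) paths[!file.exists(paths)] else character()
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  params <- default_params()
  params[names(config$params)] <- config$params
  config$params <- params
  config
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end analysis from a configuration
#'
#' Stages present in the config are run in order (cross-link search over
#' all MGF files, replicate consensus and network export, structure
#' restraint assessment, proteome quantification, qPCR quantification);
#' absent inputs skip their stages. Every stage logs counts in/out, writes
#' its TSV outputs under `out_dir` and contributes to `summary.json`; a
#' stage failure aborts with the stage name after writing the partial
#' manifest.
#'
#' @param config Config list or YAML path (see [validate_config()]).
#' @param quiet Suppress stage logging.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  p <- config$params
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  manifest <- character()
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  finish_stage <- function(name, files) manifest <<- c(manifest, files)
  fail <- function(stage, e) {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  proteins <- NULL
  if (!is.null(config$fasta)) proteins <- read_fasta(config$fasta)

  consensus <- NULL
  if (!is.null(config$mgf) && length(config$mgf) && !is.null(proteins)) {
    tryCatch({
      # rank the database by mean iBAQ when a quant table covers the FASTA
      abundance <- NULL
      if (!is.null(config$abundance)) {
        tabs <- read_protein_groups(config$abundance)
        if (length(tabs$ibaq) &&
            any(names(proteins) %in% rownames(tabs$ibaq))) {
          mean_ibaq <- rowMeans(tabs$ibaq, na.rm = TRUE)
          abundance <- mean_ibaq[names(proteins)]
          abundance[is.na(abundance)] <- 0
        }
      }
      db <- build_search_database(proteins, abundance,
                                  n_top = min(p$n_top, length(proteins)))
      index <- peptide_index(db, max_missed = p$max_missed,
                             length_range = p$peptide_length)
      log_msg("search database: %d proteins -> %d peptides",
              length(db), nrow(index))
      all_hits <- list()
      for (cond in names(config$mgf)) {
        for (path in config$mgf[[cond]]) {
          spectra <- read_mgf(path)
          hits <- xl_search(spectra, index, p$ms1_tol_ppm, p$ms2_tol_ppm,
                            p$charge_window)
          log_msg("xl_search %s: %d spectra -> %d hits",
                  basename(path), length(spectra), nrow(hits))
          all_hits[[length(all_hits) + 1L]] <- hits
        }
      }
      hits <- do.call(rbind, all_hits)
      consensus <- consensus_crosslinks(hits, max_score = p$max_score)
      edges <- build_network(consensus)
      dec <- decoy_report(hits)
      files <- c(write_tsv(hits, file.path(out, "hits.tsv")),
                 write_tsv(consensus, file.path(out, "consensus.tsv")),
                 write_tsv(edges, file.path(out, "network.tsv")))
      finish_stage("xl", files)
      tallies <- attr(edges, "tallies")
      summary$crosslinks <- list(
        n_spectra_hits = nrow(hits),
        n_consensus = nrow(consensus),
        n_accepted = sum(consensus$accepted),
        inter_intra = tallies,
        decoy = dec)
    }, error = function(e) fail("xl_search", e))
  }

  if (!is.null(config$structure) && !is.null(consensus) &&
      !is.null(proteins)) {
    tryCatch({
      model <- read_structure(config$structure)
      assessments <- assess_links(consensus, model, proteins,
                                  threshold = p$distance_threshold)
      restraints <- restraint_summary(assessments)
      files <- c(write_tsv(assessments, file.path(out, "assessments.tsv")),
                 write_tsv(restraints, file.path(out, "restraints.tsv")))
      finish_stage("struct", files)
      summary$restraints <- restraints
    }, error = function(e) fail("struct_validate", e))
  }

  if (!is.null(config$abundance) && !is.null(config$design)) {
    tryCatch({
      tabs <- read_protein_groups(config$abundance)
      design <- utils::read.delim(config$design, stringsAsFactors = FALSE)
      condition <- design$condition[match(colnames(tabs$intensity),
                                          design$sample_id)]
      conds <- unique(condition)
      norm <- equalise_medians(tabs$intensity)
      files <- character()
      quant_counts <- list()
      for (pair in utils::combn(conds, 2, simplify = FALSE)) {
        res <- differential_abundance(norm, condition, pair[2], pair[1],
                                      min_obs = p$min_obs, lfc = p$lfc,
                                      alpha = p$alpha)
        nm <- sprintf("quant_%s_vs_%s.tsv", pair[2], pair[1])
        files <- c(files, write_tsv(res, file.path(out, nm)))
        quant_counts[[paste(pair[2], "vs", pair[1])]] <- list(
          tested = sum(!is.na(res$p)),
          up = sum(res$call == "up"), down = sum(res$call == "down"),
          condition_specific = sum(res$call == "condition_specific"))
        log_msg("quant %s vs %s: %d tested, %d up, %d down",
                pair[2], pair[1], sum(!is.na(res$p)),
                sum(res$call == "up"), sum(res$call == "down"))
      }
      if (!is.null(config$localisation) && length(tabs$ibaq)) {
        locmap <- utils::read.delim(config$localisation,
                                    stringsAsFactors = FALSE)
        loc <- stats::setNames(locmap$compartment, locmap$protein)
        rel <- sweep(tabs$ibaq, 2, colSums(tabs$ibaq, na.rm = TRUE), "/")
        la <- localisation_abundance(rel, loc, condition)
        files <- c(files,
                   write_tsv(la$profile, file.path(out, "localisation_profile.tsv")),
                   write_tsv(la$tests, file.path(out, "localisation_tests.tsv")))
        summary$localisation <- list(
          n_significant = sum(la$tests$adj_p < 0.01))
      }
      finish_stage("quant", files)
      summary$quant <- quant_counts
    }, error = function(e) fail("proteome_quant", e))
  }

  if (!is.null(config$ct)) {
    tryCatch({
      ct <- utils::read.delim(config$ct, stringsAsFactors = FALSE)
      control <- if (!is.null(config$control_condition))
        config$control_condition else ct$condition[1]
      ref <- if (!is.null(config$ref_gene)) config$ref_gene else "HPRT1"
      q <- ddct_fold_change(ct, ref_gene = ref, control_condition = control)
      files <- c(write_tsv(q$summary, file.path(out, "qpcr_summary.tsv")),
                 write_tsv(q$tests, file.path(out, "qpcr_tests.tsv")))
      finish_stage("qpcr", files)
      summary$qpcr <- list(n_genes = length(unique(q$summary$gene)))
    }, error = function(e) fail("qpcr_quant", e))
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(c(manifest, file.path(out, "summary.json")),
                       file.path(out, "manifest.json"))
  invisible(summary)
}

#' Write the default synthetic fixture set
#'
#' Generates and writes, under `out_dir`: the synthetic proteome FASTA and
#' localisation map, cross-linked MGF peak lists (one file per condition
#' and replicate), a protein-groups-style abundance TSV with its design
#' table, a toy mmCIF structure with planted near/far site pairs, a qPCR
#' Ct TSV, and `truth.json` recording every planted effect.
#'
#' @param out_dir Output directory (created).
#' @param seed Master seed; child seeds are derived per generator with
#'   [child_seed()].
#' @param n_proteins,n_links,coverage,noise_peaks Benchmark scale for the
#'   cross-link fixtures (defaults 30 proteins, 40 links, 85% coverage,
#'   5 noise peaks per spectrum).
#' @param conditions Condition labels.
#' @return Invisibly, a list of file paths plus the truth objects.
#' @export
make_fixtures <- function(out_dir, seed = 17L, n_proteins = 30L,
                          n_links = 40L, coverage = 0.85, noise_peaks = 5L,
                          conditions = c("undiff", "RA", "RA_PMA")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prot <- gen_proteome(n_proteins, seed = child_seed(seed, 0L))
  fasta <- file.path(out_dir, "proteome.fasta")
  write_fasta(prot$sequences, fasta)
  locmap <- file.path(out_dir, "localisation.tsv")
  write_tsv(data.frame(protein = names(prot$localisation),
                       compartment = unname(prot$localisation)), locmap)

  mgf_paths <- list()
  xl_truth <- list()
  for (ci in seq_along(conditions)) {
    xl <- gen_xl_spectra(prot, n_links = n_links, coverage = coverage,
                         noise_peaks = noise_peaks,
                         conditions = conditions[ci],
                         seed = child_seed(seed, ci))
    xl_truth[[conditions[ci]]] <- xl$truth
    reps <- unique(vapply(xl$spectra, `[[`, "", "replicate_id"))
    paths <- character()
    for (r in reps) {
      sel <- Filter(function(s) s$replicate_id == r, xl$spectra)
      path <- file.path(out_dir,
                        sprintf("xl_%s_%s.mgf", conditions[ci], r))
      write_mgf(sel, path)
      paths <- c(paths, path)
    }
    mgf_paths[[conditions[ci]]] <- paths
  }

  ab <- gen_abundance(seed = child_seed(seed, 10L), conditions = conditions)
  pg <- data.frame(accession = rownames(ab$intensity),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(ab$intensity))) {
    pg[[paste("Intensity", colnames(ab$intensity)[j])]] <-
      ifelse(is.na(ab$intensity[, j]), 0, ab$intensity[, j])
    pg[[paste("iBAQ", colnames(ab$ibaq)[j])]] <-
      ifelse(is.na(ab$ibaq[, j]), 0, ab$ibaq[, j])
  }
  abundance <- file.path(out_dir, "protein_groups.tsv")
  write_tsv(pg, abundance)
  design <- file.path(out_dir, "design.tsv")
  write_tsv(ab$samples, design)

  # toy structure: planted near/far pairs over dedicated chain pairs
  set.seed(child_seed(seed, 20L))
  sprot <- gen_proteome(8L, mean_length = 120L,
                        seed = child_seed(seed, 21L))$sequences
  names(sprot) <- sprintf("SYNS%04d", seq_along(sprot))
  pairs <- data.frame(
    protein_a = names(sprot)[c(1, 3, 5, 7)],
    site_a = c(20L, 35L, 50L, 15L),
    protein_b = names(sprot)[c(2, 4, 6, 8)],
    site_b = c(30L, 40L, 25L, 60L),
    distance = c(12, 18.5, 45, 30), stringsAsFactors = FALSE)
  cif <- file.path(out_dir, "toy_structure.cif")
  st <- gen_structure_toy(sprot, pairs, cif)
  struct_fasta <- file.path(out_dir, "structure_proteins.fasta")
  write_fasta(sprot, struct_fasta)

  planted_ct <- data.frame(
    gene = c("TGM2", "TGM2", "RET"),
    condition = conditions[c(2, 3, 2)],
    ddct = c(-2, -2, -1.5), stringsAsFactors = FALSE)
  planted_ct <- planted_ct[!is.na(planted_ct$condition), , drop = FALSE]
  qp <- gen_ct(genes = c("TGM2", "SYN1", "RET", "DBH"),
               planted = planted_ct,
               conditions = conditions, seed = child_seed(seed, 30L))
  ct <- file.path(out_dir, "ct_table.tsv")
  write_tsv(qp$ct, ct)

  truth <- list(seed = seed,
                crosslinks = xl_truth,
                abundance = ab$truth,
                structure = st$truth,
                qpcr = qp$truth)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(fasta = fasta, localisation = locmap, mgf = mgf_paths,
                 abundance = abundance, design = design, structure = cif,
                 structure_fasta = struct_fasta, ct = ct,
                 truth = truth, truth_path = truth_path))
}
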