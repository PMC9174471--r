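# Quantitative proteome statistics: iBAQ and relative iBAQ, subcellular
# localisation abundance with Bonferroni-corrected t-tests, equalise-medians
# normalisation, differential abundance with BH-adjusted volcano calls,
# presence/absence and Fisher over-representation.

#' iBAQ and relative iBAQ from raw intensities
#'
#' iBAQ divides a protein's summed intensity by its number of
#' theoretically observable tryptic peptides, making values comparable
#' across proteins; relative iBAQ further divides by the per-sample iBAQ
#' total, giving a molar-fraction-like abundance that sums to 1 per sample.
#'
#' @param intensity Protein x sample numeric matrix (rownames =
#'   accessions); `NA` allowed.
#' @param peptide_counts Named integer vector of theoretical peptide counts
#'   per protein (e.g. from [digest()] with `length_range = c(7, 30)`,
#'   `max_missed = 0`). Proteins with count 0 are dropped with a warning.
#' @return List with `ibaq` and `relative_ibaq` matrices.
#' @export
compute_ibaq <- function(intensity, peptide_counts) {
  counts <- peptide_counts[rownames(intensity)]
  bad <- is.na(counts) | counts < 1
  if (any(bad)) {
    warning(sprintf("%d proteins without theoretical peptides excluded",
                    sum(bad)))
    intensity <- intensity[!bad, , drop = FALSE]
    counts <- counts[!bad]
  }
  ibaq <- intensity / counts
  totals <- colSums(ibaq, na.rm = TRUE)
  rel <- sweep(ibaq, 2, totals, "/")
  list(ibaq = ibaq, relative_ibaq = rel)
}

#' Subcellular localisation abundance profile with pairwise t-tests
#'
#' Sums relative iBAQ values over all proteins annotated to each
#' compartment, per sample; reports per-condition mean and standard error
#' and pairwise two-tailed t-tests between conditions with Bonferroni
#' adjustment over the family of tests actually performed.
#'
#' @param relative_ibaq Protein x sample matrix of relative iBAQ.
#' @param localisation Named character vector protein -> compartment.
#' @param condition Character vector of condition labels per sample
#'   (column order).
#' @param var_equal Use the pooled-variance Student test (default `TRUE`).
#' @return List with `sums` (compartment x sample), `profile` (compartment
#'   x condition mean and SE) and `tests` (pairwise comparisons with raw
#'   and Bonferroni-adjusted p).
#' @export
localisation_abundance <- function(relative_ibaq, localisation, condition,
                                   var_equal = TRUE) {
  stopifnot(length(condition) == ncol(relative_ibaq))
  mapped <- intersect(rownames(relative_ibaq), names(localisation))
  comp <- sort(unique(localisation[mapped]))
  sums <- t(vapply(comp, function(cc) {
    prot <- mapped[localisation[mapped] == cc]
    colSums(relative_ibaq[prot, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(relative_ibaq))))
  rownames(sums) <- comp
  conds <- unique(condition)
  profile <- do.call(rbind, lapply(comp, function(cc)
    do.call(rbind, lapply(conds, function(cd) {
      v <- sums[cc, condition == cd]
      data.frame(compartment = cc, condition = cd, mean = mean(v),
                 se = stats::sd(v) / sqrt(length(v)), n = length(v),
                 stringsAsFactors = FALSE)
    }))))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(comp, function(cc)
    do.call(rbind, lapply(pairs, function(pp) {
      x <- sums[cc, condition == pp[1]]
      y <- sums[cc, condition == pp[2]]
      if (length(x) < 2 || length(y) < 2 ||
          (stats::sd(x) == 0 && stats::sd(y) == 0))
        return(NULL)
      tt <- stats::t.test(x, y, var.equal = var_equal)
      data.frame(compartment = cc, condition_a = pp[1], condition_b = pp[2],
                 diff = mean(x) - mean(y), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))))
  if (!is.null(tests)) {
    # Bonferroni family = tests actually run
    tests$adj_p <- pmin(1, tests$p * nrow(tests))
    rownames(tests) <- NULL
  }
  list(sums = sums, profile = profile, tests = tests)
}

#' Equalise-medians normalisation on the log2 scale
#'
#' Shifts each sample's log2 intensities so that all sample medians equal
#' the grand median of the per-sample medians. Idempotent.
#'
#' @param intensity Protein x sample matrix of positive intensities (`NA`
#'   allowed); or an already-log2 matrix with `log = FALSE`.
#' @param log Take log2 first (default `TRUE`).
#' @return Normalised log2 matrix.
#' @export
equalise_medians <- function(intensity, log = TRUE) {
  x <- if (log) log2(intensity) else intensity
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med))) stop("sample with no finite values")
  sweep(x, 2, med - stats::median(med), "-")
}

# Vectorised two-sample t-tests on the rows of two matrices.
row_t_test <- function(xa, xb, var_equal = TRUE) {
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  va <- apply(xa, 1, stats::var, na.rm = TRUE)
  vb <- apply(xb, 1, stats::var, na.rm = TRUE)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(estimate = ma - mb, t = t, p = p, n_a = na, n_b = nb)
}

#' Differential protein abundance between two conditions
#'
#' Two-sample two-tailed t-test per protein on normalised log2 intensities
#' (pooled-variance Student by default, Welch by flag), Benjamini-Hochberg
#' adjustment across tested proteins, and volcano calls at the
#' `|log2FC| > lfc` and `adj_p < alpha` thresholds. The log2 fold-change is
#' mean(condition A) minus mean(condition B). Proteins with fewer than
#' `min_obs` observations in either condition are not tested and are routed
#' to presence/absence logic.
#'
#' @param log2_table Normalised protein x sample log2 matrix.
#' @param condition Condition label per column.
#' @param cond_a,cond_b The two condition labels to compare (A vs B).
#' @param min_obs Minimum non-missing values per condition (default 2).
#' @param lfc log2 fold-change call threshold (default 0.8, strict >).
#' @param alpha Adjusted-p call threshold (default 0.05, strict <).
#' @param var_equal Pooled-variance Student test (default) or Welch.
#' @return Data frame with `protein`, `log2fc`, `p`, `adj_p`, `call`
#'   (`up`, `down`, `unchanged`) for tested proteins, plus untested
#'   condition-specific proteins (call `condition_specific`, see
#'   [presence_absence()]) with `NA` statistics.
#' @export
differential_abundance <- function(log2_table, condition, cond_a, cond_b,
                                   min_obs = 2L, lfc = 0.8, alpha = 0.05,
                                   var_equal = TRUE) {
  xa <- log2_table[, condition == cond_a, drop = FALSE]
  xb <- log2_table[, condition == cond_b, drop = FALSE]
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  testable <- na >= min_obs & nb >= min_obs
  tt <- row_t_test(xa[testable, , drop = FALSE], xb[testable, , drop = FALSE],
                   var_equal = var_equal)
  adj <- stats::p.adjust(tt$p, method = "BH")
  call <- ifelse(adj < alpha & tt$estimate > lfc, "up",
          ifelse(adj < alpha & tt$estimate < -lfc, "down", "unchanged"))
  res <- data.frame(protein = rownames(log2_table)[testable],
                    log2fc = tt$estimate, p = tt$p, adj_p = adj,
                    call = call, n_a = tt$n_a, n_b = tt$n_b,
                    stringsAsFactors = FALSE)
  pa <- presence_absence(log2_table, condition, cond_a, cond_b, min_obs)
  spec <- c(pa$specific_a, pa$specific_b)
  if (length(spec))
    res <- rbind(res, data.frame(
      protein = spec, log2fc = NA_real_, p = NA_real_, adj_p = NA_real_,
      call = "condition_specific",
      n_a = na[spec], n_b = nb[spec], stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Condition-specific (presence/absence) proteins
#'
#' A protein is condition-specific when it is observed at least `min_obs`
#' times in one condition and never in the other.
#'
#' @inheritParams differential_abundance
#' @return List with `specific_a` and `specific_b` accession vectors.
#' @export
presence_absence <- function(log2_table, condition, cond_a, cond_b,
                             min_obs = 2L) {
  xa <- log2_table[, condition == cond_a, drop = FALSE]
  xb <- log2_table[, condition == cond_b, drop = FALSE]
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  list(specific_a = rownames(log2_table)[na >= min_obs & nb == 0],
       specific_b = rownames(log2_table)[nb >= min_obs & na == 0])
}

#' One-sided Fisher over-representation across gene sets
#'
#' Hypergeometric upper-tail test of a gene list against each set, with
#' Benjamini-Hochberg adjustment across sets. Sets with no overlap with
#' the background are skipped.
#'
#' @param gene_list Character vector (must be a subset of `background`).
#' @param background Character universe.
#' @param gene_sets Named list of character vectors.
#' @return Data frame with per-set overlap counts, `p` and `adj_p`.
#' @export
ora_fisher <- function(gene_list, background, gene_sets) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  if (!all(gene_list %in% background))
    stop("gene_list must be a subset of background")
  N <- length(background); n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    if (!length(set)) return(NULL)
    k <- length(intersect(gene_list, set))
    K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, list_size = n,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), list_size = integer(),
                      background_size = integer(), p = numeric(),
                      adj_p = numeric()))
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Read a protein-groups-like TSV into intensity and iBAQ matrices
#'
#' Expects an accession column plus `Intensity <sample>` and
#' `iBAQ <sample>` columns, the customary layout of quantification
#' software output tables.
#'
#' @param path TSV path.
#' @param accession_col Name of the accession column.
#' @return List with `intensity` and `ibaq` matrices (may have 0 columns
#'   when absent); zeros are converted to `NA` (not observed).
#' @export
read_protein_groups <- function(path, accession_col = "accession") {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!accession_col %in% names(tab))
    stop(sprintf("missing accession column '%s'", accession_col))
  grab <- function(prefix) {
    cols <- grep(paste0("^", prefix, " "), names(tab), value = TRUE)
    m <- as.matrix(tab[, cols, drop = FALSE])
    rownames(m) <- tab[[accession_col]]
    colnames(m) <- sub(paste0("^", prefix, " "), "", cols)
    m[m == 0] <- NA
    m
  }
  list(intensity = grab("Intensity"), ibaq = grab("iBAQ"))
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (set name, description, genes; tab-separated).
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  sets
}
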