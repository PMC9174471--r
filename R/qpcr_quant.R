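# Relative gene expression by the 2^-ddCt method with reference-gene
# normalisation, geometric-mean control baseline and primer-efficiency
# estimation from dilution series.

#' Relative expression fold-changes by 2^-ddCt
#'
#' Technical replicates are first averaged on the Ct scale. Per biological
#' sample, dCt = Ct(gene) - Ct(reference); the baseline is the control
#' condition's mean dCt (equivalently, the log2 of the geometric mean of
#' the control samples' linear 2^-dCt ratios, so the control condition's
#' geometric-mean fold-change is exactly 1); ddCt = dCt - baseline and
#' fold = 2^-ddCt. Two-tailed t-tests between conditions are computed on
#' the ddCt (log2 fold) scale.
#'
#' @param ct Data frame with columns `gene`, `sample_id`, `condition`,
#'   `replicate`, `technical_rep`, `ct` (cycles, positive).
#' @param ref_gene Reference gene present in every sample (e.g. a
#'   housekeeping transcript); samples missing it are dropped with a
#'   warning.
#' @param control_condition Condition defining the baseline.
#' @param var_equal Pooled-variance Student t-test (default `TRUE`).
#' @return List with `per_sample` (per sample and gene: dCt, ddCt, fold),
#'   `summary` (per gene and condition: mean fold, SE, n) and `tests`
#'   (per gene, pairwise two-tailed t-tests on ddCt).
#' @export
ddct_fold_change <- function(ct, ref_gene, control_condition,
                             var_equal = TRUE) {
  stopifnot(all(c("gene", "sample_id", "condition", "ct") %in% names(ct)),
            all(ct$ct > 0))
  if (!ref_gene %in% ct$gene) stop("reference gene absent from table")
  # average technical replicates on the Ct scale
  key <- interaction(ct$gene, ct$sample_id, drop = TRUE)
  avg <- do.call(rbind, lapply(split(ct, key), function(d) data.frame(
    gene = d$gene[1], sample_id = d$sample_id[1], condition = d$condition[1],
    ct = mean(d$ct), stringsAsFactors = FALSE)))
  refs <- avg[avg$gene == ref_gene, c("sample_id", "ct")]
  names(refs)[2] <- "ct_ref"
  dat <- merge(avg[avg$gene != ref_gene, ], refs, by = "sample_id",
               all.x = TRUE)
  if (anyNA(dat$ct_ref)) {
    warning("samples without reference gene dropped")
    dat <- dat[!is.na(dat$ct_ref), ]
  }
  dat$dct <- dat$ct - dat$ct_ref
  if (!control_condition %in% dat$condition)
    stop("control condition absent")
  per_sample <- do.call(rbind, lapply(split(dat, dat$gene), function(g) {
    baseline <- mean(g$dct[g$condition == control_condition])
    g$ddct <- g$dct - baseline
    g$fold <- 2^(-g$ddct)
    g
  }))
  rownames(per_sample) <- NULL
  summary <- do.call(rbind, lapply(
    split(per_sample, interaction(per_sample$gene, per_sample$condition,
                                  drop = TRUE)),
    function(d) data.frame(
      gene = d$gene[1], condition = d$condition[1],
      mean_fold = mean(d$fold), se_fold = stats::sd(d$fold) / sqrt(nrow(d)),
      geo_mean_fold = 2^mean(-d$ddct), n = nrow(d),
      stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  conds <- unique(per_sample$condition)
  pairs <- if (length(conds) > 1) utils::combn(conds, 2, simplify = FALSE)
           else list()
  tests <- do.call(rbind, lapply(split(per_sample, per_sample$gene),
                                 function(g)
    do.call(rbind, lapply(pairs, function(pp) {
      x <- g$ddct[g$condition == pp[1]]
      y <- g$ddct[g$condition == pp[2]]
      if (length(x) < 2 || length(y) < 2) return(NULL)
      p <- tryCatch(stats::t.test(x, y, var.equal = var_equal)$p.value,
                    error = function(e) NA_real_)  # constant groups
      data.frame(gene = g$gene[1], condition_a = pp[1], condition_b = pp[2],
                 log2_ratio = mean(y) - mean(x), p = p,
                 stringsAsFactors = FALSE)
    }))))
  if (!is.null(tests)) rownames(tests) <- NULL
  list(per_sample = per_sample, summary = summary, tests = tests)
}

#' Primer amplification efficiency from a dilution series
#'
#' Least-squares fit of Ct against log10(template amount); the efficiency
#' is `10^(-1/slope) - 1`, so a slope of -3.3219 (perfect doubling per
#' cycle) gives an efficiency of 1.
#'
#' @param log10_amount Numeric vector of log10 template amounts (>= 3
#'   distinct points).
#' @param ct Observed Ct values.
#' @return List with `slope`, `intercept`, `efficiency`, `r_squared`.
#' @export
primer_efficiency <- function(log10_amount, ct) {
  stopifnot(length(log10_amount) == length(ct))
  if (length(unique(log10_amount)) < 3)
    stop("at least 3 distinct dilution points required")
  fit <- stats::lm(ct ~ log10_amount)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0) stop("singular dilution fit")
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       efficiency = 10^(-1 / slope) - 1,
       r_squared = r2)
}
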