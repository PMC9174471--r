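test_that("iBAQ equalises peptide-count bias and relative values sum to 1", {
  intensity <- matrix(c(100, 300), 2, 1,
                      dimnames = list(c("p1", "p2"), "s1"))
  res <- compute_ibaq(intensity, c(p1 = 1L, p2 = 3L))
  expect_equal(unname(res$ibaq[, 1]), c(100, 100))
  expect_equal(unname(res$relative_ibaq[, 1]), c(0.5, 0.5))
  # single protein
  one <- compute_ibaq(matrix(50, 1, 1, dimnames = list("p", "s")),
                      c(p = 5L))
  expect_equal(unname(one$relative_ibaq[1, 1]), 1)
  # random table: column sums 1 within 1e-12
  set.seed(3)
  m <- matrix(runif(60, 1, 100), 10, 6,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:6)))
  counts <- setNames(sample(1:20, 10, replace = TRUE), rownames(m))
  rel <- compute_ibaq(m, counts)$relative_ibaq
  expect_equal(unname(colSums(rel)), rep(1, 6), tolerance = 1e-12)
  # zero-count protein excluded with warning
  counts2 <- counts; counts2["p1"] <- 0L
  expect_warning(res2 <- compute_ibaq(m, counts2), "excluded")
  expect_false("p1" %in% rownames(res2$ibaq))
})

test_that("equalise-medians shifts each sample to the grand median and is idempotent", {
  x <- matrix(2^c(19, 20, 21, 21, 22, 23), 3, 2,
              dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  norm <- equalise_medians(x)
  med <- apply(norm, 2, median)
  expect_equal(unname(med), rep(21, 2))     # grand median of (20, 22)
  # shifts are -1 and +1
  expect_equal(unname(norm[, 2] - log2(x[, 2])), rep(-1, 3))
  # already equal -> identity; idempotence
  norm2 <- equalise_medians(norm, log = FALSE)
  expect_equal(norm2, norm)
})

test_that("differential abundance reproduces hand-checked BH and sign conventions", {
  # hand BH: (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(21)
  m <- matrix(rnorm(10 * 12, 20, 0.3), 10, 12,
              dimnames = list(paste0("p", 1:10),
                              paste0("s", 1:12)))
  cond <- rep(c("undiff", "RA"), each = 6)
  m[1, cond == "RA"] <- m[1, cond == "RA"] + 2
  res_ab <- differential_abundance(m, cond, "RA", "undiff")
  res_ba <- differential_abundance(m, cond, "undiff", "RA")
  expect_equal(res_ab$log2fc, -res_ba$log2fc, tolerance = 1e-12)
  expect_equal(res_ab$call[res_ab$protein == "p1"], "up")
  # identical groups -> fc 0, unchanged
  vals <- c(20, 21, 20.5, 21.5, 20.2, 21.2)
  m2 <- matrix(c(vals, vals), 1, 12, dimnames = list("pX", paste0("s", 1:12)))
  cond2 <- rep(c("A", "B"), each = 6)
  r2 <- differential_abundance(m2, cond2, "A", "B")
  expect_equal(r2$log2fc, 0)
  expect_equal(r2$call, "unchanged")
  # agreement with stats::t.test on a random protein
  tt <- t.test(m[2, cond == "RA"], m[2, cond == "undiff"], var.equal = TRUE)
  expect_equal(res_ab$p[res_ab$protein == "p2"], tt$p.value, tolerance = 1e-12)
})

test_that("printed fold-changes and log2 fold-changes are mutually consistent", {
  tab <- read.delim(system.file("extdata", "table1_selected.tsv",
                                package = "fxlms"))
  expect_equal(round(log2(tab$fc_ra), 2), tab$log2fc_ra, tolerance = 0.01)
  expect_equal(round(log2(tab$fc_rapma), 2), tab$log2fc_rapma,
               tolerance = 0.01)
  expect_equal(round(2^tab$log2fc_ra, 1), round(tab$fc_ra, 1),
               tolerance = 0.2)
})

test_that("presence/absence requires the min-obs floor and zero on the other side", {
  m <- matrix(NA_real_, 3, 12,
              dimnames = list(c("pa", "pb", "pc"), paste0("s", 1:12)))
  cond <- rep(c("RA", "undiff"), each = 6)
  m["pa", cond == "RA"] <- 20          # 6/6 vs 0/6 -> RA-specific
  m["pb", cond == "RA"][1] <- 20       # 1/6 vs 0/6 -> neither at min_obs 2
  m["pc", ] <- 20                      # complete -> neither
  pa <- presence_absence(m, cond, "RA", "undiff", min_obs = 2)
  expect_equal(pa$specific_a, "pa")
  expect_length(pa$specific_b, 0L)
  res <- differential_abundance(m, cond, "RA", "undiff")
  expect_equal(res$call[res$protein == "pa"], "condition_specific")
})

test_that("localisation abundance partitions unity and tests with Bonferroni", {
  set.seed(9)
  n <- 60
  prot <- paste0("p", seq_len(n))
  cond <- rep(c("undiff", "RA"), each = 4)
  rel <- matrix(runif(n * 8), n, 8, dimnames = list(prot, paste0("s", 1:8)))
  rel <- sweep(rel, 2, colSums(rel), "/")
  loc <- setNames(rep(c("cytosol", "nucleus", "ER"), each = n / 3), prot)
  la <- localisation_abundance(rel, loc, cond)
  expect_equal(unname(colSums(la$sums)), rep(1, 8), tolerance = 1e-12)
  # family size = number of tests performed
  expect_equal(la$tests$adj_p, pmin(1, la$tests$p * nrow(la$tests)))
  # identical replicate values -> p = 1
  rel2 <- matrix(rep(c(0.6, 0.4), each = 1, times = 8), 2, 8,
                 dimnames = list(c("x1", "x2"), paste0("s", 1:8)))
  la2 <- localisation_abundance(rel2, c(x1 = "cytosol", x2 = "nucleus"),
                                cond)
  expect_true(all(la2$tests$adj_p == 1))
})

test_that("a planted compartment shift is detected after Bonferroni", {
  set.seed(33)
  cond <- rep(c("undiff", "RA"), each = 6)
  # 9 compartments as single pseudo-proteins; ER shifted by +0.05 in RA
  base <- c(0.30, 0.25, 0.10, 0.08, 0.10, 0.07, 0.04, 0.02, 0.04)
  comp <- c("cytosol", "nucleus", "ER", "dense cytosol", "mitochondrium",
            "plasma membrane", "lysosome", "peroxisome", "golgi")
  m <- vapply(seq_along(cond), function(j) {
    v <- base + rnorm(9, 0, 0.005)
    if (cond[j] == "RA") v[3] <- v[3] + 0.05
    v / sum(v)
  }, numeric(9))
  rownames(m) <- paste0("prot_", seq_len(9))
  la <- localisation_abundance(m, setNames(comp, rownames(m)), cond)
  er <- la$tests[la$tests$compartment == "ER", ]
  expect_lt(er$adj_p, 0.01)
})

test_that("Fisher over-representation matches the exact hypergeometric", {
  background <- paste0("g", 1:1000)
  set10 <- paste0("g", 1:10)
  sets <- list(hit = set10, miss = paste0("g", 501:520))
  res <- ora_fisher(set10, background, sets)
  # all-10-of-10 overlap: P(X >= 10) = 1 / C(1000,10) * C(10,10)*C(990,0)
  p_exact <- 1 / choose(1000, 10)
  expect_equal(res$p[res$set == "hit"], p_exact, tolerance = 1e-9)
  # disjoint set -> p = 1
  expect_equal(res$p[res$set == "miss"], 1)
  # list = set = background -> p = 1 (no enrichment signal)
  res2 <- ora_fisher(background, background, list(all = background))
  expect_equal(res2$p, 1)
  # cross-check one mid-size case against fisher.test
  lst <- paste0("g", 1:50)
  st <- paste0("g", c(1:8, 900:950))
  p_pkg <- ora_fisher(lst, background, list(s = st))$p
  k <- length(intersect(lst, st)); K <- length(st)
  ft <- fisher.test(matrix(c(k, K - k, 50 - k, 1000 - K - 50 + k), 2),
                    alternative = "greater")
  expect_equal(p_pkg, ft$p.value, tolerance = 1e-9)
  # BH never below raw p, monotone on sorted p
  expect_true(all(res$adj_p >= res$p))
})

test_that("protein-groups TSV reader splits intensity and iBAQ columns", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(accession = c("p1", "p2"),
                   check.names = FALSE)
  df[["Intensity s1"]] <- c(10, 0)
  df[["Intensity s2"]] <- c(5, 7)
  df[["iBAQ s1"]] <- c(1, 0)
  df[["iBAQ s2"]] <- c(0.5, 0.7)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_protein_groups(path)
  expect_equal(colnames(got$intensity), c("s1", "s2"))
  expect_true(is.na(got$intensity["p2", "s1"]))  # zero -> missing
  expect_equal(got$ibaq["p1", "s2"], 0.5)
})
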