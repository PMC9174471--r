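const <- mass_constants()

test_that("search database keeps top-ranked targets and reversed decoys", {
  seqs <- setNames(replicate(10, random_peptide(40)), paste0("P", 1:10))
  ab <- 10:1
  db <- build_search_database(seqs, ab, n_top = 8)
  expect_length(db, 16L)
  expect_equal(sum(attr(db, "is_decoy")), 8L)
  expect_true(all(startsWith(names(db)[9:16], "REV_")))
  # reversal rule
  db2 <- build_search_database(c(X = "MKRAG"), n_top = 1)
  expect_equal(unname(db2[["REV_X"]]), "GARKM")
  expect_error(build_search_database(seqs, n_top = 0), "n_top")
  expect_warning(build_search_database(seqs, n_top = 20), "using all")
})

test_that("candidate enumeration matches precursor mass within 6 ppm", {
  seqs <- setNames(replicate(6, random_peptide(60)), paste0("P", 1:6))
  index <- peptide_index(seqs, max_missed = 2, length_range = c(5, 20))
  ma <- index$mass[3]; mb <- index$mass[7]
  z <- 4L
  mk_spec <- function(neutral) make_spectrum(
    mz = c(300, 400), charge = z,
    precursor_mz = (neutral + z * const$proton) / z)

  # exact single-linker mass -> candidate present
  cand <- enumerate_candidates(mk_spec(ma + mb + 12), index)
  hitrow <- cand[cand$linker_count == 1 &
                 pmin(cand$idx_a, cand$idx_b) == min(3, 7) &
                 pmax(cand$idx_a, cand$idx_b) == max(3, 7), ]
  expect_gte(nrow(hitrow), 1L)

  # 7 ppm off the double-linker mass -> no candidate for that pair
  off <- (ma + mb + 24) * (1 + 7e-6)
  cand2 <- enumerate_candidates(mk_spec(off), index)
  expect_false(any(cand2$linker_count == 2 &
                   pmin(cand2$idx_a, cand2$idx_b) == min(3, 7) &
                   pmax(cand2$idx_a, cand2$idx_b) == max(3, 7)))

  # charge outside the window -> empty
  s <- mk_spec(ma + mb + 12); s$precursor_charge <- 3L
  expect_equal(nrow(enumerate_candidates(s, index)), 0L)
})

test_that("enumeration agrees with a brute-force pair scan", {
  set.seed(31)
  seqs <- setNames(replicate(5, random_peptide(50)), paste0("P", 1:5))
  index <- peptide_index(seqs, max_missed = 2, length_range = c(5, 20))
  z <- 5L
  i <- 4L; j <- 11L
  M <- index$mass[i] + index$mass[j] + 12
  s <- make_spectrum(c(300, 400), charge = z,
                     precursor_mz = (M * (1 + 3e-6) + z * const$proton) / z)
  cand <- enumerate_candidates(s, index)
  # oracle: all O(n^2) pairs within 6 ppm
  Mn <- z * s$precursor_mz - z * const$proton
  want <- list()
  for (a in seq_len(nrow(index))) for (b in a:nrow(index)) for (lc in 1:2) {
    theo <- index$mass[a] + index$mass[b] + 12 * lc
    if (abs(1e6 * (Mn - theo) / theo) <= 6)
      want[[length(want) + 1L]] <- c(a, b, lc)
  }
  want <- do.call(rbind, want)
  got <- as.matrix(cand[, c("idx_a", "idx_b", "linker_count")])
  expect_equal(nrow(got), nrow(want))
  expect_true(any(got[, 1] == i & got[, 2] == j & got[, 3] == 1))
})

test_that("fragment scoring counts matched theoretical ions", {
  pep_a <- list(sequence = "TVTAMDVVYALKR", protein_id = "A", start = 1L,
                is_decoy = FALSE)
  pep_b <- list(sequence = "IAGEASRLAHYNK", protein_id = "B", start = 1L,
                is_decoy = FALSE)
  # complete unshifted y-ladder of peptide A at exact m/z
  y <- fragment_ions(pep_a$sequence, series = "y", charges = 1)
  M <- peptide_mass(pep_a$sequence) + peptide_mass(pep_b$sequence) + 12
  z <- 4L
  s <- make_spectrum(y$mz, charge = z,
                     precursor_mz = (M + z * const$proton) / z)
  hit <- score_candidate(s, pep_a, pep_b, 1L)
  expect_gte(hit$matched_fragments_a, 12L)

  # pure far-off noise matches nothing
  s2 <- make_spectrum(y$mz * (1 + 50e-6), charge = z,
                      precursor_mz = (M + z * const$proton) / z)
  hit2 <- score_candidate(s2, pep_a, pep_b, 1L)
  expect_equal(hit2$matched_fragments_a + hit2$matched_fragments_b, 0L)

  # empty peak list gives zero counts
  s3 <- make_spectrum(numeric(0), charge = z,
                      precursor_mz = (M + z * const$proton) / z)
  hit3 <- score_candidate(s3, pep_a, pep_b, 1L)
  expect_equal(hit3$matched_fragments_a + hit3$matched_fragments_b, 0L)
})

test_that("confidence classification applies the ratio and fragment floors", {
  mk <- function(ma, mb, la = 13L, lb = 13L)
    list(matched_fragments_a = ma, matched_fragments_b = mb,
         ratio = (ma + mb) / (la + lb))
  expect_equal(classify_confidence(mk(20, 20)), "high")          # 40/26 > 1.5
  expect_equal(classify_confidence(mk(16, 16)), "intermediate")  # ratio too low
  expect_equal(classify_confidence(mk(10, 40)), "rejected")      # min <= 15
  # boundaries are strict
  expect_equal(classify_confidence(mk(18, 40)), "intermediate")
  expect_equal(classify_confidence(mk(15, 40)), "rejected")
  # exhaustive agreement with the rule over a grid
  for (ma in c(0, 10, 15, 16, 18, 19, 30)) for (mb in c(0, 15, 16, 19, 40)) {
    h <- mk(ma, mb)
    want <- if (min(ma, mb) > 18 && h$ratio > 1.5) "high"
            else if (min(ma, mb) > 15) "intermediate" else "rejected"
    expect_equal(classify_confidence(h), want)
  }
})

test_that("confidence is monotone and symmetric in the peptides", {
  mk <- function(ma, mb) list(matched_fragments_a = ma,
                              matched_fragments_b = mb,
                              ratio = (ma + mb) / 26)
  lv <- c(rejected = 0, intermediate = 1, high = 2)
  set.seed(13)
  for (i in 1:50) {
    ma <- sample(0:40, 1); mb <- sample(0:40, 1)
    base <- lv[classify_confidence(mk(ma, mb))]
    more <- lv[classify_confidence(mk(ma + sample(1:5, 1), mb))]
    expect_gte(more, base)
    expect_equal(classify_confidence(mk(ma, mb)),
                 classify_confidence(mk(mb, ma)))
  }
})

test_that("site assignment defaults to the middle residue and uses shift evidence", {
  mk_hit <- function(seq_a, ann_a = NULL) {
    list(peptide_a = list(sequence = seq_a, start = 1L),
         peptide_b = list(sequence = "PEPTIDEK", start = 1L),
         annotation_a = ann_a, annotation_b = NULL)
  }
  # 13-mer, no evidence -> site 7, interval [1,13]
  h <- assign_site(mk_hit(strrep("A", 12) %+% "K"))
  expect_equal(h$site_a, 7L)
  expect_equal(h$interval_a, c(1L, 13L))
  # 12-mer, no evidence -> site 6 (N-terminal tie)
  h2 <- assign_site(mk_hit(strrep("A", 11) %+% "K"))
  expect_equal(h2$site_a, 6L)
  # 13-mer with shifted y9 and unshifted y8 -> interval [5,5], site 5
  ann <- data.frame(series = c("y", "y"), index = c(9L, 8L),
                    charge = 1L, shifted = c(TRUE, FALSE))
  h3 <- assign_site(mk_hit(strrep("A", 12) %+% "K", ann))
  expect_equal(h3$interval_a, c(5L, 5L))
  expect_equal(h3$site_a, 5L)
})

test_that("decoy report counts decoy-containing fractions per condition", {
  hits <- data.frame(condition = rep("undiff", 205),
                     contains_decoy = c(TRUE, rep(FALSE, 204)))
  rep1 <- decoy_report(hits)
  expect_equal(rep1$n_decoy, 1L)
  expect_equal(rep1$decoy_fraction, 1 / 205, tolerance = 1e-12)
  hits2 <- data.frame(condition = rep("RA", 100),
                      contains_decoy = rep(FALSE, 100))
  expect_equal(decoy_report(hits2)$decoy_fraction, 0)
})
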