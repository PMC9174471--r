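test_that("consensus score reproduces the replicate-evidence table exhaustively", {
  # independent oracle: literal category-count lookup
  oracle <- function(ev) {
    h <- sum(ev == "high"); i <- sum(ev == "intermediate")
    if (h == 3) 1L else if (h == 2) 2L
    else if (h == 1 && i >= 1) 3L else if (i == 3) 4L
    else if (i == 2) 5L else if (h == 1) 6L else if (i == 1) 7L
    else NA_integer_
  }
  states <- c("high", "intermediate", "absent")
  grid <- expand.grid(r1 = states, r2 = states, r3 = states,
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    ev <- unlist(grid[r, ])
    expect_equal(consensus_score(ev), oracle(ev), info = paste(ev, collapse = ","))
  }
  # the quoted anchor cases
  expect_equal(consensus_score(c("high", "high", "high")), 1L)
  expect_equal(consensus_score(c("high", "intermediate", "absent")), 3L)
  expect_equal(consensus_score(c("intermediate", "absent", "absent")), 7L)
})

test_that("score is monotone under upgrading any replicate's evidence", {
  states <- c("absent", "intermediate", "high")
  grid <- expand.grid(r1 = states, r2 = states, r3 = states,
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    ev <- unlist(grid[r, ])
    s0 <- consensus_score(ev)
    if (is.na(s0)) next
    for (k in 1:3) {
      lvl <- match(ev[k], states)
      if (lvl < 3) {
        up <- ev; up[k] <- states[lvl + 1]
        expect_lte(consensus_score(up), s0)
      }
    }
  }
})

test_that("acceptance is score <= 4 with inclusive boundary", {
  expect_true(accept_link(4L))
  expect_false(accept_link(5L))
  expect_true(accept_link(1L))
  expect_false(accept_link(NA_integer_))
})

test_that("homo-multimer flag is closed-interval peptide overlap", {
  expect_true(flag_homomultimer(10, 22, 15, 27))
  expect_false(flag_homomultimer(10, 22, 23, 30))
  expect_true(flag_homomultimer(10, 22, 22, 30))  # shared residue 22
  expect_warning(got <- flag_homomultimer(10, 22, 15, 27, intra = FALSE))
  expect_false(got)
})

test_that("hits aggregate into consensus links with replicate evidence", {
  mk_hit <- function(rep_id, conf, pa = "P1", pb = "P2", sa = 50L, sb = 70L,
                     ia = c(45L, 55L), ib = c(65L, 75L)) {
    data.frame(spectrum_id = paste0("s", rep_id), condition = "undiff",
               replicate_id = rep_id, protein_a = pa, protein_b = pb,
               peptide_a = "AAAAKAAAK", peptide_b = "CCCCKCCCK",
               start_a = 46L, start_b = 66L, linker_count = 1L,
               matched_a = 20L, matched_b = 20L, ratio = 2,
               confidence = conf, site_a = 5L, site_b = 5L,
               protein_site_a = sa, protein_site_b = sb,
               interval_a_lo = ia[1], interval_a_hi = ia[2],
               interval_b_lo = ib[1], interval_b_hi = ib[2],
               contains_decoy = FALSE, stringsAsFactors = FALSE)
  }
  hits <- rbind(mk_hit("r1", "high"), mk_hit("r2", "high", sa = 52L),
                mk_hit("r3", "intermediate", sa = 48L))
  cons <- consensus_crosslinks(hits, replicates = c("r1", "r2", "r3"))
  expect_equal(nrow(cons), 1L)  # overlapping intervals merge to one link
  expect_equal(cons$n_high, 2L)
  expect_equal(cons$n_intermediate, 1L)
  expect_equal(cons$score, 2L)  # high in two replicates
})

test_that("consensus distinguishes evidence patterns and swapped peptides merge", {
  mk_hit <- function(rep_id, conf, pa, pb, sa, sb) {
    data.frame(spectrum_id = paste0(pa, pb, rep_id), condition = "undiff",
               replicate_id = rep_id, protein_a = pa, protein_b = pb,
               peptide_a = "AAAAKAAAK", peptide_b = "CCCCKCCCK",
               start_a = sa - 4L, start_b = sb - 4L, linker_count = 1L,
               matched_a = 20L, matched_b = 20L, ratio = 2,
               confidence = conf, site_a = 5L, site_b = 5L,
               protein_site_a = sa, protein_site_b = sb,
               interval_a_lo = sa - 2L, interval_a_hi = sa + 2L,
               interval_b_lo = sb - 2L, interval_b_hi = sb + 2L,
               contains_decoy = FALSE, stringsAsFactors = FALSE)
  }
  hits <- rbind(
    mk_hit("r1", "high", "P1", "P2", 50L, 70L),
    mk_hit("r2", "high", "P2", "P1", 70L, 50L),   # swapped orientation
    mk_hit("r1", "intermediate", "P3", "P3", 10L, 90L),
    mk_hit("r2", "intermediate", "P3", "P3", 10L, 90L),
    mk_hit("r3", "intermediate", "P3", "P3", 10L, 90L))
  cons <- consensus_crosslinks(hits, replicates = c("r1", "r2", "r3"))
  expect_equal(nrow(cons), 2L)
  p12 <- cons[cons$protein_a == "P1", ]
  expect_equal(p12$score, 2L)          # high in two replicates
  expect_true(p12$accepted)
  expect_equal(p12$link_type, "inter_protein")
  p33 <- cons[cons$protein_a == "P3", ]
  expect_equal(p33$score, 4L)          # intermediate in three
  expect_true(p33$accepted)
  expect_equal(p33$link_type, "intra_protein")
})

test_that("network aggregation collapses residue pairs and tallies link types", {
  links <- data.frame(
    condition = c("RA", "RA", "RA_PMA", "RA", "undiff"),
    protein_a = c("P1", "P1", "P1", "P2", "P3"),
    protein_b = c("P2", "P2", "P2", "P9", "P3"),
    site_a = c(10L, 30L, 10L, 5L, 8L), site_b = c(40L, 60L, 40L, 9L, 80L),
    n_high = 3L, n_intermediate = 0L, score = 1L, accepted = TRUE,
    link_type = c("inter_protein", "inter_protein", "inter_protein",
                  "inter_protein", "intra_protein"),
    homomultimer = FALSE, n_spectra = 1L, contains_decoy = FALSE,
    stringsAsFactors = FALSE)
  edges <- build_network(links)
  e12 <- edges[edges$source == "P1" & edges$target == "P2", ]
  expect_equal(nrow(e12), 1L)
  expect_equal(e12$n_links, 2L)               # two residue pairs
  expect_true(e12$in_RA && e12$in_RA_PMA)
  expect_false(e12$in_undiff)
  tallies <- attr(edges, "tallies")
  expect_equal(tallies$inter[tallies$condition == "RA"], 3L)
  expect_equal(tallies$intra[tallies$condition == "undiff"], 1L)
  # order invariance
  edges2 <- build_network(links[sample(nrow(links)), ])
  rownames(edges2) <- NULL
  expect_equal(edges2, edges, ignore_attr = TRUE)
})
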