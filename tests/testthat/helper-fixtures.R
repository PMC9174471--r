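# Shared in-code fixtures for the test suite.

`%+%` <- function(a, b) paste0(a, b)

# Independent brute-force digestion oracle: enumerate every substring that
# starts after a cleavage site (or at 1) and ends at a cleavage site (or
# the C-terminus), counting internal K/R.
brute_force_digest <- function(seqn, max_missed, length_range = c(1L, 1000L)) {
  chars <- strsplit(seqn, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cuts <- which(chars %in% c("K", "R"))
  starts <- c(1L, cuts + 1L)
  ends <- unique(c(cuts, n))
  starts <- starts[starts <= n]
  out <- list()
  for (s in starts) for (e in ends) {
    if (e < s) next
    internal <- sum(chars[s:e] %in% c("K", "R")) -
      as.integer(chars[e] %in% c("K", "R"))
    len <- e - s + 1L
    if (internal <= max_missed && len >= length_range[1] &&
        len <= length_range[2])
      out[[length(out) + 1L]] <- paste(chars[s:e], collapse = "")
  }
  sort(unlist(out))
}

# Independent residue-mass summation over the same IUPAC table, written
# from the table rather than via peptide_mass internals.
ref_mass <- function(seqn, cys_mod = 57.021464) {
  tab <- c(G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
           V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
           I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
           K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
           F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)
  chars <- strsplit(seqn, "", fixed = TRUE)[[1]]
  sum(tab[chars]) + 18.010565 + cys_mod * sum(chars == "C")
}

# A spectrum record holding given peaks at exact m/z.
make_spectrum <- function(mz, charge = 4L, precursor_mz = 500,
                          id = "s1", condition = "undiff",
                          replicate = "r1") {
  ord <- order(mz)
  list(spectrum_id = id, precursor_mz = precursor_mz,
       precursor_charge = charge,
       peaks = cbind(mz = mz[ord], intensity = rep(100, length(mz))),
       condition = condition, replicate_id = replicate)
}

# Random canonical peptide sequence.
random_peptide <- function(n) {
  paste(sample(c("G","A","S","P","V","T","C","L","I","N",
                 "D","Q","K","E","M","H","F","R","Y","W"),
               n, replace = TRUE), collapse = "")
}

# Minimal consensus-link row for structure assessment tests.
make_link <- function(protein_a, site_a, protein_b, site_b,
                      homomultimer = FALSE, condition = "undiff") {
  data.frame(condition = condition, protein_a = protein_a,
             protein_b = protein_b, site_a = site_a, site_b = site_b,
             score = 1L, accepted = TRUE,
             link_type = if (protein_a == protein_b) "intra_protein"
                         else "inter_protein",
             homomultimer = homomultimer, stringsAsFactors = FALSE)
}
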