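# small fixtures shared across test files

tiny_truth <- function() {
  synthetic_truth(
    complex_specs = list(
      complex_spec("CPLX-A", c("P1", "P2", "P3"), ic50_capture = 0.5),
      complex_spec("CPLX-B", c("Q1", "Q2"), ic50_capture = 5),
      complex_spec("CPLX-A-cand", "X1", ic50_capture = 0.5,
                   annotated = FALSE)),
    mark_table = data.frame(
      peptide_id = c("pepA", "pepA", "pepB"),
      modform = c("K1ac", "K2ac", "K9me1"),
      marks = c("mK1ac", "mK2ac", "mK9me1"),
      baseline = c(40, 5, 20),
      ic50 = c(1, NA, NA),
      hill = 1),
    planted_gi50 = 7)
}

# hand-built stoichiometry rows (one form, one dose, given replicate values)
stoich_rows <- function(modform, values, dose = 0, peptide_id = "pep",
                        marks = modform) {
  data.frame(peptide_id = peptide_id, modform = modform, marks = marks,
             dose = dose, replicate = seq_along(values),
             stoichiometry = values, no_unmod = FALSE)
}

# brute-force O(n^2) oracle for inter-chain contacts
contacts_oracle <- function(coords, chain, cutoff) {
  n <- nrow(coords)
  cnt <- 0L
  resi <- integer(0)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (chain[i] != chain[j] &&
        sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff) {
      cnt <- cnt + 1L
      resi <- c(resi, i, j)
    }
  }
  list(n_contacts = cnt, interface_residues = sort(unique(resi)))
}

# brute-force O(n^2) oracle for LIS/LIA on a symmetrized PAE
lis_lia_oracle <- function(pae, chain, cutoff) {
  n <- nrow(pae)
  scores <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (chain[i] != chain[j]) {
      m <- (pae[i, j] + pae[j, i]) / 2
      if (m < cutoff) scores <- c(scores, (cutoff - m) / cutoff)
    }
  }
  list(lis = if (length(scores)) mean(scores) else 0, lia = length(scores))
}
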