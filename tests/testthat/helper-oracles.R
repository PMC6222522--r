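# Independent brute-force oracles the unit tests check the implementation
# against. These deliberately avoid the package's own lookup/enumeration
# shortcuts.

# all multisets of size dp over `codes`, by enumerating ordered tuples and
# collapsing to sorted tuples
brute_multisets <- function(codes, dp) {
  tuples <- do.call(expand.grid,
                    c(rep(list(codes), dp), stringsAsFactors = FALSE))
  keys <- apply(tuples, 1, function(r) paste(sort(r), collapse = "|"))
  unique(keys)
}

# brute-force matcher: scan every database row under every allowed adduct
# interpretation of a feature, return the formula with the smallest
# unsigned ppm error within tolerance (NA if none)
brute_match <- function(mz, charge, adduct, db, ppm_tol = 20,
                        adducts = c("deprotonated", "formate")) {
  proton <- 1.00727646688
  formate <- 12 + 2 * 15.9949146196 + 1.00782503207 + 0.00054857990907
  best_ppm <- Inf
  best_formula <- NA_character_
  for (ad in adducts) {
    if (ad == "formate" && charge != 1) next
    if (adduct != "unknown" && adduct != ad) next
    neutral <- if (ad == "deprotonated") mz * charge + charge * proton
      else mz - formate
    for (i in seq_len(nrow(db))) {
      ppm <- abs(db$neutral_mass[i] - neutral) / db$neutral_mass[i] * 1e6
      if (ppm <= ppm_tol && ppm < best_ppm) {
        best_ppm <- ppm
        best_formula <- db$formula[i]
      }
    }
  }
  best_formula
}

# reference monoisotopic masses, written out longhand
atomic_mass_oracle <- c(C = 12, H = 1.00782503207, O = 15.9949146196)

mass_oracle <- function(nC, nH, nO) {
  nC * atomic_mass_oracle[["C"]] + nH * atomic_mass_oracle[["H"]] +
    nO * atomic_mass_oracle[["O"]]
}

# peak list printed for the tandem spectrum of the
# (epi)catechin-(epi)catechin-3-O-gallate dimer (precursor m/z 729.1488)
dimer_gallate_reference_peaks <- function() {
  tibble::tibble(
    mz = c(729.1488, 577.1350, 559.1221, 451.1044, 433.0946, 425.0854,
           407.0770, 289.0717, 287.0559),
    intensity = c(20, 100, 35, 40, 30, 25, 90, 60, 45)
  )
}
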