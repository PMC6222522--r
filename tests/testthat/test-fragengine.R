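test_that("neutral loss masses are the canonical flavan-3-ol values", {
  nl <- neutral_losses()
  expect_equal(round(nl$mass[nl$label == "phloroglucinol"], 4), 126.0317)
  expect_equal(round(nl$mass[nl$label == "rda_catechol"], 4), 152.0473)
  expect_equal(round(nl$mass[nl$label == "rda_pyrogallol"], 4), 168.0423)
  expect_equal(round(nl$mass[nl$label == "water"], 4), 18.0106)
  expect_equal(round(nl$mass[nl$label == "gallate"], 4), 152.0110)
})

test_that("quinone methide ions reproduce the diagnostic monomer m/z", {
  qm <- qm_fragments("Cat-GalCat")
  term_galcat <- qm[qm$role == "terminal" & qm$subunit == "GalCat", ]
  expect_equal(round(term_galcat$mz, 4), 305.0667)
  ext_cat <- qm[qm$role == "extension" & qm$subunit == "Cat", ]
  expect_equal(round(ext_cat$mz, 4), 287.0561)
  term_cat <- qm[qm$role == "terminal" & qm$subunit == "Cat", ]
  expect_equal(round(term_cat$mz, 4), 289.0718)

  qm2 <- qm_fragments("Cat-Cat:Gal")
  term_catgal <- qm2[qm2$role == "terminal" & qm2$subunit == "Cat:Gal", ]
  expect_equal(round(term_catgal$mz, 4), 441.0827)

  expect_error(qm_fragments("Cat"), "dp >= 2")
})

test_that("terminal/extension complements rebuild the precursor", {
  # for dimers and trimers: terminal(S) + extension(complement) formulas
  # plus H2 reconstitute the precursor formula element-wise
  for (nm in c("Cat-Cat:Gal", "Cat-GalCat", "Cat-Cat-GalCat",
               "Cat-GalCat-GalCat:Gal")) {
    cc <- as_composition(nm)
    prec <- parse_formula(composition_formula(cc))
    qm <- qm_fragments(cc)
    for (i in which(qm$role == "terminal")) {
      sub <- qm$comp[[i]]
      comp_counts <- cc - sub
      if (sum(comp_counts) == 0) next
      ext <- qm[qm$role == "extension", ]
      ext_match <- ext[vapply(ext$comp, function(x) all(x == comp_counts),
                              logical(1)), ]
      expect_gte(nrow(ext_match), 1)
      total <- formula_add(parse_formula(qm$formula[i]),
                           parse_formula(ext_match$formula[1]))
      expect_identical(render_formula(total), render_formula(prec))
    }
  }
})

test_that("sequential losses follow the published dimer arithmetic", {
  frags <- generate_fragments("Cat-Cat:Gal")
  mz4 <- round(frags$mz, 4)
  expect_equal(round(frags$mz[frags$structure == "precursor"], 4), 729.1461)
  # gallate loss to the catechin dimer ion (structure VI)
  expect_true(577.1351 %in% mz4)
  expect_equal(frags$structure[mz4 == 577.1351], "VI")
  # VI minus water
  expect_true(559.1246 %in% mz4)
  # HRF then gallate (structure I) and its dehydrate (II)
  expect_true(451.1035 %in% mz4)
  expect_equal(frags$structure[mz4 == 451.1035], "I")
  expect_true(433.0929 %in% mz4)
  expect_equal(frags$structure[mz4 == 433.0929], "II")
  # RDA chain down to structure V
  expect_true(407.0772 %in% mz4)
  expect_equal(frags$structure[mz4 == 407.0772], "V")
  # QM monomer ions
  expect_true(all(c(289.0718, 287.0561) %in% mz4))
})

test_that("the catechin trimer loses phloroglucinol to the printed ion", {
  frags <- generate_fragments("Cat-Cat-Cat")
  mz4 <- round(frags$mz, 4)
  expect_true(739.1668 %in% mz4) # [M-H] 865.1985 minus C6H6O3
  expect_equal(round(frags$mz[frags$structure == "precursor"], 4), 865.1985)
  # catechin dimer QM ions appear as both terminal and extension forms
  expect_true(all(c(577.1351, 575.1195) %in% mz4))
})

test_that("gallocatechin extension evidence is absent for Cat-Cat:Gal", {
  frags <- generate_fragments("Cat-Cat:Gal")
  ppm_to_305 <- abs(frags$mz - 305.0667) / 305.0667 * 1e6
  expect_true(all(ppm_to_305 > 20))
})

test_that("fragment sets conserve formulas and stay below the precursor", {
  for (nm in c("Cat-Cat", "Cat-Cat:Gal", "GalCat-GalCat:Gal",
               "Cat-GalCat-Cat:Gal")) {
    cc <- as_composition(nm)
    prec_counts <- parse_formula(composition_formula(cc))
    frags <- generate_fragments(cc)
    counts <- lapply(frags$formula, parse_formula)
    # all element counts non-negative and every fragment fits inside the
    # precursor formula
    for (ct in counts) {
      expect_true(all(ct >= 0))
      expect_true(all(prec_counts[names(ct)] - ct >= 0))
    }
    prec_mz <- frags$mz[frags$structure == "precursor"]
    others <- frags[frags$structure != "precursor" &
                      frags$charge == frags$charge[frags$structure == "precursor"], ]
    expect_true(all(others$mz < prec_mz))
    # deterministic descending order
    expect_true(!is.unsorted(rev(frags$mz)))
  }
})

test_that("loss validity is gated on composition", {
  prec <- generate_fragments("Cat-Cat")[1, ]
  expect_error(loss_fragments(prec, "Cat-Cat", losses = "gallate"),
               "gallate-free")
  # no gallate or pyrogallol-RDA products from a plain catechin dimer
  frags <- generate_fragments("Cat-Cat")
  expect_false(any(grepl("gallate", frags$pathway)))
  expect_false(any(grepl("C8H8O4", frags$pathway)))
  # pyrogallol RDA appears once gallocatechin is present
  frags2 <- generate_fragments("Cat-GalCat")
  expect_true(any(grepl("C8H8O4", frags2$pathway)))
})

test_that("doubly charged precursors keep singly charged fragments", {
  frags <- generate_fragments("Cat-Cat-Cat-Cat-Cat-Cat", z = 2)
  prec <- frags[frags$structure == "precursor", ]
  expect_equal(prec$charge, 2L)
  expect_equal(round(prec$mz, 4), 864.1907)
  expect_true(all(frags$charge[frags$structure != "precursor"] == 1L))
})

test_that("annotation matches every printed dimer fragment at 20 ppm", {
  ann <- annotate_spectrum(dimer_gallate_reference_peaks(), "Cat-Cat:Gal", tolerance_ppm = 20)
  a <- ann$annotated
  expect_equal(nrow(a), 9)
  expect_true(all(!is.na(a$fragment_formula)))
  expect_true(all(a$ppm_error <= 20))
  # the two QM monomer ions carry terminal/extension role evidence
  expect_equal(a$role[abs(a$observed_mz - 289.0717) < 1e-3], "terminal")
  expect_equal(a$role[abs(a$observed_mz - 287.0559) < 1e-3], "extension")
  # noise peak stays unannotated
  noisy <- dplyr::bind_rows(dimer_gallate_reference_peaks(),
                            tibble::tibble(mz = 500.0, intensity = 5))
  ann2 <- annotate_spectrum(noisy, "Cat-Cat:Gal")
  expect_true(is.na(ann2$annotated$fragment_formula[
    ann2$annotated$observed_mz == 500.0]))
})

test_that("the summary flags absent gallocatechin extension evidence", {
  ann <- annotate_spectrum(dimer_gallate_reference_peaks(), "Cat-Cat:Gal")
  s <- ann$summary
  galcat_ext <- s[s$subunit == "GalCat" & s$role == "extension", ]
  expect_false(galcat_ext$observed)
  cat_term <- s[s$subunit == "Cat" & s$role == "terminal", ]
  expect_true(cat_term$observed)
  cat_ext <- s[s$subunit == "Cat" & s$role == "extension", ]
  expect_true(cat_ext$observed)
  expect_error(annotate_spectrum(dimer_gallate_reference_peaks()[0, ], "Cat-Cat"), "empty")
})

test_that("annotation output file has the documented columns", {
  ann <- annotate_spectrum(dimer_gallate_reference_peaks(), "Cat-Cat:Gal")
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotation(ann, path)
  header <- readLines(path, n = 1)
  expect_equal(header, paste("observed_mz,intensity,fragment_formula",
                             "theoretical_mz,ppm_error,pathway",
                             "structure_label", sep = ","))
})
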