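make_feature <- function(mz, charge = 1, adduct = "unknown", rt = 5,
                         abundance = 5000, sample_id = "s1",
                         replicate = "r1") {
  tibble::tibble(sample_id = sample_id, replicate = replicate, rt = rt,
                 mz = mz, charge = charge, adduct = adduct,
                 abundance = abundance)
}

test_that("abundance filtering keeps the threshold and allowed charges", {
  f <- dplyr::bind_rows(
    make_feature(577.1, abundance = 749),
    make_feature(577.1, abundance = 750),
    make_feature(577.1, abundance = 751),
    make_feature(577.1, abundance = 9000, charge = 3)
  )
  kept <- filter_features(f, match_config())
  expect_equal(kept$abundance, c(750, 751))
  expect_equal(nrow(filter_features(f[0, ], match_config())), 0)
  # order is preserved
  f2 <- dplyr::bind_rows(make_feature(900, abundance = 800),
                         make_feature(600, abundance = 800))
  expect_equal(filter_features(f2, match_config())$mz, c(900, 600))
})

test_that("printed dimer and trimer ions match their formulas", {
  db <- pcd_database()
  m1 <- match_features(make_feature(577.1351), db)
  expect_equal(m1$matches$formula, "C30H26O12")
  expect_equal(m1$matches$polymer, "Cat-Cat")
  expect_equal(m1$matches$adduct_assigned, "deprotonated")

  m2 <- match_features(make_feature(865.1985), db)
  expect_equal(m2$matches$formula, "C45H38O18")

  # same mass pushed 25 ppm off no longer matches at 20 ppm
  m3 <- match_features(make_feature(577.1351 * (1 + 25e-6)), db)
  expect_equal(nrow(m3$matches), 0)
  expect_equal(nrow(m3$rejects), 1)
})

test_that("the 20 ppm tolerance boundary is inclusive", {
  db <- pcd_database()
  theo <- db$neutral_mass[db$formula == "C30H26O12"][1]
  at_edge <- mz_from_mass(theo * (1 + 20e-6), "deprotonated", 1)
  beyond <- mz_from_mass(theo * (1 + 20.1e-6), "deprotonated", 1)
  m_edge <- match_features(make_feature(at_edge), db)
  expect_equal(nrow(m_edge$matches), 1)
  expect_equal(round(m_edge$matches$ppm_error, 3), 20)
  m_beyond <- match_features(make_feature(beyond), db)
  expect_equal(nrow(m_beyond$matches), 0)
})

test_that("matching agrees with a brute-force scan over entries x adducts", {
  db <- pcd_database(2, 4) # small enough for the O(n^2) oracle
  set.seed(23)
  rows <- db[sample.int(nrow(db), 12), ]
  charges <- sample(1:2, 12, replace = TRUE)
  adducts <- sample(c("deprotonated", "formate", "unknown"), 12,
                    replace = TRUE)
  adducts[charges == 2] <- "deprotonated"
  jitter <- 1 + rnorm(12, 0, 8e-6)
  mz <- ifelse(adducts == "formate",
               mz_from_mass(rows$neutral_mass, "formate", 1),
               (rows$neutral_mass - charges * 1.00727646688) / charges) *
    jitter
  feats <- make_feature(mz, charge = charges, adduct = adducts)
  # a few hopeless features too
  feats <- dplyr::bind_rows(feats, make_feature(c(123.456, 2999.9)))
  got <- match_features(feats, db)
  all_feats <- dplyr::bind_cols(
    tibble::tibble(feature_id = seq_len(nrow(feats))), feats)
  for (i in seq_len(nrow(all_feats))) {
    expected <- brute_match(all_feats$mz[i], all_feats$charge[i],
                            all_feats$adduct[i], db)
    hit <- got$matches$formula[got$matches$feature_id == i]
    if (is.na(expected)) {
      expect_length(hit, 0)
    } else {
      expect_equal(hit, expected)
    }
  }
})

test_that("charge states reconstruct consistent neutral masses", {
  db <- pcd_database()
  M <- db$neutral_mass[db$name == "Cat-Cat-Cat-Cat"]
  f1 <- make_feature(mz_from_mass(M, "deprotonated", 1), charge = 1)
  f2 <- make_feature(mz_from_mass(M, "deprotonated", 2), charge = 2)
  m <- match_features(dplyr::bind_rows(f1, f2), db)
  expect_equal(nrow(m$matches), 2)
  expect_lt(abs(diff(m$matches$neutral_mass)), 1e-6)
  expect_equal(unique(m$matches$formula), "C60H50O24")
})

test_that("formate features reconstruct the same neutral mass", {
  db <- pcd_database()
  M <- db$neutral_mass[db$name == "Cat-Cat"]
  f <- make_feature(mz_from_mass(M, "formate", 1), adduct = "formate")
  m <- match_features(f, db)
  expect_equal(m$matches$formula, "C30H26O12")
  expect_equal(m$matches$adduct_assigned, "formate")
  expect_equal(m$matches$neutral_mass, M, tolerance = 1e-9)
})

test_that("rt clustering honours the configured tolerance", {
  db <- pcd_database()
  M <- db$neutral_mass[db$name == "Cat-Cat"]
  mz <- mz_from_mass(M, "deprotonated", 1)
  f <- dplyr::bind_rows(
    make_feature(mz, rt = 5.000),
    make_feature(mz, rt = 5.05)
  )
  m <- match_features(f, db)
  one <- group_matches(m, match_config(rt_group_tolerance = 0.10))
  expect_equal(one$groups$n_isomers, 1)
  expect_equal(one$groups$rt_list[[1]], 5.025)
  two <- group_matches(m, match_config(rt_group_tolerance = 0.01))
  expect_equal(two$groups$n_isomers, 2)
  expect_equal(two$groups$rt_list[[1]], c(5.000, 5.05))
  # single match: one group, one rt
  single <- group_matches(match_features(make_feature(mz, rt = 7.7), db),
                          match_config())
  expect_equal(single$groups$n_isomers, 1)
  expect_equal(single$groups$rt_list[[1]], 7.7)
})

test_that("per-sample areas sum within isomer peaks", {
  db <- pcd_database()
  M <- db$neutral_mass[db$name == "Cat-Cat"]
  mz <- mz_from_mass(M, "deprotonated", 1)
  f <- dplyr::bind_rows(
    make_feature(mz, rt = 5.00, sample_id = "a", abundance = 1000,
                 replicate = "r1"),
    make_feature(mz, rt = 5.01, sample_id = "a", abundance = 2000,
                 replicate = "r2"),
    make_feature(mz, rt = 5.00, sample_id = "b", abundance = 500)
  )
  g <- group_matches(match_features(f, db), match_config())
  expect_equal(nrow(g$peaks), 2) # one peak, two samples
  expect_equal(sort(g$peaks$area), c(500, 3000))
  expect_equal(g$groups$n_isomers, 1)
})

test_that("the report table is formatted and sorted like the publication", {
  db <- pcd_database()
  fx <- published_compounds()
  cfg <- match_config()
  m <- match_features(filter_features(fixture_features(fx), cfg), db, cfg)
  g <- group_matches(m, cfg)
  rep <- report_table(g)
  expect_equal(names(rep),
               c("rt_list", "mean_rt", "formula", "polymer",
                 "mean_experimental_mass", "mean_ppm_error", "charge_note"))
  cat_cat <- rep[rep$polymer == "Cat-Cat", ]
  expect_equal(cat_cat$mean_experimental_mass, "578.1401")
  expect_equal(cat_cat$mean_ppm_error, "4.0")
  expect_equal(cat_cat$rt_list, "4.68, 4.72, 5.31, 5.63")
  # the heptamer is flagged as a doubly charged species
  hept <- rep[rep$formula == "C105H86O42", ]
  expect_equal(hept$charge_note, "doubly charged")
  # sorted by formula mass
  masses <- formula_mass(rep$formula)
  expect_true(!is.unsorted(masses))
  # empty input: header-only table
  empty <- group_matches(match_features(make_feature(123.4), db),
                         match_config())
  expect_equal(nrow(report_table(empty)), 0)
  path <- withr::local_tempfile(fileext = ".csv")
  report_table(empty, path)
  expect_equal(length(readLines(path)), 1)
})

test_that("feature files round trip and invalid ones name the problem", {
  f <- dplyr::bind_rows(make_feature(577.1351), make_feature(593.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(f, path)
  back <- read_features(path)
  expect_equal(back$mz, f$mz)
  expect_true(all(back$adduct == "unknown"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,replicate,rt,mz\ns1,r1,5,577.1", bad)
  expect_error(read_features(bad), "charge")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,replicate,rt,mz,charge,adduct,abundance",
               "s1,r1,5,577.1,1,protonated,900"), bad2)
  expect_error(read_features(bad2), "row 1")
})
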