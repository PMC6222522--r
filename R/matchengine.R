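#' Matching configuration
#'
#' Settings of the feature-extraction/matching stage: ppm tolerance of the
#' database query (default +/-20 ppm, inclusive), minimum abundance
#' (default 750 counts; signal smaller than that is excluded, the boundary
#' itself is kept), allowed charge magnitudes and adduct kinds, and the
#' retention-time tolerance used to merge matches of one formula into
#' isomer peaks.
#'
#' @param ppm_tolerance Positive ppm tolerance for database matching.
#' @param min_abundance Minimum feature abundance retained (counts).
#' @param charges Allowed charge magnitudes (subset of 1:2).
#' @param adducts Allowed adduct kinds (subset of `"deprotonated"`,
#'   `"formate"`).
#' @param rt_group_tolerance Single-linkage RT tolerance in minutes for
#'   isomer-peak clustering. The default (0.02 min, about one second) is
#'   tight enough to keep the most closely retained isomer pairs reported
#'   for amide HILIC separations (0.04 min apart) as distinct peaks.
#' @return A `match_config` list.
#' @export
match_config <- function(ppm_tolerance = 20, min_abundance = 750,
                         charges = c(1, 2),
                         adducts = c("deprotonated", "formate"),
                         rt_group_tolerance = 0.02) {
  stopifnot(ppm_tolerance > 0, min_abundance >= 0, rt_group_tolerance >= 0)
  if (!all(charges %in% c(1, 2))) {
    stop("`charges` must be a subset of {1, 2}", call. = FALSE)
  }
  adducts <- match.arg(adducts, .adduct_kinds, several.ok = TRUE)
  structure(
    list(ppm_tolerance = ppm_tolerance, min_abundance = min_abundance,
         charges = sort(unique(charges)), adducts = adducts,
         rt_group_tolerance = rt_group_tolerance),
    class = "match_config"
  )
}

.feature_cols <- c("sample_id", "replicate", "rt", "mz", "charge",
                   "adduct", "abundance")

#' Read an LC-MS feature table
#'
#' Comma-delimited with the header
#' `sample_id,replicate,rt,mz,charge,adduct,abundance`; `rt` in minutes,
#' `charge` the magnitude (negative mode implied), `adduct` one of
#' `deprotonated`, `formate`, or empty/`unknown` when the feature finder
#' did not assign one. Parsing problems are reported with row numbers.
#'
#' @param path Path to a feature CSV.
#' @return A tibble of features with a `feature_id` column prepended.
#' @export
read_features <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.feature_cols, names(x))
  if (length(missing) > 0) {
    stop(sprintf("feature file lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x$adduct <- as.character(x$adduct)
  x$adduct[is.na(x$adduct) | x$adduct == ""] <- "unknown"
  bad <- which(!x$adduct %in% c(.adduct_kinds, "unknown"))
  if (length(bad) > 0) {
    stop(sprintf("row %d: unknown adduct `%s`", bad[1], x$adduct[bad[1]]),
         call. = FALSE)
  }
  for (col in c("rt", "mz", "abundance")) {
    bad <- which(is.na(x[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("row %d: missing or non-numeric `%s`", bad[1], col),
           call. = FALSE)
    }
  }
  bad <- which(x$mz <= 0 | x$rt < 0 | x$abundance < 0)
  if (length(bad) > 0) {
    stop(sprintf("row %d: mz must be > 0, rt and abundance >= 0", bad[1]),
         call. = FALSE)
  }
  if (!"feature_id" %in% names(x)) {
    x <- dplyr::bind_cols(tibble::tibble(feature_id = seq_len(nrow(x))), x)
  }
  x
}

#' Abundance and charge filtering of features
#'
#' Retains features with `abundance >= min_abundance` (the threshold value
#' itself is kept) and a charge magnitude in the allowed set. Row order is
#' preserved.
#'
#' @param features Feature tibble (see [read_features()]).
#' @param config A [match_config()].
#' @return The retained rows.
#' @export
filter_features <- function(features, config = match_config()) {
  keep <- features$abundance >= config$min_abundance &
    features$charge %in% config$charges
  tibble::as_tibble(features[keep, , drop = FALSE])
}

# distinct-formula view of a database, with canonical composition name and
# candidate count per formula
.db_formulas <- function(db) {
  canon <- db[order(-db$n_galcatgal, -db$n_cat, db$name, method = "radix"), ]
  canon <- canon[!duplicated(canon$formula), ]
  n_cand <- table(db$formula)
  tibble::tibble(
    formula = canon$formula,
    polymer = canon$name,
    dp = canon$dp,
    theoretical_mass = canon$neutral_mass,
    knm = canon$knm,
    kmd = canon$kmd,
    n_candidates = as.integer(n_cand[canon$formula])
  )
}

#' Match features against the theoretical database
#'
#' Each feature is interpreted under every allowed adduct consistent with
#' its charge (its own adduct only, if assigned); each interpretation
#' reconstructs a neutral mass, which is queried against the database
#' within the ppm tolerance (inclusive). The interpretation/entry pair with
#' the smallest unsigned ppm error wins; ties prefer deprotonation, then
#' lower degree of polymerization. At most one match is returned per
#' feature; unmatched features go to a rejects table, not an error.
#'
#' Matching is formula-level: the result carries the canonical composition
#' plus the count of compositions sharing the formula, since isomeric
#' compositions have identical exact mass.
#'
#' @param features Filtered feature tibble.
#' @param db A `pcd_db` tibble.
#' @param config A [match_config()].
#' @return A `pcd_matches` object: list with `matches`, `rejects` tibbles
#'   and the `config`. Use [tidy()] / [glance()] to extract.
#' @export
match_features <- function(features, db, config = match_config()) {
  if (!"feature_id" %in% names(features)) {
    features <- dplyr::bind_cols(
      tibble::tibble(feature_id = seq_len(nrow(features))), features)
  }
  dbf <- .db_formulas(db)
  ord <- order(dbf$theoretical_mass)
  dbf <- dbf[ord, ]
  masses <- dbf$theoretical_mass

  # one row per (feature, adduct interpretation)
  interp <- purrr::map_dfr(config$adducts, function(ad) {
    ok <- if (ad == "formate") features$charge == 1 else rep(TRUE, nrow(features))
    ok <- ok & (features$adduct == "unknown" | features$adduct == ad)
    f <- features[ok, , drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    f$adduct_assigned <- ad
    f$neutral_mass <- if (ad == "deprotonated") {
      f$mz * f$charge + f$charge * .proton_mass
    } else {
      f$mz - .formate_shift
    }
    f
  })

  if (is.null(interp) || nrow(interp) == 0) {
    matches <- tibble::tibble()
    rejects <- features
  } else {
    # nearest database mass via binary search on the sorted mass vector
    idx <- findInterval(interp$neutral_mass, masses)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(masses))
    pick <- ifelse(
      abs(interp$neutral_mass - masses[lo]) <=
        abs(masses[hi] - interp$neutral_mass), lo, hi)
    hit <- dbf[pick, ]
    interp$formula <- hit$formula
    interp$polymer <- hit$polymer
    interp$dp <- hit$dp
    interp$theoretical_mass <- hit$theoretical_mass
    interp$knm <- hit$knm
    interp$n_candidates <- hit$n_candidates
    interp$ppm_signed <- ppm_error(interp$theoretical_mass,
                                   interp$neutral_mass, signed = TRUE)
    interp$ppm_error <- abs(interp$ppm_signed)

    within <- interp[interp$ppm_error <= config$ppm_tolerance, , drop = FALSE]
    best <- within |>
      dplyr::arrange(.data$feature_id, .data$ppm_error,
                     .data$adduct_assigned != "deprotonated", .data$dp) |>
      dplyr::distinct(.data$feature_id, .keep_all = TRUE)
    matches <- tibble::as_tibble(best[order(best$feature_id), ])

    rej_ids <- setdiff(features$feature_id, matches$feature_id)
    rejects <- features[features$feature_id %in% rej_ids, , drop = FALSE]
    if (nrow(rejects) > 0 && nrow(interp) > 0) {
      best_ppm <- interp |>
        dplyr::group_by(.data$feature_id) |>
        dplyr::summarise(best_ppm = min(.data$ppm_error), .groups = "drop")
      rejects <- dplyr::left_join(rejects, best_ppm, by = "feature_id")
    }
    rejects <- tibble::as_tibble(rejects)
  }

  structure(list(matches = matches, rejects = rejects, config = config),
            class = "pcd_matches")
}

#' @export
tidy.pcd_matches <- function(x, ...) x$matches

#' @export
glance.pcd_matches <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$matches) + nrow(x$rejects),
    n_matched = nrow(x$matches),
    n_rejected = nrow(x$rejects),
    n_formulas = dplyr::n_distinct(x$matches$formula),
    median_ppm_error = stats::median(x$matches$ppm_error),
    mean_ppm_error = mean(x$matches$ppm_error)
  )
}

#' @export
print.pcd_matches <- function(x, ...) {
  cat(sprintf("<pcd_matches> %d matched, %d rejected (tolerance %.3g ppm)\n",
              nrow(x$matches), nrow(x$rejects), x$config$ppm_tolerance))
  print(x$matches, ...)
  invisible(x)
}

#' Group matches into isomer peaks and formula-level compound groups
#'
#' Matches sharing a formula are clustered on retention time with single
#' linkage: sorted RTs are chained while consecutive gaps are within
#' `rt_group_tolerance`, so replicate detections of one chromatographic
#' peak merge while resolved isomers stay apart. Each cluster is one isomer
#' peak (at the mean RT of its members); each formula yields one compound
#' group carrying the sorted peak RT list, the mean experimental neutral
#' mass and mean unsigned ppm error over member features, and per-sample
#' summed abundances.
#'
#' @param matches A `pcd_matches` object or its `matches` tibble.
#' @param config A [match_config()]; only `rt_group_tolerance` is used.
#' @return A `pcd_groups` object: list with `groups` (one row per formula)
#'   and `peaks` (one row per sample x isomer peak, with summed `area`).
#' @export
group_matches <- function(matches, config = match_config()) {
  m <- if (inherits(matches, "pcd_matches")) matches$matches else matches
  if (nrow(m) == 0) {
    groups <- tibble::tibble(
      formula = character(), polymer = character(), dp = integer(),
      theoretical_mass = numeric(), knm = integer(),
      rt_list = list(), mean_rt = numeric(), n_isomers = integer(),
      mean_experimental_mass = numeric(), mean_ppm_error = numeric(),
      doubly_charged = logical(), n_candidates = integer())
    peaks <- tibble::tibble(
      formula = character(), polymer = character(), knm = integer(),
      peak = integer(), rt = numeric(), sample_id = character(),
      area = numeric())
    return(structure(list(groups = groups, peaks = peaks),
                     class = "pcd_groups"))
  }
  tol <- config$rt_group_tolerance

  m <- m[order(m$formula, m$rt, method = "radix"), ]
  m <- m |>
    dplyr::group_by(.data$formula) |>
    dplyr::mutate(peak = cumsum(c(TRUE, diff(.data$rt) > tol))) |>
    dplyr::ungroup()

  peak_rt <- m |>
    dplyr::group_by(.data$formula, .data$peak) |>
    dplyr::summarise(rt = mean(.data$rt), .groups = "drop")

  peaks <- m |>
    dplyr::group_by(.data$formula, .data$polymer, .data$knm, .data$peak,
                    .data$sample_id) |>
    dplyr::summarise(area = sum(.data$abundance), .groups = "drop") |>
    dplyr::left_join(peak_rt, by = c("formula", "peak")) |>
    dplyr::select("formula", "polymer", "knm", "peak", "rt", "sample_id",
                  "area")

  groups <- m |>
    dplyr::group_by(.data$formula, .data$polymer, .data$dp,
                    .data$theoretical_mass, .data$knm, .data$n_candidates) |>
    dplyr::summarise(
      mean_experimental_mass = mean(.data$neutral_mass),
      mean_ppm_error = mean(.data$ppm_error),
      doubly_charged = any(.data$charge == 2),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      peak_rt |>
        dplyr::group_by(.data$formula) |>
        dplyr::summarise(rt_list = list(sort(.data$rt)),
                         mean_rt = mean(.data$rt),
                         n_isomers = dplyr::n(), .groups = "drop"),
      by = "formula"
    ) |>
    dplyr::arrange(.data$theoretical_mass, .data$mean_rt) |>
    dplyr::select("formula", "polymer", "dp", "theoretical_mass", "knm",
                  "rt_list", "mean_rt", "n_isomers",
                  "mean_experimental_mass", "mean_ppm_error",
                  "doubly_charged", "n_candidates")

  structure(list(groups = groups, peaks = peaks), class = "pcd_groups")
}

#' @export
tidy.pcd_groups <- function(x, ...) x$groups

#' @export
glance.pcd_groups <- function(x, ...) {
  tibble::tibble(
    n_formulas = nrow(x$groups),
    n_isomer_peaks = sum(x$groups$n_isomers),
    mean_ppm_error = mean(x$groups$mean_ppm_error)
  )
}

#' @export
print.pcd_groups <- function(x, ...) {
  cat(sprintf("<pcd_groups> %d formulas, %d isomer peaks\n",
              nrow(x$groups), sum(x$groups$n_isomers)))
  print(x$groups, ...)
  invisible(x)
}

#' Format compound groups as a report table
#'
#' One row per formula with columns `rt_list` (2-decimal RTs joined by
#' `", "`), `mean_rt` (2 dp), `formula`, `polymer`, `mean_experimental_mass`
#' (4 dp), `mean_ppm_error` (1 dp) and `charge_note` (marks species
#' observed doubly charged). Rows are sorted by theoretical formula mass,
#' then mean RT.
#'
#' @param groups A `pcd_groups` object.
#' @param path Optional CSV destination; when given the formatted table is
#'   also written there.
#' @return The formatted tibble, invisibly when `path` is given.
#' @export
report_table <- function(groups, path = NULL) {
  g <- groups$groups
  out <- tibble::tibble(
    rt_list = vapply(g$rt_list,
                     function(r) paste(sprintf("%.2f", r), collapse = ", "),
                     character(1)),
    mean_rt = sprintf("%.2f", g$mean_rt),
    formula = g$formula,
    polymer = g$polymer,
    mean_experimental_mass = sprintf("%.4f", g$mean_experimental_mass),
    mean_ppm_error = sprintf("%.1f", g$mean_ppm_error),
    charge_note = ifelse(g$doubly_charged, "doubly charged", "")
  )
  if (!is.null(path)) {
    readr::write_csv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
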