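#' The four grape-derived flavan-3-ol subunits
#'
#' Registry of the monomer units used to build the theoretical compound
#' database: (epi)catechin (`Cat`), (epi)gallocatechin (`GalCat`) and their
#' 3-O-gallate esters (`Cat:Gal`, `GalCat:Gal`). Gallocatechin-type units
#' carry a trihydroxylated (pyrogallol) B-ring, catechin-type units a
#' catechol B-ring; gallate esters add C7H4O4.
#'
#' @return A tibble with columns `code`, `formula`, `monoisotopic_mass`,
#'   `has_gallate`, `b_ring_hydroxyls`.
#' @examples
#' monomer_units()
#' @export
monomer_units <- function() {
  tibble::tibble(
    code = c("Cat", "GalCat", "Cat:Gal", "GalCat:Gal"),
    formula = c("C15H14O6", "C15H14O7", "C22H18O10", "C22H18O11"),
    monoisotopic_mass = formula_mass(c("C15H14O6", "C15H14O7",
                                       "C22H18O10", "C22H18O11")),
    has_gallate = c(FALSE, FALSE, TRUE, TRUE),
    b_ring_hydroxyls = c(2L, 3L, 2L, 3L)
  )
}

.unit_codes <- c("Cat", "GalCat", "Cat:Gal", "GalCat:Gal")
.count_cols <- c("n_cat", "n_galcat", "n_catgal", "n_galcatgal")

# formula element counts for a composition given per-unit counts; B-type
# condensation removes one H2 per interflavan bond (dp - 1 bonds)
.composition_elements <- function(n_cat, n_galcat, n_catgal, n_galcatgal) {
  dp <- n_cat + n_galcat + n_catgal + n_galcatgal
  g <- n_catgal + n_galcatgal
  list(
    C = 15L * dp + 7L * g,
    H = 14L * dp + 4L * g - 2L * (dp - 1L),
    O = 6L * n_cat + 7L * n_galcat + 10L * n_catgal + 11L * n_galcatgal
  )
}

#' Derived chemical formula of a subunit composition
#'
#' The formula is the sum of the monomer formulas minus one H2 per
#' interflavan bond (B-type, single linkage): a composition of `dp` units
#' loses `dp - 1` H2.
#'
#' @param composition A composition name such as `"Cat-Cat:Gal"`, or a named
#'   vector/list with counts `n_cat`, `n_galcat`, `n_catgal`, `n_galcatgal`.
#' @return A formula string in Hill order.
#' @examples
#' composition_formula("Cat-Cat")          # "C30H26O12"
#' composition_formula(c(n_cat = 1, n_catgal = 1))
#' @export
composition_formula <- function(composition) {
  cc <- as_composition(composition)
  el <- .composition_elements(cc["n_cat"], cc["n_galcat"],
                              cc["n_catgal"], cc["n_galcatgal"])
  render_formula(c(C = unname(el$C), H = unname(el$H), O = unname(el$O)))
}

#' Canonical display name of a composition
#'
#' Unit codes joined by `-` in the fixed order Cat, GalCat, Cat:Gal,
#' GalCat:Gal, one token per unit (e.g. `{2 Cat, 1 GalCat}` is
#' `"Cat-Cat-GalCat"`).
#'
#' @inheritParams composition_formula
#' @return A single name string.
#' @examples
#' composition_name(c(n_cat = 2, n_galcat = 1))
#' @export
composition_name <- function(composition) {
  cc <- as_composition(composition)
  paste(rep(.unit_codes, times = cc), collapse = "-")
}

#' Convert a name or count vector to a canonical composition count vector
#'
#' @inheritParams composition_formula
#' @return Named integer vector `n_cat`, `n_galcat`, `n_catgal`,
#'   `n_galcatgal`.
#' @examples
#' as_composition("Cat-Cat-GalCat:Gal")
#' @export
as_composition <- function(composition) {
  if (is.character(composition) && length(composition) == 1) {
    tokens <- strsplit(composition, "-", fixed = TRUE)[[1]]
    bad <- setdiff(tokens, .unit_codes)
    if (length(bad) > 0) {
      stop(sprintf("unknown subunit code `%s` in composition `%s`",
                   bad[1], composition), call. = FALSE)
    }
    out <- stats::setNames(
      as.integer(table(factor(tokens, levels = .unit_codes))), .count_cols)
  } else {
    if (is.data.frame(composition)) composition <- as.list(composition[1, ])
    composition <- unlist(composition)
    bad <- setdiff(names(composition), .count_cols)
    if (length(bad) > 0) {
      stop(sprintf("unknown composition count `%s`", bad[1]), call. = FALSE)
    }
    out <- stats::setNames(integer(4), .count_cols)
    out[names(composition)] <- as.integer(composition)
  }
  if (any(out < 0)) stop("subunit counts must be non-negative", call. = FALSE)
  if (sum(out) < 1) stop("composition must contain at least one unit",
                         call. = FALSE)
  out
}

#' Number of distinct linear sequences of a polymer
#'
#' For a fixed linkage type, a chain of `dp` positions each filled from
#' `n_subunit_types` monomers admits `n_subunit_types ^ dp` distinct
#' sequences (e.g. 2 types at DP 3 give 8, at DP 4 give 16). The database
#' itself collapses these to compositions, which is why chromatographic
#' isomer peaks per formula can exceed the database entry count.
#'
#' @param n_subunit_types Number of distinct monomer types (>= 1).
#' @param dp Degree of polymerization (>= 1).
#' @return Numeric count of sequences.
#' @examples
#' sequence_isomer_count(2, 4) # 16
#' @export
sequence_isomer_count <- function(n_subunit_types, dp) {
  stopifnot(n_subunit_types >= 1, dp >= 1)
  n_subunit_types^dp
}

#' Build the theoretical proanthocyanidin compound database
#'
#' Enumerates every multiset of subunits with degree of polymerization in
#' `[dp_min, dp_max]` (one entry per composition; sequence permutations and
#' epimers share a formula and are intentionally collapsed) and derives each
#' entry's formula, neutral monoisotopic mass, and Kendrick coordinates.
#' With the default four subunits and DP 2-10 this yields 996 entries.
#'
#' @param dp_min,dp_max Degree-of-polymerization range (1 <= dp_min <=
#'   dp_max). Monomers are excluded from the default range.
#' @param subunits Character vector of subunit codes drawn from
#'   `monomer_units()$code`.
#' @return A `pcd_db` tibble with columns `name`, `dp`, `n_cat`, `n_galcat`,
#'   `n_catgal`, `n_galcatgal`, `formula`, `neutral_mass`, `knm`, `kmd`,
#'   ordered by dp then name.
#' @examples
#' db <- pcd_database()
#' nrow(db) # 996
#' @seealso [formula_candidates()], [write_pcd_db()]
#' @export
pcd_database <- function(dp_min = 2, dp_max = 10,
                         subunits = monomer_units()$code) {
  if (length(subunits) < 1) {
    stop("`subunits` must name at least one monomer", call. = FALSE)
  }
  bad <- setdiff(subunits, .unit_codes)
  if (length(bad) > 0) {
    stop(sprintf("unknown subunit code `%s`", bad[1]), call. = FALSE)
  }
  if (!(dp_min >= 1 && dp_min <= dp_max)) {
    stop("need 1 <= dp_min <= dp_max", call. = FALSE)
  }
  active <- .unit_codes %in% subunits

  per_dp <- lapply(seq(dp_min, dp_max), function(dp) {
    ranges <- lapply(active, function(a) if (a) 0:dp else 0L)
    grid <- do.call(expand.grid, stats::setNames(ranges, .count_cols))
    grid[rowSums(grid) == dp, , drop = FALSE]
  })
  counts <- dplyr::bind_rows(per_dp)

  el <- .composition_elements(counts$n_cat, counts$n_galcat,
                              counts$n_catgal, counts$n_galcatgal)
  mass <- el$C * .atomic_masses[["C"]] + el$H * .atomic_masses[["H"]] +
    el$O * .atomic_masses[["O"]]
  kp <- kendrick_transform(mass)

  db <- tibble::as_tibble(counts)
  db$dp <- db$n_cat + db$n_galcat + db$n_catgal + db$n_galcatgal
  db$name <- purrr::pmap_chr(db[.count_cols], function(...) {
    paste(rep(.unit_codes, times = c(...)), collapse = "-")
  })
  db$formula <- sprintf("C%dH%dO%d", el$C, el$H, el$O)
  db$neutral_mass <- mass
  db$knm <- kp$knm
  db$kmd <- kp$kmd
  db <- db[order(db$dp, db$name, method = "radix"),
           c("name", "dp", .count_cols, "formula", "neutral_mass",
             "knm", "kmd")]
  db <- tibble::as_tibble(db)
  attr(db, "dp_range") <- c(dp_min, dp_max)
  attr(db, "subunits") <- subunits
  class(db) <- c("pcd_db", class(db))
  db
}

#' Compositions in a database matching a chemical formula
#'
#' Distinct compositions can share one molecular formula (formula-level
#' ambiguity: swapping a gallocatechin + catechin-gallate pair for a
#' catechin + gallocatechin-gallate pair preserves the formula). Candidates
#' are returned with the canonical representative first: maximal
#' gallocatechin-gallate count, then maximal catechin count, then name.
#'
#' @param db A `pcd_db` tibble from [pcd_database()].
#' @param formula A Hill-order formula string.
#' @return The matching rows of `db`, canonically ordered (zero rows if the
#'   formula is absent).
#' @examples
#' db <- pcd_database()
#' formula_candidates(db, "C67H54O29")
#' @export
formula_candidates <- function(db, formula) {
  hits <- db[db$formula == formula, , drop = FALSE]
  hits <- hits[order(-hits$n_galcatgal, -hits$n_cat, hits$name,
                     method = "radix"), , drop = FALSE]
  tibble::as_tibble(hits)
}

#' Export a compound database as CSV
#'
#' One row per composition with the fixed header
#' `name,dp,n_cat,n_galcat,n_catgal,n_galcatgal,formula,neutral_mass,knm,kmd`;
#' masses are printed with 6 decimals and Kendrick mass defects with 4. Row
#' order (dp ascending, then name) and formatting are deterministic, so
#' re-export is byte-identical.
#'
#' @param db A `pcd_db` tibble.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_pcd_db <- function(db, path) {
  out <- tibble::tibble(
    name = db$name, dp = db$dp,
    n_cat = db$n_cat, n_galcat = db$n_galcat,
    n_catgal = db$n_catgal, n_galcatgal = db$n_galcatgal,
    formula = db$formula,
    neutral_mass = sprintf("%.6f", db$neutral_mass),
    knm = db$knm,
    kmd = sprintf("%.4f", db$kmd)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a compound database written by [write_pcd_db()]
#'
#' @param path Path to a database CSV.
#' @return A `pcd_db` tibble.
#' @export
read_pcd_db <- function(path) {
  db <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("name", "dp", .count_cols, "formula", "neutral_mass",
              "knm", "kmd")
  missing <- setdiff(needed, names(db))
  if (length(missing) > 0) {
    stop(sprintf("database file lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  class(db) <- c("pcd_db", class(db))
  db
}

#' @export
glance.pcd_db <- function(x, ...) {
  tibble::tibble(
    n_compositions = nrow(x),
    n_formulas = dplyr::n_distinct(x$formula),
    dp_min = min(x$dp),
    dp_max = max(x$dp),
    mass_min = min(x$neutral_mass),
    mass_max = max(x$neutral_mass)
  )
}
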