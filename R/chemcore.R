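# Monoisotopic atomic masses (Da). C is exactly 12 by definition; values for
# the other elements are the standard monoisotopic masses at >= 6 decimals.
# Only C/H/O are exercised by the shipped subunits; the table is extensible.
.atomic_masses <- c(
  C  = 12,
  H  = 1.00782503207,
  O  = 15.9949146196,
  N  = 14.0030740048,
  S  = 31.97207100,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668
)

.proton_mass <- 1.00727646688
.electron_mass <- 0.00054857990907
# HCOO- (formate anion, incl. electron): the m/z shift of an [M+HCOO]- adduct
.formate_shift <- 12 + 2 * 15.9949146196 + 1.00782503207 + 0.00054857990907

.adduct_kinds <- c("deprotonated", "formate")

#' Physical constants used in all mass arithmetic
#'
#' Returns the monoisotopic atomic masses and the particle/adduct masses the
#' package uses for every m/z computation, as a tibble. All values are in
#' daltons.
#'
#' @return A tibble with columns `constant` and `mass_da`.
#' @examples
#' mass_constants()
#' @export
mass_constants <- function() {
  tibble::tibble(
    constant = c(paste0("atomic_", names(.atomic_masses)),
                 "proton", "electron", "formate_adduct_shift"),
    mass_da = unname(c(.atomic_masses, .proton_mass, .electron_mass,
                       .formate_shift))
  )
}

#' Parse a chemical formula string
#'
#' Parses Hill-style formula strings such as `"C30H26O12"` into a named
#' integer vector of element counts. Element symbols must be known to the
#' package mass table; counts must be positive integers (a missing count
#' means 1). `parse_formula(render_formula(f))` recovers `f`.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C30H26O12")
#' @seealso [render_formula()], [formula_mass()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("`text` must be a single formula string", call. = FALSE)
  }
  if (!nzchar(text)) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (paste(tokens, collapse = "") != text) {
    # reconstruct the first offending stretch for the error message
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(tokens)) {
      covered[seq(m[i], m[i] + attr(m, "match.length")[i] - 1)] <- TRUE
    }
    bad_at <- which(!covered)[1]
    stop(sprintf("malformed formula `%s`: cannot parse at `%s`",
                 text, substr(text, bad_at, nchar(text))), call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt_chr <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(cnt_chr), suppressWarnings(as.integer(cnt_chr)), 1L)
  bad_sym <- setdiff(sym, names(.atomic_masses))
  if (length(bad_sym) > 0) {
    stop(sprintf("unknown element `%s` in formula `%s`", bad_sym[1], text),
         call. = FALSE)
  }
  if (any(is.na(cnt)) || any(cnt <= 0L)) {
    bad <- tokens[is.na(cnt) | cnt <= 0L][1]
    stop(sprintf("invalid element count in token `%s` of formula `%s`",
                 bad, text), call. = FALSE)
  }
  counts <- tapply(cnt, sym, sum)
  out <- stats::setNames(as.integer(counts), names(counts))
  out[order(match(names(out), names(.atomic_masses)))]
}

#' Render element counts as a Hill-order formula string
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' elements with count zero are dropped and a count of one is implicit.
#'
#' @param counts Named integer vector of element counts (all >= 0).
#' @return A single formula string.
#' @examples
#' render_formula(c(C = 30, H = 26, O = 12))
#' @export
render_formula <- function(counts) {
  counts <- .validate_counts(counts)
  counts <- counts[counts > 0]
  if (length(counts) == 0) return("")
  elems <- names(counts)
  rest <- sort(setdiff(elems, c("C", "H")))
  ord <- c(intersect(c("C", "H"), elems), rest)
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

.validate_counts <- function(counts) {
  if (is.character(counts) && length(counts) == 1) counts <- parse_formula(counts)
  if (is.null(names(counts)) && length(counts) > 0) {
    stop("element counts must be a named vector", call. = FALSE)
  }
  bad <- setdiff(names(counts), names(.atomic_masses))
  if (length(bad) > 0) {
    stop(sprintf("unknown element `%s`", bad[1]), call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("element counts must be non-negative", call. = FALSE)
  }
  counts
}

#' Add, subtract and scale chemical formulas
#'
#' Element-wise arithmetic on formulas given as strings or named count
#' vectors. `formula_subtract()` errors if any element count would become
#' negative.
#'
#' @param f,g Formula strings or named count vectors.
#' @param n Non-negative integer multiplier.
#' @return Named integer vector of element counts.
#' @examples
#' formula_add("C15H14O6", "C7H4O4")
#' formula_multiply("C15H12O6", 3)
#' @export
formula_add <- function(f, g) {
  f <- .validate_counts(f); g <- .validate_counts(g)
  elems <- union(names(f), names(g))
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(f)] <- out[names(f)] + f
  out[names(g)] <- out[names(g)] + g
  out[order(match(names(out), names(.atomic_masses)))]
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f, g) {
  f <- .validate_counts(f); g <- .validate_counts(g)
  elems <- union(names(f), names(g))
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(f)] <- out[names(f)] + f
  out[names(g)] <- out[names(g)] - g
  if (any(out < 0)) {
    stop(sprintf("subtraction would give a negative count for `%s`",
                 names(out)[out < 0][1]), call. = FALSE)
  }
  out[order(match(names(out), names(.atomic_masses)))]
}

#' @rdname formula_add
#' @export
formula_multiply <- function(f, n) {
  f <- .validate_counts(f)
  stopifnot(length(n) == 1, n >= 0, n == as.integer(n))
  out <- f * as.integer(n)
  storage.mode(out) <- "integer"
  out
}

#' Monoisotopic mass of a chemical formula
#'
#' Sum of element count times monoisotopic atomic mass. Vectorised over a
#' character vector of formula strings; also accepts a single named count
#' vector. The empty formula has mass 0.
#'
#' @param x Character vector of formula strings, or a named count vector.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' formula_mass("C15H12O6") # the Kendrick base unit, 288.063388 Da
#' formula_mass(c("C15H14O6", "C22H18O10"))
#' @export
formula_mass <- function(x) {
  if (is.numeric(x)) {
    counts <- .validate_counts(x)
    return(sum(counts * .atomic_masses[names(counts)]))
  }
  vapply(x, function(s) {
    counts <- parse_formula(s)
    sum(counts * .atomic_masses[names(counts)])
  }, numeric(1), USE.NAMES = FALSE)
}

.check_ion <- function(adduct, z) {
  adduct <- match.arg(adduct, .adduct_kinds)
  if (!all(z %in% c(1, 2))) {
    stop("charge magnitude `z` must be 1 or 2", call. = FALSE)
  }
  if (adduct == "formate" && any(z != 1)) {
    stop("formate adducts are only supported at z = 1", call. = FALSE)
  }
  adduct
}

#' Negative-mode ion m/z from neutral mass, and back
#'
#' `mz_from_mass()` computes the m/z of a deprotonated `[M - zH]^z-` or
#' formate `[M + HCOO]^-` ion from the neutral monoisotopic mass;
#' `mass_from_mz()` is its exact algebraic inverse. Deprotonation removes
#' `z` protons: `(M - z * m_proton) / z`; the formate adduct adds the
#' formate anion mass at z = 1.
#'
#' @param mass Neutral monoisotopic mass in Da (positive).
#' @param mz Ion m/z (positive).
#' @param adduct `"deprotonated"` or `"formate"`.
#' @param z Charge magnitude, 1 or 2 (formate requires 1).
#' @return Numeric vector of m/z values (or neutral masses).
#' @examples
#' mz_from_mass(578.1424, "deprotonated", 1) # 577.1351
#' mass_from_mz(623.1406, "formate", 1)      # 578.1424
#' @export
mz_from_mass <- function(mass, adduct = c("deprotonated", "formate"), z = 1) {
  adduct <- .check_ion(adduct, z)
  if (any(mass <= 0)) stop("neutral mass must be positive", call. = FALSE)
  if (adduct == "deprotonated") (mass - z * .proton_mass) / z
  else mass + .formate_shift
}

#' @rdname mz_from_mass
#' @export
mass_from_mz <- function(mz, adduct = c("deprotonated", "formate"), z = 1) {
  adduct <- .check_ion(adduct, z)
  if (any(mz <= 0)) stop("m/z must be positive", call. = FALSE)
  if (adduct == "deprotonated") mz * z + z * .proton_mass
  else mz - .formate_shift
}

#' Relative mass error in parts per million
#'
#' `|theoretical - experimental| / theoretical * 1e6` by default (the
#' unsigned convention used for reported mean errors); set `signed = TRUE`
#' for the signed form `(theoretical - experimental) / theoretical * 1e6`.
#'
#' @param theoretical Theoretical mass in Da (positive).
#' @param experimental Measured mass in Da.
#' @param signed Report the signed error instead of the magnitude?
#' @return Numeric vector of ppm errors.
#' @examples
#' ppm_error(578.1424, 578.1401) # 4.0 ppm
#' @export
ppm_error <- function(theoretical, experimental, signed = FALSE) {
  if (any(theoretical <= 0)) {
    stop("theoretical mass must be positive", call. = FALSE)
  }
  err <- (theoretical - experimental) / theoretical * 1e6
  if (signed) err else abs(err)
}
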