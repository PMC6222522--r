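# Full-precision mass of the repeat unit C15H12O6 (catechin extension unit,
# i.e. catechin less H2). Used as the default Kendrick divisor; the printed
# 4-decimal value 288.0634 reproduces the same 4-dp results but the full
# precision keeps the homologous-series invariance exact.
.kendrick_base_mass <- function() formula_mass("C15H12O6")

# round half away from zero; base round() is half-to-even
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Modified Kendrick transform with base unit C15H12O6
#'
#' Rescales neutral monoisotopic ("IUPAC") masses so that the catechin
#' extension unit C15H12O6 has integer mass 288:
#' `kendrick_mass = iupac_mass * 288 / mass(C15H12O6)`. The Kendrick nominal
#' mass (KNM) is the Kendrick mass rounded to the nearest integer (half away
#' from zero) and the Kendrick mass defect is `KMD = KNM - kendrick_mass`,
#' reported to 4 decimals. Polymers differing only by whole extension units
#' share a KMD, so homologous proanthocyanidin series fall on one value
#' (pure catechin polymers at -0.0152).
#'
#' Kendrick quantities are computed from the NEUTRAL mass, not the ion m/z:
#' the catechin trimer sits at KNM 866, not at its [M-H]- m/z of 865.
#'
#' @param mass Numeric vector of neutral monoisotopic masses (Da, positive).
#' @param base_mass Divisor mass of the repeat unit; defaults to the
#'   full-precision monoisotopic mass of C15H12O6 (288.063388). Pass
#'   `288.0634` to emulate the printed-constant convention exactly.
#' @return A tibble with columns `iupac_mass`, `kendrick_mass`, `knm`
#'   (integer), `kmd` (4 decimals, `|kmd| <= 0.5`).
#' @examples
#' kendrick_transform(formula_mass("C45H38O18")) # knm 866, kmd -0.0152
#' @export
kendrick_transform <- function(mass, base_mass = NULL) {
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  if (is.null(base_mass)) base_mass <- .kendrick_base_mass()
  km <- mass * 288 / base_mass
  knm <- .round_half_away(km)
  tibble::tibble(
    iupac_mass = mass,
    kendrick_mass = km,
    knm = as.integer(knm),
    kmd = round(knm - km, 4)
  )
}

#' Kendrick coordinate shift caused by adding a chemical group
#'
#' Adding a group (e.g. one oxygen for an extra B-ring hydroxyl, or C7H4O4
#' for a gallate ester) moves every polymer by a fixed (KNM, KMD) offset:
#' the nominal Kendrick mass of the group, and that integer minus the
#' group's Kendrick mass. Oxygen shifts (KNM, KMD) by (16, +0.0086); a
#' gallate by (152, +0.0225); one whole extension unit by (288, 0).
#'
#' @param delta Formula string or named count vector of the added group.
#' @param base_mass See [kendrick_transform()].
#' @return A tibble with columns `knm_shift` (integer) and `kmd_shift`
#'   (4 decimals).
#' @examples
#' kmd_shift("O")      # 16, 0.0086
#' kmd_shift("C7H4O4") # 152, 0.0225
#' @export
kmd_shift <- function(delta, base_mass = NULL) {
  m <- formula_mass(delta)
  if (m <= 0) stop("`delta` must have positive mass", call. = FALSE)
  if (is.null(base_mass)) base_mass <- .kendrick_base_mass()
  km <- m * 288 / base_mass
  knm <- .round_half_away(km)
  tibble::tibble(knm_shift = as.integer(knm), kmd_shift = round(knm - km, 4))
}

#' Kendrick scatter data for a compound database
#'
#' One row per database entry with its Kendrick coordinates and a flag
#' marking membership in the set of identified formulas, ready for a
#' KMD-vs-KNM scatter (theoretical entries as points, identifications
#' circled).
#'
#' @param db A `pcd_db` tibble from [pcd_database()].
#' @param identified Character vector of identified formulas (may be empty).
#' @return A tibble with columns `name`, `formula`, `dp`, `knm`, `kmd`,
#'   `identified`.
#' @seealso [plot_kendrick()]
#' @export
kendrick_plot_data <- function(db, identified = character()) {
  tibble::tibble(
    name = db$name,
    formula = db$formula,
    dp = db$dp,
    knm = db$knm,
    kmd = db$kmd,
    identified = db$formula %in% identified
  )
}

#' Retention-time vs Kendrick-nominal-mass bubble data
#'
#' Flattens grouped identifications into one row per (sample, isomer peak)
#' with the peak's KNM, retention time and summed peak area, suitable for a
#' bubble chart with area-proportional dot sizes. Rows without a usable
#' area are dropped with a warning.
#'
#' @param peaks A `pcd_groups` object from [group_matches()], or a tibble
#'   with columns `sample_id`, `knm`, `rt`, `area`.
#' @return A tibble with columns `sample_id`, `formula`, `knm`, `rt`,
#'   `area`.
#' @seealso [plot_abundance()]
#' @export
abundance_plot_data <- function(peaks) {
  if (inherits(peaks, "pcd_groups")) peaks <- peaks$peaks
  needed <- c("sample_id", "knm", "rt", "area")
  missing <- setdiff(needed, names(peaks))
  if (length(missing) > 0) {
    stop(sprintf("peak table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- is.na(peaks$area) | peaks$area <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d peak(s) without a positive area", sum(bad)),
            call. = FALSE)
    peaks <- peaks[!bad, , drop = FALSE]
  }
  cols <- intersect(c("sample_id", "formula", "knm", "rt", "area"),
                    names(peaks))
  tibble::as_tibble(peaks[, cols, drop = FALSE])
}

#' Kendrick mass defect scatter plot
#'
#' KNM on x, KMD on y; every theoretical composition as a point, identified
#' formulas circled. Diagonal bands of constant degree of polymerization
#' are visible by construction.
#'
#' @param data Output of [kendrick_plot_data()] (or a `pcd_db`, which is
#'   transformed with no identifications).
#' @return A ggplot object.
#' @export
plot_kendrick <- function(data) {
  if (inherits(data, "pcd_db")) data <- kendrick_plot_data(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$knm, y = .data$kmd)) +
    ggplot2::geom_point(size = 0.8, colour = "black") +
    ggplot2::labs(x = "Kendrick nominal mass",
                  y = "Kendrick mass defect") +
    ggplot2::theme_bw()
  if (any(data$identified)) {
    p <- p + ggplot2::geom_point(
      data = data[data$identified, , drop = FALSE],
      shape = 21, size = 2.6, colour = "red", fill = NA, stroke = 0.7
    )
  }
  p
}

#' Retention time vs Kendrick nominal mass bubble plot
#'
#' One panel per sample; KNM on x, retention time on y, dot area
#' proportional to summed peak area.
#'
#' @param data Output of [abundance_plot_data()].
#' @return A ggplot object.
#' @export
plot_abundance <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$knm, y = .data$rt,
                                     size = .data$area)) +
    ggplot2::geom_point(alpha = 0.6, colour = "#4a1486") +
    ggplot2::scale_size_area(max_size = 8, name = "peak area") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "Kendrick nominal mass", y = "Retention time (min)") +
    ggplot2::theme_bw()
}
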