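#' Diagnostic neutral losses of flavan-3-ol fragmentation
#'
#' The neutral losses behind the characteristic negative-mode pathways:
#' heterocyclic ring fission of the C-ring releases phloroglucinol
#' (C6H6O3); retro-Diels-Alder cleavage loses the B-ring-containing
#' fragment (C8H8O3 for a catechol B-ring, C8H8O4 for pyrogallol); plus
#' water and the gallate ester (C7H4O4).
#'
#' @return A tibble with columns `label`, `formula`, `mass`.
#' @export
neutral_losses <- function() {
  tibble::tibble(
    label = c("phloroglucinol", "rda_catechol", "rda_pyrogallol",
              "water", "gallate"),
    formula = c("C6H6O3", "C8H8O3", "C8H8O4", "H2O", "C7H4O4"),
    mass = formula_mass(c("C6H6O3", "C8H8O3", "C8H8O4", "H2O", "C7H4O4"))
  )
}

# element counts and summary stats of a sub-composition
.comp_info <- function(cc) {
  dp <- sum(cc)
  el <- .composition_elements(cc[["n_cat"]], cc[["n_galcat"]],
                              cc[["n_catgal"]], cc[["n_galcatgal"]])
  list(
    dp = dp,
    counts = c(C = el$C, H = el$H, O = el$O),
    n_gallate = cc[["n_catgal"]] + cc[["n_galcatgal"]],
    has_catechol = (cc[["n_cat"]] + cc[["n_catgal"]]) > 0,
    has_pyrogallol = (cc[["n_galcat"]] + cc[["n_galcatgal"]]) > 0
  )
}

.fragment_row <- function(counts, charge, pathway, structure, role = "none",
                          subunit = NA_character_, n_losses = 0L,
                          comp = NULL) {
  mass <- sum(counts * .atomic_masses[names(counts)])
  tibble::tibble(
    formula = render_formula(counts),
    neutral_mass = mass,
    charge = as.integer(charge),
    mz = (mass - charge * .proton_mass) / charge,
    pathway = pathway,
    structure = structure,
    role = role,
    subunit = subunit,
    n_losses = as.integer(n_losses),
    comp = list(comp)
  )
}

#' Quinone methide (interflavan bond) fragments of a composition
#'
#' Interflavan cleavage splits the polymer into a terminal-side and an
#' extension-side part. For every non-empty proper sub-multiset S of the
#' composition the terminal-side ion is `[poly(S) - H]-` and the
#' extension-side ion is `[poly(S) - 2H - H]-` (the extension part leaves 2
#' Da lighter), where poly(S) is the sub-polymer formula. Because the
#' composition is a multiset, the fragments are the union over all sequence
#' isomers. Single-unit ions carry the subunit code as role evidence: the
#' terminal catechin ion at m/z 289.0718 vs its extension counterpart at
#' 287.0561 distinguish where a unit sat in the chain.
#'
#' @param composition A composition name (e.g. `"Cat-Cat:Gal"`) or named
#'   count vector; must have dp >= 2.
#' @return A fragment tibble (formula, neutral_mass, charge, mz, pathway,
#'   structure, role, subunit, n_losses).
#' @export
qm_fragments <- function(composition) {
  cc <- as_composition(composition)
  if (sum(cc) < 2) {
    stop("quinone methide cleavage needs an interflavan bond (dp >= 2)",
         call. = FALSE)
  }
  grid <- expand.grid(n_cat = 0:cc[["n_cat"]],
                      n_galcat = 0:cc[["n_galcat"]],
                      n_catgal = 0:cc[["n_catgal"]],
                      n_galcatgal = 0:cc[["n_galcatgal"]])
  sizes <- rowSums(grid)
  grid <- grid[sizes >= 1 & sizes < sum(cc), , drop = FALSE]

  h2 <- c(H = 2L)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sub <- stats::setNames(as.integer(grid[i, ]), .count_cols)
    info <- .comp_info(sub)
    nm <- composition_name(sub)
    unit <- if (info$dp == 1) .unit_codes[which(sub == 1)] else NA_character_
    dplyr::bind_rows(
      .fragment_row(info$counts, 1L,
                    paste0("QM terminal [", nm, " - H]-"),
                    "III", role = "terminal", subunit = unit, comp = sub),
      .fragment_row(formula_subtract(info$counts, h2), 1L,
                    paste0("QM extension [", nm, " - 2H - H]-"),
                    "III", role = "extension", subunit = unit, comp = sub)
    )
  })
  out
}

# structure label from loss multiplicities (h = HRF, r = RDA, g = gallate,
# w = water); QM-derived fragments keep label III via `qm`
.structure_label <- function(h, r, g, w, qm = FALSE) {
  if (qm) return("III")
  if (h > 0) return(if (w > 0) "II" else "I")
  if (r > 0) return(if (w > 0) "V" else "IV")
  if (g > 0) return("VI")
  "other"
}

# enumerate loss multiset combinations valid for a fragment whose (sub-)
# composition is `cc`: water freely repeatable, gallate bounded by the
# gallate count, HRF by the unit count (one intact A-ring each), RDA at
# most once with the B-ring variant gated on unit presence
.loss_combos <- function(cc, max_losses) {
  info <- .comp_info(cc)
  combos <- expand.grid(
    h = 0:min(info$dp, max_losses),
    r_cat = 0:(if (info$has_catechol) 1 else 0),
    r_pyr = 0:(if (info$has_pyrogallol) 1 else 0),
    g = 0:min(info$n_gallate, max_losses),
    w = 0:max_losses
  )
  tot <- rowSums(combos)
  combos[tot >= 1 & tot <= max_losses & (combos$r_cat + combos$r_pyr) <= 1, ,
         drop = FALSE]
}

#' Sequential neutral-loss fragments
#'
#' Applies every valid combination of up to `max_losses` neutral losses to
#' a precursor-like fragment: water (always available), gallate (only while
#' the fragment still carries a gallate ester), phloroglucinol via
#' heterocyclic ring fission (at most once per unit with an intact A-ring)
#' and one retro-Diels-Alder loss (catechol variant requires a
#' catechin-type unit, pyrogallol variant a gallocatechin-type unit).
#' Structure labels follow the canonical pathway scheme: HRF products are
#' I (II once dehydrated), RDA products IV (V once dehydrated), plain
#' gallate loss VI.
#'
#' @param precursor A one-row fragment tibble (e.g. the precursor row of
#'   [generate_fragments()]); its `comp` column carries the composition the
#'   loss validity is judged against.
#' @param composition Composition of the precursor (name or counts); used
#'   when `precursor` lacks composition information.
#' @param max_losses Maximum number of sequential losses (>= 0).
#' @param losses Optional restriction to a subset of loss labels (see
#'   [neutral_losses()]); requesting `"gallate"` for a gallate-free
#'   composition is an error.
#' @return A fragment tibble, one row per loss combination.
#' @export
loss_fragments <- function(precursor, composition = NULL, max_losses = 3,
                           losses = NULL) {
  stopifnot(max_losses >= 0)
  if (is.null(composition)) {
    cc <- precursor$comp[[1]]
    if (is.null(cc)) stop("no composition available for the precursor",
                          call. = FALSE)
  } else {
    cc <- as_composition(composition)
  }
  info <- .comp_info(cc)
  if (!is.null(losses)) {
    losses <- match.arg(losses, neutral_losses()$label, several.ok = TRUE)
    if ("gallate" %in% losses && info$n_gallate == 0) {
      stop("gallate loss requested for a gallate-free composition",
           call. = FALSE)
    }
  }
  combos <- .loss_combos(cc, max_losses)
  if (!is.null(losses)) {
    if (!"phloroglucinol" %in% losses) combos <- combos[combos$h == 0, ]
    if (!"rda_catechol" %in% losses) combos <- combos[combos$r_cat == 0, ]
    if (!"rda_pyrogallol" %in% losses) combos <- combos[combos$r_pyr == 0, ]
    if (!"gallate" %in% losses) combos <- combos[combos$g == 0, ]
    if (!"water" %in% losses) combos <- combos[combos$w == 0, ]
  }
  if (nrow(combos) == 0) return(qm_fragments("Cat-Cat")[0, ])

  base_counts <- parse_formula(precursor$formula[1])
  charge <- precursor$charge[1]
  qm_derived <- isTRUE(precursor$structure[1] == "III")
  loss_masses <- stats::setNames(neutral_losses()$mass, neutral_losses()$label)
  loss_formulas <- stats::setNames(lapply(neutral_losses()$formula,
                                          parse_formula),
                                   neutral_losses()$label)

  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    k <- combos[i, ]
    delta <- stats::setNames(integer(0), character(0))
    steps <- character(0)
    add <- function(delta, lf, n) {
      if (n > 0) formula_add(delta, formula_multiply(lf, n)) else delta
    }
    delta <- add(delta, loss_formulas$phloroglucinol, k$h)
    delta <- add(delta, loss_formulas$rda_catechol, k$r_cat)
    delta <- add(delta, loss_formulas$rda_pyrogallol, k$r_pyr)
    delta <- add(delta, loss_formulas$gallate, k$g)
    delta <- add(delta, loss_formulas$water, k$w)
    steps <- c(if (k$h > 0) rep("HRF(-C6H6O3)", k$h),
               if (k$r_cat > 0) "RDA(-C8H8O3)",
               if (k$r_pyr > 0) "RDA(-C8H8O4)",
               if (k$g > 0) rep("-gallate", k$g),
               if (k$w > 0) rep("-H2O", k$w))
    counts <- tryCatch(formula_subtract(base_counts, delta),
                       error = function(e) NULL)
    if (is.null(counts) || sum(counts) == 0) return(NULL)
    .fragment_row(
      counts, charge,
      paste(c(precursor$pathway[1], steps), collapse = " "),
      .structure_label(k$h, k$r_cat + k$r_pyr, k$g, k$w, qm = qm_derived),
      role = precursor$role[1], subunit = precursor$subunit[1],
      n_losses = sum(k), comp = cc
    )
  })
}

#' Generate the diagnostic fragment set of a composition
#'
#' Union of the precursor ion, all quinone methide cleavage products, and
#' sequential neutral-loss products applied to the precursor and to each QM
#' fragment, deduplicated on (formula, charge) keeping the shortest pathway
#' trace, ordered by descending m/z. Fragment ions are singly charged by
#' default even when the precursor is doubly charged, matching how
#' product-ion spectra of multiply charged proanthocyanidins are read.
#'
#' @param composition Composition name or count vector (must be in the
#'   database domain, i.e. dp >= 2 for QM fragments to exist).
#' @param adduct,z Precursor ion species (see [mz_from_mass()]).
#' @param max_losses Maximum sequential neutral losses (default 3, deep
#'   enough for the dehydrated HRF and RDA products of galloylated
#'   precursors).
#' @return A fragment tibble; the first row is the precursor.
#' @examples
#' frags <- generate_fragments("Cat-Cat:Gal")
#' frags[frags$structure == "VI", c("mz", "pathway")]
#' @export
generate_fragments <- function(composition, adduct = "deprotonated", z = 1,
                               max_losses = 3) {
  cc <- as_composition(composition)
  adduct <- .check_ion(adduct, z)
  info <- .comp_info(cc)
  nm <- composition_name(cc)

  precursor <- .fragment_row(info$counts, 1L, paste0("[", nm, " - H]-"),
                             "precursor", comp = cc)
  # report the precursor at its actual ion species; fragments stay z = 1
  precursor$charge <- as.integer(z)
  precursor$mz <- mz_from_mass(precursor$neutral_mass, adduct, z)

  prec1 <- precursor
  prec1$charge <- 1L
  prec1$mz <- (prec1$neutral_mass - .proton_mass)

  qm <- qm_fragments(cc)

  loss_sets <- list(loss_fragments(prec1, cc, max_losses = max_losses))
  for (i in seq_len(nrow(qm))) {
    row <- qm[i, ]
    loss_sets[[length(loss_sets) + 1]] <-
      loss_fragments(row, row$comp[[1]], max_losses = max_losses)
  }

  frags <- dplyr::bind_rows(c(list(precursor, qm), loss_sets))
  frags$trace_len <- frags$n_losses + (frags$structure == "III")
  frags <- frags[order(frags$trace_len, method = "radix"), ]
  frags <- frags[!duplicated(paste(frags$formula, frags$charge)), ]
  frags$trace_len <- NULL
  frags <- frags[order(-frags$mz), ]
  tibble::as_tibble(frags)
}

#' Annotate an MS/MS peak list against a composition's fragment set
#'
#' Each observed peak is matched to the generated fragment with the
#' smallest unsigned ppm error within the tolerance (default 20 ppm; looser
#' than a typical MS1 tolerance because product-ion mass accuracy is
#' poorer). The summary reports, for each registered subunit, whether
#' terminal and/or extension quinone methide evidence was observed --
#' presence/absence of these diagnostic monomer ions is how a composition
#' is confirmed (e.g. no peak near m/z 305.0667 means no gallocatechin
#' extension unit).
#'
#' @param peaks A two-column data frame/tibble (`mz`, `intensity`) or a
#'   numeric matrix.
#' @param composition Composition name or count vector.
#' @param tolerance_ppm Annotation tolerance in ppm.
#' @param ... Passed to [generate_fragments()].
#' @return A `pcd_annotation` object: list with `annotated` (one row per
#'   peak), `summary` (one row per subunit x role), `composition`,
#'   `tolerance_ppm`.
#' @export
annotate_spectrum <- function(peaks, composition, tolerance_ppm = 20, ...) {
  if (is.matrix(peaks)) {
    peaks <- tibble::tibble(mz = peaks[, 1], intensity = peaks[, 2])
  }
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    nm <- names(peaks)
    peaks <- tibble::tibble(mz = peaks[[1]], intensity = peaks[[2]])
  }
  if (nrow(peaks) == 0) stop("peak list is empty", call. = FALSE)
  cc <- as_composition(composition)
  frags <- generate_fragments(cc, ...)

  ann <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    ppm <- abs(peaks$mz[i] - frags$mz) / frags$mz * 1e6
    j <- which.min(ppm)
    if (ppm[j] <= tolerance_ppm) {
      tibble::tibble(
        observed_mz = peaks$mz[i], intensity = peaks$intensity[i],
        fragment_formula = frags$formula[j], theoretical_mz = frags$mz[j],
        ppm_error = ppm[j], pathway = frags$pathway[j],
        structure = frags$structure[j], role = frags$role[j],
        subunit = frags$subunit[j]
      )
    } else {
      tibble::tibble(
        observed_mz = peaks$mz[i], intensity = peaks$intensity[i],
        fragment_formula = NA_character_, theoretical_mz = NA_real_,
        ppm_error = NA_real_, pathway = NA_character_,
        structure = NA_character_, role = NA_character_,
        subunit = NA_character_
      )
    }
  })

  units <- monomer_units()
  summary <- tidyr::crossing(subunit = units$code,
                             role = c("terminal", "extension")) |>
    dplyr::mutate(
      theoretical_mz = purrr::map2_dbl(.data$subunit, .data$role, function(u, r) {
        m <- units$monoisotopic_mass[units$code == u]
        if (r == "terminal") m - .proton_mass
        else m - 2 * .atomic_masses[["H"]] - .proton_mass
      }),
      in_composition = .data$subunit %in% rep(.unit_codes, times = cc),
      observed = purrr::map_lgl(.data$theoretical_mz, function(mz0) {
        any(abs(peaks$mz - mz0) / mz0 * 1e6 <= tolerance_ppm)
      })
    )

  structure(list(annotated = ann, summary = summary, composition = cc,
                 tolerance_ppm = tolerance_ppm),
            class = "pcd_annotation")
}

#' @export
tidy.pcd_annotation <- function(x, ...) x$annotated

#' @export
glance.pcd_annotation <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x$annotated),
    n_annotated = sum(!is.na(x$annotated$fragment_formula)),
    mean_ppm_error = mean(x$annotated$ppm_error, na.rm = TRUE),
    tolerance_ppm = x$tolerance_ppm
  )
}

#' @export
print.pcd_annotation <- function(x, ...) {
  cat(sprintf("<pcd_annotation> %s: %d/%d peaks annotated at %.3g ppm\n",
              composition_name(x$composition),
              sum(!is.na(x$annotated$fragment_formula)),
              nrow(x$annotated), x$tolerance_ppm))
  print(x$annotated, ...)
  invisible(x)
}

#' Write an annotation result as CSV
#'
#' Columns `observed_mz,intensity,fragment_formula,theoretical_mz,
#' ppm_error,pathway,structure_label`.
#'
#' @param annotation A `pcd_annotation` object.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  a <- annotation$annotated
  out <- tibble::tibble(
    observed_mz = a$observed_mz, intensity = a$intensity,
    fragment_formula = a$fragment_formula,
    theoretical_mz = a$theoretical_mz, ppm_error = a$ppm_error,
    pathway = a$pathway, structure_label = a$structure
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
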