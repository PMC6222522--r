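#' Read and write MGF peak lists
#'
#' Minimal Mascot Generic Format support for tandem spectra: `BEGIN
#' IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`, `CHARGE` headers
#' (negative polarity written as e.g. `1-`) and whitespace-delimited
#' `m/z intensity` peak lines. No installed package parses MGF, and the
#' format is line-oriented enough that a small reader is the right tool.
#'
#' `read_msms()` dispatches on content: files containing `BEGIN IONS` are
#' parsed as MGF (first spectrum returned), anything else as headerless
#' two-column delimited text.
#'
#' @param path File path.
#' @return `read_mgf()`: a tibble with one row per spectrum and columns
#'   `title`, `pepmass`, `charge`, `peaks` (list of `mz`/`intensity`
#'   tibbles). `read_msms()`: a single `mz`/`intensity` tibble.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) == 0 || length(starts) != length(ends)) {
    stop(sprintf("`%s` is not a well-formed MGF file", path), call. = FALSE)
  }
  purrr::map_dfr(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1):(ends[i] - 1)]
    block <- block[nzchar(trimws(block))]
    is_header <- grepl("^[A-Z]+=", block)
    headers <- block[is_header]
    get <- function(key) {
      hit <- headers[startsWith(headers, paste0(key, "="))]
      if (length(hit) == 0) NA_character_
      else sub(paste0("^", key, "="), "", hit[1])
    }
    charge_chr <- get("CHARGE")
    charge <- if (is.na(charge_chr)) NA_integer_
      else as.integer(sub("[+-]$", "", charge_chr))
    pep <- get("PEPMASS")
    pepmass <- if (is.na(pep)) NA_real_
      else as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]][1])
    peak_lines <- block[!is_header]
    fields <- strsplit(trimws(peak_lines), "[ \t]+")
    bad <- which(lengths(fields) < 2)
    if (length(bad) > 0) {
      stop(sprintf("malformed peak line in `%s`: `%s`", path,
                   peak_lines[bad[1]]), call. = FALSE)
    }
    peaks <- tibble::tibble(
      mz = as.numeric(vapply(fields, `[`, character(1), 1)),
      intensity = as.numeric(vapply(fields, `[`, character(1), 2))
    )
    tibble::tibble(title = get("TITLE"), pepmass = pepmass,
                   charge = charge, peaks = list(peaks))
  })
}

#' @rdname read_mgf
#' @param spectra A tibble as returned by [read_mgf()], or a single
#'   `mz`/`intensity` tibble (written as one untitled spectrum).
#' @param polarity `"negative"` or `"positive"`; sets the CHARGE sign.
#' @export
write_mgf <- function(spectra, path, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  sign_chr <- if (polarity == "negative") "-" else "+"
  if (!"peaks" %in% names(spectra)) {
    spectra <- tibble::tibble(title = "spectrum_1", pepmass = NA_real_,
                              charge = NA_integer_, peaks = list(spectra))
  }
  out <- unlist(purrr::map(seq_len(nrow(spectra)), function(i) {
    p <- spectra$peaks[[i]]
    c("BEGIN IONS",
      if (!is.na(spectra$title[i])) paste0("TITLE=", spectra$title[i]),
      if (!is.na(spectra$pepmass[i]))
        sprintf("PEPMASS=%.6f", spectra$pepmass[i]),
      if (!is.na(spectra$charge[i]))
        paste0("CHARGE=", spectra$charge[i], sign_chr),
      sprintf("%.6f %.2f", p$mz, p$intensity),
      "END IONS", "")
  }))
  writeLines(out, path)
  invisible(path)
}

#' @rdname read_mgf
#' @export
read_msms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(lines == "BEGIN IONS")) {
    return(read_mgf(path)$peaks[[1]])
  }
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t,]+")
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    stop(sprintf("line %d of `%s` is not `mz intensity`", bad[1], path),
         call. = FALSE)
  }
  tibble::tibble(
    mz = as.numeric(vapply(fields, `[`, character(1), 1)),
    intensity = as.numeric(vapply(fields, `[`, character(1), 2))
  )
}
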