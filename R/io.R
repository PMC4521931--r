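# Canonical evidence dialect: UTF-8 TSV, header row, empty string = missing.
EVIDENCE_COLS <- c("sequence", "protein", "charge",
                   "intensity_l", "intensity_m", "intensity_h", "replicate")

# MaxQuant-style header aliases accepted out of the box.
MAXQUANT_ALIASES <- c(
  Sequence = "sequence", Proteins = "protein", Charge = "charge",
  "Intensity L" = "intensity_l", "Intensity M" = "intensity_m",
  "Intensity H" = "intensity_h", Experiment = "replicate"
)

#' Read a peptide-evidence table
#'
#' Reads the canonical tab-separated evidence dialect (columns `sequence`,
#' `protein`, `charge`, `intensity_l`, `intensity_m`, `intensity_h`,
#' `replicate`; empty string = missing). MaxQuant-style headers
#' (`Sequence`, `Proteins`, `Intensity L`, ..., `Experiment`) are mapped
#' automatically; other dialects via `mapping`. Rows with non-numeric
#' intensities are skipped with a warning naming the line numbers
#' (`on_error = "skip"`, default) or abort the read.
#'
#' @param path Path to a TSV file.
#' @param mapping Optional named character vector, file column ->
#'   canonical column.
#' @param on_error `"skip"` (default) or `"abort"` for malformed rows.
#' @return The evidence tibble.
#' @export
read_evidence <- function(path, mapping = NULL, on_error = c("skip", "abort")) {
  on_error <- match.arg(on_error)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  if (!is.null(mapping)) {
    names(raw)[match(names(mapping), names(raw))] <- unname(mapping)
  } else if (!all(EVIDENCE_COLS %in% names(raw))) {
    hit <- intersect(names(MAXQUANT_ALIASES), names(raw))
    names(raw)[match(hit, names(raw))] <- unname(MAXQUANT_ALIASES[hit])
  }
  missing_cols <- setdiff(EVIDENCE_COLS, names(raw))
  if (length(missing_cols)) {
    abort(paste0("evidence file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[, EVIDENCE_COLS]

  num_cols <- c("charge", "intensity_l", "intensity_m", "intensity_h")
  parsed <- lapply(raw[num_cols], function(x) suppressWarnings(as.numeric(x)))
  bad_row <- Reduce(`|`, lapply(num_cols, function(cn) {
    !is.na(raw[[cn]]) & is.na(parsed[[cn]])
  }))
  if (any(bad_row)) {
    lines <- which(bad_row) + 1L # header offset
    msg <- sprintf("%d malformed row(s) at line(s) %s", sum(bad_row),
                   paste(head(lines, 10), collapse = ", "))
    if (on_error == "abort") abort(paste0(msg, "."))
    warn(paste0(msg, "; skipped."))
  }
  for (cn in num_cols) raw[[cn]] <- parsed[[cn]]
  raw$charge <- as.integer(raw$charge)
  raw[!bad_row, , drop = FALSE]
}

#' Write a peptide-evidence table (canonical dialect)
#'
#' UTF-8, LF line endings, fixed column order, empty string for missing —
#' output is hashable and round-trips through [read_evidence()]
#' bit-exactly.
#'
#' @param evidence Evidence tibble.
#' @param path Output path.
#' @return `evidence`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  readr::write_tsv(evidence[, EVIDENCE_COLS], path, na = "")
  invisible(evidence)
}

#' Read a flat annotation table
#'
#' Accepts the four-column dialect `accession, term_id, term_label,
#' namespace` (header required) or a minimal headerless two-column
#' `accession, term_id` form.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `accession`, `term_id`, `term_label`,
#'   `namespace`.
#' @export
read_annotations <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("accession", first, fixed = TRUE)
  tab <- readr::read_tsv(path, col_names = has_header,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!has_header) {
    if (ncol(tab) != 2) abort("headerless annotation files must have exactly 2 columns.")
    names(tab) <- c("accession", "term_id")
  }
  if (!all(c("accession", "term_id") %in% names(tab))) {
    abort("annotation file must contain `accession` and `term_id` columns.")
  }
  if (!"term_label" %in% names(tab)) tab$term_label <- NA_character_
  if (!"namespace" %in% names(tab)) tab$namespace <- NA_character_
  tab[, c("accession", "term_id", "term_label", "namespace")]
}

#' Read a centroided peak list
#'
#' Two-column whitespace-separated text (`m/z intensity`, `#` comments
#' allowed) or MGF; the format is taken from the file extension unless
#' given. For MGF files the peaks of all `BEGIN IONS` blocks are returned
#' with a `spectrum` index column (use [read_mgf()] for block metadata).
#'
#' @param path Input path.
#' @param format `"auto"`, `"table"` or `"mgf"`.
#' @return A tibble with columns `mz`, `intensity` (and `spectrum` for
#'   multi-spectrum MGF input), sorted by `mz` within spectrum.
#' @export
read_peaklist <- function(path, format = c("auto", "table", "mgf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "table"
  }
  if (format == "mgf") {
    spectra <- read_mgf(path)
    out <- purrr::map_dfr(seq_len(nrow(spectra)), function(i) {
      dplyr::mutate(spectra$peaks[[i]], spectrum = i)
    })
    return(out)
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- stringr::str_split_fixed(stringr::str_trim(lines), "\\s+", 2)
  peaks <- suppressWarnings(
    tibble::tibble(mz = as.numeric(parts[, 1]), intensity = as.numeric(parts[, 2]))
  )
  if (any(is.na(peaks$mz)) || any(is.na(peaks$intensity))) {
    abort("malformed peak-list line(s): expected two numeric columns.")
  }
  dplyr::arrange(peaks, .data$mz)
}

#' Write a two-column peak list
#' @param peaks Tibble with `mz`, `intensity`.
#' @param path Output path.
#' @return `peaks`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  readr::write_delim(peaks[, c("mz", "intensity")], path, delim = " ", col_names = FALSE)
  invisible(peaks)
}

#' Read an MGF peak-list file
#'
#' Minimal Mascot Generic Format reader: one row per `BEGIN IONS` /
#' `END IONS` block with `TITLE`, `PEPMASS` and `CHARGE` honoured and the
#' centroided peaks as a nested tibble.
#'
#' @param path Input path.
#' @return Tibble with columns `title`, `pepmass`, `charge`, `peaks`
#'   (list of tibbles `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readr::read_lines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    abort("malformed MGF: unbalanced BEGIN IONS/END IONS blocks.")
  }
  purrr::map_dfr(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1):(ends[i] - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    meta <- setNames(vals, toupper(keys))
    peak_lines <- stringr::str_trim(block[!kv])
    peak_lines <- peak_lines[nzchar(peak_lines)]
    parts <- stringr::str_split_fixed(peak_lines, "\\s+", 2)
    charge_str <- meta["CHARGE"]
    charge <- if (is.na(charge_str)) NA_integer_ else {
      as.integer(stringr::str_match(charge_str, "(\\d+)")[, 2]) *
        ifelse(grepl("-", charge_str, fixed = TRUE), -1L, 1L)
    }
    tibble::tibble(
      title = unname(meta["TITLE"]),
      pepmass = as.numeric(stringr::str_split_fixed(meta["PEPMASS"], "\\s+", 2)[, 1]),
      charge = charge,
      peaks = list(tibble::tibble(mz = as.numeric(parts[, 1]),
                                  intensity = as.numeric(parts[, 2])))
    )
  })
}

#' Write spectra to MGF
#'
#' @param spectra Tibble as returned by [read_mgf()] (columns `title`,
#'   `pepmass`, `charge`, `peaks`).
#' @param path Output path.
#' @return `spectra`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  out <- character()
  for (i in seq_len(nrow(spectra))) {
    pk <- spectra$peaks[[i]]
    out <- c(
      out, "BEGIN IONS",
      paste0("TITLE=", spectra$title[i]),
      paste0("PEPMASS=", format(spectra$pepmass[i], digits = 15)),
      paste0("CHARGE=", abs(spectra$charge[i]), ifelse(spectra$charge[i] < 0, "-", "+")),
      paste(format(pk$mz, digits = 15, trim = TRUE),
            format(pk$intensity, digits = 15, trim = TRUE)),
      "END IONS"
    )
  }
  readr::write_lines(out, path)
  invisible(spectra)
}

#' Write a differential-regulation record table
#'
#' Mirrors the published table layout (`accession`, averages, log2 values,
#' z-scores, tiers, directions, fold changes). `digits = 2` gives the
#' 2-decimal table-compatible formatting; the default writes shortest-
#' representation full precision.
#'
#' @param records Records tibble from [silac_differential()] (or
#'   [tidy()] of its result).
#' @param path Output path.
#' @param digits Optional number of decimals for numeric columns.
#' @return `records`, invisibly.
#' @export
write_records <- function(records, path, digits = NULL) {
  out <- records
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) sprintf(paste0("%.", digits, "f"), x))
    out[num] <- lapply(out[num], function(x) ifelse(x == "NA", "", x))
  }
  readr::write_tsv(out, path, na = "")
  invisible(records)
}
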