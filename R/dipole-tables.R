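#' Path to a bundled dipole-table fixture
#'
#' The package ships the published per-molecule dipole tables for one coil of
#' the L-FF and D-FF diphenylalanine nanotubes (PM3-RHF and Amber variants)
#' and the single-molecule dipoles of the two enantiomers.
#'
#' @param file Fixture file name; with no argument, lists available fixtures.
#' @return Full path to the fixture (or a character vector of names).
#' @examples
#' helichir_fixture()
#' helichir_fixture("lff_pm3.tsv")
#' @export
helichir_fixture <- function(file = NULL) {
  dir <- system.file("extdata", package = "helichir")
  if (is.null(file)) return(list.files(dir, pattern = "\\.(tsv|pdb)$"))
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop_helichir(sprintf("no bundled fixture '%s'.", file), "io")
  }
  path
}

#' Read a per-molecule dipole table
#'
#' Reads the package's TSV dialect: '#'-prefixed metadata lines
#' (`# key=value`), one header row, then one row per molecule with columns
#' `i`, `Dx`, `Dy`, `Dz` and optionally `Di` and origin columns `ox`, `oy`,
#' `oz`. Both the ASCII hyphen and the Unicode minus (U+2212, as typeset in
#' published tables) are accepted as negative signs.
#'
#' Magnitudes are recomputed from the components. When a `Di` column is
#' present and disagrees with the recomputed norm by more than 0.002 Debye
#' (beyond printed-rounding error), a warning is raised and the offending
#' rows are recorded in the `magnitude_mismatch` attribute; the printed
#' values are kept in the `di_printed` column, never silently altered.
#'
#' @param path Path to a TSV dipole table.
#' @return A [coil_dipoles] tibble with `method`/`label` metadata.
#' @examples
#' read_dipole_table(helichir_fixture("dff_amber.tsv"))
#' @export
read_dipole_table <- function(path) {
  if (!file.exists(path)) {
    stop_helichir(sprintf("dipole table '%s' does not exist.", path), "io")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- gsub("\u2212", "-", lines, fixed = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  meta_lines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2) {
    stop_helichir(sprintf("'%s': no header or data rows.", path), "format")
  }
  meta <- parse_metadata(meta_lines)
  header <- tolower(trimws(strsplit(body[[1]], "\t", fixed = TRUE)[[1]]))
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad_width <- which(lengths(rows) != length(header))
  if (length(bad_width)) {
    stop_helichir(
      sprintf("'%s': row %d has %d fields, header has %d.", path,
              bad_width[[1]], lengths(rows)[bad_width[[1]]], length(header)),
      "format"
    )
  }
  cells <- do.call(rbind, rows)
  colnames(cells) <- header
  parsed <- matrix(NA_real_, nrow(cells), ncol(cells),
                   dimnames = dimnames(cells))
  for (j in seq_len(ncol(cells))) {
    vals <- suppressWarnings(as.numeric(trimws(cells[, j])))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop_helichir(
        sprintf("'%s': non-numeric value '%s' at row %d, column '%s'.",
                path, cells[bad[[1]], j], bad[[1]], header[[j]]),
        "format"
      )
    }
    parsed[, j] <- vals
  }
  df <- as_tibble(parsed)
  coil <- coil_dipoles(df, method = meta$method, label = meta$label)
  if ("di_printed" %in% names(coil)) {
    delta <- abs(coil$di_printed - coil$di)
    off <- which(delta > 0.002)
    if (length(off)) {
      attr(coil, "magnitude_mismatch") <- tibble(
        i = coil$i[off], di_printed = coil$di_printed[off],
        di_computed = coil$di[off], delta = delta[off]
      )
      warn(
        sprintf(paste0("'%s': printed magnitude disagrees with its own ",
                       "components at row(s) %s (max delta %.3f Debye); ",
                       "recomputed values are used."),
                basename(path), paste(coil$i[off], collapse = ", "),
                max(delta[off])),
        class = "helichir_magnitude_mismatch"
      )
    }
  }
  coil
}

parse_metadata <- function(meta_lines) {
  out <- list(method = NULL, label = NULL)
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      out[[key]] <- val
    }
  }
  out
}

#' Write a per-molecule dipole table
#'
#' Serializes a [coil_dipoles] object to the TSV dialect of
#' [read_dipole_table()] at full precision (17 significant digits), so that a
#' read/write round trip reproduces the coil bit-for-bit. A `di_printed`
#' column, when present, is written back as the `Di` column; otherwise the
#' recomputed magnitude is written.
#'
#' @param coil A [coil_dipoles] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dipole_table <- function(coil, path) {
  coil <- as_coil(coil)
  meta <- character(0)
  if (!is.null(attr(coil, "label"))) {
    meta <- c(meta, sprintf("# label=%s", attr(coil, "label")))
  }
  if (!is.null(attr(coil, "method"))) {
    meta <- c(meta, sprintf("# method=%s", attr(coil, "method")))
  }
  num <- function(x) sprintf("%.17g", x)
  di_out <- if ("di_printed" %in% names(coil)) coil$di_printed else coil$di
  cols <- list(i = as.character(coil$i), Dx = num(coil$dx),
               Dy = num(coil$dy), Dz = num(coil$dz), Di = num(di_out))
  if (all(c("ox", "oy", "oz") %in% names(coil))) {
    cols$ox <- num(coil$ox)
    cols$oy <- num(coil$oy)
    cols$oz <- num(coil$oz)
  }
  header <- paste(names(cols), collapse = "\t")
  body <- do.call(paste, c(unname(cols), sep = "\t"))
  ok <- tryCatch({
    writeLines(c(meta, header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    stop_helichir(sprintf("cannot write dipole table to '%s'.", path), "io")
  }
  invisible(path)
}
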