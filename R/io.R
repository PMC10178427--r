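#' Construct a Raman spectrum object
#'
#' @param wavenumbers Strictly increasing numeric axis (cm^-1).
#' @param intensities Numeric vector of the same length (arbitrary device units).
#' @param sample_id Sample identifier.
#' @param day Measurement day 0-7, or `NA` if unknown.
#' @param meta Free-form metadata list (e.g. `laser_nm`, `exposure_s`).
#' @return A `raman_spectrum`.
#' @export
new_spectrum <- function(wavenumbers, intensities, sample_id = NA_character_,
                         day = NA_integer_, meta = list()) {
  if (length(wavenumbers) != length(intensities))
    stop("format error: wavenumber and intensity vectors differ in length", call. = FALSE)
  if (any(!is.finite(wavenumbers)) || any(!is.finite(intensities)))
    stop("format error: non-finite values in spectrum", call. = FALSE)
  if (any(diff(wavenumbers) <= 0))
    stop("format error: wavenumbers must be strictly increasing", call. = FALSE)
  if (!is.na(day) && (day < 0 || day > 7))
    stop("validation error: day must be in 0..7", call. = FALSE)
  structure(
    list(wavenumbers = as.numeric(wavenumbers),
         intensities = as.numeric(intensities),
         sample_id = sample_id, day = day, meta = meta),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum: %d points, %.0f-%.0f cm^-1, sample %s, day %s\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              x$sample_id, ifelse(is.na(x$day), "?", x$day)))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Parses whitespace-delimited `wavenumber intensity` rows; lines beginning
#' with `#` are treated as comments (header metadata of the form
#' `# key: value` is collected into `meta`).
#'
#' @param path File path.
#' @return A `raman_spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("parse error: file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in lines[is_comment]) {
    mm <- regmatches(h, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(mm) == 3) meta[[trimws(mm[2])]] <- trimws(mm[3])
  }
  data_lines <- which(!is_comment & nzchar(trimws(lines)))
  parts <- strsplit(trimws(lines[data_lines]), "\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("parse error: line ", data_lines[bad[1]], " does not have two columns", call. = FALSE)
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  nn <- which(is.na(w) | is.na(y))
  if (length(nn))
    stop("parse error: non-numeric value at line ", data_lines[nn[1]], call. = FALSE)
  day <- if (!is.null(meta$day)) as.integer(meta$day) else NA_integer_
  sid <- if (!is.null(meta$sample_id)) meta$sample_id else NA_character_
  meta$day <- NULL
  meta$sample_id <- NULL
  new_spectrum(w, y, sample_id = sid, day = day, meta = meta)
}

#' Write a spectrum as a two-column text file
#'
#' Values are written with 10 significant digits, so a write/read round trip
#' is lossless well beyond instrument precision. `sample_id`, `day` and any
#' metadata are stored in `# key: value` header lines.
#'
#' @param spectrum A `raman_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  hdr <- character(0)
  if (!is.na(spectrum$sample_id)) hdr <- c(hdr, paste0("# sample_id: ", spectrum$sample_id))
  if (!is.na(spectrum$day)) hdr <- c(hdr, paste0("# day: ", spectrum$day))
  for (k in names(spectrum$meta))
    hdr <- c(hdr, sprintf("# %s: %s", k, format(spectrum$meta[[k]], digits = 10)))
  body <- sprintf("%.10g %.10g", spectrum$wavenumbers, spectrum$intensities)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a cohort to disk
#'
#' Writes one two-column spectrum file per row, a tab-separated manifest
#' (`spectrum_path`, `sample_id`, `day`, `severity`) and a JSON sidecar with
#' the generator provenance.
#'
#' @param cohort A `raman_cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "raman_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spectra"), showWarnings = FALSE)
  w <- wavenumbers(cohort)
  paths <- sprintf("spectra/spec_%04d.txt", seq_len(nrow(cohort)))
  for (i in seq_len(nrow(cohort))) {
    sp <- new_spectrum(w, cohort$intensity[[i]], sample_id = cohort$sample_id[i],
                       day = cohort$day[i], meta = list(severity = cohort$severity[i]))
    write_spectrum(sp, file.path(dir, paths[i]))
  }
  manifest <- tibble::tibble(
    spectrum_path = paths,
    sample_id = cohort$sample_id,
    day = cohort$day,
    severity = cohort$severity
  )
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- attr(cohort, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, file.path(dir, "generator.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(mpath)
}

#' Load a cohort manifest
#'
#' Reads a tab-separated manifest with columns `spectrum_path`, `sample_id`
#' and `day` (plus any extras such as `severity`), validates every record and
#' checks that each referenced spectrum file exists.
#'
#' @param path Manifest TSV path.
#' @param check_paths Verify that referenced spectrum files exist.
#' @return A tibble of manifest records (paths resolved relative to the
#'   manifest location).
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("resolution error: manifest not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("spectrum_path", "sample_id", "day")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: manifest lacks column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- tibble::as_tibble(df)
  if (nrow(df)) {
    if (any(df$day < 0 | df$day > 7 | df$day != floor(df$day)))
      stop("validation error: day values must be integers in 0..7", call. = FALSE)
    if (anyDuplicated(df$spectrum_path))
      stop("validation error: duplicate spectrum_path entries", call. = FALSE)
    df$spectrum_path <- file.path(dirname(path), df$spectrum_path)
    if (check_paths) {
      gone <- df$spectrum_path[!file.exists(df$spectrum_path)]
      if (length(gone))
        stop("resolution error: missing spectrum file(s): ",
             paste(utils::head(gone, 5), collapse = ", "), call. = FALSE)
    }
  }
  df$day <- as.integer(df$day)
  df
}

#' Read a cohort back from a manifest
#'
#' @param path Manifest TSV path (as written by [write_cohort()]).
#' @return A `raman_cohort` tibble.
#' @export
read_cohort <- function(path) {
  manifest <- load_manifest(path)
  spectra <- lapply(manifest$spectrum_path, read_spectrum)
  if (nrow(manifest) == 0) stop("data error: empty manifest", call. = FALSE)
  w <- spectra[[1]]$wavenumbers
  lens <- lengths(lapply(spectra, `[[`, "intensities"))
  if (length(unique(lens)) != 1)
    stop("shape error: spectra of unequal length in manifest", call. = FALSE)
  sev <- if ("severity" %in% names(manifest)) manifest$severity else
    vapply(spectra, function(s) {
      v <- suppressWarnings(as.numeric(s$meta$severity))
      if (length(v) == 1 && is.finite(v)) v else NA_real_
    }, numeric(1))
  out <- tibble::tibble(
    sample_id = manifest$sample_id,
    day = manifest$day,
    severity = sev,
    intensity = lapply(spectra, `[[`, "intensities")
  )
  new_cohort(out, wavenumbers = w,
             provenance = list(imported_from = path))
}

#' Import a matrix-layout CSV of spectra
#'
#' Permissive importer for external data stored as one spectrum per row: the
#' first column is a label (interpreted as the measurement day when integer
#' 0-7, otherwise kept as sample_id) and the remaining columns are
#' intensities. Wavenumbers are taken from numeric column headers when
#' present, otherwise an index grid is used.
#'
#' @param path CSV path.
#' @return A `raman_cohort` tibble.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("parse error: matrix CSV needs a label plus intensities", call. = FALSE)
  labels <- df[[1]]
  intens <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(intens) <- "double"
  hdr <- suppressWarnings(as.numeric(colnames(df)[-1]))
  w <- if (all(is.finite(hdr)) && all(diff(hdr) > 0)) hdr else seq_len(ncol(intens))
  day <- suppressWarnings(as.integer(labels))
  is_day <- !is.na(day) & day >= 0 & day <= 7
  out <- tibble::tibble(
    sample_id = if (all(is_day)) sprintf("R%03d", seq_len(nrow(intens))) else as.character(labels),
    day = ifelse(is_day, day, NA_integer_),
    severity = NA_real_,
    intensity = lapply(seq_len(nrow(intens)), function(i) unname(intens[i, ]))
  )
  new_cohort(out, wavenumbers = w, provenance = list(imported_from = path))
}
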