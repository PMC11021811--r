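# File I/O: cohort tables, force-displacement curves, Raman spectra,
# pipeline configuration.

.required_cohort_cols <- c("animal_id", "population", "strain", "sex",
                           "body_mass")

#' Read a cohort table from CSV
#'
#' The cohort CSV schema is one row per animal with required columns
#' `animal_id`, `population`, `strain`, `sex`, `body_mass`; every other
#' column is treated as a trait. Empty cells and `NA` are read as missing
#' (never as zero). Unknown trait columns (not in the bundled
#' [trait_registry()]) are preserved with a warning.
#'
#' @param path CSV file path.
#' @return A `cohort_table` data frame.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  miss <- setdiff(.required_cohort_cols, names(tab))
  if (length(miss)) {
    stop("read_cohort: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$animal_id)) {
    stop("read_cohort: duplicate animal_id values", call. = FALSE)
  }
  bad_sex <- setdiff(unique(tab$sex[!is.na(tab$sex)]), c("F", "M"))
  if (length(bad_sex)) {
    stop("read_cohort: sex must be 'F' or 'M' (found: ",
         paste(bad_sex, collapse = ", "), ")", call. = FALSE)
  }
  if (any(tab$body_mass <= 0, na.rm = TRUE)) {
    stop("read_cohort: body_mass must be > 0", call. = FALSE)
  }
  traits <- setdiff(names(tab), .required_cohort_cols)
  reg <- tryCatch(trait_registry(), error = function(e) NULL)
  if (!is.null(reg)) {
    unknown <- setdiff(traits, reg$name)
    if (length(unknown)) {
      warning("read_cohort: columns not in the trait registry kept as ",
              "untyped traits: ", paste(unknown, collapse = ", "),
              call. = FALSE)
    }
  }
  structure(tab, class = c("cohort_table", "data.frame"))
}

#' Write a cohort table to CSV
#'
#' Missing values are written as empty cells.
#'
#' @param table Cohort table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a force-displacement curve from two-column CSV
#'
#' Expected columns `displacement_mm`, `force_N`; metadata may precede the
#' header as `# key: value` comment lines (recognized keys: `span`,
#' `preload`, `rate`, `id`).
#'
#' @param path CSV file path.
#' @return An [fd_curve()].
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(span = 7, preload = -0.1, rate = 0.1, id = NULL)
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+)$", ml))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta)) {
      v <- type.convert(m[3], as.is = TRUE)
      if (is.numeric(v)) v <- as.numeric(v)
      meta[[m[2]]] <- v
    }
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  need <- c("displacement_mm", "force_N")
  if (!all(need %in% names(tab))) {
    stop("read_curve: expected columns displacement_mm, force_N",
         call. = FALSE)
  }
  fd_curve(tab$displacement_mm, tab$force_N, span = meta$span,
           preload = meta$preload, rate = meta$rate, id = meta$id)
}

#' Write a force-displacement curve to CSV
#'
#' @param curve An [fd_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# span: %g", curve$meta$span), con)
  writeLines(sprintf("# preload: %g", curve$meta$preload), con)
  if (!is.null(curve$meta$id)) {
    writeLines(sprintf("# id: %s", curve$meta$id), con)
  }
  utils::write.csv(data.frame(displacement_mm = curve$displacement,
                              force_N = curve$force),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a Raman spectrum from two-column CSV
#'
#' Expected columns `wavenumber_cm1`, `intensity`; `# id: ...` comment
#' lines are honored.
#'
#' @param path CSV file path.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  id <- NULL
  m <- regmatches(lines, regexec("^#\\s*id\\s*:\\s*(.+)$", lines))
  hit <- which(lengths(m) == 2L)
  if (length(hit)) id <- m[[hit[1]]][2]
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  need <- c("wavenumber_cm1", "intensity")
  if (!all(need %in% names(tab))) {
    stop("read_spectrum: expected columns wavenumber_cm1, intensity",
         call. = FALSE)
  }
  raman_spectrum(tab$wavenumber_cm1, tab$intensity, id = id)
}

#' Write a Raman spectrum to CSV
#'
#' @param spectrum A [raman_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(spectrum$meta$id)) {
    writeLines(sprintf("# id: %s", spectrum$meta$id), con)
  }
  utils::write.csv(data.frame(wavenumber_cm1 = spectrum$wavenumber,
                              intensity = spectrum$intensity),
                   con, row.names = FALSE)
  invisible(path)
}
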