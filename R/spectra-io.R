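#' @include AllClasses.R utils.R
NULL

#' Read a spectrum from a two-column CSV file
#'
#' Expects numeric columns wavenumber (cm^-1) and absorbance (AU). Lines
#' starting with `#` are comments; a comment of the form `# label: <text>`
#' sets the spectrum label. Rows are sorted ascending in wavenumber;
#' duplicate wavenumbers are an error (they indicate a broken export, and
#' silently averaging would hide that).
#'
#' @param path file path.
#' @param sep field separator (default ",").
#' @return a [Spectrum-class].
#' @seealso [writeSpectrumCSV()], [readSpectrumJCAMP()]
#' @export
readSpectrumCSV <- function(path, sep = ",") {
  if (!file.exists(path)) .inputError("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  label <- ""
  isComment <- startsWith(trimws(lines), "#")
  lab <- grep("^#\\s*label:", trimws(lines), value = TRUE)
  if (length(lab))
    label <- trimws(sub("^#\\s*label:", "", lab[1]))
  data <- lines[!isComment]
  # tolerate a non-numeric header row
  if (length(data) && is.na(suppressWarnings(
      as.numeric(strsplit(data[1], sep, fixed = TRUE)[[1]][1]))))
    data <- data[-1]
  if (length(data) < 2L)
    .inputError(path, ": a spectrum needs at least 2 data rows")
  lineNos <- which(!isComment)
  parts <- strsplit(data, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad))
    .inputError(path, ": malformed row at line ", lineNos[bad[1]],
                " (need >= 2 columns)")
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
  a <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  badNum <- which(is.na(w) | is.na(a))
  if (length(badNum))
    .inputError(path, ": non-numeric value at line ", lineNos[badNum[1]])
  if (anyDuplicated(w))
    .inputError(path, ": duplicate wavenumber ",
                w[duplicated(w)][1], " (upstream export bug?)")
  Spectrum(w, a, label = label)
}

#' Write a spectrum to a two-column CSV file
#'
#' Values are written at full double precision (17 significant digits) so
#' that a read/write round trip is the identity. A non-empty label becomes a
#' `# label:` comment line.
#'
#' @param spectrum a [Spectrum-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeSpectrumCSV <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) .inputError("cannot write ", path, ": ",
                                                  conditionMessage(e)))
  on.exit(close(con))
  if (nzchar(spectrum@label))
    writeLines(paste0("# label: ", spectrum@label), con)
  writeLines("wavenumber,absorbance", con)
  writeLines(sprintf("%.17g,%.17g", spectrum@wavenumbers,
                     spectrum@absorbances), con)
  invisible(path)
}

#' Resample a spectrum onto a wavenumber grid by linear interpolation
#'
#' Components and mixture must share one wavenumber grid before fitting; this
#' interpolates linearly between measured points. Extrapolation is refused:
#' every grid point must lie within the spectrum's span.
#'
#' @param spectrum a [Spectrum-class].
#' @param grid numeric wavenumber vector (ascending or not; output follows
#'   the sorted grid).
#' @return a [Spectrum-class] on `grid`.
#' @export
resampleToGrid <- function(spectrum, grid) {
  stopifnot(is(spectrum, "Spectrum"))
  grid <- sort(as.numeric(grid))
  w <- spectrum@wavenumbers
  out <- grid[grid < min(w) - 1e-9 | grid > max(w) + 1e-9]
  if (length(out))
    .inputError("grid point ", out[1], " cm-1 lies outside the spectrum span [",
                min(w), ", ", max(w), "]; extrapolation is not supported")
  a <- stats::approx(w, spectrum@absorbances, xout = grid, rule = 2)$y
  Spectrum(grid, a, label = spectrum@label)
}

#' Common fitting grid for a mixture and a component library
#'
#' Returns the mixture's own wavenumber grid restricted to the intersection
#' of the spans of all spectra involved. Using the mixture's grid keeps the
#' measured mixture exact; restricting to the common span avoids
#' extrapolation of any reference.
#'
#' @param mixture a [Spectrum-class].
#' @param library a [ComponentLibrary-class].
#' @return numeric wavenumber vector.
#' @export
commonGrid <- function(mixture, library) {
  stopifnot(is(mixture, "Spectrum"), is(library, "ComponentLibrary"))
  lo <- max(vapply(library@components, function(r)
    max(vapply(r@spectra, function(s) min(s@wavenumbers), numeric(1))),
    numeric(1)))
  hi <- min(vapply(library@components, function(r)
    min(vapply(r@spectra, function(s) max(s@wavenumbers), numeric(1))),
    numeric(1)))
  g <- mixture@wavenumbers
  g <- g[g >= lo - 1e-9 & g <= hi + 1e-9]
  if (length(g) < 2L)
    .inputError("mixture and library wavenumber spans barely overlap (",
                length(g), " shared point(s))")
  g
}

#' Reference absorbance matrix of a library on a grid
#'
#' Builds the N x M matrix of unit-concentration reference absorbances used
#' by the Beer's-law model: each selected reference spectrum is resampled to
#' `grid` and divided by its reference concentration.
#'
#' @param library a [ComponentLibrary-class].
#' @param grid numeric wavenumber vector.
#' @param select `NULL` (use each component's first reference) or a numeric
#'   vector of expected concentrations; then the reference measured nearest
#'   each expected value is used, which absorbs mild Beer's-law deviations.
#' @return numeric matrix with one row per component (rownames set), plus an
#'   attribute `refConcs` recording which reference was selected.
#' @export
libraryMatrix <- function(library, grid, select = NULL) {
  stopifnot(is(library, "ComponentLibrary"))
  N <- length(library)
  if (!is.null(select) && length(select) != N)
    .inputError("select must have one value per component")
  A <- matrix(0, N, length(grid),
              dimnames = list(componentNames(library), NULL))
  used <- numeric(N)
  for (n in seq_len(N)) {
    rec <- library@components[[n]]
    k <- if (is.null(select)) 1L
         else which.min(abs(rec@refConcs - select[n]))
    used[n] <- rec@refConcs[k]
    s <- resampleToGrid(rec@spectra[[k]], grid)
    A[n, ] <- s@absorbances / rec@refConcs[k]
  }
  attr(A, "refConcs") <- used
  A
}

#' Read a component library from a directory
#'
#' Layout: one sub-directory per component, containing files named
#' `<name>@<refconc>.csv`, each a spectrum measured at that reference
#' concentration (percent).
#'
#' @param dir directory path.
#' @return a [ComponentLibrary-class]; components in alphabetical order.
#' @seealso [writeComponentLibrary()]
#' @export
readComponentLibrary <- function(dir) {
  if (!dir.exists(dir)) .inputError("no such library directory: ", dir)
  subs <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(subs)) .inputError(dir, " contains no component directories")
  recs <- lapply(subs, function(d) {
    files <- sort(list.files(d, pattern = "@.*\\.csv$", full.names = TRUE))
    if (!length(files))
      .inputError(d, " contains no '<name>@<refconc>.csv' files")
    conc <- as.numeric(sub(".*@([0-9.eE+-]+)\\.csv$", "\\1", files))
    if (anyNA(conc))
      .inputError("cannot parse reference concentration from: ",
                  files[which(is.na(conc))[1]])
    ComponentRecord(basename(d), lapply(files, readSpectrumCSV), conc)
  })
  ComponentLibrary(recs)
}

#' Write a component library to a directory
#'
#' @param library a [ComponentLibrary-class].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeComponentLibrary <- function(library, dir) {
  stopifnot(is(library, "ComponentLibrary"))
  for (rec in library@components) {
    d <- file.path(dir, rec@name)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(rec@refConcs))
      writeSpectrumCSV(rec@spectra[[k]],
                       file.path(d, sprintf("%s@%g.csv", rec@name,
                                            rec@refConcs[k])))
  }
  invisible(dir)
}
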