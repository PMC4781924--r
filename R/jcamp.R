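#' @include spectra-io.R
NULL

#' Read a spectrum from a JCAMP-DX file (AFFN dialect)
#'
#' Supports the common uncompressed `##XYDATA=(X++(Y..Y))` block with plain
#' AFFN numbers: each data line starts with an X value followed by Y values
#' at equal X increments. `##XFACTOR`/`##YFACTOR` are applied; the X grid is
#' reconstructed from `##FIRSTX`, `##LASTX` and `##NPOINTS` when present,
#' otherwise from the per-line X values and `##DELTAX`. Compressed encodings
#' (SQZ/DIF/DUP/PAC letter forms) are rejected with a clear message, as are
#' transmittance files, which must be converted to absorbance upstream.
#'
#' @param path file path.
#' @return a [Spectrum-class] in cm^-1 / absorbance units.
#' @export
readSpectrumJCAMP <- function(path) {
  if (!file.exists(path)) .inputError("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  getLdr <- function(name) {
    re <- paste0("^##", name, "\\s*=")
    hit <- grep(re, lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(re, "", hit[1], ignore.case = TRUE))
  }
  yunits <- getLdr("YUNITS")
  if (!is.null(yunits) && grepl("TRANSMIT", yunits, ignore.case = TRUE))
    .inputError(path, ": YUNITS is transmittance; convert to absorbance ",
                "(A = -log10(T)) before reading")
  xy <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  if (!length(xy))
    .inputError(path, ": no ##XYDATA record; not a supported JCAMP-DX file")
  form <- trimws(sub("^##XYDATA\\s*=", "", lines[xy[1]], ignore.case = TRUE))
  if (!grepl("\\(\\s*X\\+\\+\\(Y\\.\\.Y\\)\\s*\\)", form))
    .inputError(path, ": only XYDATA=(X++(Y..Y)) is supported, got: ", form)
  end <- grep("^##", lines)
  end <- end[end > xy[1]]
  stopLine <- if (length(end)) min(end) - 1L else length(lines)
  data <- lines[(xy[1] + 1L):stopLine]
  data <- data[nzchar(trimws(data))]
  if (!length(data)) .inputError(path, ": empty XYDATA block")
  if (any(grepl("[A-DF-Za-df-z%@]", gsub("[eE][+-]?[0-9]", "", data))))
    .inputError(path, ": compressed XYDATA encodings (SQZ/DIF/DUP) are not ",
                "supported; export in AFFN (PAC) form")
  xfac <- as.numeric(getLdr("XFACTOR") %||% "1")
  yfac <- as.numeric(getLdr("YFACTOR") %||% "1")
  toks <- lapply(data, function(l)
    as.numeric(strsplit(trimws(l), "[,;[:space:]]+")[[1]]))
  if (anyNA(unlist(toks)))
    .inputError(path, ": non-numeric token in XYDATA block")
  lineX <- vapply(toks, `[`, numeric(1), 1L) * xfac
  ys <- unlist(lapply(toks, `[`, -1L)) * yfac
  npt <- length(ys)
  if (npt < 2L) .inputError(path, ": fewer than 2 data points")
  firstx <- as.numeric(getLdr("FIRSTX") %||% lineX[1])
  nominal <- as.numeric(getLdr("NPOINTS") %||% npt)
  if (nominal != npt)
    warning(path, ": NPOINTS=", nominal, " but ", npt, " Y values found",
            call. = FALSE)
  lastx <- getLdr("LASTX")
  dx <- if (!is.null(lastx)) (as.numeric(lastx) - firstx) / (npt - 1)
        else as.numeric(getLdr("DELTAX") %||%
               stop(path, ": need LASTX or DELTAX to space the Y values",
                    call. = FALSE))
  Spectrum(firstx + dx * (seq_len(npt) - 1L), ys,
           label = getLdr("TITLE") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
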