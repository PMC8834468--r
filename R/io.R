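#' Write / read spectra as a comma-separated table
#'
#' Dialect: first column `sample_id`, remaining columns headed by the
#' wavenumber values in descending order. Segment gaps are implicit in the
#' header (a jump larger than one step starts a new segment) and are
#' reconstructed on read.
#'
#' @param x a [nir_spectra()].
#' @param path file path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a [nir_spectra()].
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "nir_spectra"))
  df <- data.frame(sample_id = x$meta$sample_id, stringsAsFactors = FALSE)
  ab <- x$absorbance
  colnames(ab) <- format(wavenumbers(x), trim = TRUE, scientific = FALSE)
  df <- cbind(df, as.data.frame(ab, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @param step_cm1 grid step; by default inferred as the most frequent
#'   header spacing.
#' @export
read_spectra_csv <- function(path, step_cm1 = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("spectra table needs a sample_id column and at ",
                         "least one wavenumber column")
  ids <- as.character(df[[1]])
  wn <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (anyNA(wn)) stop("non-numeric wavenumber headers: ",
                      paste(colnames(df)[-1][is.na(wn)], collapse = ", "))
  d <- diff(wn)
  if (any(d >= 0)) stop("wavenumber headers are not strictly descending")
  if (is.null(step_cm1)) {
    tab <- table(round(-d, 6))
    step_cm1 <- as.numeric(names(tab)[which.max(tab)])
  }
  mult <- -d / step_cm1
  if (any(abs(mult - round(mult)) > 1e-6)) {
    stop("non-uniform abscissa: header spacing is not a multiple of step ",
         step_cm1)
  }
  keep <- rep(TRUE, length(wn))
  regions <- .runs_to_regions(wn, keep, step_cm1)
  ab <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(ab) <- "double"
  rownames(ab) <- ids
  nir_spectra(ab, regions, data.frame(sample_id = ids,
                                      stringsAsFactors = FALSE))
}

#' Write / read a single spectrum in a JCAMP-DX subset
#'
#' Supports the fixed-abscissa `##XYDATA=(X++(Y..Y))` form with
#' `##FIRSTX`/`##LASTX`/`##DELTAX`/`##NPOINTS` and `##XFACTOR`/`##YFACTOR`,
#' descending X honoured. One spectrum per file; multi-block files and
#' compressed (DIF/DUP) ordinate forms are out of scope.
#'
#' @param y numeric absorbance vector.
#' @param wavenumbers descending, uniformly spaced wavenumbers (cm^-1).
#' @param path file path.
#' @param title value for `##TITLE`.
#' @return `write_jcamp` returns `path` invisibly. `read_jcamp` returns a
#'   list with `wavenumbers` and `absorbance`. The reader errors when a
#'   data-line X value is inconsistent with `##FIRSTX`/`##DELTAX`.
#' @export
write_jcamp <- function(y, wavenumbers, path, title = "spectrum") {
  stopifnot(is.numeric(y), is.numeric(wavenumbers),
            length(y) == length(wavenumbers), length(y) >= 2)
  d <- diff(wavenumbers)
  if (any(abs(d - d[1]) > 1e-6)) {
    stop("JCAMP-DX writer requires a single uniformly spaced segment")
  }
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    paste0("##FIRSTX=", format(wavenumbers[1], scientific = FALSE)),
    paste0("##LASTX=", format(wavenumbers[length(wavenumbers)],
                              scientific = FALSE)),
    paste0("##DELTAX=", format(d[1], scientific = FALSE)),
    "##XFACTOR=1",
    "##YFACTOR=1",
    paste0("##NPOINTS=", length(y)),
    "##XYDATA=(X++(Y..Y))")
  writeLines(hdr, con)
  per <- 4L
  for (i in seq(1, length(y), by = per)) {
    j <- min(i + per - 1L, length(y))
    writeLines(paste(c(format(wavenumbers[i], scientific = FALSE),
                       sprintf("%.12g", y[i:j])), collapse = " "), con)
  }
  writeLines("##END=", con)
  invisible(path)
}

#' @rdname write_jcamp
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name) {
    rx <- paste0("^##\\s*", name, "\\s*=")
    hit <- grep(rx, lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(rx, "", hit[1], ignore.case = TRUE))
  }
  firstx <- as.numeric(get_field("FIRSTX"))
  lastx <- as.numeric(get_field("LASTX"))
  deltax <- as.numeric(get_field("DELTAX"))
  npoints <- as.numeric(get_field("NPOINTS"))
  xf <- get_field("XFACTOR"); xf <- if (is.null(xf)) 1 else as.numeric(xf)
  yf <- get_field("YFACTOR"); yf <- if (is.null(yf)) 1 else as.numeric(yf)
  if (length(firstx) == 0 || length(deltax) == 0 || length(npoints) == 0) {
    stop("JCAMP file lacks FIRSTX/DELTAX/NPOINTS")
  }
  start <- grep("^##\\s*XYDATA", lines, ignore.case = TRUE)
  if (length(start) == 0) stop("JCAMP file lacks ##XYDATA")
  end <- grep("^##\\s*END", lines, ignore.case = TRUE)
  end <- end[end > start[1]]
  if (length(end) == 0) end <- length(lines) + 1
  body <- lines[seq(start[1] + 1, end[1] - 1)]
  body <- body[nzchar(trimws(body))]

  y <- numeric(0)
  for (ln in body) {
    toks <- as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    if (anyNA(toks)) stop("unparseable JCAMP data line: ", ln)
    xline <- toks[1] * xf
    expected <- firstx * xf + deltax * xf * length(y)
    if (abs(xline - expected) > 0.5 * abs(deltax * xf)) {
      stop("JCAMP data line X (", xline, ") inconsistent with ",
           "FIRSTX/DELTAX (expected ", expected, ")")
    }
    y <- c(y, toks[-1] * yf)
  }
  if (length(y) != npoints) {
    stop("JCAMP NPOINTS=", npoints, " but ", length(y), " ordinates read")
  }
  wn <- (firstx + deltax * (seq_len(npoints) - 1)) * xf
  if (length(lastx) == 1 && abs(wn[npoints] - lastx * xf) >
        0.5 * abs(deltax * xf)) {
    stop("JCAMP LASTX inconsistent with FIRSTX + (NPOINTS-1)*DELTAX")
  }
  list(wavenumbers = wn, absorbance = y)
}

#' Write / read a spectra set as a directory of JCAMP-DX files
#'
#' One file per sample, named `<sample_id>.jdx`. Requires a single
#' contiguous segment (the acquisition axis; exclusions are applied
#' downstream of file I/O).
#'
#' @param x a [nir_spectra()].
#' @param dir directory (created if missing).
#' @return `write_spectra_jcamp` returns `dir` invisibly;
#'   `read_spectra_jcamp` returns a [nir_spectra()].
#' @export
write_spectra_jcamp <- function(x, dir) {
  stopifnot(inherits(x, "nir_spectra"))
  if (length(x$regions$high) != 1) {
    stop("JCAMP-DX export requires a single contiguous segment")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wn <- wavenumbers(x)
  for (i in seq_len(nrow(x$absorbance))) {
    id <- x$meta$sample_id[i]
    write_jcamp(x$absorbance[i, ], wn, file.path(dir, paste0(id, ".jdx")),
                title = id)
  }
  invisible(dir)
}

#' @rdname write_spectra_jcamp
#' @param step_cm1 grid step used to validate the abscissa (default: from
#'   the files).
#' @export
read_spectra_jcamp <- function(dir, step_cm1 = NULL) {
  files <- sort(list.files(dir, pattern = "\\.jdx$", full.names = TRUE))
  if (length(files) == 0) stop("no .jdx files in ", dir)
  specs <- lapply(files, read_jcamp)
  wn <- specs[[1]]$wavenumbers
  for (s in specs[-1]) {
    if (length(s$wavenumbers) != length(wn) ||
        any(abs(s$wavenumbers - wn) > 1e-6)) {
      stop("JCAMP files in ", dir, " are not on a common grid")
    }
  }
  step <- if (is.null(step_cm1)) -diff(wn)[1] else step_cm1
  ab <- do.call(rbind, lapply(specs, `[[`, "absorbance"))
  ids <- sub("\\.jdx$", "", basename(files))
  rownames(ab) <- ids
  nir_spectra(ab, region_set(wn[1], wn[length(wn)], step),
              data.frame(sample_id = ids, stringsAsFactors = FALSE))
}

#' Read a per-sample reference table
#'
#' Expects a comma-separated table whose first column identifies the sample
#' (or fermentation day) and which contains the four analyte columns
#' `ethanol`, `tss`, `ta`, `tva` (case-insensitive; extra columns are kept).
#' All concentrations must be finite and non-negative.
#'
#' @param path file path.
#' @param sample_ids optional character vector; when given, rows are
#'   reordered to match and an error lists any missing ids.
#' @return A `data.frame` with a `sample_id` column and numeric analyte
#'   columns.
#' @export
read_references <- function(path, sample_ids = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("reference table ", path, " is empty")
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  lower <- tolower(names(df))
  for (an in c("ethanol", "tss", "ta", "tva")) {
    j <- which(lower == an)
    if (length(j) == 0) stop("reference table lacks a '", an, "' column")
    names(df)[j[1]] <- an
    df[[an]] <- as.numeric(df[[an]])
    if (anyNA(df[[an]])) stop("non-numeric values in '", an, "'")
    if (any(df[[an]] < 0)) {
      stop("negative concentration in '", an, "' (row ",
           which(df[[an]] < 0)[1], ")")
    }
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, df$sample_id)
    if (length(missing) > 0) {
      stop("reference table is missing samples: ",
           paste(head(missing, 10), collapse = ", "))
    }
    df <- df[match(sample_ids, df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
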