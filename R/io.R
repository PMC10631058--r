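# Dataset and image I/O.
#
# On-disk feature-table layout (the "Table S1" layout):
#   pot_id, replicate, time_point, drought_level, salinity_level,
#   then the feature columns by canonical name. Severity integers are
#   recovered from the level labels on load.

#' Write a feature table to disk
#'
#' @param table A [feature_table()].
#' @param path Output file path.
#' @param format `"csv"` or `"xlsx"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(table, path,
                          format = c("auto", "csv", "xlsx")) {
  stopifnot(inherits(table, "feature_table"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "xlsx") "xlsx" else "csv"
  feats <- attr(table, "features")
  out <- as.data.frame(table)[, c("pot_id", "replicate", "time_point",
                                  "drought_level", "salinity_level", feats)]
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    write_minimal_xlsx(out, path)
  }
  invisible(path)
}

#' Load a feature table from CSV or XLSX
#'
#' Validates the schema, maps level labels (`W0`..`W3`, `S0`..`S3`, or
#' bare integers 0..3) to severity integers, and drops rows containing
#' missing values with a reported count.
#'
#' @param path File path; format guessed from the extension unless given.
#' @param format `"auto"`, `"csv"` or `"xlsx"`.
#' @param features Feature columns expected; defaults to every canonical
#'   feature present in the file (at least one is required).
#' @return A [feature_table()]. The number of dropped rows is attached as
#'   attribute `dropped_rows`.
#' @export
load_dataset <- function(path, format = c("auto", "csv", "xlsx"),
                         features = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "xlsx") "xlsx" else "csv"
  df <- tryCatch(
    if (format == "csv") {
      utils::read.csv(path, stringsAsFactors = FALSE)
    } else {
      as.data.frame(readxl::read_excel(path))
    },
    error = function(e)
      stop("schema error: cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("schema error: empty dataset file: ", path)
  need <- c("pot_id", "replicate", "time_point",
            "drought_level", "salinity_level")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(features)) {
    features <- intersect(feature_names(), names(df))
    if (!length(features))
      features <- setdiff(names(df), need)
  }
  miss <- setdiff(features, names(df))
  if (length(miss))
    stop("schema error: missing feature column(s): ",
         paste(miss, collapse = ", "))

  df$drought <- parse_level(df$drought_level, "W")
  df$salinity <- parse_level(df$salinity_level, "S")
  for (f in features) df[[f]] <- suppressWarnings(as.numeric(df[[f]]))

  bad <- !stats::complete.cases(df[, c(need, "drought", "salinity", features)])
  if (any(bad)) {
    message(sum(bad), " row(s) with missing/malformed values dropped")
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("schema error: no valid rows in ", path)
  out <- feature_table(df, features = features)
  attr(out, "dropped_rows") <- sum(bad)
  out
}

# "W2"/"S2" -> 2; bare "2" -> 2; anything else -> NA (row gets dropped)
parse_level <- function(x, prefix) {
  x <- as.character(x)
  lab <- toupper(trimws(x))
  out <- suppressWarnings(as.integer(sub(paste0("^", prefix), "", lab)))
  plain <- suppressWarnings(as.integer(lab))
  out[is.na(out)] <- plain[is.na(out)]
  out[!(out %in% 0:3)] <- NA_integer_
  out
}

# Minimal XLSX writer ----------------------------------------------------
# Single-sheet OOXML workbook with inline strings; enough for readxl and
# spreadsheet apps. Numbers are written with full precision.

write_minimal_xlsx <- function(df, path) {
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'), file.path(tmp, "[Content_Types].xml"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(tmp, "_rels", ".rels"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="data" sheetId="1" r:id="rId1"/></sheets>',
    '</workbook>'), file.path(tmp, "xl", "workbook.xml"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>'), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  cell <- function(v) {
    if (is.na(v)) return("<c/>")
    if (is.numeric(v))
      sprintf("<c><v>%s</v></c>", format(v, digits = 15, scientific = FALSE))
    else
      sprintf('<c t="inlineStr"><is><t>%s</t></is></c>', esc(as.character(v)))
  }
  rows <- character(nrow(df) + 1L)
  rows[1L] <- paste0("<row>", paste(vapply(names(df), cell, ""),
                                    collapse = ""), "</row>")
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) cell(df[[j]][i]), "")
    rows[i + 1L] <- paste0("<row>", paste(cells, collapse = ""), "</row>")
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", rows, "</sheetData>", "</worksheet>"),
    file.path(tmp, "xl", "worksheets", "sheet1.xml"))

  if (file.exists(path)) unlink(path)
  zip::zipr(zipfile = path,
            files = c(file.path(tmp, "[Content_Types].xml"),
                      file.path(tmp, "_rels"),
                      file.path(tmp, "xl")),
            recurse = TRUE, include_directories = FALSE)
  invisible(path)
}

# Image I/O --------------------------------------------------------------

#' Read / write gray images
#'
#' Grayscale images are numeric matrices with an attached `range`
#' attribute giving the declared gray-level range (default `c(0, 255)`).
#' `read_image()` reads PNG (via the png package; RGB is converted with
#' [to_grayscale()]) or ASCII PGM (P2). `write_pgm()` writes the
#' plain-text PGM format used for fixtures; `write_image_png()` writes
#' PNG.
#'
#' @param path File path (.png or .pgm).
#' @return A numeric gray matrix with attribute `range`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    img <- if (length(dim(a)) == 3L) to_grayscale(a * 255) else a * 255
    return(gray_image(round(img), range = c(0, 255)))
  }
  stop("format error: unsupported image extension: ", ext)
}

#' @rdname read_image
#' @param img Gray matrix.
#' @param maxval Maximum gray value written to the PGM header.
#' @export
write_pgm <- function(img, path, maxval = 255) {
  img <- round(img)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  write(t(img), file = con, ncolumns = ncol(img))
  invisible(path)
}

#' @rdname read_image
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("format error: only ASCII PGM (P2) supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.integer(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("format error: corrupt PGM: ", path)
  gray_image(matrix(vals, nrow = h, ncol = w, byrow = TRUE),
             range = c(0, maxval))
}

#' @rdname read_image
#' @export
write_image_png <- function(img, path) {
  rng <- attr(img, "range") %||% c(0, 255)
  png::writePNG((unclass(img) - rng[1]) / (rng[2] - rng[1]), path)
  invisible(path)
}

gray_image <- function(m, range = c(0, 255)) {
  m <- as.matrix(m)
  attr(m, "range") <- range
  m
}
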