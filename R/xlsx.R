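# Minimal XLSX (SpreadsheetML) writer and reader.
#
# Writing: worksheets use inline strings and plain number cells, packed into
# an uncompressed (stored) ZIP container assembled byte by byte, with CRC-32
# computed in R.  Reading: the container is unpacked with utils::unzip and
# the sheet XML parsed with xml2.  Covers exactly what session export needs:
# tabular sheets of strings and numbers, full value fidelity.

.xlsx_env <- new.env(parent = emptyenv())

# CRC-32 table as 256 x 4 little-endian byte rows (polynomial 0xEDB88320)
.crc_table <- function() {
  if (!is.null(.xlsx_env$crc)) return(.xlsx_env$crc)
  poly <- c(0x20L, 0x83L, 0xB8L, 0xEDL)
  tab <- matrix(0L, 256, 4)
  for (n in 0:255) {
    b <- c(n, 0L, 0L, 0L)
    for (k in 1:8) {
      lsb <- b[1] %% 2L
      carry <- 0L
      for (i in 4:1) { v <- b[i] + carry * 256L; b[i] <- v %/% 2L; carry <- v %% 2L }
      if (lsb) b <- bitwXor(b, poly)
    }
    tab[n + 1L, ] <- b
  }
  .xlsx_env$crc <- tab
  tab
}

.crc32 <- function(bytes) {
  tab <- .crc_table()
  crc <- c(255L, 255L, 255L, 255L)
  for (byte in as.integer(bytes)) {
    idx <- bitwXor(crc[1], byte)
    crc <- bitwXor(c(crc[2], crc[3], crc[4], 0L), tab[idx + 1L, ])
  }
  bitwXor(crc, c(255L, 255L, 255L, 255L))
}

.u16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
.u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                             (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

# write a stored (uncompressed) ZIP archive; files: named list of raw vectors
.zip_store <- function(path, files) {
  locals <- list()
  centrals <- list()
  offset <- 0
  for (nm in names(files)) {
    data <- files[[nm]]
    name <- charToRaw(nm)
    crc <- as.raw(.crc32(data))
    n <- length(data)
    local <- c(.u32(0x04034b50), .u16(20), .u16(0), .u16(0), .u16(0x21), .u16(0x56),
               crc, .u32(n), .u32(n), .u16(length(name)), .u16(0), name, data)
    central <- c(.u32(0x02014b50), .u16(20), .u16(20), .u16(0), .u16(0),
                 .u16(0x21), .u16(0x56), crc, .u32(n), .u32(n),
                 .u16(length(name)), .u16(0), .u16(0), .u16(0), .u16(0),
                 .u32(0), .u32(offset), name)
    locals[[nm]] <- local
    centrals[[nm]] <- central
    offset <- offset + length(local)
  }
  cd <- do.call(c, centrals)
  eocd <- c(.u32(0x06054b50), .u16(0), .u16(0), .u16(length(files)),
            .u16(length(files)), .u32(length(cd)), .u32(offset), .u16(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(do.call(c, c(locals, list(cd, eocd))), con)
  invisible(path)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.col_letter <- function(i) {
  out <- ""
  while (i > 0) {
    r <- (i - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    i <- (i - 1) %/% 26
  }
  out
}

.sheet_xml <- function(df) {
  ncol_ <- ncol(df)
  header <- names(df)
  rows <- character(nrow(df) + 1L)
  cell <- function(r, ci, value) {
    ref <- paste0(.col_letter(ci), r)
    if (is.na(value) || !nzchar(value)) return("")
    if (grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", value))
      sprintf('<c r="%s"><v>%s</v></c>', ref, value)
    else
      sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
              ref, .xml_escape(value))
  }
  rows[1] <- paste0('<row r="1">',
                    paste(vapply(seq_len(ncol_), function(ci)
                      sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
                              .col_letter(ci), .xml_escape(header[ci])),
                      character(1)), collapse = ""),
                    "</row>")
  for (r in seq_len(nrow(df))) {
    cells <- vapply(seq_len(ncol_), function(ci) {
      v <- df[r, ci]
      cell(r + 1L, ci, if (is.na(v)) NA_character_ else as.character(v))
    }, character(1))
    rows[r + 1L] <- paste0(sprintf('<row r="%d">', r + 1L),
                           paste(cells, collapse = ""), "</row>")
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")
}

#' Write a workbook of data frames
#'
#' Writes a list of data frames as one XLSX workbook, one worksheet per
#' element, in list order.  Cells whose character representation is a number
#' are written as number cells; everything else as inline strings.  Values
#' are written exactly as their character representation, so a re-read
#' returns the same strings.
#'
#' @param sheets named list of data frames (names become sheet names).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_workbook()]
#' @export
write_workbook <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1L, !is.null(names(sheets)))
  n <- length(sheets)
  ct <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    "</Types>")
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>")
  wb <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>",
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  .xml_escape(names(sheets)), seq_len(n), seq_len(n)),
          collapse = ""),
    "</sheets></workbook>")
  wbrels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    "</Relationships>")
  files <- list("[Content_Types].xml" = charToRaw(ct),
                "_rels/.rels" = charToRaw(rels),
                "xl/workbook.xml" = charToRaw(wb),
                "xl/_rels/workbook.xml.rels" = charToRaw(wbrels))
  for (i in seq_len(n)) {
    files[[sprintf("xl/worksheets/sheet%d.xml", i)]] <-
      charToRaw(.sheet_xml(sheets[[i]]))
  }
  .zip_store(path, files)
}

.cell_col <- function(ref) {
  letters_ <- gsub("[0-9]", "", ref)
  sum(vapply(seq_len(nchar(letters_)), function(i)
    (utf8ToInt(substr(letters_, i, i)) - 64L) * 26^(nchar(letters_) - i),
    numeric(1)))
}

#' Read a workbook written by [write_workbook()]
#'
#' Returns all worksheets as character data frames (first row taken as
#' header), preserving every cell's text exactly as stored.
#'
#' @param path an XLSX file.
#' @return named list of data frames of character columns.
#' @export
read_workbook <- function(path) {
  exdir <- tempfile("xlsx")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  utils::unzip(path, exdir = exdir)
  wb <- xml2::read_xml(file.path(exdir, "xl", "workbook.xml"))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(wb), d1 = "m")
  sheet_nodes <- xml2::xml_find_all(wb, ".//m:sheet", ns)
  sheet_names <- xml2::xml_attr(sheet_nodes, "name")
  out <- vector("list", length(sheet_names))
  names(out) <- sheet_names
  for (i in seq_along(sheet_names)) {
    sx <- xml2::read_xml(file.path(exdir, "xl", "worksheets",
                                   sprintf("sheet%d.xml", i)))
    nsx <- xml2::xml_ns_rename(xml2::xml_ns(sx), d1 = "m")
    rows <- xml2::xml_find_all(sx, ".//m:row", nsx)
    mat <- list()
    maxcol <- 0L
    for (rn in rows) {
      r <- as.integer(xml2::xml_attr(rn, "r"))
      cells <- xml2::xml_find_all(rn, "./m:c", nsx)
      vals <- list()
      for (cn in cells) {
        ci <- .cell_col(xml2::xml_attr(cn, "r"))
        maxcol <- max(maxcol, ci)
        txt <- if (identical(xml2::xml_attr(cn, "t"), "inlineStr"))
          xml2::xml_text(xml2::xml_find_first(cn, "./m:is/m:t", nsx))
        else
          xml2::xml_text(xml2::xml_find_first(cn, "./m:v", nsx))
        vals[[as.character(ci)]] <- txt
      }
      mat[[as.character(r)]] <- vals
    }
    nr <- if (length(mat)) max(as.integer(names(mat))) else 0L
    grid <- matrix(NA_character_, nrow = nr, ncol = maxcol)
    for (r in names(mat)) for (ci in names(mat[[r]]))
      grid[as.integer(r), as.integer(ci)] <- mat[[r]][[ci]]
    if (nr < 1L) { out[[i]] <- data.frame(); next }
    header <- grid[1, ]
    body <- grid[-1, , drop = FALSE]
    df <- as.data.frame(body, stringsAsFactors = FALSE)
    names(df) <- header
    out[[i]] <- df
  }
  out
}
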