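#' Read a single-band ESRI ASCII grid
#'
#' @param path file path.
#' @return list with `matrix` (rows = north to south), `xll`, `yll`,
#'   `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  list(matrix = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}

#' Write a single-band ESRI ASCII grid
#'
#' @param m numeric matrix, rows ordered north to south.
#' @param path output path.
#' @param xll,yll lower-left corner coordinates in degrees.
#' @param cellsize cell size in degrees.
#' @param nodata value used for `NA` cells.
#' @export
write_ascii_grid <- function(m, path, xll, yll, cellsize, nodata = -9999) {
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", xll), paste("yllcorner", yll),
           paste("cellsize", cellsize), paste("NODATA_value", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
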