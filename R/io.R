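#' Read a grayscale image
#'
#' Supports PNG, TIFF and PGM (plain `P2` or binary `P5`), dispatched on the
#' file extension. 8-bit (and 16-bit) integer data are scaled to `[0, 1]`;
#' float TIFF passes through. RGB input is refused: the pipeline is defined
#' on single-channel images.
#'
#' @param path File path ending in `.png`, `.tif(f)` or `.pgm`.
#' @return Numeric matrix with intensities in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = read_pgm(path),
    abort(sprintf("unsupported image extension '.%s' (use png/tif/tiff/pgm).",
                  ext))
  )
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 2) {
      img <- img[, , 1]  # gray + alpha: drop alpha
    } else {
      abort("multi-channel (RGB) images are not supported; supply grayscale.")
    }
  }
  check_image(img)
  clamp01(img)
}

#' Write a grayscale image
#'
#' PNG is written as 8-bit, TIFF as 16-bit; intensities are clipped to
#' `[0, 1]` and scaled on write, so a write/read round trip preserves values
#' to the quantization step of the chosen bit depth. PGM is written as plain
#' `P2` at 8 bits.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Destination path; format from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_image(img)
  img <- clamp01(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    pgm = write_pgm(img, path),
    abort(sprintf("unsupported image extension '.%s'.", ext))
  )
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) abort("not a PGM file (magic must be P2/P5).")
  # header tokens (width, height, maxval), skipping comments
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0) abort("truncated PGM header.")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nchar(paste(buf, collapse = "")) > 0) {
        tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (magic == "P5") {
    if (maxval > 255) abort("16-bit binary PGM is not supported.")
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  vals <- round(clamp01(img) * 255)
  con <- file(path, "wb")  # binary mode for LF-only line endings
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255",
               apply(vals, 1, paste, collapse = " ")),
             con, sep = "\n")
  invisible(path)
}

#' Read a boundary point list from CSV
#'
#' The CSV dialect is `row,col` with a header, 0-based integer pixel
#' coordinates and LF line endings; coordinates are converted to the 1-based
#' convention used throughout the package.
#'
#' @param path CSV file path.
#' @return Tibble with 1-based `row`, `col` columns.
#' @export
read_boundary <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(df))) {
    abort("boundary CSV must have `row` and `col` columns.")
  }
  tibble::tibble(row = df$row + 1, col = df$col + 1)
}

#' Write a boundary point list to CSV
#'
#' Inverse of [read_boundary()]: 1-based package coordinates are written
#' 0-based with a `row,col` header and LF line endings.
#'
#' @param points Data frame with `row`, `col` (1-based).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_boundary <- function(points, path) {
  check_points(points)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("row,col",
               paste(points$row - 1, points$col - 1, sep = ",")),
             con, sep = "\n")
  invisible(path)
}
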