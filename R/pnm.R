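# Portable pixmap (netpbm) image I/O.
#
# The package stores synthetic and augmented images as binary PPM (P6, 8-bit
# RGB). PPM is the one raster format readable and writable from base R without
# a compiled codec; every mainstream image tool converts to and from it.

#' Write an RGB image as binary PPM (P6)
#'
#' @param img numeric array `H x W x 3`, intensities in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path) {
  ovqa_assert(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3,
              "`img` must be an H x W x 3 array")
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- as.integer(round(pmin(pmax(img, 0), 255)))
  # PPM is row-major, channel-interleaved; R arrays are column-major.
  inter <- array(0L, dim = c(3, w, h))
  for (c in 1:3) inter[c, , ] <- t(matrix(px[(1:(h * w)) + (c - 1) * h * w], h, w))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(w, h), "255"), con, sep = "\n")
  writeBin(as.raw(as.vector(inter)), con)
  invisible(path)
}

#' Read a binary PPM (P6) image
#'
#' @param path file path.
#' @return numeric array `H x W x 3` with intensities in `[0, 255]`.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || nchar(ch) == 0) break
      if (ch == "#") { # comment runs to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("^[ \t\r\n]$", ch)) {
        if (length(tok) > 0) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  ovqa_assert(identical(magic, "P6"), sprintf("not a binary PPM (magic '%s')", magic),
              class = "parse_error")
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  ovqa_assert(is.finite(w) && is.finite(h) && w >= 1 && h >= 1,
              "corrupt PPM header", class = "parse_error")
  ovqa_assert(maxval == 255, "only 8-bit PPM supported", class = "parse_error")
  raw <- readBin(con, "raw", n = 3L * w * h)
  ovqa_assert(length(raw) == 3L * w * h, "truncated PPM payload", class = "parse_error")
  inter <- array(as.integer(raw), dim = c(3, w, h))
  img <- array(0, dim = c(h, w, 3))
  for (c in 1:3) img[, , c] <- t(inter[c, , ])
  img
}
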