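# Foreground-focused image preprocessing: intensity normalization, Otsu
# thresholding with an intensity floor, binary morphological opening with a
# 40 x 40 rectangle, foreground bounding box, and bilinear resize to 448 x 448.

#' Rescale image intensities to the 0-255 range
#'
#' Linear min-max rescale per image (all channels jointly, preserving colour
#' balance). A constant image maps to all zeros.
#'
#' @param img numeric array `H x W x 3` or matrix `H x W`.
#' @return same shape, values in `[0, 255]`.
#' @export
normalize_intensity <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] < .Machine$double.eps) return(img * 0)
  (img - rng[1]) / (rng[2] - rng[1]) * 255
}

# Rec. 601 luminance; the grayscale map used ahead of thresholding.
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Otsu threshold with an intensity floor
#'
#' Maximizes the between-class variance over the 256 integer thresholds of the
#' normalized grayscale histogram and returns the maximum of that level and
#' `floor`. The floor encodes the preprocessing rule that near-black pixels
#' (intensity <= 5) are always background; it also defines the value returned
#' for constant images, where no variance can be maximized.
#'
#' @param img image array or grayscale matrix with intensities in `[0, 255]`.
#' @param floor minimum returned threshold (default 5).
#' @return integer threshold in `[floor, 255]`; pixels with gray value
#'   strictly greater than it are foreground.
#' @export
otsu_threshold <- function(img, floor = 5) {
  g <- pmin(pmax(round(rgb_to_gray(img)), 0), 255)
  counts <- tabulate(as.vector(g) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)                  # class-0 mass for threshold t = level
  mu <- cumsum(p * (0:255))           # class-0 first moment
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, Inf)
  if (!any(is.finite(sigma_b) & denom > 0)) return(as.integer(floor))
  t <- which.max(sigma_b) - 1L        # level in 0..255
  as.integer(max(t, floor))
}

# ---- binary morphology with a rectangular structuring element ---------------
# Erosion/dilation via 2-D integral-image box sums: a pixel survives erosion
# iff its (sh x sw) window contains sh*sw foreground pixels; dilation iff the
# window contains any. Out-of-frame pixels count as background, so components
# touching the border erode like interior ones.

box_counts <- function(mask, sh, sw) {
  h <- nrow(mask); w <- ncol(mask)
  up <- (sh - 1L) %/% 2L; down <- sh - 1L - up
  left <- (sw - 1L) %/% 2L; right <- sw - 1L - left
  ii <- matrix(0, h + 1L, w + 1L)
  ii[-1L, -1L] <- apply(apply(mask * 1, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(h) - up, 1L); r2 <- pmin(seq_len(h) + down, h)
  c1 <- pmax(seq_len(w) - left, 1L); c2 <- pmin(seq_len(w) + right, w)
  ii[r2 + 1L, c2 + 1L] - ii[r1, c2 + 1L] - ii[r2 + 1L, c1] + ii[r1, c1]
}

binary_erode <- function(mask, sh, sw) box_counts(mask, sh, sw) == sh * sw

binary_dilate <- function(mask, sh, sw) box_counts(mask, sh, sw) > 0

#' Morphological opening with a rectangular structuring element
#'
#' Erosion followed by dilation; removes every foreground component strictly
#' smaller than the `sh x sw` rectangle.
#'
#' @param mask logical matrix.
#' @param sh,sw structuring element height and width (default 40 x 40).
#' @return logical matrix of the same shape.
#' @export
binary_opening <- function(mask, sh = 40L, sw = 40L) {
  eroded <- binary_erode(mask, sh, sw)
  # dilation must use the reflected anchor so opening is the union of all
  # SE translates contained in the mask; for the centred even-size anchor
  # used here that means swapping the up/down and left/right margins.
  up <- (sh - 1L) %/% 2L; down <- sh - 1L - up
  left <- (sw - 1L) %/% 2L; right <- sw - 1L - left
  h <- nrow(mask); w <- ncol(mask)
  ii <- matrix(0, h + 1L, w + 1L)
  ii[-1L, -1L] <- apply(apply(eroded * 1, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(h) - down, 1L); r2 <- pmin(seq_len(h) + up, h)
  c1 <- pmax(seq_len(w) - right, 1L); c2 <- pmin(seq_len(w) + left, w)
  (ii[r2 + 1L, c2 + 1L] - ii[r1, c2 + 1L] - ii[r2 + 1L, c1] + ii[r1, c1]) > 0
}

#' Extract the foreground mask and bounding box
#'
#' Normalizes, converts to luminance, thresholds with [otsu_threshold()]
#' (floor 5), opens the binary mask with a 40 x 40 rectangle at the original
#' resolution, and takes the tightest bounding box over the surviving
#' foreground. An empty mask falls back to the full frame.
#'
#' @param img image array `H x W x 3` or grayscale matrix.
#' @param se_size structuring element side (default 40).
#' @return list with `mask` (logical matrix) and `bbox`
#'   `(row_min, col_min, row_max, col_max)`, half-open on the max side.
#' @export
extract_foreground_bbox <- function(img, se_size = 40L) {
  norm <- normalize_intensity(img)
  g <- rgb_to_gray(norm)
  thr <- otsu_threshold(norm)
  mask <- g > thr
  h <- nrow(g); w <- ncol(g)
  if (h >= se_size && w >= se_size) mask <- binary_opening(mask, se_size, se_size)
  else mask <- matrix(FALSE, h, w)   # SE larger than frame removes everything
  if (!any(mask)) {
    return(list(mask = mask, bbox = c(1L, 1L, h + 1L, w + 1L)))
  }
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  list(mask = mask,
       bbox = c(min(rows), min(cols), max(rows) + 1L, max(cols) + 1L))
}

#' Bilinear resize
#'
#' Half-pixel-centre sampling, so resizing to the input size is the exact
#' identity and integer downscales average the matching source blocks.
#'
#' @param img array `H x W x 3` or matrix.
#' @param out_h,out_w output dimensions.
#' @return resized image of the input's type.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  was_mat <- is.matrix(img)
  if (was_mat) img <- array(img, dim = c(dim(img), 1L))
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  sy <- h / out_h; sx <- w / out_w
  yc <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), h - 1)
  xc <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), w - 1)
  y0 <- floor(yc); x0 <- floor(xc)
  fy <- yc - y0; fx <- xc - x0
  y0 <- as.integer(y0) + 1L; x0 <- as.integer(x0) + 1L
  y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)
  out <- array(0, dim = c(out_h, out_w, nc))
  wy0 <- matrix(1 - fy, out_h, out_w); wx0 <- matrix(1 - fx, out_h, out_w, byrow = TRUE)
  for (c in seq_len(nc)) {
    ch <- img[, , c]
    out[, , c] <- ch[y0, x0] * wy0 * wx0 + ch[y0, x1] * wy0 * (1 - wx0) +
      ch[y1, x0] * (1 - wy0) * wx0 + ch[y1, x1] * (1 - wy0) * (1 - wx0)
  }
  if (was_mat) out[, , 1] else out
}

#' Foreground-focused preprocessing to the network input size
#'
#' Normalize, find the foreground bounding box, crop to it (full frame if the
#' box is degenerate), and bilinearly resize to `size x size` (default 448).
#'
#' @param img image array `H x W x 3`.
#' @param size output side in pixels.
#' @return numeric array `size x size x 3`, intensities in `[0, 255]`.
#' @export
preprocess_image <- function(img, size = 448L) {
  norm <- normalize_intensity(img)
  fg <- extract_foreground_bbox(norm)
  b <- fg$bbox
  if (b[3] - b[1] < 1 || b[4] - b[2] < 1) b <- c(1L, 1L, nrow(norm) + 1L, ncol(norm) + 1L)
  cropped <- norm[b[1]:(b[3] - 1L), b[2]:(b[4] - 1L), , drop = FALSE]
  resize_bilinear(cropped, size, size)
}

#' Rotate an image by a small angle
#'
#' Expands the canvas to contain the rotated frame, inverse-maps with bilinear
#' interpolation (background filled with 0), then centre-crops back to the
#' original dimensions.
#'
#' @param img array `H x W x 3`.
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @return array `H x W x 3`.
#' @export
rotate_image <- function(img, angle_deg) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  th <- angle_deg * pi / 180
  ch_ <- abs(cos(th)); sh_ <- abs(sin(th))
  H2 <- ceiling(h * ch_ + w * sh_); W2 <- ceiling(w * ch_ + h * sh_)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  cy2 <- (H2 + 1) / 2; cx2 <- (W2 + 1) / 2
  yy <- matrix(seq_len(H2), H2, W2) - cy2
  xx <- matrix(seq_len(W2), H2, W2, byrow = TRUE) - cx2
  # inverse rotation of output coords into input frame
  sy <- cos(th) * yy - sin(th) * xx + cy
  sx <- sin(th) * yy + cos(th) * xx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  valid <- y0 >= 1 & x0 >= 1 & y0 < h & x0 < w
  y0v <- pmin(pmax(y0, 1), h - 1); x0v <- pmin(pmax(x0, 1), w - 1)
  out <- array(0, dim = c(H2, W2, nc))
  i00 <- cbind(as.vector(y0v), as.vector(x0v))
  for (c in seq_len(nc)) {
    chn <- img[, , c]
    v <- chn[i00] * (1 - fy) * (1 - fx) + chn[i00 + rep(c(0, 1), each = H2 * W2)] * (1 - fy) * fx +
      chn[i00 + rep(c(1, 0), each = H2 * W2)] * fy * (1 - fx) +
      chn[i00 + 1] * fy * fx
    v[!valid] <- 0
    out[, , c] <- v
  }
  r0 <- floor((H2 - h) / 2); c0 <- floor((W2 - w) / 2)
  out[r0 + seq_len(h), c0 + seq_len(w), , drop = FALSE]
}
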