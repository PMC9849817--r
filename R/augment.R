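# Five-operator image augmentation. One output per operator per input image:
# edge crop, small rotation, aspect rescale, additive Gaussian noise, and
# brightness scaling, each with its magnitude drawn from the published range.

#' Augmentation specification
#'
#' The default ranges are the published ones: edge crops drawn in
#' (0, 0.1)/(0.9, 1), brightness multiplier in (0.5, 1.5), aspect factor in
#' (0.8, 1.5), rotation angle in (3, 10) degrees, and zero-mean Gaussian noise
#' with variance 0.01 on unit-scaled intensities. Five variants per image.
#'
#' @param crop_lo,crop_hi fractional ranges for the low and high crop edges.
#' @param brightness brightness multiplier range.
#' @param ratio aspect rescale factor range.
#' @param rotation_deg rotation angle range in degrees.
#' @param noise_var Gaussian noise variance on `[0, 1]`-scaled intensities.
#' @param seed integer seed for the magnitude draws.
#' @export
aug_spec <- function(crop_lo = c(0, 0.1), crop_hi = c(0.9, 1),
                     brightness = c(0.5, 1.5), ratio = c(0.8, 1.5),
                     rotation_deg = c(3, 10), noise_var = 0.01, seed = 1L) {
  structure(list(crop_lo = crop_lo, crop_hi = crop_hi, brightness = brightness,
                 ratio = ratio, rotation_deg = rotation_deg,
                 noise_var = noise_var, seed = as.integer(seed)),
            class = "vqa_aug_spec")
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

#' Augment one image into five variants
#'
#' Applies each of the five operators once with freshly drawn magnitudes and
#' returns the variants plus a log of every draw. The input image is never
#' modified; augmentation only adds images.
#'
#' @param img numeric array `H x W x 3`, intensities in `[0, 255]`.
#' @param spec an [aug_spec()].
#' @return list with `images` (list of 5 arrays, named by operator) and
#'   `log` (named list of the drawn magnitudes).
#' @export
augment_image <- function(img, spec = aug_spec()) {
  ovqa_assert(is.array(img) && length(dim(img)) == 3, "`img` must be H x W x 3")
  h <- dim(img)[1]; w <- dim(img)[2]
  with_seed(spec$seed, {
    log <- list()
    out <- list()

    # (1) edge crop: keep [lo, hi) fraction along each axis
    lo_r <- runif1(spec$crop_lo); hi_r <- runif1(spec$crop_hi)
    lo_c <- runif1(spec$crop_lo); hi_c <- runif1(spec$crop_hi)
    r <- max(1L, floor(lo_r * h) + 1L):min(h, ceiling(hi_r * h))
    cc <- max(1L, floor(lo_c * w) + 1L):min(w, ceiling(hi_c * w))
    out$crop <- img[r, cc, , drop = FALSE]
    log$crop <- c(row_lo = lo_r, row_hi = hi_r, col_lo = lo_c, col_hi = hi_c)

    # (2) rotation
    ang <- runif1(spec$rotation_deg)
    out$rotation <- rotate_image(img, ang)
    log$rotation <- c(angle_deg = ang)

    # (3) aspect rescale: width scaled by the factor, height kept
    f <- runif1(spec$ratio)
    out$ratio <- resize_bilinear(img, h, max(1L, round(w * f)))
    log$ratio <- c(factor = f)

    # (4) additive Gaussian noise on [0,1]-scaled intensities, clipped
    noise <- array(stats::rnorm(length(img), 0, sqrt(spec$noise_var)), dim = dim(img))
    out$noise <- pmin(pmax(img / 255 + noise, 0), 1) * 255
    log$noise <- c(mean = 0, var = spec$noise_var)

    # (5) brightness multiplier, clipped to range
    b <- runif1(spec$brightness)
    out$brightness <- pmin(pmax(img * b, 0), 255)
    log$brightness <- c(factor = b)

    list(images = out, log = log)
  })
}

#' Augment every training image under a manifest
#'
#' Writes five PPM variants (`<id>_aug1..5.ppm`) per train-split image next to
#' a JSON draw log. Originals are left untouched.
#'
#' @param manifest a `vqa_manifest` whose records carry readable `image_path`s.
#' @param out_dir output directory.
#' @param seed integer seed; each image's draws derive from it and the image id.
#' @return invisible character vector of the written image paths.
#' @export
augment_corpus <- function(manifest, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  train <- Filter(function(r) r$split == "train", manifest$records)
  ids <- unique(vapply(train, `[[`, "", "image_id"))
  paths <- character(0)
  logs <- list()
  for (id in ids) {
    rec <- train[[match(id, vapply(train, `[[`, "", "image_id"))]]
    img <- read_ppm(rec$image_path)
    res <- augment_image(img, aug_spec(seed = derive_seed(seed, id)))
    for (j in seq_along(res$images)) {
      p <- file.path(out_dir, sprintf("%s_aug%d.ppm", id, j))
      write_ppm(res$images[[j]], p)
      paths <- c(paths, p)
    }
    logs[[id]] <- res$log
  }
  jsonlite::write_json(logs, file.path(out_dir, "augment_log.json"), auto_unbox = TRUE)
  invisible(paths)
}
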