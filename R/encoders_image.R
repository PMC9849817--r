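# Image encoder contracts and the feature-grid container.
#
# A registered backbone must emit exactly grid_side^2 positions of `channels`
# features for a preprocessed input; the pooled vector is the position-wise
# mean of the grid. The "tiny" stand-in is weight-free and deterministic, for
# tests and desk-scale training; "resnet152" is the randomly initialized
# reference architecture (shape contract); pretrained backbones plug in via
# [register_image_encoder()].

.encoder_registry <- new.env(parent = emptyenv())

#' Image encoder contract
#'
#' @param name backbone name (`"tiny"`, `"resnet152"`, or a registered one).
#' @param grid_side side of the square feature grid (positions P = grid_side^2).
#' @param channels output channels K (pooled vector length).
#' @param input_size expected preprocessed input side, or `NA` for any.
#' @param deterministic whether repeated calls with the same inputs and seed
#'   give identical features.
#' @return a `vqa_encoder_contract`.
#' @export
image_encoder_contract <- function(name = c("tiny", "resnet152"),
                                   grid_side = NULL, channels = NULL,
                                   input_size = NULL, deterministic = TRUE) {
  if (name[1] %in% c("tiny", "resnet152")) name <- match.arg(name)
  defaults <- switch(name,
    tiny = list(grid_side = 4L, channels = 32L, input_size = NA_integer_),
    resnet152 = list(grid_side = 14L, channels = 2048L, input_size = 448L),
    list(grid_side = grid_side, channels = channels, input_size = input_size %||% NA))
  structure(list(name = name,
                 grid_side = as.integer(grid_side %||% defaults$grid_side),
                 channels = as.integer(channels %||% defaults$channels),
                 input_size = defaults$input_size,
                 deterministic = deterministic),
            class = "vqa_encoder_contract")
}

#' Register a custom image backbone
#'
#' @param name backbone name used in configs.
#' @param fn `function(img, seed)` returning a `P' x K'` matrix or an
#'   `H x W x K'` array of raw backbone features; channels are unified to the
#'   contract's K by a seeded 1 x 1 convolution when `K' != K`.
#' @export
register_image_encoder <- function(name, fn) {
  assign(name, fn, envir = .encoder_registry)
  invisible(name)
}

# Weight-free deterministic patch featurizer: per-cell colour/texture moments
# expanded through a projection matrix derived from a fixed hash of the
# contract, independent of any user RNG state.
tiny_image_features <- function(img, grid_side, channels) {
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  h <- dim(img)[1]; w <- dim(img)[2]
  rb <- round(seq(0, h, length.out = grid_side + 1))
  cb <- round(seq(0, w, length.out = grid_side + 1))
  g <- rgb_to_gray(img)
  stats_mat <- matrix(0, grid_side^2, 8)
  p <- 0L
  for (i in seq_len(grid_side)) for (j in seq_len(grid_side)) {
    p <- p + 1L
    rr <- (rb[i] + 1):max(rb[i + 1], rb[i] + 1)
    cc <- (cb[j] + 1):max(cb[j + 1], cb[j] + 1)
    patch <- img[rr, cc, , drop = FALSE]
    gp <- g[rr, cc, drop = FALSE]
    stats_mat[p, ] <- c(mean(patch[, , 1]), mean(patch[, , 2]), mean(patch[, , 3]),
                        stats::sd(as.vector(gp)) %||% 0,
                        mean(gp), max(gp), min(gp), mean(abs(gp - mean(gp))))
  }
  stats_mat[is.na(stats_mat)] <- 0
  proj <- with_seed(derive_seed(20260909L, paste0("tiny_img", channels)),
                    matrix(stats::rnorm(8 * channels, sd = 1 / sqrt(8)), 8, channels))
  (stats_mat / 255) %*% proj
}

#' Encode an image into a feature grid
#'
#' Runs the contracted backbone, unifies channels with a seeded 1 x 1
#' convolution if needed, verifies the `(grid_side^2, K)` shape, and appends
#' the position-wise mean as the pooled K-vector.
#'
#' @param img preprocessed image array (`448 x 448 x 3` for the reference
#'   backbone).
#' @param contract an [image_encoder_contract()].
#' @param seed integer seed forwarded to stochastic backbones (weight draws).
#' @return a `vqa_feature_grid`: list with `grid` (`P x K` matrix), `pooled`
#'   (length-K vector), `grid_side`, `channels`.
#' @export
encode_image <- function(img, contract = image_encoder_contract("tiny"), seed = 1L) {
  raw <- if (exists(contract$name, envir = .encoder_registry)) {
    get(contract$name, envir = .encoder_registry)(img, seed)
  } else if (contract$name == "tiny") {
    tiny_image_features(img, contract$grid_side, contract$channels)
  } else if (contract$name == "resnet152") {
    ovqa_assert(all(dim(img)[1:2] == 448L),
                "the resnet152 contract expects a preprocessed 448 x 448 input",
                class = "contract_violation")
    resnet152_features(img, seed = seed)
  } else {
    ovqa_stop(sprintf("unknown image encoder '%s'", contract$name),
              class = "not_installed")
  }
  if (is.array(raw) && length(dim(raw)) == 3)
    raw <- matrix(raw, dim(raw)[1] * dim(raw)[2], dim(raw)[3])
  ovqa_assert(is.matrix(raw), "backbone must return a matrix or H x W x K array",
              class = "contract_violation")
  if (ncol(raw) != contract$channels) {
    # channel unification: seeded 1x1 convolution to the contracted K
    proj <- with_seed(derive_seed(seed, paste0("unify", contract$name)),
                      matrix(stats::rnorm(ncol(raw) * contract$channels,
                                          sd = 1 / sqrt(ncol(raw))),
                             ncol(raw), contract$channels))
    raw <- raw %*% proj
  }
  ovqa_assert(nrow(raw) == contract$grid_side^2 && ncol(raw) == contract$channels,
              sprintf("backbone emitted %d x %d, contract requires %d x %d",
                      nrow(raw), ncol(raw), contract$grid_side^2, contract$channels),
              class = "contract_violation")
  structure(list(grid = raw, pooled = colMeans(raw),
                 grid_side = contract$grid_side, channels = contract$channels),
            class = "vqa_feature_grid")
}
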