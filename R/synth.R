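# Synthetic corpus generator.
#
# Emulates the field-collected triplet corpus at desk scale: leaf-coloured
# images bearing k elliptical lesions, two templated questions per image with
# ground truth derivable from the generation parameters, three answer
# annotations per non-test question, and a deterministic 4-candidate
# multiple-choice set per question.

LESION_PALETTE <- list(
  brown  = c(139, 69, 19),
  black  = c(35, 30, 25),
  yellow = c(200, 180, 40),
  orange = c(210, 120, 30)
)
CROP_LABELS <- c("litchi", "citrus", "longan", "grape")
QUADRANTS <- c("top left", "top right", "bottom left", "bottom right")

#' Synthetic corpus configuration
#'
#' @param n_images number of images to generate (>= 1).
#' @param image_size square image side in pixels.
#' @param lesion_count_range inclusive integer interval for the per-image
#'   lesion count k.
#' @param leaf_color background RGB triple.
#' @param lesion_palette named list of candidate lesion RGB triples; each image
#'   draws one (the colour name is the ground truth of colour questions).
#' @param type_mix named proportions over the four question types
#'   (`yesno`, `number`, `whatwhere`, `other`); must sum to 1.
#' @param seed integer seed; the whole corpus is a pure function of it.
#' @export
synth_config <- function(n_images, image_size = 96, lesion_count_range = c(0L, 5L),
                         leaf_color = c(34, 139, 34), lesion_palette = LESION_PALETTE,
                         type_mix = c(yesno = 0.25, number = 0.25,
                                      whatwhere = 0.25, other = 0.25),
                         seed = 1L) {
  ovqa_assert(n_images >= 1, "`n_images` must be >= 1")
  ovqa_assert(abs(sum(type_mix) - 1) < 1e-8, "`type_mix` must sum to 1")
  ovqa_assert(all(names(type_mix) %in% QUESTION_TYPES) && length(type_mix) == 4,
              "`type_mix` must name the four question types")
  ovqa_assert(length(lesion_count_range) == 2 && lesion_count_range[1] >= 0 &&
                lesion_count_range[1] <= lesion_count_range[2],
              "`lesion_count_range` must be a nonnegative integer interval")
  structure(list(n_images = as.integer(n_images), image_size = as.integer(image_size),
                 lesion_count_range = as.integer(lesion_count_range),
                 leaf_color = leaf_color, lesion_palette = lesion_palette,
                 type_mix = type_mix[QUESTION_TYPES], seed = as.integer(seed)),
            class = "vqa_synth_config")
}

# One image's generation parameters. Everything an answer can ask about is
# recoverable from this record.
draw_scene <- function(cfg, idx) {
  with_seed(derive_seed(cfg$seed, paste0("scene", idx)), {
    k <- sample(cfg$lesion_count_range[1]:cfg$lesion_count_range[2], 1L)
    sz <- cfg$image_size
    rmin <- max(2, sz %/% 20); rmax <- max(rmin + 1, sz %/% 8)
    lesions <- if (k > 0) lapply(seq_len(k), function(i) {
      ry <- sample(rmin:rmax, 1L); rx <- sample(rmin:rmax, 1L)
      list(cy = sample((ry + 1):(sz - ry), 1L), cx = sample((rx + 1):(sz - rx), 1L),
           ry = ry, rx = rx)
    }) else list()
    list(image_index = idx, k = k, lesions = lesions,
         lesion_color = sample(names(cfg$lesion_palette), 1L),
         crop = sample(CROP_LABELS, 1L))
  })
}

scene_quadrant <- function(scene, image_size) {
  if (scene$k == 0) return("nowhere")
  areas <- vapply(scene$lesions, function(l) l$ry * l$rx, 0)
  l <- scene$lesions[[which.max(areas)]]
  mid <- (image_size + 1) / 2
  paste(if (l$cy <= mid) "top" else "bottom", if (l$cx <= mid) "left" else "right")
}

SYNTH_TEMPLATES <- list(
  yesno = c("is the leaf diseased", "is there any lesion on the leaf"),
  number = c("how many lesions are on the leaf",
             "how many disease spots can you count"),
  whatwhere = c("what color are the lesions", "where is the largest lesion"),
  other = c("what kind of fruit tree is shown", "which crop is this leaf from")
)

#' Ground truth of a synthetic question
#'
#' Pure function of the stored scene parameters, so stored answers can be
#' re-derived and checked at any time.
#'
#' @param scene one scene entry from the manifest's `scenes` attribute.
#' @param question_type question type.
#' @param template integer template index within the type.
#' @param cfg the generating [synth_config()].
#' @return the ground-truth answer string.
#' @export
synthetic_ground_truth <- function(scene, question_type, template, cfg) {
  switch(question_type,
    yesno = if (scene$k > 0) "yes" else "no",
    number = as.character(scene$k),
    whatwhere = if (template == 1L) {
      if (scene$k > 0) scene$lesion_color else "none"
    } else scene_quadrant(scene, cfg$image_size),
    other = scene$crop,
    ovqa_stop(sprintf("unknown question_type '%s'", question_type)))
}

# Deterministic distractor policy: an in-type wrong-but-plausible answer.
# Annotations are c(truth, truth, distractor): two annotators agree on the
# truth, the third dissents, so the majority label is always the truth.
synth_distractor <- function(truth, question_type, template, cfg) {
  alts <- switch(question_type,
    yesno = c("yes", "no"),
    number = as.character(c(cfg$lesion_count_range[1]:cfg$lesion_count_range[2],
                            cfg$lesion_count_range[2] + 1L)),
    whatwhere = if (template == 1L) c(names(cfg$lesion_palette), "none")
                else c(QUADRANTS, "nowhere"),
    other = CROP_LABELS)
  alts <- setdiff(alts, truth)
  alts[1L]
}

synth_candidates <- function(truth, question_type, template, cfg, seed) {
  alts <- switch(question_type,
    yesno = c("yes", "no", "maybe", "cannot tell"),
    number = as.character(0:max(9, cfg$lesion_count_range[2] + 3L)),
    whatwhere = if (template == 1L) c(names(cfg$lesion_palette), "none", "green")
                else c(QUADRANTS, "nowhere", "center"),
    other = c(CROP_LABELS, "apple", "mango"))
  alts <- setdiff(alts, truth)
  with_seed(seed, sample(c(truth, sample(alts, 3L))))
}

#' Generate a synthetic triplet corpus
#'
#' Writes `cfg$n_images` PPM images under `file.path(dir, "images")` and
#' returns a manifest with two questions per image, three answer annotations
#' per non-test question, four multiple-choice candidates per question, and an
#' 8:1:1-style split. The generation parameters ("scenes") are attached as
#' `attr(manifest, "scenes")` and also written to `scenes.json` so ground
#' truth stays recoverable.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if missing).
#' @param split a [split_spec()]; defaults to floor(n/10) validation and test
#'   images, mirroring the published corpus's 8:1:1 division.
#' @return a `vqa_manifest` with `scenes` attribute.
#' @export
generate_synthetic_corpus <- function(cfg, dir,
                                      split = split_spec(cfg$n_images %/% 10L,
                                                         cfg$n_images %/% 10L,
                                                         seed = cfg$seed)) {
  img_dir <- file.path(dir, "images")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir))
    ovqa_stop(sprintf("cannot create image directory '%s'", img_dir), class = "io_error")
  ids <- sprintf("img_%05d", seq_len(cfg$n_images))
  scenes <- stats::setNames(lapply(seq_len(cfg$n_images), function(i) draw_scene(cfg, i)), ids)

  paths <- stats::setNames(file.path(img_dir, paste0(ids, ".ppm")), ids)
  for (id in ids) write_ppm(render_scene(scenes[[id]], cfg), paths[[id]])

  builder <- function(image_id, split_name) {
    scene <- scenes[[image_id]]
    qmeta <- with_seed(derive_seed(cfg$seed, paste0("questions", scene$image_index)), {
      types <- sample(QUESTION_TYPES, 2L, replace = TRUE, prob = cfg$type_mix)
      lapply(seq_len(2L), function(j)
        list(type = types[j],
             template = sample(seq_along(SYNTH_TEMPLATES[[types[j]]]), 1L)))
    })
    lapply(seq_len(2L), function(j) {
      qm <- qmeta[[j]]
      truth <- synthetic_ground_truth(scene, qm$type, qm$template, cfg)
      ans <- if (split_name == "test") character(0)
             else c(truth, truth, synth_distractor(truth, qm$type, qm$template, cfg))
      vqa_record(
        image_id = image_id, image_path = paths[[image_id]],
        question_id = sprintf("%s_q%d", image_id, j),
        question = SYNTH_TEMPLATES[[qm$type]][qm$template],
        question_type = qm$type, answers = ans,
        candidates = synth_candidates(
          truth, qm$type, qm$template, cfg,
          derive_seed(cfg$seed, paste0("cand", scene$image_index, j))),
        split = split_name)
    })
  }
  manifest <- build_manifest(ids, split, record_builder = builder)
  # question meta (type/template) is recoverable from the question text; stash
  # scenes for ground-truth re-derivation.
  attr(manifest, "scenes") <- scenes
  attr(manifest, "synth_config") <- cfg
  jsonlite::write_json(scenes, file.path(dir, "scenes.json"), auto_unbox = TRUE)
  write_manifest(manifest, file.path(dir, "manifest.jsonl"))
  manifest
}

# Render one scene: leaf-coloured background with mild seeded pixel noise and
# k filled ellipses in the scene's lesion colour.
render_scene <- function(scene, cfg) {
  sz <- cfg$image_size
  img <- with_seed(derive_seed(cfg$seed, paste0("pixels", scene$image_index)), {
    base <- array(0, dim = c(sz, sz, 3))
    for (c in 1:3) base[, , c] <- cfg$leaf_color[c] + rnorm(sz * sz, sd = 6)
    base
  })
  if (scene$k > 0) {
    col <- cfg$lesion_palette[[scene$lesion_color]]
    rows <- matrix(seq_len(sz), sz, sz)
    cols <- t(rows)
    for (l in scene$lesions) {
      inside <- ((rows - l$cy) / l$ry)^2 + ((cols - l$cx) / l$rx)^2 <= 1
      for (c in 1:3) {
        ch <- img[, , c]
        ch[inside] <- col[c]
        img[, , c] <- ch
      }
    }
  }
  pmin(pmax(img, 0), 255)
}

# Template index of a synthetic record's question (inverse of SYNTH_TEMPLATES).
synth_template_of <- function(record) {
  match(record$question, SYNTH_TEMPLATES[[record$question_type]])
}
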