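# corpus: manifests, splits, vocabulary, synthetic generator, JSON-lines I/O

test_that("build_manifest reproduces the published split arithmetic", {
  ids <- sprintf("im%05d", 1:8450)
  m <- build_manifest(ids, split_spec(850, 850, seed = 3))
  sc <- m$split_counts
  expect_equal(sc$n_images[sc$split == "train"], 6750)
  expect_equal(sc$n_images[sc$split == "val"], 850)
  expect_equal(sc$n_images[sc$split == "test"], 850)
  expect_equal(sc$n_questions[sc$split == "train"], 13500)
  expect_equal(sc$n_answer_annotations[sc$split == "train"], 40500)
  expect_equal(sc$n_answer_annotations[sc$split == "test"], 0)
  # manifest-wide invariants
  expect_equal(sc$n_questions, 2L * sc$n_images)
  # partition: every id in exactly one split
  by_id <- tapply(vapply(m$records, `[[`, "", "split"),
                  vapply(m$records, `[[`, "", "image_id"),
                  function(s) length(unique(s)))
  expect_true(all(by_id == 1))
  expect_equal(length(unique(vapply(m$records, `[[`, "", "image_id"))), 8450)
})

test_that("build_manifest handles small remainders and rejects bad input", {
  m <- build_manifest(sprintf("i%02d", 1:10), split_spec(1, 1, seed = 1))
  expect_equal(m$split_counts$n_images[m$split_counts$split == "train"], 8)
  expect_error(build_manifest(character(0), split_spec(1, 1)),
               class = "orchardvqa_invalid_input")
  expect_error(build_manifest(c("a", "b"), split_spec(2, 1)),
               class = "orchardvqa_invalid_input")
  expect_error(build_manifest(c("a", "a", "b"), split_spec(1, 1)),
               class = "orchardvqa_invalid_input")
})

test_that("synthetic corpus enforces the triplet multiplicities", {
  fx <- make_tiny_corpus(n_images = 20, seed = 4, all_train = TRUE)
  m <- fx$manifest
  sc <- m$split_counts
  expect_equal(sc$n_questions[sc$split == "train"], 40)
  expect_equal(sc$n_answer_annotations[sc$split == "train"], 120)
  expect_true(all(vapply(m$records, function(r) length(r$answers) == 3, TRUE)))
  expect_true(all(vapply(m$records, function(r) length(r$candidates) == 4, TRUE)))
  # candidates contain the ground truth (majority label)
  expect_true(all(vapply(m$records, function(r)
    record_label(r) %in% r$candidates, TRUE)))
  expect_true(all(file.exists(vapply(m$records, `[[`, "", "image_path"))))
})

test_that("same seed yields byte-identical synthetic corpora", {
  root <- withr::local_tempdir()
  d <- file.path(root, "corpus")
  cfg <- synth_config(n_images = 8, image_size = 40, seed = 99)
  generate_synthetic_corpus(cfg, d)
  manifest1 <- readLines(file.path(d, "manifest.jsonl"))
  img1 <- readBin(file.path(d, "images", "img_00001.ppm"), "raw", 1e5)
  unlink(d, recursive = TRUE)
  generate_synthetic_corpus(cfg, d)   # same path, fresh run
  expect_identical(readLines(file.path(d, "manifest.jsonl")), manifest1)
  expect_identical(readBin(file.path(d, "images", "img_00001.ppm"), "raw", 1e5),
                   img1)
})

test_that("stored answers are re-derivable from the stored scene parameters", {
  fx <- make_tiny_corpus(n_images = 15, seed = 21)
  m <- fx$manifest
  scenes <- attr(m, "scenes")
  for (r in m$records) {
    if (r$split == "test") next
    tmpl <- orchardvqa:::synth_template_of(r)
    truth <- synthetic_ground_truth(scenes[[r$image_id]], r$question_type,
                                    tmpl, fx$cfg)
    expect_identical(record_label(r), truth)
  }
})

test_that("question types follow the configured mix", {
  # binomial bound: with p = 1/4 over 2n draws, each type count should be
  # within 3 sd of its expectation
  n <- 2000
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_images = n, image_size = 24, seed = 13)
  m <- generate_synthetic_corpus(cfg, dir, split = split_spec(0, 0, seed = 13))
  types <- vapply(m$records, `[[`, "", "question_type")
  draws <- 2 * n
  expected <- draws / 4
  tol <- 3 * sqrt(draws * 0.25 * 0.75)
  for (tp in c("yesno", "number", "whatwhere", "other"))
    expect_lt(abs(sum(types == tp) - expected), tol)
})

test_that("answer vocabulary is ordered train-first, first occurrence", {
  mk <- function(id, split, answers) vqa_record(
    image_id = id, question_id = paste0(id, "_q1"), question = "q",
    question_type = "other", answers = answers, split = split)
  recs <- list(mk("a", "train", c("yes", "no", "yes")),
               mk("b", "val", c("blue", "blue", "yes")),
               mk("c", "train", c("no", "no", "0")))
  m <- orchardvqa:::new_manifest(recs)
  expect_identical(build_answer_vocabulary(m), c("yes", "no", "0", "blue"))
  # vocabulary covers every non-test answer, and generator count answers
  fx <- make_tiny_corpus(n_images = 10, seed = 2)
  non_test <- unlist(lapply(Filter(function(r) r$split != "test",
                                   fx$manifest$records), `[[`, "answers"))
  expect_true(all(non_test %in% fx$manifest$answer_vocab))
})

test_that("manifest JSON-lines I/O is a faithful roundtrip", {
  fx <- make_tiny_corpus(n_images = 6, seed = 31)
  path <- file.path(fx$dir, "rt.jsonl")
  write_manifest(fx$manifest, path)
  back <- read_manifest(path)
  expect_identical(lapply(back$records, unclass),
                   lapply(fx$manifest$records, unclass))
  expect_identical(back$split_counts, fx$manifest$split_counts)
  expect_identical(back$answer_vocab, fx$manifest$answer_vocab)
})

test_that("manifest reader reports offending line numbers", {
  fx <- make_tiny_corpus(n_images = 3, seed = 5, all_train = TRUE)
  path <- file.path(fx$dir, "bad.jsonl")
  write_manifest(fx$manifest, path)
  lines <- readLines(path)
  lines[4] <- sub('"question_type":"[a-z]+"', '"question_type":"riddle"', lines[4])
  writeLines(lines, path)
  err <- expect_error(read_manifest(path), class = "orchardvqa_validation_error")
  expect_match(conditionMessage(err), "line 4")
  writeLines(c(lines[1], "{not json"), path)
  err2 <- expect_error(read_manifest(path), class = "orchardvqa_parse_error")
  expect_match(conditionMessage(err2), "line 2")
  # empty file -> empty manifest with zero counts
  writeLines(character(0), path)
  empty <- read_manifest(path)
  expect_length(empty$records, 0)
  expect_true(all(empty$split_counts$n_questions == 0))
})

test_that("record validation enforces the annotation invariants", {
  expect_error(vqa_record("i", question_id = "q", question = "x",
                          question_type = "yesno", answers = c("yes", "no"),
                          split = "train"),
               class = "orchardvqa_validation_error")
  expect_error(vqa_record("i", question_id = "q", question = "x",
                          question_type = "yesno", answers = "yes",
                          split = "test"),
               class = "orchardvqa_validation_error")
  # majority collapse with first-annotator tie-break
  expect_identical(orchardvqa:::collapse_answers(c("a", "b", "b")), "b")
  expect_identical(orchardvqa:::collapse_answers(c("c", "a", "b")), "c")
})
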