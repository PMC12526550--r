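make_manifest <- function(n_patients, imgs_per_patient = 3) {
  data.frame(
    image = sprintf("img_%03d", seq_len(n_patients * imgs_per_patient)),
    patient = rep(sprintf("pat_%03d", seq_len(n_patients)),
                  each = imgs_per_patient))
}

test_that("split_dataset is patient-disjoint with the stated fractions", {
  man <- make_manifest(100)
  sp <- split_dataset(man, seed = 1)
  pat_of <- function(ids) unique(man$patient[man$image %in% ids])
  expect_length(pat_of(sp$test), 20)
  expect_length(pat_of(sp$train), 56)
  expect_length(pat_of(sp$val), 24)
  expect_length(intersect(pat_of(sp$train), pat_of(sp$val)), 0)
  expect_length(intersect(pat_of(sp$train), pat_of(sp$test)), 0)
  expect_length(intersect(pat_of(sp$val), pat_of(sp$test)), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), man$image)
  # determinism and seed sensitivity
  expect_identical(sp, split_dataset(man, seed = 1))
  diffs <- vapply(1:20, function(s) {
    !identical(split_dataset(man, seed = s)$test, sp$test)
  }, logical(1))
  expect_true(any(diffs))
  bad <- man
  bad$patient[3] <- ""
  expect_error(split_dataset(bad), "patient")
})

test_that("horizontal flip mirrors normalised cx and keeps other fields", {
  sm <- cayolo:::generate_scene(scene_spec(preset = "easy"), seed = 2)
  p <- augment_params(hflip = 1, rotate = 0, scale = 0, translate = 0,
                      shear = 0, mosaic = 0, mixup = 0, copy_paste = 0)
  out <- augment(sm, p, seed = 1, pool = NULL)
  ord1 <- order(sm$boxes$cy, sm$boxes$cx)
  ord2 <- order(out$boxes$cy, out$boxes$cx)
  m1 <- sm$boxes[ord1, ]
  m2 <- out$boxes[ord2, ]
  # flipped set matches {1 - cx} with cy, w, h unchanged
  expect_equal(sort(m2$cx), sort(1 - m1$cx), tolerance = 1 / 256)
  expect_equal(sort(m2$cy), sort(m1$cy), tolerance = 1e-9)
  expect_equal(sort(m2$w), sort(m1$w), tolerance = 1e-9)
})

test_that("identity-parameter transform leaves image and boxes unchanged", {
  sm <- cayolo:::generate_scene(scene_spec(preset = "easy"), seed = 4)
  p <- augment_params(hflip = 0, rotate = 0, scale = 0, translate = 0,
                      shear = 0, mosaic = 0, mixup = 0, copy_paste = 0)
  out <- augment(sm, p, seed = 1)
  expect_identical(out$image, sm$image)
  expect_equal(out$boxes$cx, sm$boxes$cx, tolerance = 1e-9)
  expect_equal(out$boxes$w, sm$boxes$w, tolerance = 1e-9)
})

test_that("mosaic composes four images with boxes inside their quadrants", {
  spec <- scene_spec(preset = "easy", n_cells = c(1L, 1L), clue_fraction = 1)
  sms <- lapply(1:4, function(i) {
    cayolo:::generate_scene(spec, seed = 30 + i)
  })
  out <- cayolo:::mosaic4(sms, 256)
  expect_equal(nrow(out$boxes), 4)
  for (q in 1:4) {
    b0 <- sms[[q]]$boxes
    qr <- if (q <= 2) 0 else 128
    qc <- if (q %% 2 == 1) 0 else 128
    # recompute the expected transformed coordinates for this quadrant
    exp_x1 <- b0$x1 * 0.5 + qc
    exp_y1 <- b0$y1 * 0.5 + qr
    hit <- any(abs(out$boxes$x1 - exp_x1) < 1e-6 &
                 abs(out$boxes$y1 - exp_y1) < 1e-6)
    expect_true(hit)
    # and it lies within the quadrant's region
    inq <- out$boxes$x1 >= qc - 1e-9 & out$boxes$x2 <= qc + 128 + 1e-9 &
      out$boxes$y1 >= qr - 1e-9 & out$boxes$y2 <= qr + 128 + 1e-9
    expect_true(any(inq))
  }
})

test_that("augmentation never produces boxes outside the canvas", {
  spec <- scene_spec(preset = "easy")
  p <- augment_params()
  sms <- lapply(1:6, function(i) cayolo:::generate_scene(spec, seed = 50 + i))
  for (i in 1:20) {
    out <- augment(sms[[(i %% 6) + 1]], p, seed = 900 + i,
                   pool = sms[-((i %% 6) + 1)])
    b <- out$boxes
    if (nrow(b) == 0) next
    expect_true(all(b$cx - b$w / 2 >= -1e-9 & b$cx + b$w / 2 <= 1 + 1e-9))
    expect_true(all(b$cy - b$h / 2 >= -1e-9 & b$cy + b$h / 2 <= 1 + 1e-9))
  }
})

test_that("random_search returns the argmax with reproducible trials", {
  space <- search_space()
  # deterministic objective with a known unique optimum on the 75-point grid
  score <- function(cand) {
    -abs(log10(cand$learning_rate) + 3) - abs(cand$batch_size - 64) / 64 -
      abs(cand$weight_decay - 5e-4) * 100
  }
  r <- random_search(space, score, n_trials = 75, seed = 1)
  expect_equal(r$best$learning_rate, 0.001)
  expect_equal(r$best$batch_size, 64L)
  expect_equal(r$best$weight_decay, 5e-4)
  expect_equal(nrow(r$log), 75)
  # single-point space returns that point
  r1 <- random_search(list(learning_rate = 0.01), function(cand) 1,
                      n_trials = 5, seed = 1)
  expect_equal(r1$best$learning_rate, 0.01)
  # identical seed, identical trial sequence
  obj <- function(cand) cand$learning_rate * cand$batch_size
  ra <- random_search(space, obj, n_trials = 10, seed = 3)
  rb <- random_search(space, obj, n_trials = 10, seed = 3)
  expect_identical(ra$log, rb$log)
  # failing trials are logged and skipped
  rf <- random_search(space, function(cand) {
    if (cand$batch_size == 16) stop("boom") else 1
  }, n_trials = 75, seed = 2)
  expect_true(any(is.na(rf$log$f1)))
  expect_false(rf$best$batch_size == 16)
})

test_that("fit respects patience and returns the best-F1 checkpoint", {
  spec <- scene_spec(preset = "easy")
  ds <- generate_dataset(10, spec, seed = 60)
  m <- build_model(model_config(preset = "tiny", input_size = 128,
                                cam_positions = "P5"), seed = 1)
  p <- augment_params(hflip = 0, rotate = 0, scale = 0, translate = 0,
                      shear = 0, mosaic = 0, mixup = 0, copy_paste = 0)
  r <- fit(m, list(train = ds$samples[1:8], val = ds$samples[9:10]),
           epochs = 6, batch_size = 4, lr = 1e-3, patience = 0,
           use_augment = FALSE, aug = p, seed = 2)
  # patience 0: exactly one epoch beyond the best
  expect_equal(nrow(r$history), min(6, r$best_epoch + 1))
  expect_equal(r$best_f1, max(r$history$val_f1))
  expect_equal(r$history$val_f1[r$best_epoch], r$best_f1)
  expect_true(all(is.finite(r$history$train_loss)))
})
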