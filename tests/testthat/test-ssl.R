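test_that("scrambling yields one balanced counterpart per original window", {
  ws <- make_window_set(sprintf("P%02d", 1:10), 5)
  ds <- build_scrambled_dataset(ws, seed = 1)
  expect_equal(dim(ds$X), c(100L, 24L, 3L))
  expect_equal(sum(ds$y == 1), 50L)
  expect_equal(sum(ds$y == 0), 50L)
  # every scrambled sample has distinct donors; originals have identical ones
  scr <- ds$info[ds$info$label == 0, ]
  expect_true(all(scr$hr_donor != scr$steps_donor))
  orig <- ds$info[ds$info$label == 1, ]
  expect_true(all(orig$hr_donor == orig$steps_donor))
})

test_that("scrambling is deterministic under a fixed seed", {
  ws <- make_window_set(sprintf("P%02d", 1:6), 4, seed = 2)
  expect_identical(build_scrambled_dataset(ws, seed = 5),
                   build_scrambled_dataset(ws, seed = 5))
})

test_that("the pair mask is the donor union and is shared by both members", {
  ws <- make_window_set(c("A", "B"), 2, L = 12, seed = 3)
  ws$values[1, 1:3, 3] <- 1   # A window 1 missing minutes 1-3
  ws$values[3, 2:5, 3] <- 1   # B window 1 missing minutes 2-5
  ds <- build_scrambled_dataset(ws, seed = 4, time_match = TRUE)
  n <- nrow(ws$index)
  for (i in seq_len(n)) {
    donor_pid <- ds$info$steps_donor[n + i]
    # union mask must cover the original's own mask
    expect_true(all(ds$X[n + i, , 3] >= ws$values[i, , 3]))
    # identical mask on the original and scrambled member of the pair
    expect_identical(ds$X[i, , 3], ds$X[n + i, , 3])
    # value channels zero-filled under the mask
    expect_true(all(ds$X[n + i, ds$X[n + i, , 3] == 1, 1:2] == 0))
    expect_true(all(ds$X[i, ds$X[i, , 3] == 1, 1:2] == 0))
  }
})

test_that("scrambling requires two patients and available windows", {
  expect_error(build_scrambled_dataset(make_window_set("A", 4)),
               "at least 2 patients")
  ws <- make_window_set(c("A", "B"), 2, available = FALSE)
  expect_error(build_scrambled_dataset(ws), "no available windows")
})

test_that("step donors respect the 4-hour time-of-day bucket when possible", {
  # every patient has one window per 4-h bucket; encode the bucket as a
  # constant step value so the donor's bucket is readable from the sample
  ws <- make_window_set(sprintf("P%02d", 1:4), 6, seed = 5)
  bucket <- afwear:::window_bucket(ws$index$hour_of_day)
  for (w in seq_len(nrow(ws$index))) ws$values[w, , 2] <- bucket[w]
  ds <- build_scrambled_dataset(ws, seed = 6, time_match = TRUE)
  n <- nrow(ws$index)
  for (i in seq_len(n)) {
    donor_bucket <- ds$X[n + i, 1, 2]
    expect_equal(donor_bucket, bucket[i])
  }
})

test_that("fold training forbids leakage and embeds each patient once", {
  ws <- make_window_set(sprintf("P%02d", 1:10), 8, L = 24, seed = 7)
  # mark the first two windows of each patient as first-week (starts within
  # 7 days are all first-week here, so push later windows out by 8 days)
  later <- ws$index$window_index > 2
  ws$index$window_start[later] <- ws$index$window_start[later] + 8 * 86400
  sp <- cnn_spec(conv_filters = c(2, 2, 3), kernel_size = 3, batch_size = 16)
  fit <- train_discriminator(ws, sp, folds = 5, epochs = 2, patience = 2,
                             seed = 8)
  # no patient appears in both sets of its fold
  for (st in fit$states) {
    expect_length(intersect(st$train_patients, st$heldout_patients), 0)
  }
  # folds partition the patient set, ~20% held out each
  held <- unlist(lapply(fit$states, function(s) s$heldout_patients))
  expect_setequal(held, sprintf("P%02d", 1:10))
  expect_equal(anyDuplicated(held), 0L)
  fw <- split_first_week(ws)
  expect_equal(nrow(fw$first_week$index), 20L)
  emb <- ssl_oof_embeddings(fit, fw$first_week)
  expect_setequal(emb$patient_id, sprintf("P%02d", 1:10))
  expect_equal(anyDuplicated(emb$patient_id), 0L)
  expect_equal(sum(grepl("^e[0-9]+$", names(emb))), 3L)
  expect_true(all(is.finite(as.matrix(emb[, grepl("^e", names(emb))]))))
})

test_that("patient embeddings are means of window embeddings", {
  ws <- make_window_set(c("A", "B"), 3, L = 24, seed = 9)
  m <- build_cnn(cnn_spec(conv_filters = c(2, 2, 4), kernel_size = 3),
                 input_len = 24, seed = 10)
  emb <- embed_patient_first_week(m, ws)
  # duplicated identical windows: embedding equals the single-window one
  ws_dup <- ws
  ws_dup$values[2, , ] <- ws_dup$values[1, , ]
  ws_dup$values[3, , ] <- ws_dup$values[1, , ]
  emb_dup <- embed_patient_first_week(m, ws_dup)
  single <- cnn_embed(m, ws$values[1, , , drop = FALSE])
  expect_equal(as.numeric(emb_dup[emb_dup$patient_id == "A",
                                  paste0("e", 1:4)]),
               as.numeric(single), tolerance = 1e-12)
  # invariance to window order
  perm <- c(3, 1, 2, 4, 5, 6)
  ws_perm <- ws
  ws_perm$values <- ws$values[perm, , , drop = FALSE]
  ws_perm$index <- ws$index[perm, ]
  emb_perm <- embed_patient_first_week(m, ws_perm)
  expect_equal(emb[order(emb$patient_id), paste0("e", 1:4)],
               emb_perm[order(emb_perm$patient_id), paste0("e", 1:4)],
               tolerance = 1e-12)
})

test_that("patients without available first-week windows are excluded", {
  ws <- make_window_set(c("A", "B", "C"), 2, L = 24, seed = 11)
  ws$index$available[ws$index$patient_id == "C"] <- FALSE
  m <- build_cnn(cnn_spec(conv_filters = c(2, 2, 4), kernel_size = 3),
                 input_len = 24, seed = 12)
  expect_message(emb <- embed_patient_first_week(m, ws), "C")
  expect_setequal(emb$patient_id, c("A", "B"))
})

test_that("embeddings are invariant to the mask fill when nothing is missing", {
  # with no missingness the mask channel is all zero; perturbing what the
  # fill would have been (channels under mask) changes nothing
  ws <- make_window_set(c("A", "B"), 2, L = 24, seed = 13)
  m <- build_cnn(cnn_spec(conv_filters = c(2, 2, 4), kernel_size = 3),
                 input_len = 24, seed = 14)
  e1 <- cnn_embed(m, ws$values)
  # nonzero embedding variance: no representation collapse
  expect_gt(mean(dist(e1)), 0)
})
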