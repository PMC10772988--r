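test_that("deduplication keeps the max-kcat collider and is idempotent", {
  df <- tibble::tibble(
    smiles = c("CCO", "CCO", "CCO", "CCN"),
    sequence = c("MKVL", "MKVL", "MKVL", "MKVL"),
    temperature_C = c(30, 30, 37, 30),
    kcat_s = c(1, 10, 5, 2)
  )
  out <- deduplicate_kinetics(df)
  expect_equal(nrow(out), 3)
  hit <- dplyr::filter(out, .data$smiles == "CCO", .data$temperature_C == 30)
  expect_equal(hit$kcat_s, 10)
  # entries differing only in temperature both survive
  expect_equal(sum(out$smiles == "CCO"), 2)
  expect_equal(deduplicate_kinetics(out), out)
  # exact duplicates collapse to one
  dup <- df[c(2, 2, 2), ]
  expect_equal(nrow(deduplicate_kinetics(dup)), 1)
  # empty input stays empty
  expect_equal(nrow(deduplicate_kinetics(df[0, ])), 0)
})

test_that("oversampling triples sparse-temperature multiplicities at factor 2", {
  df <- tibble::tibble(
    smiles = rep("CCO", 10),
    sequence = paste0("MKVLWAAL", c(LETTERS[1:10])),
    temperature_C = c(rep(10, 4), rep(30, 6)),
    kcat_s = 1:10
  )
  out <- oversample_kinetics(df, seed = 3)
  expect_equal(sum(out$temperature_C == 10), 12)  # 4 originals + 2 x 4
  expect_equal(sum(out$temperature_C == 30), 6)
  # keys unchanged, only multiplicities
  expect_setequal(unique(out$sequence), unique(df$sequence))
  # no entries outside the sparse ranges: identical multiset
  mid <- dplyr::filter(df, .data$temperature_C >= 20, .data$temperature_C <= 40)
  out_mid <- oversample_kinetics(mid, seed = 3)
  expect_equal(dplyr::arrange(out_mid, .data$kcat_s),
               dplyr::arrange(validate_kinetics(mid), .data$kcat_s))
  # deterministic under a fixed seed
  expect_equal(oversample_kinetics(df, seed = 42),
               oversample_kinetics(df, seed = 42))
})

test_that("splitting partitions the data with sizes within one of target", {
  df <- toy_kinetics(n_temps = 5)  # 20 rows
  df$row_id <- seq_len(nrow(df))
  sp <- split_kinetics(df, c(0.8, 0.1, 0.1), seed = 7)
  expect_equal(vapply(sp, nrow, integer(1)), c(train = 16L, val = 2L, test = 2L))
  ids <- sort(unname(unlist(lapply(sp, `[[`, "row_id"))))
  expect_equal(ids, df$row_id)  # disjoint union
  sp2 <- split_kinetics(df, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(sp, sp2)
  # 10 entries at 80/10/10 -> 8/1/1
  sp3 <- split_kinetics(df[1:10, ], c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(unname(vapply(sp3, nrow, integer(1))), c(8L, 1L, 1L))
  expect_error(split_kinetics(df[1:2, ], c(0.8, 0.1, 0.1), seed = 1))
})

test_that("protein-disjoint splitting keeps each sequence in one partition", {
  df <- toy_kinetics(n_temps = 5)
  sp <- split_kinetics(df, c(0.5, 0.25, 0.25), seed = 11, by = "protein")
  seqs <- lapply(sp, function(x) unique(x$sequence))
  expect_length(intersect(seqs$train, seqs$val), 0)
  expect_length(intersect(seqs$train, seqs$test), 0)
  expect_length(intersect(seqs$val, seqs$test), 0)
})

test_that("evaluation metrics match their definitions", {
  expect_equal(eval_metrics(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(rmse = 0, mae = 0, r2 = 1))
  # constant prediction at the target mean has r2 = 0
  targets <- c(1, 2, 3, 6)
  m <- eval_metrics(rep(mean(targets), 4), targets)
  expect_equal(m$r2, 0)
  # hand-evaluated example
  m2 <- eval_metrics(c(0, 0), c(1, 3))
  expect_equal(m2$mae, 2)
  expect_equal(m2$rmse, sqrt(5), tolerance = 1e-4)
  expect_gte(m2$rmse, m2$mae)
  expect_warning(m3 <- eval_metrics(c(1, 2), c(5, 5)), "zero variance")
  expect_true(is.na(m3$r2))
})

test_that("the learning-rate schedule halves every ten epochs", {
  expect_identical(learning_rate_schedule(c(0, 10, 20)),
                   c(0.001, 0.0005, 0.00025))
  expect_equal(learning_rate_schedule(9), 0.001)
  expect_equal(learning_rate_schedule(19), 0.0005)
  expect_equal(learning_rate_schedule(5, lr0 = 0.01, decay = 0.1,
                                      decay_every = 5), 0.001)
})

test_that("training runs end to end, records history, and is seed-stable", {
  df <- toy_kinetics()
  ctl <- train_config(epochs = 3, batch_size = 4, seed = 21,
                      split_fractions = c(0.6, 0.2, 0.2))
  m1 <- train_kcat_model(df, config = tiny_cfg(), control = ctl,
                         oversample = FALSE)
  expect_s3_class(m1, "kcat_model")
  expect_equal(nrow(m1$history), 3 * 2)
  expect_true(all(c("epoch", "split", "rmse", "mae", "r2", "lr") %in%
                    names(m1$history)))
  expect_equal(unique(m1$history$lr), 0.001)

  m2 <- train_kcat_model(df, config = tiny_cfg(), control = ctl,
                         oversample = FALSE)
  expect_identical(m1$history, m2$history)  # deterministic run

  pred <- predict(m1, df)
  expect_s3_class(pred, "tbl_df")
  expect_equal(nrow(pred), nrow(df))
  expect_true(all(is.finite(pred$pred_log10_kcat)))
  expect_equal(pred$pred_kcat_s, 10^pred$pred_log10_kcat)

  td <- tidy(m1)
  expect_identical(td, m1$history)
  gl <- glance(m1)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$n_parameters, 0)
})

test_that("a tiny dataset can be memorized with enough epochs", {
  df <- toy_kinetics()[1:10, ]
  ctl <- train_config(epochs = 150, batch_size = 10, seed = 33, lr0 = 0.003,
                      decay_every = 1000L, split_fractions = c(0.8, 0.1, 0.1))
  m <- train_kcat_model(df, config = tiny_cfg(), control = ctl,
                        oversample = FALSE)
  final_train <- dplyr::filter(m$history, .data$split == "train",
                               .data$epoch == max(.data$epoch))
  expect_lt(final_train$rmse, 0.1)
  # loss mostly decreases across epochs (SGD noise tolerated)
  tr <- dplyr::filter(m$history, .data$split == "train")$rmse
  frac_down <- mean(diff(tr) <= 1e-6)
  expect_gte(frac_down, 0.8)
})

test_that("temperature permutation importance behaves at its edge cases", {
  df <- toy_kinetics()
  ctl <- train_config(epochs = 2, batch_size = 4, seed = 5,
                      split_fractions = c(0.6, 0.2, 0.2))
  m <- train_kcat_model(df, config = tiny_cfg(), control = ctl,
                        oversample = FALSE)
  # zero repeats: empty distribution, baseline still present
  imp0 <- permute_temperature_importance(m, df, n_repeats = 0, seed = 1)
  expect_equal(nrow(imp0$shuffled), 0)
  expect_equal(nrow(imp0$baseline), 1)
  # the baseline equals ordinary prediction metrics (identity permutation)
  met <- evaluate_kcat_model(m, df)
  expect_equal(imp0$baseline$rmse, met$rmse, tolerance = 1e-10)
  # single-temperature data is rejected
  single <- dplyr::mutate(df, temperature_C = 30)
  expect_error(permute_temperature_importance(m, single, n_repeats = 2),
               "distinct temperatures")
  # tidy() stacks baseline and shuffled rows
  imp2 <- permute_temperature_importance(m, df, n_repeats = 3, seed = 2)
  expect_equal(nrow(tidy(imp2)), 4)
})
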