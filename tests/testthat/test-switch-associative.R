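test_that("the identity mapping task is learned essentially exactly", {
  set.seed(12)
  R <- matrix(rnorm(100), 10)
  aw <- train_transfer(R, R, seed = 5, target_error = 1e-22)
  expect_lt(max(abs(R %*% t(aw$w1) - R)), 1e-9)
  expect_lt(aw$train_error[["fingers_to_words"]], 1e-20)
})

test_that("the fitted mapping matches the closed-form least squares solution", {
  set.seed(13)
  M <- matrix(rnorm(100), 10)
  A <- matrix(rnorm(100), 10)
  aw <- train_transfer(M, A, seed = 2, target_error = 1e-26)
  W_ls <- t(solve(crossprod(M), crossprod(M, A)))  # normal-equations oracle
  expect_lt(max(abs(aw$w1 - W_ls)), 1e-10)
  W_ls2 <- t(solve(crossprod(A), crossprod(A, M)))
  expect_lt(max(abs(aw$w2 - W_ls2)), 1e-10)
})

test_that("rank-deficient representations are flagged, not fatal", {
  M <- matrix(rnorm(100), 10)
  M[, 10] <- M[, 9]  # exactly dependent columns
  A <- matrix(rnorm(100), 10)
  expect_warning(aw <- train_transfer(M, A, seed = 1), "rank-deficient")
  expect_true(aw$rank_deficient)
  expect_true(all(is.finite(aw$w1)))
})

test_that("cross-modal transfer reconstructs the partner representation", {
  sys <- shared_system()
  M <- sys$datasets[[1]]$raw
  A <- sys$datasets[[3]]$raw
  expect_lt(max(abs(transfer(M[7, ], "fingers_to_words", sys$aw) - A[7, ])),
            1e-7)
  # round trip through both directions recovers every motor representation
  for (n in 1:10) {
    back <- transfer(transfer(M[n, ], "fingers_to_words", sys$aw),
                     "words_to_fingers", sys$aw)
    expect_lt(max(abs(back - M[n, ])), 1e-6)
  }
  expect_equal(transfer(rep(0, 10), "fingers_to_words", sys$aw), rep(0, 10))
  expect_error(transfer(rep(0, 10), "sideways", sys$aw))
})

test_that("transferred representations classify like native ones", {
  sys <- shared_system()
  ds3 <- sys$datasets[[3]]
  clf3 <- train_classifier(ds3, epochs = 10, seed = 77)
  for (n in 1:10) {
    native <- predict_class(clf3, ds3$features[n, ])
    moved <- transfer(sys$datasets[[1]]$raw[n, ], "fingers_to_words", sys$aw)
    expect_equal(predict_class(clf3, apply_scale(ds3$norm, moved)), native)
  }
})

test_that("heard words are recognized from their coefficients", {
  tab <- mfcc_table()
  r6 <- recognize_word(tab$values["six", ], tab)
  expect_equal(as.integer(r6), 6L)
  expect_lt(attr(r6, "distance"), 1e-12)
  # noise well inside the inter-word margin (normalized units)
  norm <- normalize_features(tab$values)
  noisy <- (norm$values["two", ] +
            countnet:::with_seed(4, rnorm(13, 0, 0.01))) * norm$scale_factors
  expect_equal(as.integer(recognize_word(noisy, tab)), 2L)
  # total function: an arbitrary vector still maps to some class
  z <- recognize_word(rep(0, 13), tab)
  expect_true(as.integer(z) %in% 1:10)
  expect_gt(attr(z, "distance"), 1)
})

test_that("the switch follows its transition table and rejects illegal events", {
  s <- switch_step("idle", "operand_heard")
  expect_equal(s$mode, "start_all")
  expect_setequal(s$directives, c("init_motor_ones", "init_auditory_ones"))
  expect_equal(switch_step("start_all", "count_tick")$mode, "counting")
  r <- switch_step("counting", "plus_heard")
  expect_equal(r$mode, "reset_auditory")
  expect_equal(r$directives, "clamp_auditory_zero")
  expect_equal(switch_step("reset_auditory", "operand_heard")$directives,
               "init_auditory_ones")
  tfw <- switch_step("counting", "operand_done")
  expect_equal(tfw$mode, "transfer_fingers_to_words")
  expect_equal(tfw$directives, "apply_w1")
  expect_equal(switch_step("transfer_fingers_to_words", "operand_done")$mode,
               "output_to_classifier")
  expect_error(switch_step("idle", "plus_heard"), "illegal")
  expect_error(switch_step("idle", "operand_done"), "illegal")
  expect_error(switch_step("nowhere", "count_tick"), "unknown mode")
  # swapped buffer roles use the mirror-image states and weights
  rm_ <- switch_step("counting", "plus_heard", roles = "swapped")
  expect_equal(rm_$mode, "reset_motor")
  expect_equal(switch_step("counting", "operand_done", roles = "swapped")$directives,
               "apply_w2")
})

test_that("no event string can reach the classifier mid-count", {
  events <- c("operand_heard", "plus_heard", "operand_done", "count_tick")
  frontier <- list(list(mode = "idle", emitted = FALSE))
  for (depth in 1:8) {
    nxt <- list()
    for (st in frontier) {
      for (ev in events) {
        out <- tryCatch(switch_step(st$mode, ev), error = function(e) NULL)
        if (is.null(out)) next
        emits <- "emit_to_classifier" %in% out$directives
        if (emits) {
          # emission happens only on entry to output_to_classifier, coming
          # from a transfer state, and never together with a count advance
          expect_equal(out$mode, "output_to_classifier")
          expect_true(st$mode %in% c("transfer_fingers_to_words",
                                     "transfer_words_to_fingers"))
          expect_false("advance_both" %in% out$directives)
        }
        if ("advance_both" %in% out$directives)
          expect_false(emits)
        nxt[[length(nxt) + 1L]] <- list(mode = out$mode, emitted = emits)
      }
    }
    frontier <- unique(nxt)
  }
  expect_gt(length(frontier), 0)
})

test_that("addition follows the five-step procedure and respects the range", {
  sys <- shared_system()
  tr <- add_numbers(2, 2, sys)
  expect_equal(tr$result_class, 4L)
  expect_equal(tr$operand_a, 2L)
  expect_gt(tr$result_likelihood, 0.5)
  expect_equal(add_numbers(1, 9, sys)$result_class, 10L)
  expect_error(add_numbers(6, 6, sys), "overflow")
  # operands can arrive as raw coefficient vectors, as heard words would
  tr2 <- add_numbers(mfcc_table()$values["three", ], 4, sys)
  expect_equal(tr2$operand_a, 3L)
  expect_equal(tr2$result_class, 7L)
  # the trace replays deterministically
  tr3 <- add_numbers(2, 2, sys)
  expect_identical(tr3$step_log, tr$step_log)
  expect_identical(tr3$probabilities, tr$probabilities)
  path <- withr::local_tempfile(fileext = ".json")
  write_trace_json(tr, path)
  expect_true(file.exists(path))
})
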