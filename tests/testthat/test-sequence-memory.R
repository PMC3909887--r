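test_that("single-unit single-step Jacobian matches the hand-derived chain rule", {
  net <- sequence_memory_net(1, 1, seed = 3)
  ctx <- 0.7
  tgt <- matrix(0.2)
  # h1 = w_in*ctx + w_rec*1 (start state is 1); y1 = w_out*h1
  h1 <- net$w_in[1, 1] * ctx + net$w_rec[1, 1]
  J <- bptt_jacobian(net, tgt, ctx)
  expect_equal(dim(J), c(1, 3))
  expect_equal(J[1, ], c(net$w_out[1, 1] * ctx,  # d/dw_in
                         net$w_out[1, 1],        # d/dw_rec (h0 = 1)
                         h1),                    # d/dw_out
               tolerance = 1e-12)
})

test_that("derivatives through the unrolled recurrence match finite differences", {
  set.seed(17)
  for (rep_ in 1:3) {
    net <- sequence_memory_net(3, 2, seed = 100 + rep_)
    targets <- matrix(runif(8, -1, 1), 4, 2)
    ctx <- runif(2, -1, 1)
    J <- bptt_jacobian(net, targets, ctx)
    f <- function(p) countnet:::net_forward_teacher(
      countnet:::set_net_params(net, p), targets, ctx)$residuals
    Jfd <- finite_diff_jacobian(f, countnet:::net_params(net))
    denom <- pmax(abs(Jfd), 1e-3)
    expect_lt(max(abs(J - Jfd) / denom), 1e-5)
  }
  # sequence length 1 reduces to the feed-forward Jacobian
  net <- sequence_memory_net(3, 2, seed = 1)
  t1 <- matrix(c(0.1, -0.2), 1, 2)
  J1 <- bptt_jacobian(net, t1, c(0.3, 0.4))
  f1 <- function(p) countnet:::net_forward_teacher(
    countnet:::set_net_params(net, p), t1, c(0.3, 0.4))$residuals
  expect_lt(max(abs(J1 - finite_diff_jacobian(f1, countnet:::net_params(net)))),
            1e-6)
})

test_that("a zero hidden state with zero context stays silent", {
  net <- sequence_memory_net(4, 3, seed = 5)
  run <- free_run(net, init_hidden = rep(0, 4), n_steps = 6,
                  context0 = rep(0, 3))
  expect_true(all(run$outputs == 0))
  expect_true(all(run$hidden == 0))
})

test_that("free_run validates its inputs", {
  net <- sequence_memory_net(2, 2)
  expect_error(free_run(net, rep(1, 2), n_steps = 0), "n_steps")
  expect_error(free_run(net, rep(1, 3), n_steps = 2))
})

test_that("start_state is the all-ones vector of the hidden size", {
  expect_equal(start_state(sequence_memory_net(10, 13)), rep(1, 10))
  expect_equal(start_state(sequence_memory_net(5, 7)), rep(1, 5))
})

test_that("a constant target sequence is learned to near-zero error", {
  tgt <- matrix(rep(c(0.3, -0.5), each = 4), 4, 2)
  net <- train_counting_net(tgt, context0 = c(0, 0), hidden_size = 3, seed = 2)
  expect_lt(net$train_perf, 1e-10)
})

test_that("trained counting nets replay their sequence in free run", {
  norm <- normalize_features(finger_joint_table())
  right_targets <- norm$values[2:11, 1:7]  # one..ten
  ctx <- norm$values["rest", 1:7]
  net <- train_counting_net(right_targets, ctx, hidden_size = 5, seed = 7)
  run <- free_run(net, n_steps = 10)
  expect_lt(max(abs(run$outputs - right_targets)), 1e-3)

  aud <- auditory_memory(seed = 11)
  expect_lt(aud$train_perf, 1e-6)
  tgt <- normalize_features(mfcc_table())$values
  run2 <- free_run(aud, n_steps = 10)
  expect_lt(max(abs(run2$outputs - tgt)), 1e-3)
})

test_that("counting can start from a stored number's state", {
  aud <- shared_system()$auditory
  full <- free_run(aud, n_steps = 10)
  # resume from the stored state of number 4: the next outputs are 5, 6, ...
  resumed <- free_run(aud, init_hidden = full$hidden[4, ], n_steps = 6,
                      context0 = full$outputs[4, ])
  expect_lt(max(abs(resumed$outputs - full$outputs[5:10, ])), 1e-8)
})

test_that("the left hand is switched off for numbers one to five", {
  mcm <- shared_system()$mcm
  for (n in c(1, 3, 5)) {
    traj <- count_with_fingers(mcm, n)
    expect_true(all(traj$hidden[, 6:10] == 0))
  }
  traj10 <- count_with_fingers(mcm, 10)
  expect_true(all(traj10$hidden[1:5, 6:10] == 0))
  expect_true(any(traj10$hidden[6:10, 6:10] != 0))
  # right-hand outputs constant from step 5 on
  right_out <- traj10$outputs[5:10, 1:7]
  expect_lt(max(abs(sweep(right_out, 2, right_out[1, ]))), 1e-12)
  expect_error(count_with_fingers(mcm, 11), "1..10")
})

test_that("representation datasets have the documented shapes and structure", {
  sys <- shared_system()
  ds <- sys$datasets
  widths <- vapply(ds, function(d) ncol(d$features), integer(1))
  expect_equal(widths, c(10L, 13L, 10L, 23L, 20L))
  for (d in ds) expect_equal(d$labels, 1:10)
  # merged variants are column concatenations of their parts
  expect_equal(ds[[4]]$raw, cbind(ds[[1]]$raw, ds[[2]]$raw))
  expect_equal(ds[[5]]$raw, cbind(ds[[1]]$raw, ds[[3]]$raw))
  # motor lateralization: left half zero for numbers 1..5
  expect_true(all(ds[[1]]$features[1:5, 6:10] == 0))
  # right-hand saturation: motor columns 1..5 constant across numbers 5..10
  sat <- ds[[1]]$features[5:10, 1:5]
  expect_lt(max(abs(sweep(sat, 2, sat[1, ]))), 1e-6)
  # word dataset is the normalized coefficient table
  expect_equal(ds[[2]]$features[1, 1], -1)
  # the final concatenated hidden state while counting to 6 is the variant-1
  # row for 6
  expect_equal(count_with_fingers(sys$mcm, 6)$hidden[6, ], ds[[1]]$raw[6, ])
})

test_that("finger representations are ordered like the number line", {
  feats <- shared_system()$datasets[[1]]$features
  D <- as.matrix(dist(feats))
  consec <- mean(D[cbind(1:9, 2:10)])
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  nonconsec <- pairs[pairs[, 2] - pairs[, 1] > 1, ]
  expect_lt(consec, mean(D[nonconsec]))
})

test_that("training is deterministic under a fixed seed", {
  n1 <- train_counting_net(matrix(c(0.1, 0.5, -0.3, 0.2), 2, 2), c(0, 0),
                           hidden_size = 2, seed = 9)
  n2 <- train_counting_net(matrix(c(0.1, 0.5, -0.3, 0.2), 2, 2), c(0, 0),
                           hidden_size = 2, seed = 9)
  expect_identical(n1$w_out, n2$w_out)
  s1 <- motor_controller_memory(seed = 4)
  s2 <- motor_controller_memory(seed = 4)
  expect_identical(s1$right$w_rec, s2$right$w_rec)
  expect_identical(s1$left$w_in, s2$left$w_in)
})

test_that("trained nets survive a JSON round trip", {
  net <- shared_system()$auditory
  path <- withr::local_tempfile(fileext = ".json")
  write_net_json(net, path)
  back <- read_net_json(path)
  expect_equal(back$w_in, net$w_in)
  expect_equal(back$w_rec, net$w_rec)
  expect_equal(back$w_out, net$w_out)
  run_a <- free_run(net, n_steps = 10)
  run_b <- free_run(back, n_steps = 10)
  expect_equal(run_b$outputs, run_a$outputs)
})
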