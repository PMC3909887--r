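#' Recurrent sequence-memory network
#'
#' A small output-feedback (Jordan-style) recurrent network with linear
#' units and no biases: `h(t) = W_in y(t-1) + W_rec h(t-1)`,
#' `y(t) = W_out h(t)`. During training the output feedback is
#' teacher-forced with the target sequence; in operation the network feeds
#' its own output back and runs autonomously. Because the units are linear
#' and bias-free, an all-zero hidden state with zero feedback stays silent
#' forever, and counting is started by incepting activation (all ones) into
#' the hidden units.
#'
#' @param hidden_size number of hidden units.
#' @param output_size number of output channels.
#' @param seed optional integer; when given, weights are drawn
#'   uniformly from (-0.5, 0.5) under this seed, otherwise they are zero.
#' @return An object of class `sequence_memory_net` with weight matrices
#'   `w_in` (hidden x output), `w_rec` (hidden x hidden),
#'   `w_out` (output x hidden).
#' @export
sequence_memory_net <- function(hidden_size, output_size, seed = NULL) {
  stopifnot(hidden_size >= 1, output_size >= 1)
  n_par <- hidden_size * output_size + hidden_size^2 + output_size * hidden_size
  w <- if (is.null(seed)) rep(0, n_par)
       else with_seed(seed, stats::runif(n_par, -0.5, 0.5))
  net <- structure(list(hidden_size = hidden_size, output_size = output_size),
                   class = "sequence_memory_net")
  set_net_params(net, w)
}

# canonical parameter flattening: c(vec(w_in), vec(w_rec), vec(w_out))
net_params <- function(net) {
  c(as.numeric(net$w_in), as.numeric(net$w_rec), as.numeric(net$w_out))
}

set_net_params <- function(net, params) {
  H <- net$hidden_size; O <- net$output_size
  stopifnot(length(params) == H * O + H * H + O * H)
  i1 <- H * O; i2 <- i1 + H * H
  net$w_in <- matrix(params[seq_len(i1)], H, O)
  net$w_rec <- matrix(params[(i1 + 1):i2], H, H)
  net$w_out <- matrix(params[(i2 + 1):length(params)], O, H)
  net
}

#' @export
print.sequence_memory_net <- function(x, ...) {
  cat(sprintf("<sequence_memory_net> hidden=%d outputs=%d (linear, no bias)\n",
              x$hidden_size, x$output_size))
  if (!is.null(x$train_perf))
    cat(sprintf("  trained: perf=%.3g epochs=%d seed=%s\n",
                x$train_perf, x$train_epochs, format(x$train_seed)))
  invisible(x)
}

#' All-ones start state
#'
#' The switch layer starts counting by initializing every hidden unit to 1
#' (setting them to 0 instead leaves the bias-free network silent).
#'
#' @param net a [sequence_memory_net()].
#' @return Numeric vector of ones, length `hidden_size`.
#' @export
start_state <- function(net) rep(1, net$hidden_size)

# Teacher-forced forward pass. targets: T x output matrix; context0: the
# step-0 output context fed back at t = 1. Returns residuals (time-major,
# channel-minor) plus hidden/output trajectories.
net_forward_teacher <- function(net, targets, context0, h0 = start_state(net)) {
  targets <- as.matrix(targets)
  T_ <- nrow(targets)
  stopifnot(ncol(targets) == net$output_size,
            length(context0) == net$output_size, length(h0) == net$hidden_size)
  H <- matrix(0, T_, net$hidden_size)
  Y <- matrix(0, T_, net$output_size)
  h <- h0
  y_prev <- context0
  for (t in seq_len(T_)) {
    h <- as.numeric(net$w_in %*% y_prev + net$w_rec %*% h)
    y <- as.numeric(net$w_out %*% h)
    H[t, ] <- h
    Y[t, ] <- y
    y_prev <- targets[t, ]  # teacher forcing of the output feedback
  }
  list(residuals = as.numeric(t(Y - targets)), hidden = H, outputs = Y)
}

#' Jacobian of a sequence memory's errors through time
#'
#' Derivatives of every teacher-forced output error with respect to every
#' weight, obtained by propagating sensitivities through the unrolled
#' recurrence (the recurrent analogue of backpropagating the unfolded
#' feed-forward net). Rows are ordered time-step-major, output-unit-minor;
#' columns follow the canonical flattening `(w_in, w_rec, w_out)`,
#' column-major within each block.
#'
#' @param net a [sequence_memory_net()].
#' @param targets T x output target matrix (teacher-forcing sequence).
#' @param context0 step-0 output context.
#' @param h0 initial hidden state (defaults to all ones).
#' @return Numeric matrix, `(T * output_size)` x `n_params`.
#' @export
bptt_jacobian <- function(net, targets, context0, h0 = start_state(net)) {
  targets <- as.matrix(targets)
  T_ <- nrow(targets)
  stopifnot(T_ >= 1, ncol(targets) == net$output_size,
            length(context0) == net$output_size)
  H <- net$hidden_size; O <- net$output_size
  nin <- H * O; nrec <- H * H; nout <- O * H
  P <- nin + nrec + nout
  J <- matrix(0, T_ * O, P)
  Sh <- matrix(0, H, P)   # d h(t) / d params
  h <- h0
  y_prev <- context0
  IH <- diag(H)
  for (t in seq_len(T_)) {
    # dh = d(w_in) y_prev + d(w_rec) h_prev + w_rec dh_prev
    Sh_new <- net$w_rec %*% Sh
    Sh_new[, seq_len(nin)] <- Sh_new[, seq_len(nin), drop = FALSE] +
      kronecker(matrix(y_prev, 1), IH)
    Sh_new[, nin + seq_len(nrec)] <- Sh_new[, nin + seq_len(nrec), drop = FALSE] +
      kronecker(matrix(h, 1), IH)
    h <- as.numeric(net$w_in %*% y_prev + net$w_rec %*% h)
    # dy = d(w_out) h + w_out dh
    Sy <- net$w_out %*% Sh_new
    Sy[, nin + nrec + seq_len(nout)] <- Sy[, nin + nrec + seq_len(nout), drop = FALSE] +
      kronecker(matrix(h, 1), diag(O))
    J[(t - 1) * O + seq_len(O), ] <- Sy
    Sh <- Sh_new
    y_prev <- targets[t, ]
  }
  J
}

#' Train a counting network on a target sequence
#'
#' Fits the network so that, teacher-forced from the all-ones start state
#' and the step-0 context, it predicts each element of the target sequence.
#' Weights are drawn from a seeded uniform(-0.5, 0.5); if Levenberg-
#' Marquardt training does not reach `tol` mean squared error, the next
#' seed is tried (up to `max_attempts`), each attempt being logged.
#'
#' @param targets T x output matrix of normalized targets (T >= 2).
#' @param context0 step-0 output context (e.g. the normalized rest
#'   configuration for the motor nets, zeros for the auditory net).
#' @param hidden_size hidden unit count.
#' @param config an [lma_config()].
#' @param seed base integer seed for weight initialization.
#' @param tol convergence threshold on the teacher-forced mean squared
#'   error.
#' @param max_attempts maximum number of re-initializations.
#' @return A trained `sequence_memory_net` with fields `train_perf`,
#'   `train_epochs`, `train_seed`, `context0`, `trace` (per-epoch
#'   performance) and `attempts` (one row per initialization tried).
#' @export
train_counting_net <- function(targets, context0, hidden_size,
                               config = lma_config(), seed = 1,
                               tol = 1e-6, max_attempts = 10) {
  targets <- as.matrix(targets)
  stopifnot(nrow(targets) >= 2)
  if (any(!is.finite(targets))) stop("non-finite targets")
  O <- ncol(targets)
  attempts <- list()
  for (k in seq_len(max_attempts)) {
    seed_k <- seed + k - 1L
    net <- sequence_memory_net(hidden_size, O, seed = seed_k)
    model <- residual_model(
      residual = function(p) {
        net_forward_teacher(set_net_params(net, p), targets, context0)$residuals
      },
      jacobian = function(p) {
        bptt_jacobian(set_net_params(net, p), targets, context0)
      }
    )
    fit <- lma_train(model, net_params(net), config)
    attempts[[k]] <- data.frame(seed = seed_k, perf = fit$perf,
                                epochs = fit$epoch,
                                stop_reason = fit$stop_reason)
    if (fit$perf < tol) {
      net <- set_net_params(net, fit$params)
      net$train_perf <- fit$perf
      net$train_epochs <- fit$epoch
      net$train_seed <- seed_k
      net$context0 <- context0
      net$trace <- fit$trace
      net$attempts <- do.call(rbind, attempts)
      return(net)
    }
  }
  stop("counting net failed to reach tol = ", tol, " in ", max_attempts,
       " attempts (best perf ",
       format(min(vapply(attempts, function(a) a$perf, numeric(1)))), ")")
}

#' Run a sequence memory autonomously
#'
#' Free-running rollout: the output at each step is fed back as the next
#' step's input. Starting from the all-ones hidden state replays the
#' learned counting sequence; starting from the stored hidden state of
#' number `k` continues the count at `k + 1`; starting from all zeros
#' keeps the bias-free network silent.
#'
#' @param net a trained [sequence_memory_net()].
#' @param init_hidden initial hidden state, length `hidden_size`.
#' @param n_steps number of steps (>= 1).
#' @param context0 feedback input for the first step; defaults to the
#'   context the net was trained with (zeros if never trained).
#' @return An object of class `hidden_trajectory`: list with `hidden`
#'   (n_steps x hidden_size) and `outputs` (n_steps x output_size).
#' @export
free_run <- function(net, init_hidden = start_state(net), n_steps,
                     context0 = NULL) {
  stopifnot(length(init_hidden) == net$hidden_size)
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (is.null(context0))
    context0 <- if (!is.null(net$context0)) net$context0 else rep(0, net$output_size)
  H <- matrix(0, n_steps, net$hidden_size)
  Y <- matrix(0, n_steps, net$output_size)
  h <- init_hidden
  y_prev <- context0
  for (t in seq_len(n_steps)) {
    h <- as.numeric(net$w_in %*% y_prev + net$w_rec %*% h)
    y <- as.numeric(net$w_out %*% h)
    H[t, ] <- h
    Y[t, ] <- y
    y_prev <- y   # self-feedback: the output is the next input
  }
  structure(list(hidden = H, outputs = Y), class = "hidden_trajectory")
}

#' Lateralized motor controller/memory
#'
#' Two independently trained counting networks model hand lateralization:
#' the right-hand net learns the opening sequence for one..five (after five
#' the right hand is fully open and its state is held), and the left-hand
#' net learns the sequence for six..ten. The left net is switched off —
#' hidden state clamped to exactly zero — whenever numbers 1-5 are
#' processed, and is started (hidden units set to 1) at step six.
#'
#' @param finger_table a [finger_joint_table()]; targets are its rows
#'   normalized per joint.
#' @param config an [lma_config()].
#' @param seed base seed; the two nets use `seed` and `seed + 100`.
#' @param hidden_per_hand hidden units per hand net.
#' @return An object of class `motor_controller_memory`: list with `right`
#'   and `left` trained nets, the normalization used (`norm`), and the
#'   per-hand column indices.
#' @export
motor_controller_memory <- function(finger_table = finger_joint_table(),
                                    config = lma_config(), seed = 1,
                                    hidden_per_hand = 5) {
  norm <- normalize_features(finger_table$values)
  vals <- norm$values
  right_cols <- 1:7
  left_cols <- 8:14
  rest <- vals["rest", ]
  right <- train_counting_net(
    targets = vals[c("one", "two", "three", "four", "five"), right_cols],
    context0 = rest[right_cols], hidden_size = hidden_per_hand,
    config = config, seed = seed)
  left <- train_counting_net(
    targets = vals[c("six", "seven", "eight", "nine", "ten"), left_cols],
    context0 = rest[left_cols], hidden_size = hidden_per_hand,
    config = config, seed = seed + 100L)
  structure(list(right = right, left = left, norm = norm,
                 right_cols = right_cols, left_cols = left_cols),
            class = "motor_controller_memory")
}

#' Count to a number with the fingers
#'
#' Runs the motor controller/memory through the counting sequence up to
#' `n`. The right net free-runs for `min(n, 5)` steps and then holds its
#' final state (right hand fully open); the left net's hidden state is
#' clamped to zero through step 5 and, from step six on, runs from its
#' all-ones start state. Each step records the concatenated 10-dimensional
#' hidden vector (right units 1-5, left units 6-10) and the 14 joint
#' outputs.
#'
#' @param mcm a [motor_controller_memory()].
#' @param n target number, 1..10.
#' @return A `hidden_trajectory` with `n` steps; `hidden` is `n` x 10,
#'   `outputs` is `n` x 14 (normalized joint values).
#' @export
count_with_fingers <- function(mcm, n) {
  stopifnot(inherits(mcm, "motor_controller_memory"))
  if (!(length(n) == 1L && n %in% 1:10)) stop("n must be in 1..10")
  Hr <- mcm$right$hidden_size; Hl <- mcm$left$hidden_size
  H <- matrix(0, n, Hr + Hl)
  Y <- matrix(0, n, mcm$right$output_size + mcm$left$output_size)
  right_run <- free_run(mcm$right, n_steps = min(n, 5))
  left_run <- if (n > 5) free_run(mcm$left, n_steps = n - 5) else NULL
  left_rest <- mcm$left$context0
  for (t in seq_len(n)) {
    rt <- min(t, 5)
    H[t, seq_len(Hr)] <- right_run$hidden[rt, ]
    Y[t, seq_len(ncol(right_run$outputs))] <- right_run$outputs[rt, ]
    if (t > 5) {
      H[t, Hr + seq_len(Hl)] <- left_run$hidden[t - 5, ]
      Y[t, ncol(right_run$outputs) + seq_len(ncol(left_run$outputs))] <-
        left_run$outputs[t - 5, ]
    } else {
      # left net switched off: hidden exactly zero, hand at rest
      Y[t, ncol(right_run$outputs) + seq_along(left_rest)] <- left_rest
    }
  }
  structure(list(hidden = H, outputs = Y), class = "hidden_trajectory")
}

#' Train the auditory sequence memory
#'
#' A single counting network (10 hidden units, 13 output channels) that
#' learns the one..ten number-word sequence of normalized MFCC vectors.
#' The step-0 context is the zero vector (there is no "rest word").
#'
#' @param mfcc a [mfcc_table()].
#' @param config an [lma_config()].
#' @param seed integer seed.
#' @param hidden_size hidden unit count.
#' @return A trained `sequence_memory_net` (with the table's normalization
#'   attached as attribute `norm`).
#' @export
auditory_memory <- function(mfcc = mfcc_table(), config = lma_config(),
                            seed = 1, hidden_size = 10) {
  norm <- normalize_features(mfcc$values)
  net <- train_counting_net(targets = norm$values,
                            context0 = rep(0, ncol(norm$values)),
                            hidden_size = hidden_size,
                            config = config, seed = seed)
  net$norm <- norm
  net
}

#' Build the five per-number representation datasets
#'
#' Collects, for each number 1..10, the feature vectors used to train the
#' competitive classifier:
#' 1. concatenated motor hidden states from the finger-counting sequence
#'    (10 values);
#' 2. the raw (per-feature normalized) MFCC row of the number word, out of
#'    sequence (13 values);
#' 3. the auditory memory's hidden state at each step of the word sequence
#'    (10 values);
#' 4. concatenation of 1 and 2 (23 values);
#' 5. concatenation of 1 and 3 (20 values).
#' Every dataset is per-feature normalized to `[-1, 1]` before use, and the
#' scale factors are kept so novel vectors (e.g. transferred hidden states)
#' can be projected into the same space.
#'
#' @param mcm a trained [motor_controller_memory()].
#' @param auditory a trained [auditory_memory()].
#' @param mfcc a [mfcc_table()].
#' @return A list of five objects of class `representation_dataset`, each
#'   with `variant`, `features` (10 x d normalized matrix), `labels`
#'   (1..10), `norm` (the `normalized_matrix` holding scale factors) and
#'   `raw` (pre-normalization features).
#' @export
build_representation_datasets <- function(mcm, auditory, mfcc = mfcc_table()) {
  stopifnot(inherits(mcm, "motor_controller_memory"),
            inherits(auditory, "sequence_memory_net"))
  if (is.null(auditory$train_perf))
    stop("auditory net is untrained")
  motor_raw <- t(vapply(1:10, function(n) {
    traj <- count_with_fingers(mcm, n)
    traj$hidden[n, ]
  }, numeric(mcm$right$hidden_size + mcm$left$hidden_size)))
  aud_raw <- free_run(auditory, n_steps = 10)$hidden
  word_raw <- normalize_features(mfcc$values)$values  # out of sequence
  make_ds <- function(variant, raw) {
    norm <- normalize_features(raw)
    structure(list(variant = variant, features = norm$values,
                   labels = 1:10, norm = norm, raw = raw),
              class = "representation_dataset")
  }
  list(make_ds(1L, motor_raw),
       make_ds(2L, word_raw),
       make_ds(3L, aud_raw),
       make_ds(4L, cbind(motor_raw, word_raw)),
       make_ds(5L, cbind(motor_raw, aud_raw)))
}

#' @export
print.representation_dataset <- function(x, ...) {
  cat(sprintf("<representation_dataset> variant %d: 10 x %d features\n",
              x$variant, ncol(x$features)))
  invisible(x)
}

#' Serialize a trained net to JSON
#'
#' @param net a `sequence_memory_net`.
#' @param path output file.
#' @export
write_net_json <- function(net, path) {
  doc <- list(hidden_size = net$hidden_size, output_size = net$output_size,
              w_in = net$w_in, w_rec = net$w_rec, w_out = net$w_out,
              context0 = net$context0,
              meta = list(seed = net$train_seed, perf = net$train_perf,
                          epochs = net$train_epochs))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
}

#' Read a net serialized by [write_net_json()]
#'
#' @param path JSON file.
#' @return A `sequence_memory_net`.
#' @export
read_net_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- sequence_memory_net(doc$hidden_size, doc$output_size)
  net$w_in <- matrix(unlist(doc$w_in), doc$hidden_size)
  net$w_rec <- matrix(unlist(doc$w_rec), doc$hidden_size)
  net$w_out <- matrix(unlist(doc$w_out), doc$output_size)
  if (!is.null(doc$context0)) net$context0 <- as.numeric(doc$context0)
  if (!is.null(doc$meta)) {
    net$train_seed <- doc$meta$seed
    net$train_perf <- doc$meta$perf
    net$train_epochs <- doc$meta$epochs
  }
  net
}
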