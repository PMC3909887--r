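#' Train the associative (cross-modal) mappings
#'
#' Learns the two linear hidden-to-hidden connections between the motor
#' and auditory layers: `w1` maps a motor hidden vector to its auditory
#' counterpart (fingers to words) and `w2` the reverse. Both are fitted by
#' Levenberg-Marquardt on the squared mapping error over the ten
#' per-number representation pairs, from a seeded uniform(-0.5, 0.5)
#' initialization, stopping when the mean squared error falls below
#' `target_error`.
#'
#' @param motor_reps 10 x 10 matrix of motor hidden representations (rows
#'   = numbers 1..10).
#' @param auditory_reps 10 x 10 matrix of auditory hidden
#'   representations.
#' @param config an [lma_config()]; the default relaxes the gradient stop
#'   (`grad_tol = 1e-30`) because this fit's stop criterion is the error
#'   floor itself, which ill-conditioned representation matrices approach
#'   through many small accepted steps while the damping anneals.
#' @param seed integer seed (the two directions use `seed` and
#'   `seed + 1`).
#' @param target_error error floor at which training stops.
#' @return Object of class `associative_weights`: list with `w1`, `w2`
#'   (10 x 10), `train_iterations` (accepted epochs per direction, from the
#'   successful initialization), `train_error` (final mean squared error
#'   per direction), `attempts` (initializations tried per direction) and
#'   `rank_deficient` flag.
#' @export
train_transfer <- function(motor_reps, auditory_reps,
                           config = lma_config(grad_tol = 1e-30,
                                               max_epochs = 200),
                           seed = 1, target_error = 1e-15) {
  motor_reps <- as.matrix(motor_reps)
  auditory_reps <- as.matrix(auditory_reps)
  stopifnot(nrow(motor_reps) == nrow(auditory_reps))
  rank_deficient <- qr(motor_reps)$rank < ncol(motor_reps) ||
    qr(auditory_reps)$rank < ncol(auditory_reps)
  if (rank_deficient)
    warning("rank-deficient representation matrices; damped/pseudo-inverse solves will be used")
  fit_dir <- function(X, Y, s, max_attempts = 10) {
    # residuals of W X' - Y' stacked sample-major; params = vec(W) (k x d)
    d <- ncol(X); k <- ncol(Y); n <- nrow(X)
    Ik <- diag(k)
    model <- residual_model(
      residual = function(p) {
        W <- matrix(p, k, d)
        as.numeric(t(X %*% t(W) - Y))
      },
      jacobian = function(p) {
        J <- matrix(0, n * k, k * d)
        for (s_ in seq_len(n))
          J[(s_ - 1) * k + seq_len(k), ] <- kronecker(matrix(X[s_, ], 1, d), Ik)
        J
      }
    )
    # near-singular representation matrices can stall the damping schedule
    # (trial gains drop below double precision); retry from a fresh seeded
    # initialization when the error floor was not reached
    best <- NULL
    for (a in seq_len(max_attempts)) {
      init <- with_seed(s + 1000L * (a - 1L), stats::runif(k * d, -0.5, 0.5))
      fit <- lma_train(model, init, config, target_perf = target_error)
      if (is.null(best) || fit$perf < best$perf)
        best <- c(fit, list(attempts = a))
      if (fit$stop_reason == "target_perf") {
        best <- c(fit, list(attempts = a))
        break
      }
    }
    list(W = matrix(best$params, k, d), iterations = best$epoch,
         error = best$perf, stop_reason = best$stop_reason,
         attempts = best$attempts)
  }
  f1 <- fit_dir(motor_reps, auditory_reps, seed)
  f2 <- fit_dir(auditory_reps, motor_reps, seed + 1L)
  structure(list(w1 = f1$W, w2 = f2$W,
                 train_iterations = c(fingers_to_words = f1$iterations,
                                      words_to_fingers = f2$iterations),
                 train_error = c(fingers_to_words = f1$error,
                                 words_to_fingers = f2$error),
                 attempts = c(fingers_to_words = f1$attempts,
                              words_to_fingers = f2$attempts),
                 rank_deficient = rank_deficient),
            class = "associative_weights")
}

#' Map a hidden vector across modalities
#'
#' Applies the learned associative connection: `w1` for fingers-to-words,
#' `w2` for words-to-fingers. A zero vector maps to zero (the connection
#' is linear).
#'
#' @param h hidden vector (length 10).
#' @param direction `"fingers_to_words"` or `"words_to_fingers"`.
#' @param aw an [train_transfer()] result.
#' @return The transferred hidden vector.
#' @export
transfer <- function(h, direction = c("fingers_to_words", "words_to_fingers"),
                     aw) {
  direction <- match.arg(direction)
  stopifnot(inherits(aw, "associative_weights"))
  W <- if (direction == "fingers_to_words") aw$w1 else aw$w2
  stopifnot(length(h) == ncol(W))
  as.numeric(W %*% h)
}

#' Recognize a heard number word
#'
#' Nearest-neighbour matcher over the normalized MFCC table: the input
#' vector is scaled by the table's per-coefficient factors and compared to
#' each word row under Euclidean distance. Always returns a class (no
#' rejection threshold); the winning distance is attached for inspection.
#'
#' @param mfcc_row 13-vector of cepstral coefficients (table units).
#' @param table a [mfcc_table()].
#' @return Integer 1..10 with attribute `distance`.
#' @export
recognize_word <- function(mfcc_row, table = mfcc_table()) {
  stopifnot(is.numeric(mfcc_row), all(is.finite(mfcc_row)))
  norm <- normalize_features(table$values)
  x <- apply_scale(norm, mfcc_row)
  d <- sqrt(rowSums(sweep(norm$values, 2L, x, "-")^2))
  i <- which.min(d)
  structure(as.integer(i), distance = unname(d[i]))
}

# ---- switch state machine ------------------------------------------------

switch_modes <- c("idle", "start_all", "counting", "reset_auditory",
                  "reset_motor", "transfer_fingers_to_words",
                  "transfer_words_to_fingers", "output_to_classifier")

#' One transition of the switch layer's state machine
#'
#' The switch orchestrates the two counting memories. Events are
#' `operand_heard` (a number word was recognized), `plus_heard` (the sum
#' operator), `count_tick` (both active nets advance one step) and
#' `operand_done` (the operand counter has reached its target). The
#' transition table (default roles: motor net = accumulator, auditory net
#' = operand counter; `roles = "swapped"` exchanges them):
#'
#' | mode | event | next mode | directives |
#' |---|---|---|---|
#' | idle | operand_heard | start_all | init_motor_ones, init_auditory_ones |
#' | start_all | count_tick | counting | advance_both |
#' | counting | count_tick | counting | advance_both |
#' | counting | plus_heard | reset_auditory | clamp_auditory_zero |
#' | reset_auditory | operand_heard | start_all | init_auditory_ones |
#' | counting | operand_done | transfer_fingers_to_words | apply_w1 |
#' | transfer_fingers_to_words | operand_done | output_to_classifier | emit_to_classifier |
#' | output_to_classifier | operand_heard | start_all | init_motor_ones, init_auditory_ones |
#'
#' (with `reset_motor`, `apply_w2` and `transfer_words_to_fingers`
#' replacing their counterparts under swapped roles). Any other
#' (mode, event) pair is an illegal transition and errors.
#'
#' @param mode current mode (one of the eight switch modes).
#' @param event event name (`operand_heard`, `plus_heard`, `operand_done`,
#'   `count_tick`).
#' @param roles `"default"` (motor accumulates) or `"swapped"`.
#' @return List with `mode` (next mode) and `directives` (character
#'   vector of side-effect directives).
#' @export
switch_step <- function(mode, event, roles = c("default", "swapped")) {
  roles <- match.arg(roles)
  if (!mode %in% switch_modes) stop("unknown mode: ", mode)
  counter <- if (roles == "default") "auditory" else "motor"
  reset_mode <- paste0("reset_", counter)
  transfer_mode <- if (roles == "default") "transfer_fingers_to_words"
                   else "transfer_words_to_fingers"
  apply_dir <- if (roles == "default") "apply_w1" else "apply_w2"
  key <- paste(mode, event, sep = "|")
  init_all <- c("init_motor_ones", "init_auditory_ones")
  tab <- list(
    "idle|operand_heard" = list("start_all", init_all),
    "start_all|count_tick" = list("counting", "advance_both"),
    "counting|count_tick" = list("counting", "advance_both"),
    "counting|plus_heard" = list(reset_mode,
                                 paste0("clamp_", counter, "_zero")),
    "counting|operand_done" = list(transfer_mode, apply_dir),
    "output_to_classifier|operand_heard" = list("start_all", init_all)
  )
  tab[[paste0(reset_mode, "|operand_heard")]] <-
    list("start_all", paste0("init_", counter, "_ones"))
  tab[[paste0(transfer_mode, "|operand_done")]] <-
    list("output_to_classifier", "emit_to_classifier")
  hit <- tab[[key]]
  if (is.null(hit))
    stop("illegal transition: event '", event, "' in mode '", mode, "'")
  list(mode = hit[[1]], directives = hit[[2]])
}

# runtime wrapper advancing the motor controller one count step at a time
motor_runtime <- function(mcm) {
  list(mcm = mcm, step = 0L,
       right_h = start_state(mcm$right), right_y = mcm$right$context0,
       left_h = rep(0, mcm$left$hidden_size), left_y = mcm$left$context0)
}

motor_tick <- function(rt) {
  rt$step <- rt$step + 1L
  if (rt$step <= 5L) {
    h <- as.numeric(rt$mcm$right$w_in %*% rt$right_y +
                    rt$mcm$right$w_rec %*% rt$right_h)
    rt$right_h <- h
    rt$right_y <- as.numeric(rt$mcm$right$w_out %*% h)
  }  # right hand fully open after five: state held
  if (rt$step == 6L) rt$left_h <- start_state(rt$mcm$left)
  if (rt$step >= 6L) {
    h <- as.numeric(rt$mcm$left$w_in %*% rt$left_y +
                    rt$mcm$left$w_rec %*% rt$left_h)
    rt$left_h <- h
    rt$left_y <- as.numeric(rt$mcm$left$w_out %*% h)
  }
  rt
}

motor_hidden <- function(rt) c(rt$right_h, if (rt$step >= 6L) rt$left_h
                                           else rep(0, rt$mcm$left$hidden_size))

auditory_runtime <- function(net) {
  list(net = net, step = 0L, h = start_state(net),
       y = if (!is.null(net$context0)) net$context0 else rep(0, net$output_size))
}

auditory_tick <- function(rt) {
  rt$step <- rt$step + 1L
  h <- as.numeric(rt$net$w_in %*% rt$y + rt$net$w_rec %*% rt$h)
  rt$h <- h
  rt$y <- as.numeric(rt$net$w_out %*% h)
  rt
}

#' Two-operand addition with the counting system
#'
#' Executes the five-step embodied addition procedure on a trained system:
#' (1) the first operand is heard and both nets count up to it; (2) the
#' sum operator resets the auditory net while the motor memory holds the
#' first operand; (3) the second operand is heard and both nets count
#' again — the auditory net up to the second operand, the motor net on to
#' the total; (4) the motor hidden state is transferred to auditory form
#' through the associative connection `w1`; (5) the resulting
#' representation (motor hidden plus its transferred auditory image, the
#' classifier's native 20-dimensional layout) is emitted to the
#' competitive classifier.
#'
#' Operands are given as numbers and looked up as their word's MFCC row,
#' or directly as 13-vectors; either way they pass through
#' [recognize_word()], as heard words would.
#'
#' @param a,b operands (1..10, or 13-vectors of MFCCs); the sum must not
#'   exceed 10, the largest representable number.
#' @param system a trained system from [train_number_system()] (needs
#'   `mcm`, `auditory`, `aw`, `classifier`, `datasets`, `mfcc`).
#' @return Object of class `addition_trace`: list with `operand_a`,
#'   `operand_b`, `result_class`, `result_likelihood`, `probabilities` and
#'   `step_log` (data frame of mode/event/directive records).
#' @export
add_numbers <- function(a, b, system) {
  to_row <- function(x) {
    if (length(x) == 1L && is.numeric(x)) {
      if (!x %in% 1:10) stop("operands must be in 1..10")
      system$mfcc$values[x, ]
    } else x
  }
  a_n <- as.integer(recognize_word(to_row(a), system$mfcc))
  b_n <- as.integer(recognize_word(to_row(b), system$mfcc))
  if (a_n + b_n > 10)
    stop("overflow: ", a_n, " + ", b_n,
         " exceeds the representation range (1..10)")
  log_ <- list()
  note <- function(mode, event, directives, detail = "") {
    log_[[length(log_) + 1L]] <<- data.frame(
      mode = mode, event = event,
      directives = paste(directives, collapse = "+"), detail = detail)
  }
  mode <- "idle"
  mrt <- motor_runtime(system$mcm)
  art <- auditory_runtime(system$auditory)
  # step 1: first operand heard, both nets count to a
  tr <- switch_step(mode, "operand_heard"); mode <- tr$mode
  note(mode, "operand_heard", tr$directives, sprintf("operand %d", a_n))
  for (i in seq_len(a_n)) {
    tr <- switch_step(mode, "count_tick"); mode <- tr$mode
    mrt <- motor_tick(mrt); art <- auditory_tick(art)
    note(mode, "count_tick", tr$directives, sprintf("count %d", i))
  }
  # step 2: plus heard, auditory reset, motor holds the first operand
  tr <- switch_step(mode, "plus_heard"); mode <- tr$mode
  art$h <- rep(0, system$auditory$hidden_size); art$step <- 0L
  note(mode, "plus_heard", tr$directives, "auditory cleared")
  # step 3: second operand heard, both count again
  tr <- switch_step(mode, "operand_heard"); mode <- tr$mode
  art <- auditory_runtime(system$auditory)
  note(mode, "operand_heard", tr$directives, sprintf("operand %d", b_n))
  for (i in seq_len(b_n)) {
    tr <- switch_step(mode, "count_tick"); mode <- tr$mode
    mrt <- motor_tick(mrt); art <- auditory_tick(art)
    note(mode, "count_tick", tr$directives,
         sprintf("auditory %d, motor %d", i, mrt$step))
  }
  # step 4: transfer the total from fingers to words via w1
  tr <- switch_step(mode, "operand_done"); mode <- tr$mode
  mh <- motor_hidden(mrt)
  th <- transfer(mh, "fingers_to_words", system$aw)
  note(mode, "operand_done", tr$directives, "w1 applied to motor hidden")
  # step 5: emit to the classifier
  tr <- switch_step(mode, "operand_done"); mode <- tr$mode
  ds5 <- system$datasets[[5]]
  feat <- apply_scale(ds5$norm, c(mh, th))
  probs <- classify(system$classifier, feat)
  cls <- which.max(probs)
  note(mode, "operand_done", tr$directives,
       sprintf("classified as %d (p=%.3f)", cls, probs[cls]))
  structure(list(operand_a = a_n, operand_b = b_n,
                 result_class = as.integer(cls),
                 result_likelihood = unname(probs[cls]),
                 probabilities = probs,
                 step_log = do.call(rbind, log_)),
            class = "addition_trace")
}

#' @export
print.addition_trace <- function(x, ...) {
  cat(sprintf("<addition_trace> %d + %d -> %d (likelihood %.3f)\n",
              x$operand_a, x$operand_b, x$result_class, x$result_likelihood))
  invisible(x)
}

#' Serialize an addition trace to JSON
#'
#' @param trace an `addition_trace`.
#' @param path output file.
#' @export
write_trace_json <- function(trace, path) {
  jsonlite::write_json(unclass(trace), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
}
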