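#' Levenberg-Marquardt configuration
#'
#' Hyperparameters of the damped Gauss-Newton trainer used throughout the
#' package. Defaults follow the standard neural-network practice: damping
#' starts at `mu_init = 1e-3`, is multiplied by 10 after every rejected
#' trial step and by 0.1 after every accepted one, and training stops when
#' the performance gradient falls below `grad_tol`, the epoch cap is
#' reached, or `mu` overflows `mu_max`.
#'
#' @param mu_init initial damping scalar (> 0).
#' @param mu_increase factor applied to `mu` on rejection (> 1).
#' @param mu_decrease factor applied to `mu` on acceptance (in (0, 1)).
#' @param mu_max damping cap; exceeding it aborts the run.
#' @param grad_tol minimum performance gradient (infinity norm of the
#'   gradient of the mean squared residual); stop below it.
#' @param max_epochs accepted-iteration cap.
#' @return An object of class `lma_config`.
#' @export
lma_config <- function(mu_init = 1e-3, mu_increase = 10, mu_decrease = 0.1,
                       mu_max = 1e10, grad_tol = 1e-7, max_epochs = 1000) {
  stopifnot(mu_init > 0, mu_increase > 1,
            mu_decrease > 0, mu_decrease < 1,
            mu_max > mu_init, grad_tol > 0, max_epochs >= 1)
  structure(list(mu_init = mu_init, mu_increase = mu_increase,
                 mu_decrease = mu_decrease, mu_max = mu_max,
                 grad_tol = grad_tol, max_epochs = max_epochs),
            class = "lma_config")
}

#' Residual model for the Levenberg-Marquardt trainer
#'
#' Wraps the two callbacks the optimizer needs: `residual(params)`
#' returning the residual vector e, and `jacobian(params)` returning the
#' matrix J of first derivatives of each residual with respect to each
#' parameter (rows = residuals, columns = parameters).
#'
#' @param residual function: numeric parameter vector -> residual vector.
#' @param jacobian function: numeric parameter vector -> Jacobian matrix.
#' @return An object of class `residual_model`.
#' @export
residual_model <- function(residual, jacobian) {
  stopifnot(is.function(residual), is.function(jacobian))
  structure(list(residual = residual, jacobian = jacobian),
            class = "residual_model")
}

# Initial optimizer state for a parameter vector.
lma_init_state <- function(model, params, config) {
  r <- model$residual(params)
  if (any(!is.finite(r))) stop("non-finite residuals at initial parameters")
  list(params = params, mu = config$mu_init, epoch = 0L,
       perf = mean(r^2), grad_norm = NA_real_, stop_reason = "none")
}

# Solve (J'J + mu I) delta = J'e; falls back to the pseudo-inverse when the
# damped normal matrix is numerically singular.
lma_solve <- function(JtJ, g_half, mu) {
  A <- JtJ
  diag(A) <- diag(A) + mu
  tryCatch(solve(A, g_half),
           error = function(e) {
             sv <- svd(A)
             d <- sv$d
             inv <- ifelse(d > max(d) * 1e-12, 1 / d, 0)
             sv$v %*% (inv * crossprod(sv$u, g_half))
           })
}

#' One Levenberg-Marquardt iteration
#'
#' Computes the damped Gauss-Newton update `delta = (J'J + mu I)^-1 J' e`
#' and applies it tentatively. If the trial parameters reduce the
#' performance (mean of squared residuals) the step is accepted and `mu`
#' shrinks by `mu_decrease`; otherwise `mu` grows by `mu_increase` and the
#' solve is retried within the same step, so every counted epoch reduces
#' the performance. `mu` exceeding `mu_max` aborts with
#' `stop_reason = "mu_overflow"`.
#'
#' @param model a [residual_model()].
#' @param state optimizer state as returned by [lma_step()] itself or
#'   created internally by [lma_train()]; a plain parameter vector is also
#'   accepted for the first call.
#' @param config an [lma_config()].
#' @return Updated state: list with `params`, `mu`, `epoch`, `perf`
#'   (mean squared residual), `grad_norm` (infinity norm of the gradient of
#'   the mean squared residual) and `stop_reason`
#'   (`none`/`grad_tol`/`max_epochs`/`mu_overflow`).
#' @export
lma_step <- function(model, state, config = lma_config()) {
  if (is.numeric(state)) state <- lma_init_state(model, state, config)
  if (state$stop_reason != "none")
    stop("lma_step called on a stopped state (", state$stop_reason, ")")
  r <- model$residual(state$params)
  n <- length(r)
  J <- model$jacobian(state$params)
  stopifnot(nrow(J) == n, ncol(J) == length(state$params))
  g_half <- crossprod(J, r)                  # J'e
  state$grad_norm <- max(abs(2 * g_half / n))  # gradient of mean(e^2)
  if (state$grad_norm < config$grad_tol) {
    state$stop_reason <- "grad_tol"
    return(state)
  }
  JtJ <- crossprod(J)
  mu <- state$mu
  repeat {
    delta <- lma_solve(JtJ, g_half, mu)
    trial <- state$params - as.numeric(delta)
    r_try <- model$residual(trial)
    perf_try <- mean(r_try^2)
    if (is.finite(perf_try) && perf_try < state$perf) {
      state$params <- trial
      state$perf <- perf_try
      state$mu <- mu * config$mu_decrease
      state$epoch <- state$epoch + 1L
      if (state$epoch >= config$max_epochs) state$stop_reason <- "max_epochs"
      return(state)
    }
    mu <- mu * config$mu_increase
    if (mu > config$mu_max) {
      state$mu <- mu
      state$stop_reason <- "mu_overflow"
      return(state)
    }
  }
}

#' Train a residual model with Levenberg-Marquardt
#'
#' Iterates [lma_step()] until the performance gradient drops below
#' `grad_tol`, `max_epochs` accepted steps have been taken, the damping
#' overflows, or (optionally) the performance reaches `target_perf`.
#'
#' @param model a [residual_model()].
#' @param init_params finite numeric start vector.
#' @param config an [lma_config()].
#' @param target_perf optional performance level at which to stop early
#'   (used e.g. to count iterations-to-error-floor).
#' @param snapshots if `TRUE`, keep a copy of the parameter vector after
#'   every accepted epoch.
#' @return List with final `params`, `perf`, `epoch`, `grad_norm`, `mu`,
#'   `stop_reason`, a per-accepted-epoch `trace` data frame
#'   (`epoch`, `perf`, `grad_norm`, `mu`) and, if requested, `snapshots`.
#' @export
#' @examples
#' # quadratic bowl: residuals A x - b
#' A <- diag(3); b <- c(1, 2, 3)
#' m <- residual_model(function(x) A %*% x - b, function(x) A)
#' fit <- lma_train(m, rep(0, 3))
#' fit$params
lma_train <- function(model, init_params, config = lma_config(),
                      target_perf = NULL, snapshots = FALSE) {
  if (any(!is.finite(init_params))) stop("non-finite initial parameters")
  state <- lma_init_state(model, init_params, config)
  trace <- vector("list", config$max_epochs)
  snaps <- if (snapshots) vector("list", config$max_epochs) else NULL
  while (state$stop_reason == "none") {
    prev_epoch <- state$epoch
    state <- lma_step(model, state, config)
    if (state$epoch > prev_epoch) {  # an accepted step was taken
      trace[[state$epoch]] <- data.frame(epoch = state$epoch,
                                         perf = state$perf,
                                         grad_norm = state$grad_norm,
                                         mu = state$mu)
      if (snapshots) snaps[[state$epoch]] <- state$params
    }
    if (!is.null(target_perf) && state$perf <= target_perf &&
        state$stop_reason == "none") {
      state$stop_reason <- "target_perf"
    }
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  out <- list(params = state$params, perf = state$perf, epoch = state$epoch,
              grad_norm = state$grad_norm, mu = state$mu,
              stop_reason = state$stop_reason, trace = trace)
  if (snapshots) out$snapshots <- snaps[seq_len(state$epoch)]
  out
}

#' Central finite-difference Jacobian
#'
#' Independent derivative check used in tests and available for validating
#' custom residual models.
#'
#' @param f function: parameter vector -> residual vector.
#' @param x evaluation point.
#' @param h step size.
#' @return Numeric matrix, `length(f(x))` x `length(x)`.
#' @export
finite_diff_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
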