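# One trained counting system shared across test files (training takes a few
# seconds; tests that need a converged system reuse this one).
.system_cache <- new.env(parent = emptyenv())

shared_system <- function() {
  if (is.null(.system_cache$sys))
    .system_cache$sys <- train_number_system(seed = 42)
  .system_cache$sys
}

# textbook Levenberg-Marquardt transcription, kept deliberately independent of
# the package implementation; used as a trajectory oracle
reference_lm <- function(residual, jacobian, x, n_steps,
                         mu = 1e-3, mu_inc = 10, mu_dec = 0.1, mu_max = 1e10) {
  path <- list(x)
  r <- residual(x)
  perf <- mean(r^2)
  for (k in seq_len(n_steps)) {
    J <- jacobian(x)
    g <- t(J) %*% r
    A0 <- t(J) %*% J
    repeat {
      step <- solve(A0 + mu * diag(ncol(J)), g)
      x_try <- x - as.numeric(step)
      r_try <- residual(x_try)
      p_try <- mean(r_try^2)
      if (is.finite(p_try) && p_try < perf) {
        x <- x_try; r <- r_try; perf <- p_try; mu <- mu * mu_dec
        break
      }
      mu <- mu * mu_inc
      if (mu > mu_max) return(path)
    }
    path[[k + 1]] <- x
  }
  path
}
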