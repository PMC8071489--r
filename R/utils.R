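# internal validation helpers

stop_ggp <- function(msg, class, ...) {
  stop(structure(class = c(class, "ggpgmr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ggp(sprintf("`%s` must be a finite numeric scalar", name),
             "ggpgmr_validation_error")
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper)
    stop_ggp(sprintf("`%s` = %g outside allowed range", name, x),
             "ggpgmr_validation_error")
  invisible(x)
}

# deterministic child-seed derivation: one global seed fans out to
# per-purpose streams so any single trace can be regenerated in isolation
child_seed <- function(seed, index, stream = 0L) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729 +
     as.numeric(index) * 131) %% 2147483647
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  k <- as.integer(window)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  # pad the filter edges with shrinking one-sided means
  half <- k %/% 2
  for (i in seq_len(half)) {
    sm[i] <- mean(x[1:(i + half)])
    sm[n - i + 1L] <- mean(x[(n - i + 1L - half):n])
  }
  sm
}
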