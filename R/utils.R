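# internal helpers shared across modules

#' @keywords internal
stop_invalid <- function(msg, class = "habtrap_invalid_parameter") {
  stop(structure(class = c(class, "habtrap_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package generators draw through this,
# so a single integer seed makes every synthetic dataset reproducible without
# perturbing user RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_invalid("`seed` must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed so that modules drawing from the same master seed do
# not share RNG streams (splittable-seed contract for the generators).
#' @keywords internal
split_seed <- function(seed, k) {
  # double arithmetic: products exceed .Machine$integer.max but stay exact
  # well below 2^53
  (as.numeric(seed) * 69069 + as.numeric(k) * 1013) %% 2147483563
}

#' @keywords internal
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  ok_low <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_low || x > upper)
    stop_invalid(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper))
  invisible(x)
}
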