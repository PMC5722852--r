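#' Combine integers into a single reproducible seed
#'
#' Deterministically hashes a sequence of non-negative integers into a single
#' seed below `2^31`, so that independent random streams (per subject, per
#' restart, per stage) can be derived from one top-level seed without
#' collisions from naive arithmetic.
#'
#' @param ... Integer-like scalars (coerced with `as.numeric`).
#' @return A single integer in `[0, 2147483628]`.
#' @examples
#' seed_combine(1, 4)
#' seed_combine(1, 4) == seed_combine(1, 4)
#' @export
seed_combine <- function(...) {
  v <- vapply(list(...), as.numeric, numeric(1))
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("seed components must be finite and non-negative")
  }
  m <- 2147483629 # largest prime below 2^31; keeps doubles exact in the loop
  s <- 0
  for (x in v) {
    s <- (s * 7919 + (x %% m) + 1) %% m
  }
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# stopifnot-style scalar checks with readable messages
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper),
          class = "neckereeg_validation_error")
  }
  invisible(x)
}

logistic <- function(eta) stats::plogis(eta)

# trapezoidal rule over possibly irregular grid (thin wrapper kept private so
# the public quadrature convention lives in one place)
trapz2d <- function(f_axis, t_axis, z) {
  per_f <- apply(z, 1L, function(row) pracma::trapz(t_axis, row))
  pracma::trapz(f_axis, per_f)
}
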