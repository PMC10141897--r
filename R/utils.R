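# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations do not
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a slide-level seed from a cohort seed; kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 7919 * as.double(index)) %% 2147480000)
}

# Log-scale SD of a mean-one log-normal with coefficient of variation cv.
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Mean-one log-normal draws with coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- cv_to_sdlog(cv)
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
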