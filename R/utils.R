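# internal helpers shared across the package

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded operations do not perturb the ambient
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# draw n sub-seeds from the ambient (already seeded) stream
draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# recursively apply f over the numeric leaves of parameter lists a (and b),
# copying non-numeric leaves from a; errors on structural mismatch
map_params <- function(f, a, b = NULL) {
  if (is.list(a)) {
    if (!is.null(b)) {
      if (!is.list(b) || length(b) != length(a) ||
          !identical(names(a), names(b)))
        stopf("parameter structures do not match")
    }
    out <- lapply(seq_along(a), function(i)
      map_params(f, a[[i]], if (is.null(b)) NULL else b[[i]]))
    names(out) <- names(a)
    out
  } else if (is.numeric(a)) {
    if (!is.null(b)) {
      if (!is.numeric(b) || length(a) != length(b) ||
          !identical(dim(a), dim(b)))
        stopf("parameter structures do not match")
      f(a, b)
    } else {
      f(a)
    }
  } else {
    a
  }
}

# sum of squared numeric leaves (used for parameter distances in tests)
param_sumsq <- function(a) {
  tot <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) tot <<- tot + sum(x^2)
    invisible(NULL)
  }
  walk(a)
  tot
}
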