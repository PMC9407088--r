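# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded components never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Min-max rescale to [0, 1]; a constant input maps to all zeros.
normalize01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("cannot normalize non-finite intensities")
  d <- rng[2] - rng[1]
  if (d == 0) return(array(0, dim = dim(x) %||% length(x)))
  (x - rng[1]) / d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reflect (half-sample symmetric) index into 1..n: 0 -> 1, -1 -> 2, n+1 -> n.
reflect_index <- function(j, n) {
  repeat {
    bad_lo <- j < 1L
    bad_hi <- j > n
    if (!any(bad_lo) && !any(bad_hi)) return(j)
    j[bad_lo] <- 1L - j[bad_lo]
    j[bad_hi] <- 2L * n + 1L - j[bad_hi]
  }
}

# Wrap an angle in degrees to [0, 360).
wrap_deg <- function(a) ((a %% 360) + 360) %% 360

# Error condition used for degenerate geometric samples.
degenerate_error <- function(msg) {
  stop(errorCondition(msg, class = c("fmritemplate_degenerate", "error")))
}

# Error condition used when robust estimation cannot find a model.
ransac_failure <- function(msg) {
  stop(errorCondition(msg, class = c("fmritemplate_ransac_failure", "error")))
}
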