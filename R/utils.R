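# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `fn()` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library calls never perturb a caller's random
#' stream.
#'
#' @param seed single integer seed.
#' @param fn zero-argument function to evaluate.
#' @return the value of `fn()`.
#' @keywords internal
#' @noRd
with_rng_seed <- function(seed, fn) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  fn()
}

# binary matrix validation: 0/1, no NAs
check_binary_mask <- function(m, arg = "mask") {
  if (!is.matrix(m)) stop(sprintf("'%s' must be a matrix", arg), call. = FALSE)
  v <- as.vector(m)
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop(sprintf("'%s' must be binary (0/1) with no missing values", arg),
         call. = FALSE)
  invisible(TRUE)
}

as_plain_matrix <- function(x) {
  m <- as.matrix(x)
  dimnames(m) <- NULL
  m
}

# Dice overlap of two binary masks (used by QC and tests alike)
#' Dice similarity coefficient between two binary masks
#'
#' @param a,b binary matrices of identical shape.
#' @return Dice coefficient in \[0, 1\]; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  check_binary_mask(a, "a"); check_binary_mask(b, "b")
  if (!identical(dim(a), dim(b))) stop("mask shapes differ", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a * b) / denom
}
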