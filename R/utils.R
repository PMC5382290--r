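`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-seed for a named pipeline stage
#'
#' All stochastic stages draw their randomness from one master seed; each
#' stage perturbs it by a stable hash of its own name so that re-running a
#' single stage reproduces the full-pipeline behaviour bit for bit.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

ccm_log <- function(...) {
  if (isTRUE(getOption("ccmigrate.verbose", FALSE))) {
    message(sprintf("[ccmigrate %s] ", format(Sys.time(), "%H:%M:%S")),
            sprintf(...))
  }
  invisible(NULL)
}

#' Timed stage logging to stderr
#' @param stage stage name.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_stage_timer <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  on.exit(ccm_log("%s finished in %.1f s", stage,
                  proc.time()[["elapsed"]] - t0))
  expr
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) return(rep(NA_real_, length(v)))
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotation matrix about unit axis by angle (radians), Rodrigues form
rotation_matrix <- function(axis, angle) {
  a <- unitize(axis)
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
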