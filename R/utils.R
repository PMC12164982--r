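#' @keywords internal
"_PACKAGE"

# Condition helper: all package errors carry a class so the CLI can map them
# to exit codes (config -> 2, data -> 3, numeric -> 4).
abort <- function(msg, class = "piezotraj_data_error", call. = FALSE) {
  stop(structure(
    class = c(class, "piezotraj_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

abort_config  <- function(msg) abort(msg, "piezotraj_config_error")
abort_numeric <- function(msg) abort(msg, "piezotraj_numeric_error")

# Run code with a locally seeded RNG, restoring global RNG state afterwards.
# Every stochastic operation in the package funnels through this, so a single
# integer seed makes whole pipelines reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) {
    abort_config(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}
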