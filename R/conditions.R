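# Typed error conditions. Every malformed input raises a classed condition so
# callers (and tests) can distinguish format, validation, model, parameter and
# I/O failures without parsing messages.

sk_stop <- function(subclass, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "sk_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

sk_format_error    <- function(msg) sk_stop("sk_format_error", msg)
sk_validation_error <- function(msg) sk_stop("sk_validation_error", msg)
sk_model_error     <- function(msg) sk_stop("sk_model_error", msg)
sk_parameter_error <- function(msg) sk_stop("sk_parameter_error", msg)
sk_io_error        <- function(msg) sk_stop("sk_io_error", msg)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
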