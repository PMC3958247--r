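# Classed error conditions so callers (and the CLI) can distinguish bad
# parameters / bad input files (exit 1) from broken invariants (exit 2).

ft_stop <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "fatiguetrack_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_param     <- function(msg, ...) ft_stop("ft_param_error", msg, ...)
stop_input     <- function(msg, ...) ft_stop("ft_input_error", msg, ...)
stop_format    <- function(msg, ...) ft_stop("ft_format_error", msg, ...)
stop_invariant <- function(msg, ...) ft_stop("ft_invariant_error", msg, ...)
stop_sequence  <- function(msg, ...) ft_stop("ft_sequence_error", msg, ...)

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
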