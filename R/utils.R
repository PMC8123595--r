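#' @keywords internal
"_PACKAGE"

# Deterministic child-seed derivation: all randomness in the package flows
# from one root seed; independent stages draw from child generators so that
# adding a stage never perturbs the streams of the others.
# Arithmetic stays exact in doubles (< 2^53) and the result fits in a
# 32-bit integer.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 1103515 + 7919 * as.numeric(stream) + 1) %% m)
}

stop_dronelab <- function(msg, class, data = list()) {
  cond <- structure(
    class = c(class, "dronelab_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
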