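# Classed conditions so callers can distinguish failure modes programmatically.
pk_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "posturekit_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
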