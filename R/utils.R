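# Internal helpers shared across modules.

# Classed errors so callers can distinguish failure modes programmatically.
cs_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "calyxscan_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

cs_assert <- function(cond, msg, class = "calyxscan_parameter_error") {
  if (!isTRUE(cond)) cs_stop(msg, class)
}

# Derive a per-stage 32-bit seed from a master seed; keeps every random draw
# traceable to the master while staying below .Machine$integer.max.
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 1103L + stage * 12289) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
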