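# Classed conditions shared across the package. The CLI maps these classes
# to exit codes (parse -> 2, degeneracy -> 3, capability -> 4).

fp_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fp_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fp_stop_label <- function(label, where = "input") {
  fp_stop("fp_error_label", "unknown population label '%s' in %s", label, where)
}

fp_stop_parse <- function(msg, ...) fp_stop("fp_error_parse", msg, ...)
fp_stop_degenerate <- function(msg, ...) fp_stop("fp_error_degenerate", msg, ...)
fp_stop_capability <- function(msg, ...) fp_stop("fp_error_capability", msg, ...)
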