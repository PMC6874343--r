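# Classed conditions so callers (and the CLI) can distinguish usage errors
# from data errors.  All inherit from "sdtl_error".
stop_sdtl <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(paste0("sdtl_", class), "sdtl_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
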