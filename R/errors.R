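# Classed conditions so callers (and the CLI) can map failures to exit codes.

hpStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    list(message = msg, call = sys.call(-1)),
    class = c(class, "hammingpairsError", "error", "condition")
  ))
}

stopParameter  <- function(fmt, ...) hpStop("hpParameterError", fmt, ...)
stopFormat     <- function(fmt, ...) hpStop("hpFormatError", fmt, ...)
stopIdentifier <- function(fmt, ...) hpStop("hpIdentifierError", fmt, ...)
stopInput      <- function(fmt, ...) hpStop("hpInputError", fmt, ...)
stopBounds     <- function(fmt, ...) hpStop("hpBoundsError", fmt, ...)
stopIO         <- function(fmt, ...) hpStop("hpIOError", fmt, ...)
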