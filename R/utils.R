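#' @keywords internal
"_PACKAGE"

## Condition constructors. Every rejection carries a subclass so callers (and
## tests) can distinguish schema problems from integrity or parse problems.

pse_error <- function(subclass, message, ...) {
  stop(errorCondition(message, ..., class = c(subclass, "psecontext_error")))
}

pse_schema_error    <- function(msg, ...) pse_error("psecontext_schema_error", msg, ...)
pse_integrity_error <- function(msg, ...) pse_error("psecontext_integrity_error", msg, ...)
pse_parse_error     <- function(msg, ...) pse_error("psecontext_parse_error", msg, ...)
pse_domain_error    <- function(msg, ...) pse_error("psecontext_domain_error", msg, ...)
pse_design_error    <- function(msg, ...) pse_error("psecontext_design_error", msg, ...)
pse_contract_error  <- function(msg, ...) pse_error("psecontext_contract_error", msg, ...)
pse_io_error        <- function(msg, ...) pse_error("psecontext_io_error", msg, ...)

#' Derive a per-stage child seed from a master seed
#'
#' All randomized stages draw their seed deterministically from the single
#' master seed in the analysis configuration, so that the whole pipeline is
#' reproducible from one integer while stages remain decoupled.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"simulate"`, `"bootstrap"`).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

## z-score helper used throughout model fitting; returns x unchanged when the
## scale would degenerate (constant vector), callers guard separately.
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(x - mean(x, na.rm = TRUE))
  (x - mean(x, na.rm = TRUE)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Simple timestamped logger writing to a connection or stderr.
pse_log <- function(..., file = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(line)
}
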