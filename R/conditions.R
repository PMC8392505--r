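# Structured error conditions shared across modules. Every user-facing
# validation failure carries a class so callers (and the CLI) can react
# without string-matching messages.

stop_config <- function(field, msg, call = sys.call(-1)) {
  stop(errorCondition(
    sprintf("invalid configuration: `%s` %s", field, msg),
    class = c("seaomega_config_error", "seaomega_error", "error", "condition"),
    call = call
  ))
}

stop_insufficient <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(
    sprintf("insufficient data: %s", msg),
    class = c("seaomega_insufficient_data_error", "seaomega_error", "error", "condition"),
    call = call
  ))
}

stop_schema <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(
    sprintf("schema error: %s", msg),
    class = c("seaomega_schema_error", "seaomega_error", "error", "condition"),
    call = call
  ))
}

stop_degenerate <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(
    sprintf("degenerate design: %s", msg),
    class = c("seaomega_degenerate_error", "seaomega_error", "error", "condition"),
    call = call
  ))
}

warn_degenerate <- function(msg) {
  warning(warningCondition(
    msg,
    class = c("seaomega_degenerate_warning", "warning", "condition")
  ))
}

#' FBDG status categories
#'
#' The four food-based dietary guideline (FBDG) categories used throughout
#' the package: no FBDG at all (`none`), an FBDG without any seafood
#' recommendation (`no_recommendation`), an FBDG recommending seafood with a
#' serving size in g/day (`rec_with_serving`), and an FBDG recommending
#' seafood without a serving size (`rec_without_serving`).
#'
#' @return Character vector of the four category names, in this order.
#' @export
#' @examples
#' fbdg_levels()
fbdg_levels <- function() {
  c("none", "no_recommendation", "rec_with_serving", "rec_without_serving")
}

# Categories counted as "has a seafood recommendation" when the FBDG status
# is dichotomized for the quadrant analysis.
fbdg_recommendation_levels <- function() {
  c("rec_with_serving", "rec_without_serving")
}
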