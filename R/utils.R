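# small shared helpers

#' Null-coalescing helper
#' @name grapes-or-or-grapes
#' @param a,b values; `b` when `a` is NULL
#' @return `a` unless NULL, else `b`
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a
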