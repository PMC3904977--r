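#' @importFrom rlang .data %||%
#' @importFrom dplyr n
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

utils::globalVariables(c("."))
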