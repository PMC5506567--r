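#' @useDynLib activeNER, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom jsonlite write_json fromJSON
#' @importFrom stats optim median approx setNames runif rgamma
#' @importFrom utils head tail modifyList read.table write.table
NULL
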