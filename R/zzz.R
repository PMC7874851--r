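#' @useDynLib sfdiskin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd aov pf ptukey approx setNames
#' @importFrom utils read.csv write.csv
NULL
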