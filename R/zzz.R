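#' @keywords internal
#' @aliases fastaforge-package
#' @useDynLib fastaforge, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom utils head packageVersion write.table
#' @importFrom stats setNames
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  populate_registry()
}
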