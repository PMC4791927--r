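.onLoad <- function(libname, pkgname) {
  # ChemmineOB's compiled layer resolves Rcpp runtime symbols lazily; the
  # Rcpp shared library must be loaded before any OBMol-returning call.
  loadNamespace("Rcpp")
  invisible()
}
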