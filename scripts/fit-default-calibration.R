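#!/usr/bin/env Rscript
# Fits the packaged default calibration model: exact Lipinski descriptors of
# a synthetic fixture panel regressed on their fragment-additive estimates.
# Writes inst/extdata/calibration-default.json. Run from the repository
# root after any change to the fixture generator or descriptor code:
#   Rscript scripts/fit-default-calibration.R

suppressMessages(devtools::load_all("."))

panel <- make_fixtures(seed = 1L, n_parents = 25L)
exact <- lipinski_descriptors(panel)
raw <- do.call(rbind, lapply(panel, function(parent) {
  dec <- decompose(parent)
  frag_d <- lipinski_descriptors(lapply(dec$fragments, function(f) f$graph))
  as.data.frame(t(colSums(frag_d)))
}))

model <- calibrate(exact, raw)
print(model)
write_calibration(model, file.path("inst", "extdata",
                                   "calibration-default.json"))
cat("wrote inst/extdata/calibration-default.json\n")
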