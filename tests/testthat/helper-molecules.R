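# Shared fixture molecules, built programmatically from SMILES at test time.

mol <- function(smiles, name = "") smiles_to_molecule(smiles, name)

# the worked self-benchmarking example: thiophene + sulfonamide +
# 2,5-dimethylfuran + carboxylic acid, connected through sulfonamide and ring junctions
WORKED_EXAMPLE_SMILES <- "Cc1oc(C)c(C(O)=O)c1NS(=O)(=O)c1cccs1"

worked_parent <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- mol(WORKED_EXAMPLE_SMILES, "worked-example")
    cache
  }
})

# a small panel covering the supported element/type range
typing_panel_smiles <- c(
  "c1ccccc1", "Cc1ccccc1", "CCO", "CCN", "CC(=O)NC", "CC(=O)O", "CC([O-])=O",
  "c1ccncc1", "c1cc[nH]c1", "c1ccsc1", "c1ccoc1", "CS(=O)(=O)N", "CSC",
  "CS(C)=O", "CC#N", "C=CC", "C[N+](C)(C)C", "ClCCBr", "FC(F)(F)I",
  "OCP(O)(O)=O")
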