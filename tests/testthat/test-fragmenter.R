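test_that("rotatable bonds follow the torsion convention", {
  expect_equal(nrow(find_rotatable_bonds(mol("Cc1ccccc1"))), 0L)

  # biphenyl: only the ring-ring bond
  bip <- mol("c1ccc(cc1)-c1ccccc1")
  rb <- find_rotatable_bonds(bip)
  expect_equal(nrow(rb), 1L)
  expect_true(all(bip$atoms$sybyl[unlist(rb)] == "C.ar"))

  # ethylbenzene: only the ring-CH2 bond (CH2-CH3 is terminal)
  eb <- mol("CCc1ccccc1")
  rb <- find_rotatable_bonds(eb)
  expect_equal(nrow(rb), 1L)
  expect_setequal(eb$atoms$sybyl[unlist(rb)], c("C.3", "C.ar"))

  # amide C(=O)-N is excluded; the flanking single bonds are not
  am <- mol("CCC(=O)NCC")
  rb <- find_rotatable_bonds(am)
  el <- am$atoms$element
  pairs <- paste(el[rb$i], el[rb$j])
  expect_false(any(pairs %in% c("C N", "N C") &
                     (am$atoms$sybyl[rb$i] == "C.2" |
                        am$atoms$sybyl[rb$j] == "C.2")))
})

test_that("the worked four-fragment example decomposes as printed", {
  dec <- decompose(worked_parent())
  kinds <- vapply(dec$fragments, function(f) f$kind, character(1))
  expect_equal(sum(kinds == "rigid"), 2L)
  expect_equal(sum(kinds == "linker"), 2L)
  keys <- canonical_keys(lapply(dec$fragments, function(f) f$graph))
  # thiophene C4H4S and 2,5-dimethylfuran (CH3)2C4H2O rigids;
  # sulfonamide SO2N and carboxylic acid C(O)OH linkers
  expect_setequal(keys[kinds == "rigid"], c("c1cccs1", "Cc1ccc(o1)C"))
  expect_setequal(keys[kinds == "linker"], c("NS(=O)=O", "OC=O"))
  expect_equal(nrow(dec$junctions), 3L)
})

test_that("single-rigid and rigid-plus-linker molecules decompose correctly", {
  dec <- decompose(mol("Cc1ccccc1", "toluene"))
  expect_length(dec$fragments, 1L)
  expect_equal(dec$fragments[[1]]$kind, "rigid")
  expect_equal(nrow(dec$fragments[[1]]$graph$atoms), 7L)

  dec <- decompose(mol("CCc1ccccc1", "ethylbenzene"))
  kinds <- vapply(dec$fragments, function(f) f$kind, character(1))
  expect_setequal(kinds, c("rigid", "linker"))
  sizes <- vapply(dec$fragments, function(f) nrow(f$graph$atoms), integer(1))
  expect_setequal(sizes, c(6L, 2L))
  expect_error(decompose(molecule_graph(
    data.frame(element = character(), charge = integer()),
    data.frame(), validate = FALSE)), "empty|no atoms")
})

test_that("decomposition partitions atoms, keeps rigids pure and linkers apart", {
  panel <- c("CCc1ccccc1", WORKED_EXAMPLE_SMILES, "c1ccc(cc1)-c1ccccc1",
             "CCCCCC", "Cc1ccccc1", "c1ccc(CNCc2ccccc2)cc1",
             "OC(=O)c1ccc(cc1)S(=O)(=O)Nc1ccccc1")
  for (smi in panel) {
    parent <- mol(smi)
    dec <- decompose(parent)
    sizes <- vapply(dec$fragments, function(f) nrow(f$graph$atoms),
                    integer(1))
    expect_equal(sum(sizes), nrow(parent$atoms), info = smi)
    for (f in dec$fragments) {
      if (f$kind == "rigid") {
        expect_equal(nrow(find_rotatable_bonds(f$graph)), 0L, info = smi)
        expect_gte(nrow(f$graph$atoms), 4L)
      }
    }
    if (nrow(dec$junctions)) {
      kind_of <- vapply(dec$fragments, function(f) f$kind, character(1))
      both_linker <- kind_of[dec$junctions$frag_a] == "linker" &
        kind_of[dec$junctions$frag_b] == "linker"
      expect_false(any(both_linker), info = smi)
    }
  }
})

test_that("reassembling fragments along junctions reproduces the parent", {
  panel <- c("CCc1ccccc1", WORKED_EXAMPLE_SMILES, "c1ccc(CNCc2ccccc2)cc1",
             "OC(=O)c1ccc(cc1)S(=O)(=O)Nc1ccccc1")
  for (smi in panel) {
    parent <- mol(smi)
    dec <- decompose(parent)
    ids <- names(dec$fragments)
    offs <- integer(length(ids)); names(offs) <- ids
    atoms <- NULL; bonds <- NULL; off <- 0L
    for (id in ids) {
      g <- dec$fragments[[id]]$graph
      offs[id] <- off
      b <- g$bonds; b$i <- b$i + off; b$j <- b$j + off
      atoms <- rbind(atoms, g$atoms); bonds <- rbind(bonds, b)
      off <- off + nrow(g$atoms)
    }
    j <- dec$junctions
    for (k in seq_len(nrow(j))) {
      bonds <- rbind(bonds, data.frame(
        i = offs[j$frag_a[k]] + j$atom_a[k],
        j = offs[j$frag_b[k]] + j$atom_b[k], order = 1L))
    }
    rebuilt <- fill_hydrogen_counts(
      molecule_graph(atoms, bonds, validate = FALSE))
    expect_equal(canonical_key(rebuilt), canonical_key(parent), info = smi)
  }
})

test_that("hydrogen saturation is valence-exact and idempotent", {
  # a CH2 cut from two neighbours saturates to methane-like minus kept bonds
  ch2 <- molecule_graph(data.frame(element = c("C", "C"), charge = 0L),
                        data.frame(i = 1, j = 2, order = 1),
                        validate = FALSE)
  f <- new_fragment("linker", fill_hydrogen_counts(ch2))
  expect_equal(f$graph$atoms$hcount, c(3L, 3L))
  f2 <- saturate_with_hydrogens(f)
  expect_identical(f2$graph, f$graph)

  # the three-atom C.3-C.3-N.3 linker: capacities 3, 2, 2
  lnk <- new_fragment("linker", mol("CCN"))
  expect_equal(lnk$conn$sat, c(3L, 2L, 2L))
})

test_that("connection annotations reflect junction partners", {
  dec <- decompose(worked_parent())
  kinds <- vapply(dec$fragments, function(f) f$kind, character(1))
  keys <- canonical_keys(lapply(dec$fragments, function(f) f$graph))
  thio <- dec$fragments[[which(keys == "c1cccs1")]]
  # thiophene was bonded to the sulfonamide sulfur
  expect_true(all(unlist(thio$conn) == "S.O2"))
  sulf <- dec$fragments[[which(keys == "NS(=O)=O")]]
  expect_equal(sum(sulf$conn$orig), 2L)  # one bond at N, one at S
  acid <- dec$fragments[[which(keys == "OC=O")]]
  expect_equal(sum(acid$conn$orig), 1L)
  # a rigid with no junctions carries no connections
  dec2 <- decompose(mol("Cc1ccccc1"))
  expect_length(dec2$fragments[[1]]$conn, 0L)
})
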