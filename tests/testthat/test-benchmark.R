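test_that("fingerprint Tanimoto is symmetric, bounded and 1 for identical", {
  expect_equal(fingerprint_tc(mol("c1ccccc1"), mol("c1ccccc1")), 1)
  expect_lt(fingerprint_tc(mol("c1ccccc1"), mol("C1CCCCC1")), 1)
  set.seed(31)
  pool <- c("c1ccccc1", "c1ccncc1", "CCO", "CCN", "CCc1ccccc1",
            "Cc1cccs1", "OC(=O)c1ccccc1", "CS(=O)(=O)Nc1ccccc1")
  for (k in 1:10) {
    a <- mol(sample(pool, 1)); b <- mol(sample(pool, 1))
    expect_equal(fingerprint_tc(a, b), fingerprint_tc(b, a))
    expect_gte(fingerprint_tc(a, b), 0)
    expect_lte(fingerprint_tc(a, b), 1)
  }
})

test_that("MCS Tanimoto matches hand-computed overlaps", {
  benzene <- mol("c1ccccc1"); toluene <- mol("Cc1ccccc1")
  # MCS is the ring: 6 / (6 + 7 - 6)
  expect_equal(mcs_tc(benzene, toluene), 6 / 7, tolerance = 1e-9)
  expect_equal(mcs_tc(toluene, toluene), 1)
  # disjoint chemistries share no typed atoms at all
  expect_equal(mcs_tc(mol("CCCC"), benzene), 0)
  # equality with 1 only for isomorphic graphs on the fixture panel
  fx <- make_fixtures(seed = 7, n_parents = 3)
  for (i in seq_along(fx)) {
    for (j in seq_len(i)) {
      tc <- mcs_tc(fx[[i]], fx[[j]], time_budget = 10)
      if (is.na(tc)) next
      expect_lte(tc, 1)
      if (i == j) expect_equal(tc, 1)
      else if (canonical_key(fx[[i]]) != canonical_key(fx[[j]])) {
        expect_lt(tc, 1)
      }
    }
  }
})

test_that("leader clustering follows the greedy rule", {
  same <- lapply(rep("c1ccccc1", 4), mol)
  cl <- cluster_compounds(same, 0.7)
  expect_length(cl$clusters, 1L)

  distinct <- lapply(c("CCO", "c1ccccc1", "NCCN"), mol)
  cl <- cluster_compounds(distinct, 0.7)
  expect_length(cl$clusters, 3L)
  expect_setequal(unlist(cl$clusters), seq_along(distinct))

  # hand-traced greedy assignment on a crafted panel
  panel <- lapply(c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "CCO",
                    "CCCO"), mol)
  tc <- tanimoto_matrix(panel)
  keys <- canonical_keys(panel)
  ord <- order(keys)
  reps <- integer(0); want <- list()
  for (i in ord) {
    hit <- FALSE
    for (ci in seq_along(reps)) {
      if (tc[i, reps[ci]] >= 0.5) {
        want[[ci]] <- c(want[[ci]], i); hit <- TRUE; break
      }
    }
    if (!hit) { reps <- c(reps, i); want[[length(want) + 1L]] <- i }
  }
  got <- cluster_compounds(panel, 0.5)
  expect_identical(got$clusters, want)
})

test_that("reconstructibility is a rigid-inventory subset check", {
  parent <- worked_parent()
  lib_self <- consolidate(decompose(parent))
  expect_true(reconstructible(parent, lib_self))
  lib_other <- consolidate(decompose(mol("CCc1ccccc1", "eb")))
  expect_false(reconstructible(parent, lib_other))
  # flag equals the brute-force key-subset check across a panel
  fx <- make_fixtures(seed = 9, n_parents = 4)
  lib <- consolidate(unlist(lapply(fx[1:2], function(m) {
    decompose(m)$fragments
  }), recursive = FALSE))
  for (m in fx) {
    dec <- decompose(m)
    kinds <- vapply(dec$fragments, function(f) f$kind, character(1))
    rk <- canonical_keys(lapply(dec$fragments[kinds == "rigid"],
                                function(f) f$graph))
    expect_equal(reconstructible(m, lib), all(rk %in% rigid_keys(lib)))
  }
})

test_that("fixture generation is deterministic and self-consistent", {
  fx <- make_fixtures(seed = 42, n_parents = 10)
  fx2 <- make_fixtures(seed = 42, n_parents = 10)
  expect_identical(canonical_keys(fx), canonical_keys(fx2))
  thr <- ro5_thresholds("modified")
  for (m in fx) {
    expect_s3_class(m, "molecule_graph")
    expect_silent(validate_molecule_graph(m))
    k <- attr(m, "n_fragments")
    expect_true(k >= 2 && k <= 6)
    # the decomposition recovers the generating fragment multiset
    dec <- decompose(m)
    keys <- sort(canonical_keys(lapply(dec$fragments, function(f) f$graph)))
    expect_identical(keys, attr(m, "fragment_keys"))
    expect_true(passes_ro5(lipinski_descriptors(m), thr, "final"))
  }
})

test_that("single-fragment molecules are reported as not executed", {
  rep1 <- self_benchmark(list(mol("Cc1ccccc1", "toluene")),
                         benchmark_config(max_level = 2L))
  expect_false(rep1$per_compound$executed[1])
  expect_true(is.na(rep1$per_compound$max_tc[1]))
  expect_equal(unname(rep1$fractions["tc>=1"]), 0)
})

test_that("cumulative reconstruction fractions are monotone in the cutoff", {
  fx <- make_fixtures(seed = 42, n_parents = 4)
  rep <- self_benchmark(fx, benchmark_config())
  fr <- rep$fractions
  expect_true(all(diff(fr) >= 0))  # cutoffs ordered 1.0, 0.8, 0.6, 0.5
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("cross-validation holds out clusters and rescoring is monotone", {
  # two chemically distinct groups that share their rigid inventory
  g1 <- lapply(c("CCc1ccccc1", "CCCc1ccccc1"), mol)
  g2 <- lapply(c("OCC(=O)Oc1ccccc1", "NCC(=O)Oc1ccccc1"), mol)
  actives <- c(g1, g2)
  for (i in seq_along(actives)) actives[[i]]$name <- sprintf("a%d", i)
  rep <- cross_validate(actives, benchmark_config(max_level = 4L),
                        tc_cluster = 0.7)
  expect_gte(length(rep$clusters$clusters), 2L)
  expect_true(all(rep$per_compound$best_tc1d >= 0))
  expect_lte(rep$fractions[["tc2d>=0.6"]], rep$fractions[["tc2d>=0.5"]])
  # held-out compounds whose rigids all exist elsewhere are reconstructible
  expect_true(any(rep$per_compound$reconstructible))
  expect_error(cross_validate(lapply(rep("c1ccccc1", 3), mol)),
               "two clusters")
})
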