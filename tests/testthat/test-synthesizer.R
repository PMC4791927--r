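make_lib <- function(frags, mode = "unsaturated") {
  consolidate(frags, linker_mode = mode)
}

test_that("compose joins fragments in all and only the legal orientations", {
  # the two-fragment worked example: pyridine rigid + C-C-N linker
  py <- new_fragment("rigid", mol("c1ccncc1"))
  py$conn[["1"]] <- c("C.3", "N.3")
  lnk <- new_fragment("linker", mol("CCN"))
  lnk$conn$orig <- c(1L, 0L, 1L)
  lib <- make_lib(list(py, lnk))
  ids <- sort(names(lib$fragments))
  m1 <- synth_from_fragment(ensure_descriptors(lib), grep("rigid", ids,
                                                          value = TRUE))
  m2 <- synth_from_fragment(ensure_descriptors(lib), grep("linker", ids,
                                                          value = TRUE))
  prods <- compose(m1, m2)
  # bonding through the terminal carbon or the nitrogen: two 2-molecules
  expect_length(prods, 2L)
  expect_true(all(vapply(prods, function(m) m$level, integer(1)) == 2L))
  for (m in prods) validate_molecule_graph(m$graph)

  # two identical rigids accepting each other give a biphenyl-like product
  bz <- new_fragment("rigid", mol("c1ccccc1"))
  bz$conn[["1"]] <- "C.ar"
  lib2 <- ensure_descriptors(make_lib(list(bz)))
  r1 <- synth_from_fragment(lib2, names(lib2$fragments))
  prods2 <- compose(r1, r1)
  expect_length(prods2, 1L)
  expect_equal(prods2[[1]]$key, canonical_key(mol("c1ccc(cc1)-c1ccccc1")))

  # linkers never bond to each other
  l1 <- new_fragment("linker", mol("CC")); l1$conn$orig <- c(1L, 1L)
  lib3 <- ensure_descriptors(make_lib(list(l1)))
  lm <- synth_from_fragment(lib3, names(lib3$fragments))
  expect_length(compose(lm, lm), 0L)
})

test_that("exhaustive synthesis matches the brute-force oracle", {
  n_checked <- 0L
  seed <- 0L
  while (n_checked < 20L) {
    seed <- seed + 1L
    lib <- random_small_library(seed)
    if (is.null(lib)) next
    n_checked <- n_checked + 1L
    cfg <- synthesis_config(max_level = 3L, linker_mode = "unsaturated",
                            prefilter = FALSE)
    got <- synthesis_keys(synthesize_exhaustive(lib, cfg))
    want <- oracle_enumerate(lib, 3L)
    expect_identical(got, want, info = paste("seed", seed))
  }
  expect_gte(n_checked, 20L)
})

test_that("the worked example is rebuilt at level 4 from its own fragments", {
  parent <- worked_parent()
  lib <- consolidate(decompose(parent), linker_mode = "unsaturated")
  res <- synthesize_exhaustive(lib, synthesis_config(
    max_level = 4L, linker_mode = "unsaturated"))
  lv <- synthesis_levels(res)
  key <- canonical_key(parent)
  expect_true(key %in% names(lv))
  expect_equal(unname(lv[key]), 4L)
})

test_that("a connectionless rigid yields only itself", {
  bz <- new_fragment("rigid", mol("c1ccccc1"))
  lib <- make_lib(list(bz))
  res <- synthesize_exhaustive(lib, synthesis_config(max_level = 5L))
  expect_equal(synthesis_keys(res), "c1ccccc1")
  expect_error(
    synthesize_exhaustive(structure(list(fragments = list()),
                                    class = "esynth_library")),
    "empty")
})

test_that("bounded synthesis is contained in exhaustive synthesis", {
  parent <- worked_parent()
  lib <- consolidate(decompose(parent), linker_mode = "saturated")
  cfg_inf <- synthesis_config(max_level = 3L, linker_mode = "saturated",
                              bloom_n = 1e5)
  ex <- synthesize_exhaustive(lib, cfg_inf)
  bd <- synthesize_bounded(lib, cfg_inf)
  expect_setequal(synthesis_keys(bd), synthesis_keys(ex))

  cfg1 <- synthesis_config(max_level = 3L, linker_mode = "saturated",
                           level_capacity = 1, bloom_n = 1e5)
  bd1 <- synthesize_bounded(lib, cfg1)
  expect_true(all(synthesis_keys(bd1) %in% synthesis_keys(ex)))
  expect_lt(length(synthesis_keys(bd1)), length(synthesis_keys(ex)))
  expect_true(all(bd1$level_counts <= 1))

  cfg0 <- synthesis_config(max_level = 3L, linker_mode = "saturated",
                           wall_time_limit = 0, bloom_n = 1e5)
  bd0 <- synthesize_bounded(lib, cfg0)
  expect_true(bd0$truncated)
  expect_true(all(synthesis_levels(bd0) == 1L))
})

test_that("levels count fragment instances and products keep valid valences", {
  parent <- worked_parent()
  lib <- consolidate(decompose(parent), linker_mode = "unsaturated")
  res <- synthesize_exhaustive(lib, synthesis_config(
    max_level = 4L, linker_mode = "unsaturated"))
  for (m in res$molecules) {
    expect_equal(m$level, length(m$frag_ids))
    expect_silent(validate_molecule_graph(m$graph))
    expect_true(all(m$conn >= 0))
  }
})

test_that("synthesis output is deterministic across runs", {
  lib <- random_small_library(3)
  cfg <- synthesis_config(max_level = 3L, linker_mode = "unsaturated")
  k1 <- synthesis_keys(synthesize_exhaustive(lib, cfg))
  k2 <- synthesis_keys(synthesize_exhaustive(lib, cfg))
  expect_identical(k1, k2)
})

test_that("the pre-synthesis gate checks MW, HBD, HBA but not logP", {
  thr <- ro5_thresholds("modified")
  est <- data.frame(MW = 571, HBA = 2, HBD = 1, logP = 1)
  expect_false(passes_ro5(est, thr, "pre_synthesis"))
  est <- data.frame(MW = 570, HBA = 10, HBD = 5, logP = 7.2)
  expect_true(passes_ro5(est, thr, "pre_synthesis"))
  expect_true(passes_ro5(est, thr, "final"))
  est <- data.frame(MW = 400, HBA = 4, HBD = 2, logP = 9)
  expect_true(passes_ro5(est, thr, "pre_synthesis"))
  expect_false(passes_ro5(est, thr, "final"))
})
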