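test_that("exact descriptors match formula mass and Lipinski counting", {
  d <- lipinski_descriptors(list(mol("c1ccccc1"), mol("CS(=O)(=O)N"),
                                 mol("CCO")))
  # benzene: no N/O at all
  expect_equal(d$HBA[1], 0)
  expect_equal(d$HBD[1], 0)
  expect_equal(d$MW[1], 6 * 12.011 + 6 * 1.008, tolerance = 1e-6)
  # methanesulfonamide: N + 2 O acceptors, one N-H donor group
  expect_equal(d$HBA[2], 3)
  expect_gte(d$HBD[2], 1)
  # agreement with the toolkit's whole-molecule values
  ob <- ob_descriptors(list(mol("c1ccccc1"), mol("CS(=O)(=O)N"),
                            mol("CCO")))
  expect_equal(d$MW, as.numeric(ob$MW), tolerance = 0.05)
  expect_equal(d$HBD, as.numeric(ob$HBD))
})

test_that("raw estimates are additive and mass-balanced", {
  parent <- worked_parent()
  dec <- decompose(parent)
  lib <- ensure_descriptors(consolidate(dec, linker_mode = "unsaturated"))
  # single fragment: estimate equals the fragment's own descriptors
  id <- names(lib$fragments)[1]
  est1 <- estimate_descriptors(id, lib)
  expect_equal(unlist(est1), unlist(lib$descriptors[id, ]))
  # additivity of the raw estimate
  ids <- names(lib$fragments)
  est_all <- estimate_descriptors(ids, lib)
  expect_equal(est_all$MW, sum(lib$descriptors$MW))
  expect_error(estimate_descriptors("rigid:missing", lib), "missing")
})

test_that("MW mass balance holds exactly for synthesized molecules", {
  parent <- worked_parent()
  lib <- consolidate(decompose(parent), linker_mode = "unsaturated")
  res <- synthesize_exhaustive(lib, synthesis_config(
    max_level = 4L, linker_mode = "unsaturated"))
  lib <- ensure_descriptors(lib)
  for (m in res$molecules) {
    raw <- estimate_descriptors(m, lib)
    bonds_formed <- m$level - 1L
    expect_equal(molecular_weight(m$graph),
                 raw$MW - 2 * 1.008 * bonds_formed, tolerance = 1e-9)
    # saturation can only add donors
    exact_hbd <- sum(m$graph$atoms$element %in% c("N", "O") &
                       m$graph$atoms$hcount >= 1L)
    expect_gte(raw$HBD, exact_hbd)
    # the N+O count is conserved by bonding
    exact_hba <- sum(m$graph$atoms$element %in% c("N", "O"))
    expect_equal(raw$HBA, exact_hba)
  }
})

test_that("calibration recovers linear maps and reports correlations", {
  x <- data.frame(MW = seq(100, 500, length.out = 20), HBA = 1:20,
                  HBD = (1:20) / 2, logP = seq(-2, 6, length.out = 20))
  cal <- calibrate(x, x)  # exact == raw
  for (d in names(cal$model)) {
    expect_equal(cal$model[[d]]$slope, 1, tolerance = 1e-9)
    expect_equal(cal$model[[d]]$intercept, 0, tolerance = 1e-7)
    expect_equal(cal$model[[d]]$pcc, 1, tolerance = 1e-9)
  }
  # known slope without noise is recovered exactly
  raw <- x; raw$MW <- (x$MW - 5) / 0.8
  cal <- calibrate(x, raw)
  expect_equal(cal$model$MW$slope, 0.8, tolerance = 1e-9)
  expect_equal(cal$model$MW$intercept, 5, tolerance = 1e-6)
  # known slope with noise: within sampling error
  set.seed(99)
  n <- 500
  truth <- runif(n, 0, 10)
  raw <- data.frame(MW = truth, HBA = truth, HBD = truth, logP = truth)
  exact <- raw * 0.8
  exact$logP <- exact$logP + rnorm(n, 0, 0.1)
  cal <- calibrate(exact, raw)
  expect_equal(cal$model$logP$slope, 0.8, tolerance = 0.03)
  expect_error(calibrate(exact, transform(raw, MW = 1)), "degenerate")

  # applying the model transforms estimates (and clamps counts)
  est <- data.frame(MW = 100, HBA = 0.1, HBD = 0, logP = 1)
  cal2 <- calibrate(x, x)
  out <- apply_calibration(data.frame(MW = 100, HBA = -1, HBD = -2,
                                      logP = 1), cal2)
  expect_gte(out$HBA, 0)
  expect_gte(out$HBD, 0)

  # JSON round trip
  p <- tempfile(fileext = ".json")
  write_calibration(cal, p)
  cal_back <- read_calibration(p)
  expect_equal(cal_back$model$logP$slope, cal$model$logP$slope)
})

test_that("tightening thresholds never enlarges the pass set", {
  set.seed(5)
  est <- data.frame(MW = runif(200, 200, 700), HBA = sample(0:14, 200, TRUE),
                    HBD = sample(0:8, 200, TRUE), logP = runif(200, -2, 9))
  thr_loose <- ro5_thresholds("modified")
  thr_tight <- ro5_thresholds("classic")
  pass_loose <- vapply(seq_len(200), function(i) {
    passes_ro5(est[i, ], thr_loose, "final")
  }, logical(1))
  pass_tight <- vapply(seq_len(200), function(i) {
    passes_ro5(est[i, ], thr_tight, "final")
  }, logical(1))
  expect_true(all(!pass_tight | pass_loose))
  expect_false(passes_ro5(data.frame(MW = 510, HBA = 1, HBD = 1, logP = 1),
                          thr_tight, "final"))
})

test_that("ROC AUC equals the exhaustive pair statistic", {
  # perfectly separating scores
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  # brute force over all positive-negative pairs on a small table
  set.seed(13)
  scores <- c(0.9, 0.8, 0.8, 0.1, 0.7, 0.3, 0.8, 0.2)
  labels <- c(1, 1, 0, 0, 1, 0, 1, 0)
  pairs <- expand.grid(p = which(labels == 1), n = which(labels == 0))
  brute <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                       ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(scores, labels), brute)
  # label-independent scores at large n sit near 0.5
  sc <- runif(4000); lb <- sample(0:1, 4000, TRUE)
  expect_lt(abs(roc_auc(sc, lb) - 0.5), 0.05)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("the packaged default calibration loads and behaves sanely", {
  cal <- default_calibration()
  expect_s3_class(cal, "esynth_calibration")
  for (d in c("MW", "HBA", "HBD", "logP")) {
    expect_true(is.finite(cal$model[[d]]$slope))
  }
  # MW estimates overshoot (saturation hydrogens), so the fitted slope
  # must map estimates back down
  expect_lte(cal$model$MW$slope, 1)
  expect_gt(cal$model$MW$pcc, 0.95)
  expect_gt(cal$model$HBA$pcc, 0.95)
})
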