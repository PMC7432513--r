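quietProfile <- function(id = "s1", ...) {
  subjectProfile(id, occlusionRate = 0, ...)
}

test_that("the 3-D Gaussian step-norm constant is correct by Monte Carlo", {
  set.seed(1)
  s <- 0.013
  norms <- sqrt(rowSums(matrix(rnorm(3e5, 0, s), ncol = 3)^2))
  expect_lt(abs(mean(norms) / (2 * sqrt(2 / pi) * s) - 1), 0.01)
})

test_that("zero intensity and zero noise yield static frames and zero truth", {
  pr <- quietProfile(intensity = 0, minuteSd = 0)
  sim <- simulateSession(list(pr), simConfig(nSubjects = 1,
                                             sessionLength = 1,
                                             frameRate = 5, seed = 3))
  dt <- frameData(sim$stream)
  spread <- dt[, .(s = max(x_m) - min(x_m) + max(y_m) - min(y_m) +
                     max(z_m) - min(z_m)), by = joint]
  expect_lt(max(spread$s), 1e-12)
  expect_true(all(pathLength(sim$truth[[1]]) == 0))
})

test_that("identical seeds reproduce sessions bit for bit", {
  cfg <- simConfig(nSubjects = 2, sessionLength = 1, frameRate = 5, seed = 9)
  profs <- list(subjectProfile("a"), subjectProfile("b", group = "control"))
  s1 <- simulateSession(profs, cfg)
  s2 <- simulateSession(profs, cfg)
  expect_identical(frameData(s1$stream), frameData(s2$stream))
  expect_identical(pathLength(s1$truth[["a"]]), pathLength(s2$truth[["a"]]))
  s3 <- simulateSession(profs, simConfig(nSubjects = 2, sessionLength = 1,
                                         frameRate = 5, seed = 10))
  expect_false(identical(frameData(s1$stream), frameData(s3$stream)))
})

test_that("expected per-minute path length matches the intensity target", {
  # minute-level variability off: this isolates the calibration constant
  means <- vapply(1:10, function(k) {
    pr <- quietProfile(intensity = 6, minuteSd = 0)
    sim <- simulateSession(list(pr), simConfig(nSubjects = 1,
                                               sessionLength = 2,
                                               frameRate = 10, seed = 100 + k))
    mean(pathLength(sim$truth[[1]])["head", ])
  }, 0)
  expect_lt(abs(mean(means) / 6 - 1), 0.02)
})

test_that("the calibration holds across frame rates and intensities", {
  for (cfg in list(c(f = 5, lam = 2), c(f = 20, lam = 12))) {
    means <- vapply(1:6, function(k) {
      pr <- quietProfile(intensity = cfg[["lam"]], minuteSd = 0)
      sim <- simulateSession(list(pr), simConfig(
        nSubjects = 1, sessionLength = 2, frameRate = cfg[["f"]],
        seed = 200 + k))
      mean(pathLength(sim$truth[[1]]))
    }, 0)
    expect_lt(abs(mean(means) / cfg[["lam"]] - 1), 0.03)
  }
})

test_that("without occlusion the pipeline reproduces the ground truth", {
  pr <- list(quietProfile("a"), quietProfile("b", group = "control"))
  sim <- simulateSession(pr, simConfig(nSubjects = 2, sessionLength = 2,
                                       frameRate = 10, seed = 17))
  ms <- quantifySession(sim$stream, setNames(
    lapply(sim$slotMap$subject_id, sessionMeta, sessionLength = 2),
    as.character(sim$slotMap$persistent_id)))
  for (k in seq_len(nrow(sim$slotMap))) {
    sid <- sim$slotMap$subject_id[k]
    pid <- as.character(sim$slotMap$persistent_id[k])
    expect_lt(max(abs(pathLength(ms[[pid]]) - pathLength(sim$truth[[sid]]))),
              1e-9)
  }
})

test_that("occlusions create missing or reduced minutes, never inflated ones", {
  pr <- subjectProfile("a", occlusionRate = 6, occlusionDuration = 4)
  sim <- simulateSession(list(pr), simConfig(nSubjects = 1,
                                             sessionLength = 3,
                                             frameRate = 10, seed = 23))
  ms <- quantifySession(sim$stream, sessionMeta("a", sessionLength = 3))
  measured <- pathLength(ms[[1]])
  truth <- pathLength(sim$truth[["a"]])
  expect_true(all(is.na(measured) | measured <= truth + 1e-9))
  expect_gt(sum(is.na(measured) | measured < truth - 1e-9), 0)
})

test_that("more than six subjects is a capacity error", {
  profs <- lapply(1:7, function(i) quietProfile(paste0("s", i)))
  expect_error(simulateSession(profs, simConfig(nSubjects = 6, seed = 1)),
               "capacity|6")
  expect_error(simConfig(nSubjects = 7), "nSubjects")
})

test_that("two-group simulation recovers a null effect", {
  set.seed(33)
  # analytic minute-value shortcut at large n: d-hat concentrates near 0
  g1 <- makeMatrixList(10, 100, function(r, c)
    matrix(simulateMinuteValues(r * c, 6, 1.5), r))
  g2 <- makeMatrixList(10, 100, function(r, c)
    matrix(simulateMinuteValues(r * c, 6, 1.5), r), prefix = "n")
  cmp <- compareGroups(g1, g2)
  expect_lt(mean(abs(cmp$d)), 0.05)
})

test_that("the programmed shift matches the analytic within-minute noise", {
  # frame-level minute values at minuteSd = 0 should have the predicted SD
  pr <- quietProfile(intensity = 6, minuteSd = 0)
  vals <- unlist(lapply(1:12, function(k) {
    sim <- simulateSession(list(pr), simConfig(nSubjects = 1,
                                               sessionLength = 3,
                                               frameRate = 10, seed = 400 + k))
    pathLength(sim$truth[[1]])["head", ]
  }))
  predicted <- sqrt(JointMotion:::.withinMinuteVar(6, 10))
  expect_lt(abs(sd(vals) / predicted - 1), 0.35)  # 36 minutes, loose check
})

test_that("observer counts behave at the agreement extremes", {
  perfect <- simulateObserverCounts(30, rateA = 6, agreementProb = 1,
                                    seed = 5)
  expect_identical(perfect$observer_a, perfect$observer_b)
  expect_identical(as.numeric(observerKappa(perfect)), 1)

  chance <- simulateObserverCounts(600, rateA = 6, agreementProb = 0,
                                   seed = 6)
  expect_lt(abs(as.numeric(observerKappa(chance))), 0.05)

  again <- simulateObserverCounts(30, rateA = 6, agreementProb = 1, seed = 5)
  expect_identical(perfect, again)
})
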