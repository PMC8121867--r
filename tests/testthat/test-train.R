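test_that("patient-level splits follow the 75/12.5/12.5 contract", {
  pats <- data.frame(patient_id = sprintf("p%02d", 1:80),
                     label = rep(c(0L, 1L), each = 40))
  cfg <- mcConfig(seed = 3)
  sp <- mcPatientSplit(pats, 1, cfg, "cell")
  expect_length(sp$train, 60)
  expect_length(sp$validation, 10)
  expect_length(sp$test, 10)
  # determinism
  sp2 <- mcPatientSplit(pats, 1, cfg, "cell")
  expect_identical(sp, sp2)
  # partition property across repetitions, stratification in train
  for (r in c(2, 9, 31)) {
    s <- mcPatientSplit(pats, r, cfg, "cell")
    all3 <- c(s$train, s$validation, s$test)
    expect_setequal(all3, pats$patient_id)
    expect_equal(anyDuplicated(all3), 0)
    expect_equal(length(unique(pats$label[pats$patient_id %in% s$train])), 2)
  }
  # MIL mode: held-out 25% is all test
  sm <- mcPatientSplit(pats, 1, cfg, "mil")
  expect_length(sm$train, 60)
  expect_length(sm$validation, 0)
  expect_length(sm$test, 20)
  expect_error(mcPatientSplit(pats[1:3, ], 1, cfg), "4 patients")
  expect_error(
    mcPatientSplit(data.frame(patient_id = c("a", "b", "c", "d"),
                              label = c(0L, 0L, 0L, 1L)), 1, cfg),
    "too few")
})

test_that("rocAuc equals the concordant-pair probability, ties counted half", {
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(rocAuc(c(0, 0, 1), c(1, 2, 3)), 1)
  expect_equal(rocAuc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(44)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    l <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- sample(seq(0, 1, 0.25), n, TRUE)   # coarse grid forces ties
    expect_equal(rocAuc(l, s), pairAuc(l, s))
  }
  # invariance under strictly monotone transforms
  l <- c(0, 1, 1, 0, 1, 0, 0, 1)
  s <- c(0.1, 0.9, 0.4, 0.4, 0.7, 0.2, 0.5, 0.3)
  expect_equal(rocAuc(l, s), rocAuc(l, exp(3 * s)))
  expect_equal(rocAuc(l, s), rocAuc(l, rank(s, ties.method = "average")))
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "one class")
  expect_error(rocAuc(c(0, 1), 0.5), "equal length")
})

test_that("rocAuc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:20) {
    l <- c(0, 1, sample(0:1, 30, TRUE))
    s <- round(runif(32), 2)
    expect_equal(rocAuc(l, s),
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("promyelocyte fraction is the plain proportion", {
  s <- new("PatientSample", patient_id = "p", label = 1L,
           cohort = "discovery",
           cell_types = c(rep("promyelocyte", 20), rep("blast", 180)),
           paths = sprintf("c%03d.png", 1:200), cells = list())
  expect_equal(promyelocyteFraction(s), 0.10)
  s@cell_types <- rep("blast", 200)
  expect_equal(promyelocyteFraction(s), 0)
  fr <- promyelocyteFraction(smallCohort())
  expect_length(fr, 6)
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("training rejects class-missing splits", {
  tens <- smallTensors()
  cfg <- fastConfig()
  ids <- sort(unique(tens$manifest$patient_id))
  apl <- ids[startsWith(ids, "disc_apl")]
  sp <- list(rep_id = 1, train = apl[1:2], validation = apl[3],
             test = setdiff(ids, apl))
  expect_error(trainCellClassifier(tens, sp, "all_cells", cfg),
               "class is absent")
  expect_error(trainMil(tens, sp, "all_cells", cfg), "class is absent")
})

test_that("a small Monte-Carlo run is out-of-fold, complete and ensemble-ready", {
  tens <- smallTensors()
  cfg <- fastConfig(n_reps = 2)
  run <- runMonteCarlo(tens, mode = "cell", scope = "all_cells",
                       config = cfg)
  expect_s4_class(run$ensemble, "SmearEnsemble")
  expect_length(ensembleModels(run$ensemble), 2)
  expect_true(all(vapply(ensembleModels(run$ensemble),
                         function(m) m@trained, logical(1))))
  # every pooled prediction comes from that repetition's test split
  for (r in 1:2) {
    sp <- run$ensemble@splits[[r]]
    cells_r <- run$report$per_cell[run$report$per_cell$rep_id == r, ]
    expect_true(all(cells_r$patient_id %in% sp$test))
    expect_false(any(cells_r$patient_id %in% c(sp$train, sp$validation)))
  }
  expect_true(is.finite(run$report$auc_cell))
  # n_reps = 1 also produces a report
  run1 <- runMonteCarlo(tens, mode = "cell", scope = "all_cells",
                        config = fastConfig(n_reps = 1))
  expect_length(ensembleModels(run1$ensemble), 1)
  expect_equal(unique(run1$report$per_cell$rep_id), 1)
})

test_that("ensemble prediction is the unweighted mean of member scores", {
  tens <- smallTensors()
  m1 <- buildCellClassifier(seed = 1)
  m2 <- buildCellClassifier(seed = 2)
  sp <- list(rep_id = 1, train = character(), validation = character(),
             test = character())
  mk <- function(models) new("SmearEnsemble", models = models,
                             splits = rep(list(sp), length(models)),
                             mode = "cell", scope = "all_cells",
                             config = list())
  r1 <- ensemblePredict(mk(list(m1)), tens)
  r2 <- ensemblePredict(mk(list(m2)), tens)
  r12 <- ensemblePredict(mk(list(m1, m2)), tens)
  expect_equal(r12$per_cell$score,
               (r1$per_cell$score + r2$per_cell$score) / 2,
               tolerance = 1e-12)
  # identical members leave the score unchanged
  rdup <- ensemblePredict(mk(list(m1, m1)), tens)
  expect_equal(rdup$per_cell$score, r1$per_cell$score, tolerance = 1e-12)
  # cell-mode per-sample score is the mean per-cell score of that patient
  p <- r1$per_sample$patient_id[1]
  expect_equal(r1$per_sample$score[1],
               mean(r1$per_cell$score[r1$per_cell$patient_id == p]))
  expect_error(ensemblePredict(mk(list(m1)),
                               list(X = tens$X,
                                    manifest = tens$manifest[0, ])),
               "empty cohort")
})

test_that("MIL training honors the bag contract end-to-end", {
  tens <- smallTensors()
  cfg <- fastConfig(n_reps = 1)
  sp <- mcPatientSplit(smallCohort(), 1, cfg, "mil")
  fit <- suppressWarnings(trainMil(tens, sp, "all_cells", cfg))
  expect_true(fit$model@trained)
  expect_true(all(fit$samples$patient_id %in% sp$test))
  # returned bag probability equals the mean of the returned per-cell
  # probabilities for every test patient (identity re-checked end-to-end
  # on the renormalized binary scale via the model's own aggregation)
  for (p in fit$samples$patient_id) {
    ix <- which(tens$manifest$patient_id == p)
    pred <- predictBag(fit$model, tens$X[, , , ix, drop = FALSE])
    expect_equal(pred$bag_probs, colMeans(pred$per_cell_probs),
                 tolerance = 1e-6)
    expect_equal(fit$samples$score[fit$samples$patient_id == p],
                 pred$p_apl_binary, tolerance = 1e-6)
  }
})

test_that("evaluation reports serialize to JSON and CSV", {
  tens <- smallTensors()
  run <- runMonteCarlo(tens, mode = "cell", scope = "all_cells",
                       config = fastConfig(n_reps = 1))
  d <- withr::local_tempdir()
  writeReport(run$report, d)
  expect_true(file.exists(file.path(d, "report.json")))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(js$mode, "cell")
  expect_true(is.numeric(js$auc_cell))
  expect_true(file.exists(file.path(d, "per_cell.csv")))
  expect_true(file.exists(file.path(d, "roc.png")))
})
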