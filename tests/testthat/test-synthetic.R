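test_that("rendering is deterministic given the seed", {
  set.seed(11)
  a <- renderCellImage("APL", "promyelocyte", size = 48)
  set.seed(11)
  b <- renderCellImage("APL", "promyelocyte", size = 48)
  expect_identical(a, b)
  set.seed(12)
  c <- renderCellImage("APL", "promyelocyte", size = 48)
  expect_false(identical(a, c))
})

test_that("noise-free, granule-free rendering is a pure function of geometry", {
  p <- morphologyParams(noise_sd = 0, granule_density = 0)
  set.seed(1)
  a <- renderCellImage("APL", "blast", p, size = 48)
  set.seed(999)
  b <- renderCellImage("APL", "blast", p, size = 48)
  expect_identical(a, b)
})

test_that("unknown cell types are rejected with a named enum error", {
  expect_error(renderCellImage("APL", "megakaryocyte"), class = "cellTypeError")
  expect_error(renderCellImage("APL", "megakaryocyte"),
               "segmented neutrophil")
})

test_that("APL regime concentrates chromatin absorbance at the nucleus center", {
  # independent oracle: radial absorbance profile over a centered nucleus
  # disc, computed directly from pixels, no renderer internals
  ratioFor <- function(cls, n = 60, size = 64) {
    vapply(seq_len(n), function(i) {
      im <- renderCellImage(cls, "blast", size = size)
      g <- (im[, , 1] + im[, , 2] + im[, , 3]) / 3
      ctr <- (size + 1) / 2
      xi <- matrix(seq_len(size), size, size)
      r <- sqrt((xi - ctr)^2 + (t(xi) - ctr)^2)
      nucR <- 0.30 * size          # default nucleus radius
      inner <- r < 0.5 * nucR
      outer <- r >= 0.5 * nucR & r < 0.9 * nucR
      (255 - mean(g[inner])) / (255 - mean(g[outer]))
    }, numeric(1))
  }
  set.seed(21)
  apl <- ratioFor("APL")
  set.seed(22)
  non <- ratioFor("non-APL")
  expect_gt(mean(apl), mean(non))
  expect_gt(mean(apl), 1)     # condensed center: more absorbance centrally
  expect_lt(mean(non), 1)     # dispersed rim: more absorbance peripherally
})

test_that("morphology and batch parameter validation enforces the invariants", {
  expect_error(morphologyParams(chromatin_centrality = 1.2), "centrality")
  expect_error(morphologyParams(granule_density = -1), "granule")
  expect_error(morphologyParams(nucleus_radius_px = 0), "radius")
  expect_error(batchEffect(color_shift_rgb = c(100, 0, 0)), "64")
  expect_error(batchEffect(class_correlation = 2), "class_correlation")
  expect_error(cohortConfig(cells_per_patient = 50), "100")
  bad <- defaultMixtures(); bad$apl[1] <- bad$apl[1] + 0.1
  expect_error(cohortConfig(mixtures = bad), "sum to 1")
})

test_that("an empty cohort yields a header-only manifest", {
  d <- withr::local_tempdir()
  cfg <- cohortConfig(n_apl = 0, n_nonapl = 0, seed = 3)
  co <- simulateCohort(cfg, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  man <- read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), 0)
  expect_true(all(c("patient_id", "label", "cell_type", "path") %in%
                  names(man)))
})

test_that("cohort generation matches its configuration and is reproducible", {
  co <- smallCohort()
  man <- manifest(co)
  expect_equal(length(unique(man$patient_id)), 6)
  expect_true(all(table(man$patient_id) == 100))
  labs <- patientLabels(co)
  expect_equal(sum(labs == 1), 3)
  # byte-identical regeneration from the same config
  d2 <- withr::local_tempdir()
  cfg <- cohortConfig(n_apl = 3, n_nonapl = 3, cells_per_patient = 100,
                      image_size = 32, seed = 42)
  co2 <- simulateCohort(cfg, d2)
  man2 <- manifest(co2)
  expect_equal(man$patient_id, man2$patient_id)
  expect_equal(man$cell_type, man2$cell_type)
  some <- man$path[c(1, 57, 301, 599)]
  for (p in some)
    expect_identical(readBin(file.path(co@root, p), "raw", 1e6),
                     readBin(file.path(d2, p), "raw", 1e6))
})

test_that("per-class mixtures land within exact binomial bounds", {
  # one APL patient at the default 200 cells and promyelocyte weight 0.4
  d <- withr::local_tempdir()
  cfg <- cohortConfig(n_apl = 1, n_nonapl = 0, image_size = 32, seed = 17)
  expect_equal(cfg$cells_per_patient, 200)
  co <- simulateCohort(cfg, d)
  man <- manifest(co)
  expect_equal(nrow(man), 200)
  npro <- sum(man$cell_type == "promyelocyte")
  bounds <- qbinom(c(0.005, 0.995), 200, 0.4)
  expect_gte(npro, bounds[1])
  expect_lte(npro, bounds[2])
})

test_that("era assignment follows the class-correlation confound", {
  d <- withr::local_tempdir()
  cfg <- cohortConfig(n_apl = 4, n_nonapl = 4, cells_per_patient = 100,
                      image_size = 32, seed = 5,
                      batch = batchEffect(class_correlation = 1))
  man <- manifest(simulateCohort(cfg, d))
  era <- tapply(man$era_id, man$patient_id, unique)
  lab <- tapply(man$label, man$patient_id, unique)
  expect_true(all(era[lab == 1] == "pre2018"))
  expect_true(all(era[lab == 0] == "post2018"))
})

test_that("cohort config YAML round-trips", {
  d <- withr::local_tempdir()
  cfg <- cohortConfig(n_apl = 2, n_nonapl = 3, cells_per_patient = 150,
                      image_size = 64, seed = 9,
                      batch = batchEffect(class_correlation = 0.7))
  f <- file.path(d, "cfg.yaml")
  writeCohortConfig(cfg, f)
  back <- readCohortConfig(f)
  expect_equal(back$n_apl, 2L)
  expect_equal(back$cells_per_patient, 150L)
  expect_equal(back$batch$class_correlation, 0.7)
  expect_equal(back$morphology$apl$chromatin_centrality,
               cfg$morphology$apl$chromatin_centrality)
})
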