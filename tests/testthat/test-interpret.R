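test_that("an image identical to its baseline attributes nothing", {
  m <- buildCellClassifier(seed = 1)
  img <- randomImages(1, size = 32, seed = 2)[, , , 1]
  am <- integratedGradients(m, img, steps = 10, baseline = img)
  expect_equal(am$values, matrix(0, 32, 32))
  expect_error(integratedGradients(m, img, steps = 1), "steps")
})

test_that("integrated gradients are exact for a linear surrogate", {
  set.seed(3)
  img <- array(runif(18 * 18 * 3), c(18, 18, 3))
  base <- gaussianBlurImage(img, 2)
  wlin <- array(rnorm(length(img), sd = 0.2), dim(img))
  gradFun <- function(P) {
    g <- P
    for (k in seq_len(dim(P)[4])) g[, , , k] <- wlin
    g
  }
  got <- smearMIL:::.igCore(gradFun, img, base, 60)
  exact <- apply(wlin * (img - base), c(1, 2), sum)
  expect_equal(got, exact, tolerance = 1e-4)
})

test_that("the completeness axiom holds with error shrinking in the step count", {
  m <- buildCellClassifier(seed = 6)
  set.seed(7)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  base <- gaussianBlurImage(img, 1)
  dp <- deltaPrediction(m, img) - deltaPrediction(m, base)
  errs <- vapply(c(25, 50, 100, 200), function(st) {
    am <- integratedGradients(m, img, steps = st, baseline = base)
    abs(sum(am$values) - dp)
  }, numeric(1))
  expect_lt(errs[4], errs[1])
  expect_lt(errs[3], 0.05)
})

test_that("consensus attribution is a seeded mean over members", {
  models <- lapply(1:4, function(s) buildCellClassifier(seed = s))
  sp <- list(rep_id = 1, train = character(), validation = character(),
             test = character())
  ens <- new("SmearEnsemble", models = models, splits = rep(list(sp), 4),
             mode = "cell", scope = "all_cells", config = list())
  img <- randomImages(1, size = 32, seed = 9)[, , , 1]
  one <- consensusAttribution(ens, img, n_models = 1, seed = 3, steps = 10)
  member <- integratedGradients(models[[one$members]], img, steps = 10)
  expect_equal(one$values, member$values)
  # identical models: consensus equals the single map
  ens2 <- new("SmearEnsemble", models = rep(models[1], 3),
              splits = rep(list(sp), 3), mode = "cell",
              scope = "all_cells", config = list())
  cons <- consensusAttribution(ens2, img, n_models = 3, seed = 1, steps = 10)
  expect_equal(cons$values,
               integratedGradients(models[[1]], img, steps = 10)$values,
               tolerance = 1e-12)
  # seeded determinism
  a <- consensusAttribution(ens, img, n_models = 2, seed = 5, steps = 10)
  b <- consensusAttribution(ens, img, n_models = 2, seed = 5, steps = 10)
  expect_identical(a$values, b$values)
  expect_error(consensusAttribution(ens, img, n_models = 9), "exceeds")
})

test_that("most predictive cells rank by score with lexicographic tie-break", {
  rep <- list(per_cell = data.frame(
    rep_id = 1, patient_id = c("pa", "pb", "pc"),
    path = c("a.png", "b.png", "c.png"), cell_type = "blast",
    label = c(1, 0, 0), score = c(0.9, 0.1, 0.5)))
  top <- rankMostPredictiveCells(rep, 1)
  expect_equal(top$apl$patient_id, "pa")
  expect_equal(top$non_apl$patient_id, "pb")
  z <- rankMostPredictiveCells(rep, 0)
  expect_equal(nrow(z$apl), 0)
  tie <- list(per_cell = data.frame(
    rep_id = 1, patient_id = c("pz", "pa"), path = c("z.png", "a.png"),
    cell_type = "blast", label = c(1, 1), score = c(0.7, 0.7)))
  t1 <- rankMostPredictiveCells(tie, 2)
  expect_equal(t1$apl$patient_id, c("pa", "pz"))
  expect_warning(big <- rankMostPredictiveCells(rep, 10), "truncated")
  expect_equal(nrow(big$apl), 3)
})

test_that("latent features concatenate 68 dimensions per ensemble member", {
  sp <- list(rep_id = 1, train = character(), validation = character(),
             test = character())
  m1 <- buildMilClassifier(seed = 1)
  m2 <- buildMilClassifier(seed = 2)
  X <- randomImages(5, size = 32, seed = 4)
  e1 <- new("SmearEnsemble", models = list(m1), splits = list(sp),
            mode = "mil", scope = "all_cells", config = list())
  f1 <- extractLatentFeatures(e1, X)
  expect_equal(dim(f1), c(5, 68))
  e2 <- new("SmearEnsemble", models = list(m1, m2),
            splits = rep(list(sp), 2), mode = "mil", scope = "all_cells",
            config = list())
  f2 <- extractLatentFeatures(e2, X)
  expect_equal(dim(f2), c(5, 136))
  expect_equal(attr(f2, "per_model_dim"), 68)
  # duplicated member duplicates its 68-block
  edup <- new("SmearEnsemble", models = list(m1, m1),
              splits = rep(list(sp), 2), mode = "mil",
              scope = "all_cells", config = list())
  fd <- extractLatentFeatures(edup, X)
  expect_equal(fd[, 1:68], fd[, 69:136])
  # the last three dimensions of a block are the softmax output
  expect_equal(unname(fd[, 66:68]), unname(predictCells(m1, X)),
               tolerance = 1e-12)
  ecell <- new("SmearEnsemble", models = list(buildCellClassifier(seed = 1)),
               splits = list(sp), mode = "cell", scope = "all_cells",
               config = list())
  expect_error(extractLatentFeatures(ecell, X), "mode error")
})

test_that("PCA keeps the minimal dimensionality reaching 99% variance", {
  set.seed(10)
  # rank-2 features plus tiny noise: eigen-spectrum oracle says 2 dims
  U <- matrix(rnorm(80 * 2), 80, 2)
  V <- matrix(rnorm(2 * 12), 2, 12)
  F2 <- U %*% V + matrix(rnorm(80 * 12, sd = 1e-6), 80, 12)
  ev <- eigen(cov(scale(F2)), only.values = TRUE)$values
  expect_gte(sum(ev[1:2]) / sum(ev), 0.99)   # oracle: 2 dims suffice
  expect_lt(sum(ev[1]) / sum(ev), 0.99)      # oracle: 1 dim does not
  emb <- embedLatent(F2, labels = rep(c(0, 1), 40), seed = 3)
  expect_equal(emb$pca_dims_kept, 2)
  expect_gte(emb$explained_variance_kept, 0.99)
  # full-rank random features still retain >= 99%
  Fr <- matrix(rnorm(60 * 10), 60, 10)
  er <- embedLatent(Fr, seed = 1)
  expect_gte(er$explained_variance_kept, 0.99)
  expect_equal(dim(er$coords), c(60, 2))
})

test_that("seeded embeddings are bit-reproducible and densities are per class", {
  set.seed(11)
  F0 <- matrix(rnorm(70 * 6), 70, 6)
  lab <- rep(c(0, 1), 35)
  e1 <- embedLatent(F0, labels = lab, seed = 21)
  e2 <- embedLatent(F0, labels = lab, seed = 21)
  expect_identical(e1$coords, e2$coords)
  expect_named(e1$density_by_class, c("0", "1"))
  expect_true(all(is.finite(e1$coords)))
  e3 <- embedLatent(F0, labels = lab, seed = 22)
  expect_false(identical(e1$coords, e3$coords))
  expect_error(embedLatent(F0[1:2, ]), "at least 3")
})

test_that("attribution overlays blend a diverging colormap over the image", {
  img <- randomImages(1, size = 16, seed = 1)[, , , 1]
  v <- matrix(rnorm(16 * 16), 16, 16)
  d <- withr::local_tempdir()
  f <- file.path(d, "ov.png")
  out <- attributionOverlay(img, v, f)
  expect_true(file.exists(f))
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("APL-predictive cells attribute mostly to the nucleus when the planted effect is nuclear", {
  fit <- trainedCellFit()
  top <- rankMostPredictiveCells(list(per_cell = fit$cells), 4)
  tens <- smallTensors()
  size <- dim(tens$X)[1]
  ctr <- (size + 1) / 2
  xi <- matrix(seq_len(size), size, size)
  r <- sqrt((xi - ctr)^2 + (t(xi) - ctr)^2)
  nuc <- r < 0.30 * size * 1.1            # generous default nucleus disc
  ratios <- vapply(seq_len(nrow(top$apl)), function(i) {
    ix <- which(tens$manifest$path == top$apl$path[i])
    am <- integratedGradients(fit$model, tens$X[, , , ix, drop = TRUE],
                              steps = 50)
    mean(abs(am$values[nuc])) / mean(abs(am$values[!nuc]))
  }, numeric(1))
  expect_gt(mean(ratios), 1)
})
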