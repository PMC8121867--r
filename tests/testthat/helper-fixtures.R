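# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

# small planted-effect cohort: 3+3 patients, 100 cells, 32 px
smallCohort <- function() {
  if (is.null(.fixtures$cohort)) {
    d <- file.path(tempdir(), "smearmil-small-cohort")
    cfg <- cohortConfig(n_apl = 3, n_nonapl = 3, cells_per_patient = 100,
                        image_size = 32, seed = 42)
    .fixtures$cohort <- simulateCohort(cfg, d)
  }
  .fixtures$cohort
}

smallTensors <- function() {
  if (is.null(.fixtures$tensors))
    .fixtures$tensors <- loadCellMatrix(smallCohort())
  .fixtures$tensors
}

# independent reference bilinear resize (double loop, half-pixel centers)
refBilinear <- function(a, oh, ow) {
  H <- dim(a)[1]; W <- dim(a)[2]
  out <- array(0, c(oh, ow, dim(a)[3]))
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    sy <- min(max((i - 0.5) * H / oh - 0.5, 0), H - 1)
    sx <- min(max((j - 0.5) * W / ow - 0.5, 0), W - 1)
    i0 <- floor(sy); j0 <- floor(sx)
    i1 <- min(i0 + 1, H - 1); j1 <- min(j0 + 1, W - 1)
    fi <- sy - i0; fj <- sx - j0
    out[i, j, ] <- (1 - fi) * (1 - fj) * a[i0 + 1, j0 + 1, ] +
      fi * (1 - fj) * a[i1 + 1, j0 + 1, ] +
      (1 - fi) * fj * a[i0 + 1, j1 + 1, ] + fi * fj * a[i1 + 1, j1 + 1, ]
  }
  out
}

# exhaustive concordant-pair AUC oracle (ties count one half)
pairAuc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

randomImages <- function(n, size = 16, seed = 1) {
  set.seed(seed)
  array(runif(size * size * 3 * n), c(size, size, 3, n))
}

fastConfig <- function(n_reps = 2, seed = 7, ...) {
  mcConfig(n_reps = n_reps, seed = seed, lr = 1e-3, max_epochs = 4,
           patience = 2, mil_loss_threshold = 0.25, mil_max_epochs = 6, ...)
}

# one trained cell classifier on the small planted-effect cohort
trainedCellFit <- function() {
  if (is.null(.fixtures$trainedCell)) {
    cfg <- mcConfig(n_reps = 1, seed = 19, lr = 1e-3, max_epochs = 8,
                    patience = 3)
    sp <- mcPatientSplit(smallCohort(), 1, cfg, "cell")
    .fixtures$trainedCell <- trainCellClassifier(smallTensors(), sp,
                                                 "blasts_only", cfg)
  }
  .fixtures$trainedCell
}
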