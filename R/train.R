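## Patient-level Monte-Carlo cross-validation, ensembling, ROC evaluation
## and the promyelocyte-fraction baseline.

#' Monte-Carlo cross-validation configuration
#'
#' Discovery-cohort training uses repeated random patient-level splits:
#' 75% of patients train; for the cell classifier the remaining 25% is
#' split in half into a validation set (to determine convergence) and a
#' test set; for the MIL classifier the remaining 25% is all test and
#' training stops at a fixed training-loss threshold instead. Each
#' repetition's trained model joins the ensemble applied to the
#' validation cohort.
#'
#' @param n_reps number of Monte-Carlo repetitions (100 in the full-scale
#'   pipeline).
#' @param train_frac fraction of patients used for training.
#' @param mil_subsample cells drawn per bag per epoch in MIL training
#'   (all cells when the bag is smaller).
#' @param mil_loss_threshold mean bag training loss at which MIL training
#'   stops.
#' @param mil_max_epochs hard cap when the threshold is never reached
#'   (warning).
#' @param lr,batch_size Adam learning rate and cell-mode batch size.
#' @param max_epochs,patience cell-mode epoch cap and early-stopping
#'   patience on validation loss.
#' @param seed master seed; every repetition derives its own substream.
#' @return A validated list of class `mc_config`.
#' @export
mcConfig <- function(n_reps = 100, train_frac = 0.75, mil_subsample = 25,
                     mil_loss_threshold = 0.2, mil_max_epochs = 300,
                     lr = 1e-4, batch_size = 32, max_epochs = 60,
                     patience = 5, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  if (mil_subsample < 1) stop("mil_subsample must be >= 1")
  structure(list(n_reps = as.integer(n_reps), train_frac = train_frac,
                 mil_subsample = as.integer(mil_subsample),
                 mil_loss_threshold = mil_loss_threshold,
                 mil_max_epochs = as.integer(mil_max_epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "mc_config")
}

.repSeed <- function(config, rep_id, offset = 0L) {
  (config$seed %% 10000L) * 100003L + rep_id * 97L + offset
}

#' Patient-level Monte-Carlo split
#'
#' Stratified by class so both labels are always represented in training.
#' Deterministic given `(config$seed, rep_id)`. Cell mode partitions the
#' held-out 25% in half into validation and test; MIL mode uses it all as
#' test.
#'
#' @param patients data.frame with columns `patient_id` and `label`, or a
#'   [SmearCohort-class].
#' @param rep_id repetition index (1-based).
#' @param config an [mcConfig()].
#' @param mode `"cell"` or `"mil"`.
#' @return List with `rep_id` and disjoint character vectors `train`,
#'   `validation`, `test` that partition the patients.
#' @export
mcPatientSplit <- function(patients, rep_id, config = mcConfig(),
                           mode = c("cell", "mil")) {
  mode <- match.arg(mode)
  if (is(patients, "SmearCohort")) {
    labs <- patientLabels(patients)
    patients <- data.frame(patient_id = names(labs), label = unname(labs))
  }
  if (length(unique(patients$label)) < 2 || nrow(patients) < 4)
    stop("need >= 4 patients with both classes present")
  set.seed(.repSeed(config, rep_id))
  tr <- va <- te <- character()
  for (cls in sort(unique(patients$label))) {
    ids <- sort(patients$patient_id[patients$label == cls])
    n <- length(ids)
    if (n < 2)
      stop("too few patients in class ", cls, " to stratify the split")
    perm <- sample(ids)
    ntr <- max(1, min(n - 1, round(config$train_frac * n)))
    rest <- perm[-seq_len(ntr)]
    tr <- c(tr, perm[seq_len(ntr)])
    if (mode == "cell") {
      nva <- floor(length(rest) / 2)
      va <- c(va, if (nva > 0) rest[seq_len(nva)] else character())
      te <- c(te, rest[setdiff(seq_along(rest), seq_len(nva))])
    } else {
      te <- c(te, rest)
    }
  }
  list(rep_id = rep_id, train = sort(tr), validation = sort(va),
       test = sort(te))
}

## ---- Adam over the weight list ----------------------------------------

.adamInit <- function(w) {
  zero <- function(x) { x[] <- 0; x }
  list(m = list(cw = lapply(w$cw, zero), cb = lapply(w$cb, zero),
                fw = lapply(w$fw, zero), fb = lapply(w$fb, zero),
                ow = zero(w$ow), ob = zero(w$ob)),
       v = list(cw = lapply(w$cw, zero), cb = lapply(w$cb, zero),
                fw = lapply(w$fw, zero), fb = lapply(w$fb, zero),
                ow = zero(w$ow), ob = zero(w$ob)),
       t = 0L)
}

.adamStep <- function(w, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  corr <- lr * sqrt(1 - b2^st$t) / (1 - b1^st$t)
  upd <- function(wx, gx, mx, vx) {
    mx <- b1 * mx + (1 - b1) * gx
    vx <- b2 * vx + (1 - b2) * gx * gx
    wx <- wx - corr * mx / (sqrt(vx) + eps)
    list(wx, mx, vx)
  }
  for (nm in c("cw", "cb", "fw", "fb")) {
    for (l in seq_along(w[[nm]])) {
      r <- upd(w[[nm]][[l]], g[[nm]][[l]], st$m[[nm]][[l]], st$v[[nm]][[l]])
      w[[nm]][[l]] <- r[[1]]; st$m[[nm]][[l]] <- r[[2]]; st$v[[nm]][[l]] <- r[[3]]
    }
  }
  for (nm in c("ow", "ob")) {
    r <- upd(w[[nm]], g[[nm]], st$m[[nm]], st$v[[nm]])
    w[[nm]] <- r[[1]]; st$m[[nm]] <- r[[2]]; st$v[[nm]] <- r[[3]]
  }
  list(w = w, st = st)
}

.bind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

.cellLoss <- function(w, X, y) {
  p <- cnn_forward_cpp(w, X, FALSE)$probs
  -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12)))
}

.scopeRows <- function(man, scope) {
  if (scope == "blasts_only") man$cell_type %in% immatureMyeloidTypes()
  else rep(TRUE, nrow(man))
}

#' Train the single-cell classifier on one Monte-Carlo split
#'
#' Trains on three classes: training-split cells labeled by their
#' patient's class plus a blurred outgroup built from the training-split
#' images only (one blurred copy per training image, so the outgroup size
#' equals the training-set size). Early stopping monitors the
#' cross-entropy of the validation-split cells; the best-validation
#' weights are kept. Per-cell APL probabilities are returned for the
#' test-split cells only (out-of-fold).
#'
#' @param tensors preloaded cohort tensors from [loadCellMatrix()].
#' @param split a [mcPatientSplit()] assignment.
#' @param scope `"all_cells"` or `"blasts_only"` (immature myeloid
#'   compartment only).
#' @param config an [mcConfig()].
#' @param arch an [archConfig()].
#' @param outgroup include the blurred outgroup (the deconfounding
#'   mechanism); `FALSE` trains a plain two-class control, used to
#'   demonstrate batch-effect leakage.
#' @param verbose print per-epoch losses.
#' @return List with `model` (trained [SmearCNN-class]), `cells`
#'   (out-of-fold per-cell predictions: patient_id, path, cell_type,
#'   label, score), and `history` (per-epoch losses).
#' @export
trainCellClassifier <- function(tensors, split, scope = c("all_cells",
                                "blasts_only"), config = mcConfig(),
                                arch = archConfig(), outgroup = TRUE,
                                verbose = FALSE) {
  scope <- match.arg(scope)
  man <- tensors$manifest
  inscope <- .scopeRows(man, scope)
  tri <- which(man$patient_id %in% split$train & inscope)
  vai <- which(man$patient_id %in% split$validation & inscope)
  tei <- which(man$patient_id %in% split$test & inscope)
  ytr <- man$label[tri]
  if (length(unique(ytr)) < 2)
    stop("a class is absent from the training images")
  set.seed(.repSeed(config, split$rep_id, 1L))
  Xtr <- tensors$X[, , , tri, drop = FALSE]
  if (outgroup) {
    out <- makeBlurOutgroup(Xtr)
    Xtr <- .bind4(Xtr, out$images)
    ytr <- c(ytr, out$labels)
  }
  model <- buildCellClassifier(arch, seed = .repSeed(config, split$rep_id, 2L))
  w <- model@weights
  st <- .adamInit(w)
  n <- length(ytr)
  haveVal <- length(vai) > 0
  Xval <- if (haveVal) tensors$X[, , , vai, drop = FALSE] else NULL
  best <- list(loss = Inf, w = w)
  wait <- 0
  hist <- NULL
  for (ep in seq_len(config$max_epochs)) {
    idx <- sample(n)
    eploss <- 0
    for (b in seq_len(ceiling(n / config$batch_size))) {
      bi <- idx[((b - 1) * config$batch_size + 1):min(b * config$batch_size, n)]
      g <- cnn_cell_grad_cpp(w, Xtr[, , , bi, drop = FALSE], ytr[bi])
      eploss <- eploss + g$loss * length(bi)
      r <- .adamStep(w, g$grads, st, config$lr)
      w <- r$w; st <- r$st
    }
    eploss <- eploss / n
    vloss <- if (haveVal) .cellLoss(w, Xval, man$label[vai]) else eploss
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = eploss,
                                   val_loss = vloss))
    if (verbose)
      message(sprintf("rep %d epoch %d train %.4f val %.4f",
                      split$rep_id, ep, eploss, vloss))
    if (vloss < best$loss - 1e-3) {
      best <- list(loss = vloss, w = w); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  model@weights <- best$w
  model@trained <- TRUE
  cells <- if (length(tei)) {
    p <- cnn_forward_cpp(best$w, tensors$X[, , , tei, drop = FALSE], FALSE)$probs
    data.frame(rep_id = split$rep_id, patient_id = man$patient_id[tei],
               path = man$path[tei], cell_type = man$cell_type[tei],
               label = man$label[tei],
               score = suppressWarnings(aplProbability(p)))
  } else NULL
  list(model = model, cells = cells, history = hist)
}

#' Train the MIL sample classifier on one Monte-Carlo split
#'
#' Bags are training-split patients (scope-filtered); each training
#' patient additionally contributes a blurred copy of its bag labeled
#' with the outgroup class. Each epoch draws `mil_subsample` (25) randomly
#' selected cells per bag (all cells when the bag is smaller) and takes
#' one Adam step per bag on the bag-level cross-entropy of the in-network
#' mean assignment. Training stops once the mean epoch training loss
#' reaches `mil_loss_threshold` (warning + stop at `mil_max_epochs`
#' otherwise). Out-of-fold bag-level and per-cell APL probabilities are
#' returned for test-split patients.
#'
#' @inheritParams trainCellClassifier
#' @return List with `model`, `samples` (patient_id, label, score,
#'   n_cells), `cells`, and `history`.
#' @export
trainMil <- function(tensors, split, scope = c("all_cells", "blasts_only"),
                     config = mcConfig(), arch = archConfig(),
                     verbose = FALSE) {
  scope <- match.arg(scope)
  man <- tensors$manifest
  inscope <- .scopeRows(man, scope)
  set.seed(.repSeed(config, split$rep_id, 1L))
  trainIds <- intersect(split$train, unique(man$patient_id))
  bagIdx <- lapply(trainIds, function(p)
    which(man$patient_id == p & inscope))
  keep <- lengths(bagIdx) > 0
  if (!all(keep))
    warning("train patient(s) with empty bags after scope filter dropped: ",
            paste(trainIds[!keep], collapse = ", "))
  trainIds <- trainIds[keep]; bagIdx <- bagIdx[keep]
  bagLab <- vapply(bagIdx, function(ix) man$label[ix[1]], integer(1))
  if (length(unique(bagLab)) < 2)
    stop("a class is absent from the training bags")
  trRows <- sort(unique(unlist(bagIdx)))
  Xblur <- makeBlurOutgroup(tensors$X[, , , trRows, drop = FALSE])$images
  blurPos <- match(seq_len(nrow(man)), trRows)   # row -> index into Xblur
  bags <- c(lapply(seq_along(bagIdx), function(i)
              list(idx = bagIdx[[i]], y = bagLab[i], blurred = FALSE)),
            lapply(seq_along(bagIdx), function(i)
              list(idx = bagIdx[[i]], y = 2L, blurred = TRUE)))
  model <- buildMilClassifier(arch, seed = .repSeed(config, split$rep_id, 2L))
  w <- model@weights
  st <- .adamInit(w)
  hist <- NULL
  for (ep in seq_len(config$mil_max_epochs)) {
    eploss <- 0
    for (bi in sample(length(bags))) {
      bag <- bags[[bi]]
      ix <- bag$idx
      if (length(ix) > config$mil_subsample)
        ix <- sample(ix, config$mil_subsample)
      Xb <- if (bag$blurred)
        Xblur[, , , blurPos[ix], drop = FALSE]
      else tensors$X[, , , ix, drop = FALSE]
      g <- cnn_bag_grad_cpp(w, Xb, bag$y)
      eploss <- eploss + g$loss
      r <- .adamStep(w, g$grads, st, config$lr)
      w <- r$w; st <- r$st
    }
    eploss <- eploss / length(bags)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = eploss))
    if (verbose)
      message(sprintf("rep %d MIL epoch %d loss %.4f", split$rep_id, ep,
                      eploss))
    if (eploss <= config$mil_loss_threshold) break
    if (ep == config$mil_max_epochs)
      warning("MIL loss threshold ", config$mil_loss_threshold,
              " not reached within ", config$mil_max_epochs,
              " epochs; stopping at cap")
  }
  model@weights <- w
  model@trained <- TRUE
  samples <- NULL; cells <- NULL
  for (p in intersect(split$test, unique(man$patient_id))) {
    ix <- which(man$patient_id == p & inscope)
    if (!length(ix)) {
      warning("test patient ", p, " has no cells in scope; skipped")
      next
    }
    pred <- predictBag(model, tensors$X[, , , ix, drop = FALSE])
    samples <- rbind(samples, data.frame(
      rep_id = split$rep_id, patient_id = p, label = man$label[ix[1]],
      score = pred$p_apl_binary, n_cells = length(ix)))
    cells <- rbind(cells, data.frame(
      rep_id = split$rep_id, patient_id = p, path = man$path[ix],
      cell_type = man$cell_type[ix], label = man$label[ix],
      score = suppressWarnings(aplProbability(pred$per_cell_probs))))
  }
  list(model = model, samples = samples, cells = cells, history = hist)
}

#' Run Monte-Carlo cross-validation training
#'
#' Trains `config$n_reps` models on distinct random patient-level splits
#' of the discovery cohort (100 in the full-scale pipeline), pooling
#' strictly out-of-fold predictions into the discovery evaluation report.
#' The trained models form the ensemble later applied to the validation
#' cohort.
#'
#' @inheritParams trainCellClassifier
#' @param mode `"cell"` (single-cell classifier; per-sample score is the
#'   mean per-cell score) or `"mil"` (bag-level classifier).
#' @return List with `ensemble` (a [SmearEnsemble-class]) and `report`
#'   (an evaluation report, see [evaluationReport()]).
#' @export
runMonteCarlo <- function(tensors, mode = c("cell", "mil"),
                          scope = c("all_cells", "blasts_only"),
                          config = mcConfig(), arch = archConfig(),
                          verbose = FALSE) {
  mode <- match.arg(mode); scope <- match.arg(scope)
  man <- tensors$manifest
  ids <- sort(unique(man$patient_id))
  patients <- data.frame(
    patient_id = ids,
    label = vapply(ids, function(p) man$label[man$patient_id == p][1],
                   integer(1)))
  models <- vector("list", config$n_reps)
  splits <- vector("list", config$n_reps)
  cells <- NULL; samples <- NULL
  for (rep_id in seq_len(config$n_reps)) {
    split <- mcPatientSplit(patients, rep_id, config, mode)
    fit <- if (mode == "cell")
      trainCellClassifier(tensors, split, scope, config, arch, verbose)
    else trainMil(tensors, split, scope, config, arch, verbose)
    models[[rep_id]] <- fit$model
    splits[[rep_id]] <- split
    cells <- rbind(cells, fit$cells)
    if (mode == "cell") {
      if (!is.null(fit$cells)) {
        agg <- stats::aggregate(score ~ patient_id + label + rep_id,
                                fit$cells, mean)
        cnt <- stats::aggregate(cbind(n_cells = score) ~ patient_id,
                                fit$cells, length)
        samples <- rbind(samples, merge(agg, cnt, by = "patient_id"))
      }
    } else {
      samples <- rbind(samples, fit$samples)
    }
  }
  ens <- new("SmearEnsemble", models = models, splits = splits,
             mode = mode, scope = scope, config = unclass(config))
  report <- evaluationReport(cells, samples, man, mode, scope,
                             stage = "discovery")
  list(ensemble = ens, report = report)
}

#' Apply a Monte-Carlo ensemble to a held-out cohort
#'
#' Per-cell APL probabilities are the unweighted mean of the member
#' models' scores; per-sample scores are the mean per-cell score over all
#' of a patient's cells in cell mode and the mean in-network bag
#' probability over members in MIL mode.
#'
#' @param ensemble a [SmearEnsemble-class].
#' @param tensors held-out cohort tensors from [loadCellMatrix()].
#' @return An evaluation report (see [evaluationReport()]).
#' @export
ensemblePredict <- function(ensemble, tensors) {
  man <- tensors$manifest
  if (!nrow(man)) stop("empty cohort")
  inscope <- .scopeRows(man, ensemble@scope)
  rows <- which(inscope)
  if (!length(rows)) stop("no cells in scope for this ensemble")
  X <- tensors$X[, , , rows, drop = FALSE]
  nm <- length(ensemble@models)
  cellScores <- matrix(0, length(rows), nm)
  for (k in seq_len(nm)) {
    p <- cnn_forward_cpp(ensemble@models[[k]]@weights, X, FALSE)$probs
    cellScores[, k] <- suppressWarnings(aplProbability(p))
  }
  cells <- data.frame(rep_id = NA_integer_, patient_id = man$patient_id[rows],
                      path = man$path[rows], cell_type = man$cell_type[rows],
                      label = man$label[rows], score = rowMeans(cellScores))
  ids <- sort(unique(cells$patient_id))
  if (ensemble@mode == "cell") {
    samples <- do.call(rbind, lapply(ids, function(p) {
      sub <- cells[cells$patient_id == p, ]
      data.frame(rep_id = NA_integer_, patient_id = p, label = sub$label[1],
                 score = mean(sub$score), n_cells = nrow(sub))
    }))
  } else {
    samples <- do.call(rbind, lapply(ids, function(p) {
      ix <- which(man$patient_id[rows] == p)
      bagScores <- vapply(seq_len(nm), function(k) {
        pr <- cnn_forward_cpp(ensemble@models[[k]]@weights,
                              X[, , , ix, drop = FALSE], FALSE)$probs
        suppressWarnings(aplProbability(colMeans(pr)))
      }, numeric(1))
      data.frame(rep_id = NA_integer_, patient_id = p,
                 label = man$label[rows][ix[1]], score = mean(bagScores),
                 n_cells = length(ix))
    }))
  }
  evaluationReport(cells, samples, man, ensemble@mode, ensemble@scope,
                   stage = "validation")
}

#' Promyelocyte fraction of a sample
#'
#' The comparator biomarker: the proportion of a patient's cells that the
#' analyzer typed as promyelocytes (differentiation arrest in APL causes
#' promyelocyte accumulation).
#'
#' @param x a [PatientSample-class], or a [SmearCohort-class] (returns a
#'   named per-patient vector).
#' @return Fraction(s) in \[0,1\].
#' @export
promyelocyteFraction <- function(x) {
  if (is(x, "PatientSample")) {
    if (!length(x@cell_types)) stop("sample has no cells")
    return(mean(x@cell_types == "promyelocyte"))
  }
  if (is(x, "SmearCohort")) {
    m <- manifest(x)
    return(vapply(split(m$cell_type, m$patient_id),
                  function(ct) mean(ct == "promyelocyte"), numeric(1)))
  }
  stop("x must be a PatientSample or SmearCohort")
}

#' ROC AUC with ties counted one half
#'
#' Rank-based (Mann-Whitney) area under the ROC curve: the probability
#' that a random positive outscores a random negative, ties counted 1/2.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores, same length.
#' @return AUC in \[0,1\].
#' @export
rocAuc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("undefined AUC: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble an evaluation report
#'
#' @param cells pooled per-cell predictions (data.frame with label,
#'   score, patient_id, path) or NULL.
#' @param samples pooled per-sample predictions (label, score, n_cells).
#' @param man the cohort manifest (for the promyelocyte baseline).
#' @param mode,scope,stage bookkeeping tags.
#' @return List of class `smearmil_report` with per-cell and per-sample
#'   scores, `auc_cell`, `auc_sample`, `baseline_auc_promyelocyte`, and
#'   `auc_by_cellcount`.
#' @export
evaluationReport <- function(cells, samples, man, mode, scope,
                             stage = "discovery") {
  safeAuc <- function(l, s) tryCatch(rocAuc(l, s), error = function(e) NA_real_)
  auc_cell <- if (!is.null(cells)) safeAuc(cells$label, cells$score) else NA
  auc_sample <- if (!is.null(samples)) safeAuc(samples$label, samples$score)
                else NA
  ids <- sort(unique(man$patient_id))
  frac <- vapply(ids, function(p)
    mean(man$cell_type[man$patient_id == p] == "promyelocyte"), numeric(1))
  plab <- vapply(ids, function(p) man$label[man$patient_id == p][1],
                 integer(1))
  baseline <- safeAuc(plab, frac)
  bycount <- NULL
  if (!is.null(samples) && nrow(samples) >= 4) {
    br <- unique(quantile(samples$n_cells, probs = seq(0, 1, 0.25)))
    if (length(br) >= 2) {
      bin <- cut(samples$n_cells, breaks = br, include.lowest = TRUE)
      bycount <- do.call(rbind, lapply(levels(bin), function(b) {
        sub <- samples[bin == b, ]
        data.frame(bin = b, n = nrow(sub),
                   auc = safeAuc(sub$label, sub$score))
      }))
    }
  }
  structure(list(mode = mode, scope = scope, stage = stage,
                 per_cell = cells, per_sample = samples,
                 auc_cell = auc_cell, auc_sample = auc_sample,
                 baseline_auc_promyelocyte = baseline,
                 auc_by_cellcount = bycount),
            class = "smearmil_report")
}

#' @export
print.smearmil_report <- function(x, ...) {
  cat("Evaluation report [", x$stage, ", mode=", x$mode, ", scope=",
      x$scope, "]\n", sep = "")
  cat(sprintf("  per-cell AUC:   %.3f (%d predictions)\n", x$auc_cell,
              NROW(x$per_cell)))
  cat(sprintf("  per-sample AUC: %.3f (%d predictions)\n", x$auc_sample,
              NROW(x$per_sample)))
  cat(sprintf("  promyelocyte-fraction baseline AUC: %.3f\n",
              x$baseline_auc_promyelocyte))
  if (!is.null(x$auc_by_cellcount)) {
    cat("  per-sample AUC by cells-per-patient bin:\n")
    print(x$auc_by_cellcount, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes `report.json` (the AUC summary), `per_cell.csv`,
#' `per_sample.csv`, and an ROC curve plot `roc.png`.
#'
#' @param report a `smearmil_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(stage = report$stage, mode = report$mode, scope = report$scope,
         auc_cell = report$auc_cell, auc_sample = report$auc_sample,
         baseline_auc_promyelocyte = report$baseline_auc_promyelocyte,
         auc_by_cellcount = report$auc_by_cellcount),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  if (!is.null(report$per_cell))
    write.csv(report$per_cell, file.path(dir, "per_cell.csv"),
              row.names = FALSE)
  if (!is.null(report$per_sample))
    write.csv(report$per_sample, file.path(dir, "per_sample.csv"),
              row.names = FALSE)
  if (!is.null(report$per_sample) &&
      length(unique(report$per_sample$label)) == 2) {
    grDevices::png(file.path(dir, "roc.png"), 600, 600)
    plotRoc(report$per_sample$label, report$per_sample$score,
            main = sprintf("%s per-sample ROC (AUC %.3f)", report$stage,
                           report$auc_sample))
    grDevices::dev.off()
  }
  invisible(dir)
}

#' Plot an ROC curve
#' @param labels,scores binary labels and scores.
#' @param ... passed to [graphics::plot()].
#' @return The data.frame of (fpr, tpr) points, invisibly.
#' @export
plotRoc <- function(labels, scores, ...) {
  o <- order(scores, decreasing = TRUE)
  labels <- as.integer(labels)[o]
  tpr <- c(0, cumsum(labels) / sum(labels))
  fpr <- c(0, cumsum(1 - labels) / sum(labels == 0))
  graphics::plot(fpr, tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(data.frame(fpr = fpr, tpr = tpr))
}
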