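## Synthetic smear-cohort generator.
##
## The renderer plants the morphological contrast reported for APL in the
## immature myeloid compartment as a single controllable scalar: chromatin
## density inside the nucleus follows a radial gradient parameterized by
## `chromatin_centrality` (1 = chromatin condensed at the nucleus center,
## as in APL; 0 = dispersed toward the nuclear rim, as in other AML).
## Stain-color batch effects are emulated by an additive RGB shift applied
## to every cell of patients assigned to a confounded collection era.
##
## Geometry is a deterministic function of (cell type, morphology params,
## image size); the only randomness inside the renderer is granule
## placement and pixel noise. Cell-to-cell variability in a cohort comes
## from per-cell jitter of the morphology parameters drawn by
## simulateCohort().

# per-type geometry: cytoplasm radius (fraction of half image), nucleus
# scale (relative to a promyelocyte), lobe count, eccentricity, hue offset
.typeRender <- list(
  "segmented neutrophil" = list(cyto = 0.80, nuc = 0.78, lobes = 3, ecc = 0.40, hue = 0),
  "band neutrophil"      = list(cyto = 0.80, nuc = 0.85, lobes = 2, ecc = 0.55, hue = 0),
  "lymphocyte"           = list(cyto = 0.60, nuc = 1.05, lobes = 1, ecc = 0.10, hue = 15),
  "monocyte"             = list(cyto = 0.88, nuc = 0.95, lobes = 1, ecc = 0.50, hue = 10),
  "eosinophil"           = list(cyto = 0.80, nuc = 0.78, lobes = 2, ecc = 0.40, hue = -25),
  "basophil"             = list(cyto = 0.75, nuc = 0.85, lobes = 1, ecc = 0.30, hue = -45),
  "blast"                = list(cyto = 0.86, nuc = 1.08, lobes = 1, ecc = 0.20, hue = 5),
  "promyelocyte"         = list(cyto = 0.90, nuc = 1.00, lobes = 1, ecc = 0.25, hue = 0),
  "promonocyte"          = list(cyto = 0.86, nuc = 1.02, lobes = 1, ecc = 0.35, hue = 8),
  "myelocyte"            = list(cyto = 0.82, nuc = 0.90, lobes = 1, ecc = 0.30, hue = 3),
  "metamyelocyte"        = list(cyto = 0.82, nuc = 0.86, lobes = 1, ecc = 0.60, hue = 3),
  "erythroblast"         = list(cyto = 0.58, nuc = 0.95, lobes = 1, ecc = 0.10, hue = 40),
  "platelet"             = list(cyto = 0.26, nuc = 0.00, lobes = 0, ecc = 0.20, hue = -10),
  "smudge"               = list(cyto = 0.00, nuc = 1.25, lobes = 1, ecc = 0.30, hue = 0),
  "artefact"             = list(cyto = 0.50, nuc = 0.00, lobes = 0, ecc = 0.60, hue = 90),
  "unidentified"         = list(cyto = 0.70, nuc = 0.85, lobes = 1, ecc = 0.30, hue = 0)
)

.hsvCol <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv((h %% 360) / 360, s, v)))
}

#' Morphology parameters for the synthetic cell renderer
#'
#' @param nucleus_radius_px nucleus radius in pixels (for a promyelocyte;
#'   other types are scaled relative to it). `NA` means 0.30 x image size.
#' @param chromatin_centrality in \[0,1\]: 1 concentrates chromatin density
#'   at the nucleus center (APL-like condensed, central chromatin), 0 at
#'   the nuclear rim (non-APL-like dispersed, peripheral chromatin).
#' @param granule_density cytoplasmic granules per 1000 px^2 of cytoplasm.
#' @param cytoplasm_hue cytoplasm hue in degrees \[0, 360).
#' @param noise_sd additive Gaussian pixel noise SD on the 0-255 scale.
#' @return A validated list of class `morphology_params`.
#' @export
morphologyParams <- function(nucleus_radius_px = NA_real_,
                             chromatin_centrality = 0.5,
                             granule_density = 1.5,
                             cytoplasm_hue = 300,
                             noise_sd = 8) {
  if (!is.na(nucleus_radius_px) && nucleus_radius_px <= 0)
    stop("nucleus_radius_px must be > 0")
  if (chromatin_centrality < 0 || chromatin_centrality > 1)
    stop("chromatin_centrality must be in [0, 1]")
  if (granule_density < 0) stop("granule_density must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(nucleus_radius_px = nucleus_radius_px,
                 chromatin_centrality = chromatin_centrality,
                 granule_density = granule_density,
                 cytoplasm_hue = cytoplasm_hue %% 360,
                 noise_sd = noise_sd),
            class = "morphology_params")
}

#' Default class-conditional morphology
#'
#' APL immature myeloid cells get condensed, centrally concentrated
#' chromatin (centrality 0.85) and heavier granulation; non-APL immature
#' cells get dispersed, peripherally concentrated chromatin (centrality
#' 0.15). Mature cell types always render with neutral centrality 0.5, so
#' the planted class effect lives in the immature compartment only.
#'
#' @param class_label `"APL"` or `"non-APL"`.
#' @return A [morphologyParams()] object.
#' @export
defaultMorphology <- function(class_label = c("APL", "non-APL")) {
  class_label <- match.arg(class_label)
  if (class_label == "APL")
    morphologyParams(chromatin_centrality = 0.85, granule_density = 3)
  else
    morphologyParams(chromatin_centrality = 0.15, granule_density = 1.2)
}

#' Stain-color batch effect
#'
#' Emulates the era-dependent Wright-stain color drift: patients assigned
#' to the confounded era (`"pre2018"`) have a constant additive RGB shift
#' applied to all their cell images. APL patients land in the confounded
#' era with probability `class_correlation`; non-APL patients with
#' probability `era_prob_nonapl` (0 reproduces the fully one-sided
#' confound in which only APL smears predate the stain change; 0.5 for
#' both arguments gives era assignment independent of class).
#'
#' @param color_shift_rgb additive RGB offsets on the 0-255 scale, each
#'   within \[-64, 64\].
#' @param class_correlation probability an APL patient is assigned the
#'   confounded era.
#' @param era_prob_nonapl probability a non-APL patient is assigned the
#'   confounded era.
#' @return A validated list of class `batch_effect`.
#' @export
batchEffect <- function(color_shift_rgb = c(28, -14, 18),
                        class_correlation = 0, era_prob_nonapl = 0) {
  if (length(color_shift_rgb) != 3 || any(abs(color_shift_rgb) > 64))
    stop("color_shift_rgb must be 3 offsets, each within [-64, 64]")
  if (class_correlation < 0 || class_correlation > 1)
    stop("class_correlation must be in [0, 1]")
  if (era_prob_nonapl < 0 || era_prob_nonapl > 1)
    stop("era_prob_nonapl must be in [0, 1]")
  structure(list(color_shift_rgb = as.numeric(color_shift_rgb),
                 class_correlation = class_correlation,
                 era_prob_nonapl = era_prob_nonapl),
            class = "batch_effect")
}

#' Default class-conditional cell-type mixtures
#'
#' APL smears carry an elevated promyelocyte fraction (differentiation
#' arrest at the promyelocyte stage); non-APL AML smears carry more blasts
#' and monocytoid cells. Each mixture sums to 1 over the fixed cell-type
#' vocabulary.
#'
#' @return Named list with `apl` and `nonapl` probability vectors.
#' @export
defaultMixtures <- function() {
  apl <- c("promyelocyte" = 0.40, "blast" = 0.15, "myelocyte" = 0.08,
           "metamyelocyte" = 0.05, "promonocyte" = 0.02,
           "segmented neutrophil" = 0.10, "band neutrophil" = 0.05,
           "lymphocyte" = 0.08, "monocyte" = 0.02, "eosinophil" = 0.01,
           "basophil" = 0.01, "erythroblast" = 0.01, "platelet" = 0.01,
           "smudge" = 0.005, "artefact" = 0.003, "unidentified" = 0.002)
  nonapl <- c("promyelocyte" = 0.05, "blast" = 0.25, "myelocyte" = 0.04,
              "metamyelocyte" = 0.03, "promonocyte" = 0.10,
              "segmented neutrophil" = 0.12, "band neutrophil" = 0.05,
              "lymphocyte" = 0.15, "monocyte" = 0.15, "eosinophil" = 0.01,
              "basophil" = 0.01, "erythroblast" = 0.02, "platelet" = 0.01,
              "smudge" = 0.005, "artefact" = 0.003, "unidentified" = 0.002)
  list(apl = apl, nonapl = nonapl)
}

#' Synthetic cohort configuration
#'
#' @param n_apl,n_nonapl patient counts per class.
#' @param cells_per_patient cells acquired per smear; the analyzer default
#'   is 200 and the user-definable range 100-400.
#' @param image_size square image edge in pixels (128 default; 360 for
#'   full-scale parity).
#' @param mixtures per-class cell-type mixtures, see [defaultMixtures()].
#' @param morphology list with `apl` and `nonapl` [morphologyParams()].
#' @param batch a [batchEffect()].
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration including this seed.
#' @param cohort cohort tag written to the manifest (`"discovery"` or
#'   `"validation"`).
#' @return A validated list of class `cohort_config`.
#' @export
cohortConfig <- function(n_apl = 10, n_nonapl = 10, cells_per_patient = 200,
                         image_size = 128, mixtures = defaultMixtures(),
                         morphology = list(apl = defaultMorphology("APL"),
                                           nonapl = defaultMorphology("non-APL")),
                         batch = batchEffect(), seed = 1,
                         cohort = "discovery") {
  if (n_apl < 0 || n_nonapl < 0) stop("patient counts must be >= 0")
  if (cells_per_patient < 100 || cells_per_patient > 400)
    stop("cells_per_patient must be in [100, 400]")
  if (image_size < 32) stop("image_size must be >= 32")
  for (mx in mixtures) {
    if (abs(sum(mx) - 1) > 1e-9) stop("each mixture must sum to 1")
    if (!all(names(mx) %in% cellTypeVocabulary()))
      stop("mixture names must be in cellTypeVocabulary()")
  }
  stopifnot(inherits(batch, "batch_effect"),
            inherits(morphology$apl, "morphology_params"),
            inherits(morphology$nonapl, "morphology_params"))
  structure(list(n_apl = as.integer(n_apl), n_nonapl = as.integer(n_nonapl),
                 cells_per_patient = as.integer(cells_per_patient),
                 image_size = as.integer(image_size), mixtures = mixtures,
                 morphology = morphology, batch = batch,
                 seed = as.integer(seed), cohort = cohort),
            class = "cohort_config")
}

#' Render one synthetic white-blood-cell image
#'
#' Layered 2-D primitives: background, elliptical cytoplasm disc, nucleus
#' (1-3 lobes depending on cell type) with a radial chromatin-density
#' gradient set by `chromatin_centrality`, Gaussian-blob granules, pixel
#' noise, then the additive stain-color shift. Geometry is deterministic;
#' only granule placement and noise consume random numbers (from the
#' caller's R RNG stream).
#'
#' @param class_label `"APL"` or `"non-APL"`; selects which chromatin
#'   regime applies to immature myeloid types.
#' @param cell_type one of [cellTypeVocabulary()].
#' @param params a [morphologyParams()]; default class-conditional.
#' @param color_shift additive RGB batch shift (0-255 scale).
#' @param size square image edge in pixels.
#' @return Integer H x W x 3 array with values in 0-255.
#' @export
renderCellImage <- function(class_label = c("APL", "non-APL"),
                            cell_type, params = NULL,
                            color_shift = c(0, 0, 0), size = 128L) {
  class_label <- match.arg(class_label)
  if (length(cell_type) != 1 || !cell_type %in% cellTypeVocabulary())
    stop(errorCondition(
      paste0("unknown cell_type '", cell_type, "'; must be one of: ",
             paste(cellTypeVocabulary(), collapse = ", ")),
      class = c("cellTypeError", "error", "condition")))
  if (is.null(params)) params <- defaultMorphology(class_label)
  stopifnot(inherits(params, "morphology_params"))
  size <- as.integer(size)
  tp <- .typeRender[[cell_type]]

  half <- size / 2
  ctr <- (size + 1) / 2
  xi <- matrix(seq_len(size), size, size)              # row (vertical)
  yj <- matrix(rep(seq_len(size), each = size), size, size)

  img <- array(0, c(size, size, 3))
  bg <- c(236, 232, 234)
  for (ch in 1:3) img[, , ch] <- bg[ch]

  # cytoplasm (slightly anisotropic ellipse)
  cytoR <- tp$cyto * half * 0.95
  if (cytoR > 0) {
    rcx <- cytoR * 1.05
    rcy <- cytoR * 0.95
    cmask <- ((xi - ctr) / rcx)^2 + ((yj - ctr) / rcy)^2 <= 1
    ccol <- .hsvCol(params$cytoplasm_hue + tp$hue, 0.22, 0.86)
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[cmask] <- ccol[ch]; img[, , ch] <- pl
    }
  } else {
    cmask <- matrix(FALSE, size, size)
    rcx <- rcy <- 0
  }

  # nucleus with radial chromatin gradient
  nucScale <- tp$nuc
  if (nucScale > 0) {
    baseR <- if (is.na(params$nucleus_radius_px)) 0.30 * size
             else params$nucleus_radius_px
    nucR <- baseR * nucScale
    if (cytoR > 0) nucR <- min(nucR, cytoR * 0.88)
    centrality <- if (cell_type %in% immatureMyeloidTypes())
      params$chromatin_centrality else 0.5
    # normalized radius field t in [0,1]: min over lobes
    tfield <- matrix(Inf, size, size)
    lobes <- max(tp$lobes, 1)
    if (lobes == 1) {
      rx <- nucR * (1 + tp$ecc * 0.5)
      ry <- nucR * (1 - tp$ecc * 0.5)
      tfield <- sqrt(((xi - ctr) / rx)^2 + ((yj - ctr) / ry)^2)
    } else {
      ang <- if (lobes == 2) c(0, 180) else c(90, 210, 330)
      off <- if (lobes == 2) 0.40 * nucR else 0.55 * nucR
      lr <- if (lobes == 2) 0.65 * nucR else 0.52 * nucR
      for (aa in ang) {
        nx <- ctr + off * cos(aa * pi / 180)
        ny <- ctr + off * sin(aa * pi / 180)
        tt <- sqrt((xi - nx)^2 + (yj - ny)^2) / lr
        tfield <- pmin(tfield, tt)
      }
    }
    nmask <- tfield <= 1
    if (cell_type == "smudge") {
      wfield <- matrix(0.4, size, size)      # diffuse, structureless
      ncol_unit <- .hsvCol(276, 0.30, 1) / 255
    } else {
      tt <- pmin(tfield, 1)
      wfield <- centrality * (1 - tt) + (1 - centrality) * tt
      ncol_unit <- .hsvCol(272, 0.58, 1) / 255
    }
    vfield <- 0.88 - 0.62 * wfield           # dense chromatin stains darker
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[nmask] <- 255 * ncol_unit[ch] * vfield[nmask]
      img[, , ch] <- pl
    }
  } else {
    nmask <- matrix(FALSE, size, size)
  }

  # cytoplasmic granules (Poisson count, uniform placement in cytoplasm)
  if (params$granule_density > 0 && cytoR > 0) {
    cytoArea <- pi * rcx * rcy
    ngr <- rpois(1, params$granule_density * cytoArea / 1000)
    if (ngr > 0) {
      th <- runif(ngr, 0, 2 * pi)
      rr <- sqrt(runif(ngr))
      gx <- ctr + rr * rcx * cos(th)
      gy <- ctr + rr * rcy * sin(th)
      gs <- max(1.1, size / 110)
      gcol <- c(70, 115, 45)                 # subtracted: dark magenta dot
      w <- ceiling(3 * gs)
      for (g in seq_len(ngr)) {
        i0 <- max(1, round(gx[g]) - w); i1 <- min(size, round(gx[g]) + w)
        j0 <- max(1, round(gy[g]) - w); j1 <- min(size, round(gy[g]) + w)
        if (i0 > i1 || j0 > j1) next
        ii <- i0:i1; jj <- j0:j1
        d2 <- outer((ii - gx[g])^2, (jj - gy[g])^2, "+")
        blob <- exp(-d2 / (2 * gs^2))
        for (ch in 1:3)
          img[ii, jj, ch] <- img[ii, jj, ch] - gcol[ch] * blob
      }
    }
  }

  if (params$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, params$noise_sd), dim(img))
  for (ch in 1:3) img[, , ch] <- img[, , ch] + color_shift[ch]
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  img
}

#' Generate a synthetic smear cohort on disk
#'
#' Writes one subdirectory of PNG cell images per patient plus a manifest
#' CSV (columns patient_id, cohort, label, cell_type, path, era_id) and
#' the resolved configuration as YAML. APL patients are assigned to the
#' confounded stain era with probability `batch$class_correlation`, and
#' every cell of a confounded-era patient receives the additive stain
#' shift. Per-cell morphology is jittered around the class defaults
#' (nucleus radius x U(0.85, 1.15), centrality +/- U(-0.05, 0.05), hue
#' +/- U(-6, 6)). Identical configurations produce byte-identical
#' datasets.
#'
#' @param config a [cohortConfig()].
#' @param dir output directory (created if needed).
#' @return The generated cohort, as read back by [readCohort()] (invisible
#'   empty-manifest cohort when both patient counts are zero).
#' @export
simulateCohort <- function(config, dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  set.seed(config$seed)
  rows <- list()
  plan <- rbind(
    if (config$n_apl > 0)
      data.frame(class = "APL", idx = seq_len(config$n_apl)),
    if (config$n_nonapl > 0)
      data.frame(class = "non-APL", idx = seq_len(config$n_nonapl)))
  for (r in seq_len(NROW(plan))) {
    cls <- plan$class[r]
    isapl <- cls == "APL"
    pid <- sprintf("%s_%s_%02d", substr(config$cohort, 1, 4),
                   if (isapl) "apl" else "aml", plan$idx[r])
    pera <- if (isapl) config$batch$class_correlation
            else config$batch$era_prob_nonapl
    era <- if (runif(1) < pera) "pre2018" else "post2018"
    shift <- if (era == "pre2018") config$batch$color_shift_rgb else c(0, 0, 0)
    mx <- if (isapl) config$mixtures$apl else config$mixtures$nonapl
    base <- if (isapl) config$morphology$apl else config$morphology$nonapl
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    types <- sample(names(mx), config$cells_per_patient, replace = TRUE,
                    prob = mx)
    for (ci in seq_len(config$cells_per_patient)) {
      baseR <- if (is.na(base$nucleus_radius_px)) 0.30 * config$image_size
               else base$nucleus_radius_px
      p <- morphologyParams(
        nucleus_radius_px = baseR * runif(1, 0.85, 1.15),
        chromatin_centrality = min(1, max(0,
          base$chromatin_centrality + runif(1, -0.05, 0.05))),
        granule_density = base$granule_density,
        cytoplasm_hue = base$cytoplasm_hue + runif(1, -6, 6),
        noise_sd = base$noise_sd)
      img <- renderCellImage(cls, types[ci], p, shift, config$image_size)
      rel <- file.path(pid, sprintf("cell_%04d.png", ci))
      EBImage::writeImage(
        EBImage::Image(img / 255, colormode = "Color"),
        file.path(dir, rel))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, cohort = config$cohort,
        label = as.integer(isapl), cell_type = types[ci], path = rel,
        era_id = era)
    }
  }
  man <- if (length(rows)) do.call(rbind, rows)
         else data.frame(patient_id = character(), cohort = character(),
                         label = integer(), cell_type = character(),
                         path = character(), era_id = character())
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  writeCohortConfig(config, file.path(dir, "cohort_config.yaml"))
  if (nrow(man) == 0)
    return(invisible(new("SmearCohort", manifest = man, root = dir)))
  readCohort(file.path(dir, "manifest.csv"))
}

#' Write / read a cohort configuration as YAML
#'
#' @param config a [cohortConfig()].
#' @param path YAML file path.
#' @return `writeCohortConfig` returns `path` invisibly;
#'   `readCohortConfig` returns the reconstructed [cohortConfig()].
#' @export
writeCohortConfig <- function(config, path) {
  x <- unclass(config)
  x$morphology <- lapply(x$morphology, unclass)
  x$batch <- unclass(x$batch)
  x$mixtures <- lapply(x$mixtures, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeCohortConfig
#' @export
readCohortConfig <- function(path) {
  x <- yaml::read_yaml(path)
  cohortConfig(
    n_apl = x$n_apl, n_nonapl = x$n_nonapl,
    cells_per_patient = x$cells_per_patient, image_size = x$image_size,
    mixtures = lapply(x$mixtures, unlist),
    morphology = lapply(x$morphology, function(m)
      do.call(morphologyParams, m)),
    batch = do.call(batchEffect, x$batch),
    seed = x$seed, cohort = x$cohort)
}
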