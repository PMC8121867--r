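#' Cell-type vocabulary
#'
#' The fixed CellaVision-style white-blood-cell type vocabulary used
#' throughout the package. Manifest strings outside this set are mapped to
#' `"unidentified"` with a warning by [readCohort()].
#'
#' @return Character vector of the 16 recognized cell-type names.
#' @export
cellTypeVocabulary <- function() {
  c("segmented neutrophil", "band neutrophil", "lymphocyte", "monocyte",
    "eosinophil", "basophil", "blast", "promyelocyte", "promonocyte",
    "myelocyte", "metamyelocyte", "erythroblast", "platelet", "smudge",
    "artefact", "unidentified")
}

#' Immature myeloid cell types
#'
#' The immature myeloid compartment (the "Blasts" training scope): blasts,
#' promonocytes, promyelocytes, myelocytes and metamyelocytes.
#'
#' @return Character vector of the five immature myeloid type names.
#' @export
immatureMyeloidTypes <- function() {
  c("blast", "promonocyte", "promyelocyte", "myelocyte", "metamyelocyte")
}

.manifestCols <- c("patient_id", "cohort", "label", "cell_type", "path", "era_id")

#' SmearCohort: a smear dataset bound to its on-disk images
#'
#' Holds the validated cell manifest (one row per segmented cell image) and
#' the directory the image paths are relative to. Pixels are loaded lazily
#' by [loadSamples()] / [loadCellMatrix()].
#'
#' @slot manifest data.frame with columns patient_id, cohort, label (0 =
#'   non-APL, 1 = APL), cell_type, path, era_id; sorted by patient_id then
#'   path.
#' @slot root directory against which `manifest$path` is resolved.
#' @export
setClass("SmearCohort",
  representation(manifest = "data.frame", root = "character"))

setValidity("SmearCohort", function(object) {
  m <- object@manifest
  if (!all(.manifestCols %in% names(m)))
    return(paste("manifest must have columns:",
                 paste(.manifestCols, collapse = ", ")))
  if (nrow(m) == 0) return(TRUE)
  if (!all(m$label %in% c(0L, 1L)))
    return("label must be 0 (non-APL) or 1 (APL)")
  lab <- tapply(m$label, m$patient_id, function(x) length(unique(x)))
  if (any(lab > 1))
    return(paste("conflicting labels for patient(s):",
                 paste(names(lab)[lab > 1], collapse = ", ")))
  coh <- tapply(m$cohort, m$patient_id, function(x) length(unique(x)))
  if (any(coh > 1)) return("conflicting cohort assignment within a patient")
  if (!all(m$cell_type %in% cellTypeVocabulary()))
    return("cell_type outside the fixed vocabulary")
  TRUE
})

#' PatientSample: one patient's labeled bag of cell images
#'
#' The multiple-instance-learning bag: all segmented white-cell images from
#' one patient's smear together with the patient-level t(15;17) label.
#'
#' @slot patient_id patient identifier.
#' @slot label 0 = non-APL, 1 = APL.
#' @slot cohort "discovery" or "validation".
#' @slot cell_types CellaVision-style type per cell.
#' @slot paths image path per cell.
#' @slot cells list of H x W x 3 pixel arrays (0-255), possibly empty when
#'   pixels were not loaded.
#' @export
setClass("PatientSample",
  representation(patient_id = "character", label = "integer",
                 cohort = "character", cell_types = "character",
                 paths = "character", cells = "list"))

setValidity("PatientSample", function(object) {
  if (length(object@cell_types) < 1) return("a sample must contain >= 1 cell")
  if (length(object@paths) != length(object@cell_types))
    return("paths and cell_types lengths differ")
  if (length(object@cells) &&
      length(object@cells) != length(object@cell_types))
    return("cells and cell_types lengths differ")
  if (!object@label %in% c(0L, 1L)) return("label must be 0 or 1")
  TRUE
})

#' SmearCNN: a cell-level or MIL convolutional classifier
#'
#' Four stride-2 convolutions, global max-pooling, three fully connected
#' layers and a 3-class softmax (non-APL / APL / blurred). In `"mil"` mode
#' the same network is applied per cell and the bag probability is the
#' in-network arithmetic mean of the per-cell softmax assignments.
#'
#' @slot mode `"cell"` or `"mil"`.
#' @slot config architecture configuration from [archConfig()].
#' @slot weights named list of weight arrays.
#' @slot seed integer seed the weights were initialized from.
#' @slot trained logical.
#' @export
setClass("SmearCNN",
  representation(mode = "character", config = "list", weights = "list",
                 seed = "numeric", trained = "logical"))

setValidity("SmearCNN", function(object) {
  if (!object@mode %in% c("cell", "mil")) return("mode must be 'cell' or 'mil'")
  cfg <- object@config
  if (length(cfg$conv_filters) != 4) return("exactly 4 convolutional layers")
  if (length(cfg$fc_sizes) != 3) return("exactly 3 fully connected layers")
  TRUE
})

#' SmearEnsemble: Monte-Carlo-trained model ensemble
#'
#' The ordered collection of models trained across Monte-Carlo
#' cross-validation repetitions, together with the patient-level split each
#' model was trained under.
#'
#' @slot models list of [SmearCNN-class] models, one per repetition.
#' @slot splits list of split assignments (train/validation/test patient-id
#'   sets per repetition).
#' @slot mode `"cell"` or `"mil"`.
#' @slot scope `"blasts_only"` or `"all_cells"`.
#' @slot config the Monte-Carlo configuration from [mcConfig()].
#' @export
setClass("SmearEnsemble",
  representation(models = "list", splits = "list", mode = "character",
                 scope = "character", config = "list"))

setValidity("SmearEnsemble", function(object) {
  if (length(object@models) != length(object@splits))
    return("one split assignment per model required")
  if (!object@mode %in% c("cell", "mil")) return("mode must be 'cell' or 'mil'")
  if (!object@scope %in% c("blasts_only", "all_cells"))
    return("scope must be 'blasts_only' or 'all_cells'")
  TRUE
})

setMethod("show", "SmearCohort", function(object) {
  m <- object@manifest
  cat("SmearCohort:", length(unique(m$patient_id)), "patients,",
      nrow(m), "cells\n")
  if (nrow(m)) {
    tab <- table(tapply(m$label, m$patient_id, unique))
    cat("  labels: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n  root: ", object@root, "\n", sep = "")
  }
})

setMethod("show", "PatientSample", function(object) {
  cat("PatientSample", object@patient_id, "(",
      ifelse(object@label == 1L, "APL", "non-APL"), "):",
      length(object@cell_types), "cells,",
      if (length(object@cells)) "pixels loaded" else "pixels not loaded", "\n")
})

setMethod("show", "SmearCNN", function(object) {
  cfg <- object@config
  cat("SmearCNN [", object@mode, "]: conv ",
      paste(cfg$conv_filters, collapse = "-"), " (k=", cfg$conv_kernel,
      ", stride=", cfg$conv_stride, ") -> global max-pool -> fc ",
      paste(cfg$fc_sizes, collapse = "-"), " -> softmax(3); ",
      if (object@trained) "trained" else "untrained", "\n", sep = "")
})

setMethod("show", "SmearEnsemble", function(object) {
  cat("SmearEnsemble:", length(object@models), "models, mode =",
      object@mode, ", scope =", object@scope, "\n")
})

#' @describeIn SmearCohort-class Access the cell manifest.
#' @param object,x a `SmearCohort`.
#' @export
setGeneric("manifest", function(object) standardGeneric("manifest"))

#' @rdname SmearCohort-class
#' @export
setMethod("manifest", "SmearCohort", function(object) object@manifest)

#' @rdname SmearCohort-class
#' @export
setGeneric("patientIds", function(object) standardGeneric("patientIds"))

#' @rdname SmearCohort-class
#' @export
setMethod("patientIds", "SmearCohort",
          function(object) sort(unique(object@manifest$patient_id)))

#' @rdname SmearCohort-class
#' @export
setGeneric("patientLabels", function(object) standardGeneric("patientLabels"))

#' @rdname SmearCohort-class
#' @export
setMethod("patientLabels", "SmearCohort", function(object) {
  m <- object@manifest
  ids <- sort(unique(m$patient_id))
  vapply(ids, function(p) m$label[m$patient_id == p][1], integer(1))
})

#' @rdname SmearEnsemble-class
#' @param object a `SmearEnsemble`.
#' @export
setGeneric("ensembleModels", function(object) standardGeneric("ensembleModels"))

#' @rdname SmearEnsemble-class
#' @export
setMethod("ensembleModels", "SmearEnsemble", function(object) object@models)

#' @rdname SmearEnsemble-class
#' @export
setGeneric("ensembleMode", function(object) standardGeneric("ensembleMode"))

#' @rdname SmearEnsemble-class
#' @export
setMethod("ensembleMode", "SmearEnsemble", function(object) object@mode)
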