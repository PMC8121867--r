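## Reading the smear dataset format, preprocessing to model-ready tensors,
## the blurred outgroup, and cell-subset selection.

#' Read a smear cohort from its manifest
#'
#' Reads and validates a manifest CSV (columns patient_id, cohort, label,
#' cell_type, path, era_id). Unknown cell-type strings are mapped to
#' `"unidentified"` with a warning; conflicting labels for one patient are
#' an integrity error. Rows are sorted by patient_id then path so the
#' dataset ordering is deterministic.
#'
#' @param manifest_path path to the manifest CSV; image paths inside it are
#'   resolved relative to its directory.
#' @return A [SmearCohort-class].
#' @export
readCohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  m <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- setdiff(.manifestCols, "era_id")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (is.null(m$era_id)) m$era_id <- NA_character_
  if (nrow(m)) {
    bad <- !m$cell_type %in% cellTypeVocabulary()
    if (any(bad)) {
      warning("unknown cell type(s) mapped to 'unidentified': ",
              paste(unique(m$cell_type[bad]), collapse = ", "))
      m$cell_type[bad] <- "unidentified"
    }
    m$label <- as.integer(m$label)
    conf <- tapply(m$label, m$patient_id, function(x) length(unique(x)))
    if (any(conf > 1))
      stop("integrity error: conflicting labels for patient(s): ",
           paste(names(conf)[conf > 1], collapse = ", "))
    m <- m[order(m$patient_id, m$path), , drop = FALSE]
    rownames(m) <- NULL
  }
  new("SmearCohort", manifest = m[, .manifestCols, drop = FALSE],
      root = dirname(manifest_path))
}

.readCellPixels <- function(root, rel) {
  f <- file.path(root, rel)
  if (!file.exists(f)) stop("image file missing: ", f)
  img <- EBImage::readImage(f)
  a <- unclass(EBImage::imageData(img))
  if (length(dim(a)) == 2) stop("non-RGB image (grayscale): ", f)
  if (dim(a)[3] > 3) a <- a[, , 1:3]           # drop alpha
  if (dim(a)[3] != 3) stop("non-RGB image: ", f)
  round(a * 255)
}

#' Load patient bags from a cohort
#'
#' @param cohort a [SmearCohort-class].
#' @param patient_ids subset of patients (default all).
#' @param load_pixels read the image files (0-255 arrays) into the bags.
#' @return List of [PatientSample-class], ordered by patient_id.
#' @export
loadSamples <- function(cohort, patient_ids = NULL, load_pixels = TRUE) {
  m <- manifest(cohort)
  ids <- if (is.null(patient_ids)) sort(unique(m$patient_id))
         else patient_ids
  lapply(ids, function(p) {
    rows <- m[m$patient_id == p, , drop = FALSE]
    if (!nrow(rows)) stop("unknown patient: ", p)
    cells <- if (load_pixels)
      lapply(rows$path, function(rp) .readCellPixels(cohort@root, rp))
    else list()
    new("PatientSample", patient_id = p, label = rows$label[1],
        cohort = rows$cohort[1], cell_types = rows$cell_type,
        paths = rows$path, cells = cells)
  })
}

#' Preprocess a cell image to a model-ready tensor
#'
#' Resizes to `size` x `size` via bilinear interpolation (half-pixel-center
#' convention) and scales intensities into \[0,1\]. Inputs already in
#' \[0,1\] are not rescaled, so preprocessing is idempotent.
#'
#' @param image H x W x 3 array (0-255 integers or \[0,1\] reals) or an
#'   `EBImage::Image`.
#' @param size output edge in pixels; the full-scale pipeline uses 360.
#' @return `size` x `size` x 3 array with values in \[0,1\].
#' @export
preprocessImage <- function(image, size = 360) {
  if (is(image, "Image")) image <- unclass(EBImage::imageData(image))
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("format error: expected an H x W x 3 RGB image")
  x <- image
  storage.mode(x) <- "double"
  if (max(x) > 1) x <- x / 255
  if (d[1] != size || d[2] != size)
    x <- resize_bilinear_cpp(x, as.integer(size), as.integer(size))
  x
}

#' Gaussian-blur an image tensor
#'
#' Separable Gaussian blur, kernel truncated at radius `ceiling(4*sigma)`
#' and normalized, replicate padding at the borders.
#'
#' @param image H x W x 3 array.
#' @param sigma blur SD in pixels (> 0).
#' @return Blurred array of the same shape.
#' @export
gaussianBlurImage <- function(image, sigma) {
  if (sigma <= 0) stop("parameter error: sigma must be > 0")
  gauss_blur_cpp(image, sigma)
}

#' Default outgroup blur SD for a given image size
#'
#' 11 px at the full 360-px scale, scaled linearly with image size: strong
#' enough to destroy cellular morphology while preserving the global
#' stain-color statistics the outgroup is meant to expose.
#'
#' @param size image edge in pixels.
#' @return Blur SD in pixels.
#' @export
outgroupSigma <- function(size) 11 * size / 360

#' Build the blurred outgroup
#'
#' Returns one Gaussian-blurred copy of every input image, labeled with the
#' third training class (`BLURRED = 2`). The outgroup size therefore equals
#' the size of the input set; callers must pass training-split images only
#' so held-out patients never contribute outgroup members.
#'
#' @param images H x W x 3 x N array of preprocessed tensors (or a list of
#'   H x W x 3 arrays).
#' @param sigma blur SD in pixels; default [outgroupSigma()] of the input
#'   height.
#' @return List with `images` (blurred, same shape) and `labels`
#'   (`rep(2L, N)`).
#' @export
makeBlurOutgroup <- function(images, sigma = NULL) {
  if (is.list(images)) images <- stackImages(images)
  d <- dim(images)
  if (length(d) == 3) { images <- array(images, c(d, 1)); d <- dim(images) }
  if (d[4] < 1) stop("images must be nonempty")
  if (is.null(sigma)) sigma <- outgroupSigma(d[1])
  if (sigma <= 0) stop("parameter error: sigma must be > 0")
  out <- images
  for (n in seq_len(d[4]))
    out[, , , n] <- gauss_blur_cpp(images[, , , n, drop = TRUE], sigma)
  list(images = out, labels = rep(2L, d[4]))
}

#' Stack a list of equally sized H x W x 3 arrays into an H x W x 3 x N array
#' @param images list of arrays.
#' @return 4-D array.
#' @export
stackImages <- function(images) {
  stopifnot(length(images) >= 1)
  d <- dim(images[[1]])
  out <- array(0, c(d, length(images)))
  for (n in seq_along(images)) out[, , , n] <- images[[n]]
  out
}

#' Restrict a bag to immature myeloid cells
#'
#' Retains only blasts, promonocytes, promyelocytes, myelocytes and
#' metamyelocytes (the "Blasts" training scope), preserving order. An
#' empty result is flagged with a warning so the sample can be excluded
#' from blasts-only training.
#'
#' @param sample a [PatientSample-class].
#' @return The filtered `PatientSample` (possibly with zero cells, in which
#'   case validity is not enforced and a warning is raised).
#' @export
setGeneric("selectImmatureMyeloid",
           function(sample) standardGeneric("selectImmatureMyeloid"))

#' @rdname selectImmatureMyeloid
#' @export
setMethod("selectImmatureMyeloid", "PatientSample", function(sample) {
  keep <- sample@cell_types %in% immatureMyeloidTypes()
  if (!any(keep))
    warning("sample ", sample@patient_id,
            " has no immature myeloid cells; excluded from blasts-only training")
  out <- sample
  out@cell_types <- sample@cell_types[keep]
  out@paths <- sample@paths[keep]
  if (length(sample@cells)) out@cells <- sample@cells[keep]
  out
})

#' Load all cohort cells as one preprocessed tensor block
#'
#' Reads every manifest image (deterministic manifest order), preprocesses
#' it and stacks the result. Used by the training routines so image
#' decoding happens once per run, not once per Monte-Carlo repetition.
#'
#' @param cohort a [SmearCohort-class].
#' @param size target edge in pixels; `NULL` keeps the native size (all
#'   images must then agree).
#' @return List with `X` (H x W x 3 x N array in \[0,1\]) and `manifest`
#'   (the cohort manifest, row i describing `X[,,,i]`).
#' @export
loadCellMatrix <- function(cohort, size = NULL) {
  m <- manifest(cohort)
  if (!nrow(m)) stop("empty cohort")
  imgs <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    px <- .readCellPixels(cohort@root, m$path[i])
    imgs[[i]] <- if (is.null(size)) px / 255 else preprocessImage(px, size)
  }
  dims <- vapply(imgs, function(x) dim(x)[1], numeric(1))
  if (length(unique(dims)) > 1)
    stop("images have differing sizes; pass an explicit `size`")
  list(X = stackImages(imgs), manifest = m)
}
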