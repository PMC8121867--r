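## The two architectures: single-cell three-class classifier and the MIL
## sample classifier whose bag prediction is the in-network mean of the
## per-cell softmax assignments.

#' Architecture configuration
#'
#' Four stride-2 valid convolutions (ReLU), global max-pooling over spatial
#' positions (translational invariance; also makes the network input-size
#' agnostic), three fully connected ReLU layers, and a 3-class softmax
#' (non-APL / APL / blurred). The fully connected widths 32/22/11 are
#' chosen so that the concatenated last-four-layer feature space has
#' dimensionality 32 + 22 + 11 + 3 = 68.
#'
#' @param conv_filters filter counts of the 4 convolutional layers.
#' @param conv_kernel square kernel edge (pixels).
#' @param conv_stride convolution stride.
#' @param fc_sizes widths of the 3 fully connected layers.
#' @param n_classes fixed at 3.
#' @return A validated list of class `arch_config`.
#' @export
archConfig <- function(conv_filters = c(16, 32, 64, 128), conv_kernel = 3,
                       conv_stride = 2, fc_sizes = c(32, 22, 11),
                       n_classes = 3) {
  if (length(conv_filters) != 4)
    stop("config error: exactly 4 convolutional layers required")
  if (length(fc_sizes) != 3)
    stop("config error: exactly 3 fully connected layers required")
  if (n_classes != 3) stop("config error: n_classes is fixed at 3")
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 conv_stride = as.integer(conv_stride),
                 fc_sizes = as.integer(fc_sizes), n_classes = 3L),
            class = "arch_config")
}

#' Latent dimensionality of the last four layers
#' @param config an [archConfig()].
#' @return `sum(fc_sizes) + n_classes` (68 under defaults).
#' @export
latentDim <- function(config = archConfig()) {
  sum(config$fc_sizes) + config$n_classes
}

.initWeights <- function(config, seed) {
  set.seed(seed)
  he <- function(nout, nin) matrix(rnorm(nout * nin, sd = sqrt(2 / nin)),
                                   nout, nin)
  k <- config$conv_kernel
  cin <- c(3L, head(config$conv_filters, -1))
  list(
    cw = lapply(seq_len(4), function(l)
      he(config$conv_filters[l], cin[l] * k * k)),
    cb = lapply(config$conv_filters, function(f) numeric(f)),
    fw = {
      ins <- c(config$conv_filters[4], head(config$fc_sizes, -1))
      lapply(seq_len(3), function(l) he(config$fc_sizes[l], ins[l]))
    },
    fb = lapply(config$fc_sizes, function(s) numeric(s)),
    ow = he(3, config$fc_sizes[3]),
    ob = numeric(3),
    config = list(conv_kernel = config$conv_kernel,
                  conv_stride = config$conv_stride))
}

#' Build the single-cell three-class classifier
#'
#' Weight initialization (He-scaled Gaussians) is reproducible from the
#' seed; two builds with the same seed produce identical models.
#'
#' @param config an [archConfig()].
#' @param seed integer initialization seed.
#' @return An untrained [SmearCNN-class] in `"cell"` mode.
#' @export
buildCellClassifier <- function(config = archConfig(), seed = 1) {
  stopifnot(inherits(config, "arch_config"))
  new("SmearCNN", mode = "cell", config = unclass(config),
      weights = .initWeights(config, seed), seed = as.numeric(seed),
      trained = FALSE)
}

#' Build the MIL sample classifier
#'
#' Same per-cell architecture as [buildCellClassifier()]; the bag
#' probability is computed inside the network as the arithmetic mean of
#' the per-cell softmax assignments (multiple-instance learning).
#'
#' @inheritParams buildCellClassifier
#' @return An untrained [SmearCNN-class] in `"mil"` mode.
#' @export
buildMilClassifier <- function(config = archConfig(), seed = 1) {
  m <- buildCellClassifier(config, seed)
  m@mode <- "mil"
  m
}

.as4d <- function(X) {
  if (is.list(X)) {
    if (!length(X)) return(NULL)
    X <- stackImages(X)
  }
  d <- dim(X)
  if (is.null(d)) return(NULL)
  if (length(d) == 3) X <- array(X, c(d, 1))
  if (length(dim(X)) != 4) stop("expected H x W x 3 (x N) image array")
  X
}

#' Per-cell class probabilities
#'
#' @param model a [SmearCNN-class].
#' @param cells H x W x 3 x N array (or list of H x W x 3 arrays) of
#'   preprocessed tensors in \[0,1\].
#' @return N x 3 matrix with columns `non_apl`, `apl`, `blurred`; rows sum
#'   to 1. Empty input gives a 0 x 3 matrix.
#' @export
predictCells <- function(model, cells) {
  stopifnot(is(model, "SmearCNN"))
  X <- .as4d(cells)
  if (is.null(X) || dim(X)[4] == 0)
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("non_apl", "apl", "blurred"))))
  p <- cnn_forward_cpp(model@weights, X, FALSE)$probs
  colnames(p) <- c("non_apl", "apl", "blurred")
  p
}

#' Hidden last-four-layer activations per cell
#'
#' Concatenation of the three post-ReLU fully connected activations and
#' the 3-class softmax output (68 dimensions under the default
#' architecture).
#'
#' @inheritParams predictCells
#' @return N x [latentDim()] matrix.
#' @export
cellLatent <- function(model, cells) {
  stopifnot(is(model, "SmearCNN"))
  X <- .as4d(cells)
  if (is.null(X)) return(matrix(numeric(0), 0, 0))
  cnn_forward_cpp(model@weights, X, TRUE)$hidden
}

#' Binary APL probability from three-class output
#'
#' Renormalizes over the two real classes: `p_apl / (p_apl + p_nonapl)`.
#' The blurred class is a training device, not a diagnosis, so it is
#' excluded from the binary score. A degenerate all-blurred prediction
#' (`p_apl + p_nonapl == 0`) returns 0.5 with a warning.
#'
#' @param probs length-3 probability vector (non-APL, APL, blurred) or an
#'   N x 3 matrix of them.
#' @return Probability (vector) in \[0,1\].
#' @export
aplProbability <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  stopifnot(ncol(probs) == 3)
  den <- probs[, 1] + probs[, 2]
  out <- ifelse(den > 0, probs[, 2] / den, 0.5)
  if (any(den == 0))
    warning("degenerate all-blurred prediction; returning 0.5")
  unname(out)
}

#' MIL bag prediction for one patient sample
#'
#' @param model a [SmearCNN-class] (typically `"mil"` mode).
#' @param cells nonempty bag of preprocessed tensors.
#' @return List with `bag_probs` (mean of per-cell softmax assignments),
#'   `per_cell_probs` (N x 3), and `p_apl_binary`
#'   (= [aplProbability()] of `bag_probs`).
#' @export
predictBag <- function(model, cells) {
  X <- .as4d(cells)
  if (is.null(X) || dim(X)[4] == 0) stop("empty bag")
  p <- predictCells(model, X)
  bag <- colMeans(p)
  list(bag_probs = bag, per_cell_probs = p,
       p_apl_binary = aplProbability(bag))
}

#' Save / load a model checkpoint
#'
#' Weights are serialized by path with the architecture configuration
#' written alongside as YAML.
#'
#' @param model a [SmearCNN-class].
#' @param path checkpoint file path (`.rds`); the YAML sidecar gets the
#'   same path with extension `.yaml`.
#' @return `saveModel` returns `path` invisibly; `loadModel` the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(mode = model@mode, config = model@config,
               weights = model@weights, seed = model@seed,
               trained = model@trained), path)
  yaml::write_yaml(model@config[c("conv_filters", "conv_kernel",
                                  "conv_stride", "fc_sizes", "n_classes")],
                   sub("\\.rds$", ".yaml", path))
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  new("SmearCNN", mode = x$mode, config = x$config, weights = x$weights,
      seed = x$seed, trained = x$trained)
}
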