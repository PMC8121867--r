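## Integrated-gradients attribution with blurred baselines and multi-model
## consensus; ensemble latent-feature extraction with PCA/UMAP.

# Shared path-integral core. gradFun(X4d) must return the gradient of
# deltaP = P(APL) - P(non-APL) w.r.t. each image in the batch, same shape.
# Left-Riemann averaging over `steps` interpolation points alpha = k/steps,
# k = 0..steps-1 (matching a path of `steps` scaled images from baseline to
# input), then multiplication by (image - baseline) and channel summation.
.igCore <- function(gradFun, image, baseline, steps) {
  if (steps < 2) stop("parameter error: steps must be >= 2")
  d <- dim(image)
  path <- array(0, c(d, steps))
  alphas <- (seq_len(steps) - 1) / steps
  diff <- image - baseline
  for (k in seq_len(steps)) path[, , , k] <- baseline + alphas[k] * diff
  g <- gradFun(path)
  avg <- array(0, d)
  for (k in seq_len(steps)) avg <- avg + g[, , , k]
  avg <- avg / steps
  attr3 <- diff * avg
  attr3[, , 1] + attr3[, , 2] + attr3[, , 3]
}

#' Integrated-gradients attribution map for one cell image
#'
#' The baseline is the Gaussian-blurred version of the image (same blur SD
#' as the training outgroup), so attribution measures what the sharp
#' morphology adds over the stain-color context. `steps` scaled images are
#' created along the straight path from the baseline to the original; the
#' per-pixel gradient of the delta prediction P(APL) - P(non-APL) is
#' averaged along the path (left Riemann), multiplied by
#' (image - baseline) and summed over RGB channels.
#'
#' @param model a trained [SmearCNN-class].
#' @param image preprocessed H x W x 3 tensor in \[0,1\].
#' @param steps number of interpolation points (default 100).
#' @param baseline optional explicit baseline tensor; default the blurred
#'   image.
#' @param sigma blur SD for the default baseline; default
#'   [outgroupSigma()] of the image height.
#' @return An `attribution_map`: list with `values` (H x W channel-summed
#'   attributions), `baseline`, `source`, `n_models`.
#' @export
integratedGradients <- function(model, image, steps = 100, baseline = NULL,
                                sigma = NULL) {
  stopifnot(is(model, "SmearCNN"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be H x W x 3")
  if (is.null(sigma)) sigma <- outgroupSigma(d[1])
  if (is.null(baseline)) baseline <- gaussianBlurImage(image, sigma)
  vals <- .igCore(function(P) cnn_input_grad_cpp(model@weights, P)$grad,
                  image, baseline, steps)
  structure(list(values = vals, baseline = baseline,
                 source = "single-model", n_models = 1L),
            class = "attribution_map")
}

#' Delta prediction P(APL) - P(non-APL) of a model on images
#' @param model a [SmearCNN-class].
#' @param images H x W x 3 (x N) array.
#' @return Numeric vector of deltas.
#' @export
deltaPrediction <- function(model, images) {
  cnn_input_grad_cpp(model@weights, .as4d(images))$delta
}

#' Consensus attribution over a model subset
#'
#' Mean of single-model integrated-gradients maps over a seeded
#' pseudo-random subset of ensemble members (uniform sampling without
#' replacement), for robust and stable maps.
#'
#' @param ensemble a [SmearEnsemble-class].
#' @param image preprocessed H x W x 3 tensor.
#' @param n_models consensus size (default 25).
#' @param seed selection seed.
#' @param steps interpolation points per member map.
#' @return An `attribution_map` with `source = "consensus"`.
#' @export
consensusAttribution <- function(ensemble, image, n_models = 25, seed = 1,
                                 steps = 100) {
  nm <- length(ensemble@models)
  if (n_models > nm)
    stop("n_models (", n_models, ") exceeds ensemble size (", nm, ")")
  set.seed(seed)
  pick <- sort(sample(nm, n_models))
  maps <- lapply(pick, function(k)
    integratedGradients(ensemble@models[[k]], image, steps)$values)
  vals <- Reduce(`+`, maps) / length(maps)
  structure(list(values = vals, baseline = NULL, source = "consensus",
                 n_models = as.integer(n_models), members = pick),
            class = "attribution_map")
}

#' Most predictive cells of an evaluation report
#'
#' Top-k cells by APL probability and top-k by non-APL probability
#' (ascending APL score). Cells appearing in several Monte-Carlo
#' repetitions are first averaged per (patient_id, path). Ties break
#' lexicographically by (patient_id, path).
#'
#' @param report an evaluation report with per-cell scores.
#' @param k number of cells per list; larger than the cell count is
#'   truncated with a warning.
#' @return List with data.frames `apl` and `non_apl`.
#' @export
rankMostPredictiveCells <- function(report, k) {
  cells <- report$per_cell
  if (is.null(cells) || !nrow(cells)) stop("report has no per-cell scores")
  agg <- stats::aggregate(score ~ patient_id + path + label + cell_type,
                          cells, mean)
  if (k > nrow(agg)) {
    warning("k exceeds cell count; truncated to ", nrow(agg))
    k <- nrow(agg)
  }
  up <- agg[order(-agg$score, agg$patient_id, agg$path), , drop = FALSE]
  dn <- agg[order(agg$score, agg$patient_id, agg$path), , drop = FALSE]
  list(apl = utils::head(up, k), non_apl = utils::head(dn, k))
}

#' Extract ensemble latent features
#'
#' Per cell and per MIL ensemble member, concatenates the outputs of the
#' last four layers of the network — the three post-ReLU fully connected
#' activations and the 3-class softmax (32 + 22 + 11 + 3 = 68 dimensions
#' under defaults) — across all members in ensemble order (68 x n_models
#' columns; 6800 for the full 100-model ensemble).
#'
#' @param ensemble a MIL-mode [SmearEnsemble-class].
#' @param cells preprocessed H x W x 3 x N tensor block.
#' @return N x (68 * n_models) matrix with attributes `per_model_dim` and
#'   `n_models`.
#' @export
extractLatentFeatures <- function(ensemble, cells) {
  if (ensemble@mode != "mil")
    stop("mode error: latent features are extracted from a MIL ensemble")
  X <- .as4d(cells)
  feats <- lapply(ensemble@models, function(m) cellLatent(m, X))
  out <- do.call(cbind, feats)
  attr(out, "per_model_dim") <- ncol(feats[[1]])
  attr(out, "n_models") <- length(feats)
  out
}

#' PCA + UMAP embedding of latent features
#'
#' Features are standardized (zero mean, unit variance per dimension;
#' constant dimensions left at zero), PCA keeps the minimal number of
#' components reaching at least 99% cumulative explained variance, and the
#' 2-D UMAP layout is computed on the retained PCA scores with a fixed
#' seed. Per-class Gaussian kernel density grids are estimated in the
#' embedding.
#'
#' @param features cells x D matrix (e.g. from [extractLatentFeatures()]).
#' @param labels optional per-cell class labels (0/1) for the density
#'   maps.
#' @param cell_types optional per-cell types, carried through.
#' @param apl_probs optional per-cell APL probabilities for coloring.
#' @param seed embedding seed (bit-reproducible given the seed).
#' @param n_neighbors,min_dist,n_epochs UMAP hyperparameters.
#' @return A `smear_embedding`: list with `coords`, `pca_dims_kept`,
#'   `explained_variance_kept`, `density_by_class`, `per_cell_apl_prob`,
#'   `labels`, `cell_types`.
#' @export
embedLatent <- function(features, labels = NULL, cell_types = NULL,
                        apl_probs = NULL, seed = 1, n_neighbors = 15,
                        min_dist = 0.1, n_epochs = 200) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3) stop("need at least 3 cells to embed")
  mu <- colMeans(features)
  sdv <- apply(features, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  keep <- which(cum >= 0.99)[1]
  scores <- pc$x[, seq_len(keep), drop = FALSE]
  coords <- umapEmbed(scores, n_neighbors = min(n_neighbors, n - 1),
                      min_dist = min_dist, n_epochs = n_epochs, seed = seed)
  dens <- NULL
  if (!is.null(labels)) {
    dens <- lapply(split(seq_len(n), labels), function(ix) {
      if (length(ix) < 3 || sd(coords[ix, 1]) == 0 || sd(coords[ix, 2]) == 0)
        return(NULL)
      MASS::kde2d(coords[ix, 1], coords[ix, 2], n = 50,
                  lims = c(range(coords[, 1]), range(coords[, 2])))
    })
  }
  structure(list(coords = coords, pca_dims_kept = keep,
                 explained_variance_kept = cum[keep],
                 density_by_class = dens, per_cell_apl_prob = apl_probs,
                 labels = labels, cell_types = cell_types),
            class = "smear_embedding")
}

#' Render an attribution overlay
#'
#' Normalizes the map to \[-1, 1\] by its maximum absolute value, applies
#' a diverging blue-white-red colormap and alpha-blends it (alpha 0.5)
#' over the original image.
#'
#' @param image the original H x W x 3 tensor in \[0,1\].
#' @param map an `attribution_map` (or H x W matrix).
#' @param file optional PNG output path.
#' @return The blended H x W x 3 array, invisibly.
#' @export
attributionOverlay <- function(image, map, file = NULL) {
  v <- if (inherits(map, "attribution_map")) map$values else map
  mx <- max(abs(v))
  if (mx > 0) v <- v / mx
  # diverging: negative -> blue, positive -> red
  overlay <- array(0, dim(image))
  overlay[, , 1] <- pmax(v, 0) + pmin(1, 1 - abs(v))
  overlay[, , 2] <- pmin(1, 1 - abs(v))
  overlay[, , 3] <- pmax(-v, 0) + pmin(1, 1 - abs(v))
  blend <- 0.5 * image + 0.5 * overlay
  blend <- pmin(pmax(blend, 0), 1)
  if (!is.null(file))
    EBImage::writeImage(EBImage::Image(blend, colormode = "Color"), file)
  invisible(blend)
}

#' Plot UMAP panels of an embedding
#'
#' Class-density panel and APL-probability coloring, written as one PNG.
#'
#' @param embedding a `smear_embedding`.
#' @param file PNG output path.
#' @return `file`, invisibly.
#' @export
plotEmbedding <- function(embedding, file) {
  grDevices::png(file, 1200, 600)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  co <- embedding$coords
  lab <- embedding$labels
  col1 <- if (is.null(lab)) "grey30"
          else ifelse(lab == 1, "#d73027", "#4575b4")
  graphics::plot(co, col = col1, pch = 16, cex = 0.6, xlab = "UMAP 1",
                 ylab = "UMAP 2", main = "non-APL (blue) vs APL (red)")
  if (!is.null(embedding$density_by_class)) {
    for (dz in embedding$density_by_class)
      if (!is.null(dz)) graphics::contour(dz, add = TRUE, nlevels = 5,
                                          drawlabels = FALSE, col = "grey50")
  }
  pr <- embedding$per_cell_apl_prob
  col2 <- if (is.null(pr)) "grey30"
          else grDevices::rgb(pr, 0.2, 1 - pr)
  graphics::plot(co, col = col2, pch = 16, cex = 0.6, xlab = "UMAP 1",
                 ylab = "UMAP 2", main = "P(APL) per cell")
  grDevices::dev.off()
  invisible(file)
}
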