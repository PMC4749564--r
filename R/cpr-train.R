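## Cascaded pose regression: training. A cascade of boosted random-fern
## stages; each stage samples a fresh pool of pose-indexed intensity-difference
## features and fits ferns to the remaining displacement to the label.

#' Pose-indexed intensity-difference features
#'
#' Feature `i` is the image intensity at `pose + offsetA_i` minus the
#' intensity at `pose + offsetB_i`, with out-of-bounds samples clamped to the
#' nearest pixel. Because offsets ride along with the pose, the features are
#' equivariant under joint translation of image content and pose.
#'
#' @param image Grayscale `height x width` matrix.
#' @param pose `c(x, y)` pixel position (0-based).
#' @param featureDefs `P x 4` matrix of offsets `(ax, ay, bx, by)` in px.
#' @return Numeric vector of `P` intensity differences.
#' @export
poseIndexedFeatures <- function(image, pose, featureDefs) {
  featureDefs <- as.matrix(featureDefs)
  if (nrow(featureDefs) == 0) stop("featureDefs must contain at least one offset pair")
  as.numeric(.cprPoolFeatures(list(image), 0L, matrix(pose, 1, 2), featureDefs))
}

#' Random offset pairs within a disc
#' @noRd
.randomPool <- function(poolSize, radius) {
  draw <- function(n) {
    r <- radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  }
  cbind(draw(poolSize), draw(poolSize))
}

#' Train a pose-regression cascade
#'
#' Trains a cascade of `nStages` boosted random-fern stages on manually (or
#' synthetically) labeled frames. Each training frame contributes
#' `augPerFrame` initial poses (half uniform over the frame, half perturbed
#' around the label) so the cascade learns to pull estimates toward the hand
#' from anywhere in the image. At each stage a pool of `poolSize` pose-indexed
#' features is sampled; each fern greedily takes the `fernDepth` features
#' whose values correlate most strongly with a random projection of the
#' current residual displacement, and its `2^fernDepth` bins store shrunken
#' mean residuals. The median training displacement error per stage is logged
#' in `trainingMeta`.
#'
#' @param frames List of grayscale `height x width` matrices.
#' @param labels `n x 2` matrix of hand positions `(x, y)`, px, one per frame.
#' @param nStages Number of cascade stages (default 100 iterations).
#' @param nFerns Ferns per stage.
#' @param fernDepth Binary tests per fern.
#' @param poolSize Candidate features sampled per stage.
#' @param featureRadius Maximum feature offset from the pose, px.
#' @param augPerFrame Initial poses per training frame.
#' @param shrinkage Additive shrinkage on bin means (counts).
#' @param seed Integer seed.
#' @return A `CascadeModel`.
#' @export
trainCascade <- function(frames, labels, nStages = 100, nFerns = 50,
                         fernDepth = 5, poolSize = 400, featureRadius = 40,
                         augPerFrame = 10, shrinkage = 10, seed = 1) {
  if (length(frames) == 0) stop("empty training set")
  labels <- as.matrix(labels)
  if (nrow(labels) != length(frames)) stop("one label per frame is required")
  if (length(frames) < 10) stop("at least 10 labeled frames are required")
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  if (any(labels[, 1] < 0 | labels[, 1] > w - 1 | labels[, 2] < 0 | labels[, 2] > h - 1))
    stop("labels must lie inside the image bounds")
  if (all(abs(sweep(labels, 2, labels[1, ])) < 1e-9))
    warning("degenerate training set: all labels identical")
  set.seed(seed)

  nF <- length(frames)
  imgIdx <- rep(seq_len(nF) - 1L, each = augPerFrame)
  n <- length(imgIdx)
  lab <- labels[imgIdx + 1, , drop = FALSE]
  uniform <- rep(runif(n) < 0.5)
  poses <- lab + matrix(rnorm(2 * n, 0, 30), n, 2)
  poses[uniform, 1] <- runif(sum(uniform), 0, w - 1)
  poses[uniform, 2] <- runif(sum(uniform), 0, h - 1)
  poses[, 1] <- pmin(w - 1, pmax(0, poses[, 1]))
  poses[, 2] <- pmin(h - 1, pmax(0, poses[, 2]))

  nbins <- 2^fernDepth
  offsets <- array(0, c(4, fernDepth, nFerns, nStages))
  thresholds <- array(0, c(fernDepth, nFerns, nStages))
  outputs <- array(0, c(2, nbins, nFerns, nStages))
  stageErr <- numeric(nStages)
  pow2 <- 2^(seq_len(fernDepth) - 1)

  for (s in seq_len(nStages)) {
    pool <- .randomPool(poolSize, featureRadius)
    Fm <- .cprPoolFeatures(frames, imgIdx, poses, pool)
    mu <- colMeans(Fm)
    sdv <- sqrt(pmax(colMeans(Fm^2) - mu^2, 0))
    sdv[sdv < 1e-12] <- Inf  # constant features can never be selected
    Fc <- sweep(sweep(Fm, 2, mu), 2, sdv, "/")
    res <- lab - poses
    for (k in seq_len(nFerns)) {
      th <- runif(1, 0, 2 * pi)
      target <- res %*% c(cos(th), sin(th))
      tsd <- sd(target)
      if (tsd < 1e-12) tsd <- Inf
      corr <- abs(crossprod(Fc, (target - mean(target)) / tsd)) / (n - 1)
      sel <- order(-corr)[seq_len(fernDepth)]
      qs <- apply(Fm[, sel, drop = FALSE], 2, quantile, c(0.1, 0.9), names = FALSE)
      thr <- qs[1, ] + runif(fernDepth) * (qs[2, ] - qs[1, ])
      bits <- sweep(Fm[, sel, drop = FALSE], 2, thr, ">")
      bin <- as.integer(bits %*% pow2)
      cnt <- tabulate(bin + 1L, nbins)
      dx <- rowsum(res[, 1], bin, reorder = FALSE)
      dy <- rowsum(res[, 2], bin, reorder = FALSE)
      upd <- matrix(0, nbins, 2)
      rows <- as.integer(rownames(dx)) + 1L
      upd[rows, 1] <- dx / (cnt[rows] + shrinkage)
      upd[rows, 2] <- dy / (cnt[rows] + shrinkage)
      offsets[, , k, s] <- t(pool[sel, , drop = FALSE])
      thresholds[, k, s] <- thr
      outputs[, , k, s] <- t(upd)
      poses <- poses + upd[bin + 1L, , drop = FALSE]
      res <- lab - poses
    }
    poses[, 1] <- pmin(w - 1, pmax(0, poses[, 1]))
    poses[, 2] <- pmin(h - 1, pmax(0, poses[, 2]))
    stageErr[s] <- median(sqrt(rowSums((lab - poses)^2)))
  }

  new("CascadeModel", nStages = nStages, nFerns = nFerns, fernDepth = fernDepth,
      featureRadius = featureRadius, offsets = offsets, thresholds = thresholds,
      outputs = outputs,
      trainingMeta = list(stageMedianErrors = stageErr, nFrames = nF,
                          augPerFrame = augPerFrame, poolSize = poolSize,
                          shrinkage = shrinkage, seed = seed,
                          imageSize = c(w, h)))
}

#' Serialize a cascade model to a JSON container
#'
#' @param model A `CascadeModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCascadeModel <- function(model, path) {
  obj <- list(format = "prehensr-cascade", version = 1,
              nStages = model@nStages, nFerns = model@nFerns,
              fernDepth = model@fernDepth, featureRadius = model@featureRadius,
              offsets = as.numeric(model@offsets),
              thresholds = as.numeric(model@thresholds),
              outputs = as.numeric(model@outputs),
              trainingMeta = model@trainingMeta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCascadeModel
#' @export
readCascadeModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$format, "prehensr-cascade"))
    stop("not a cascade model container")
  d <- as.numeric(o$fernDepth); k <- as.numeric(o$nFerns)
  s <- as.numeric(o$nStages)
  new("CascadeModel", nStages = s, nFerns = k, fernDepth = d,
      featureRadius = as.numeric(o$featureRadius),
      offsets = array(o$offsets, c(4, d, k, s)),
      thresholds = array(o$thresholds, c(d, k, s)),
      outputs = array(o$outputs, c(2, 2^d, k, s)),
      trainingMeta = as.list(o$trainingMeta))
}
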