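# Training: combined soft-Jaccard + cross-entropy segmentation loss, binary
# cross-entropy on the tooth-level head, Adam optimisation.  Single-threaded
# and deterministic given the seed.

.JACCARD_EPS <- 1e-6
.BCE_EPS <- 1e-7

#' Segmentation loss: (1 - soft Jaccard) + voxel-mean binary cross-entropy
#'
#' Soft Jaccard uses epsilon smoothing (1e-6) so the empty/empty case is
#' defined as perfect overlap (Jaccard term 0).  Probabilities are clipped to
#' [1e-7, 1 - 1e-7] inside the cross-entropy.  Nonnegative and smooth in the
#' prediction.
#'
#' @param predProb 3D array of voxel probabilities (or matching vector)
#' @param target binary array / [BinaryMask-class] of the same shape
#' @return scalar loss
#' @export
segmentationLoss <- function(predProb, target) {
  if (methods::is(target, "BinaryMask")) target <- target@data
  if (methods::is(predProb, "CariesPrediction")) predProb <- predProb@lesionProb
  if (!all(dim(predProb) == dim(target))) stop("shape mismatch")
  tv <- as.vector(target)
  if (is.logical(tv)) tv <- as.numeric(tv)
  if (!all(tv %in% c(0, 1))) stop("target must be binary")
  p <- as.vector(predProb)
  I <- sum(p * tv)
  U <- sum(p) + sum(tv) - I
  jac <- (I + .JACCARD_EPS) / (U + .JACCARD_EPS)
  pc <- .clamp(p, .BCE_EPS, 1 - .BCE_EPS)
  bce <- -mean(tv * log(pc) + (1 - tv) * log(1 - pc))
  (1 - jac) + bce
}

# loss + gradient wrt segmentation logits and classification logit
.lossAndGrad <- function(fw, targetVec, label) {
  p <- .sigmoid(fw$logits)
  n <- length(p)
  t <- targetVec
  I <- sum(p * t); U <- sum(p) + sum(t) - I
  jac <- (I + .JACCARD_EPS) / (U + .JACCARD_EPS)
  pc <- .clamp(p, .BCE_EPS, 1 - .BCE_EPS)
  bce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
  segLoss <- (1 - jac) + bce
  # d(1-J)/dp = -[t(U+eps) - (I+eps)(1-t)]/(U+eps)^2 ; chain through sigmoid
  dJdp <- (t * (U + .JACCARD_EPS) - (I + .JACCARD_EPS) * (1 - t)) /
    (U + .JACCARD_EPS)^2
  dSeg <- (-dJdp) * p * (1 - p) + (p - t) / n
  pt <- .sigmoid(fw$clsLogit)
  ptc <- .clamp(pt, .BCE_EPS, 1 - .BCE_EPS)
  clsLoss <- -(label * log(ptc) + (1 - label) * log(1 - ptc))
  dCls <- pt - label
  list(segLoss = segLoss, clsLoss = clsLoss, dLogits = dSeg, dCls = dCls)
}

#' Train the attention U-Net on tooth volumes
#'
#' Adam (default learning rate 1e-3) on the summed segmentation and
#' classification losses, mini-batches drawn with the training seed, gradients
#' averaged over the batch.  Aborts with a diagnostic on non-finite loss.
#' Reproducible: two runs with the same network, data and seed give identical
#' loss histories.
#'
#' @param net a network from [buildNetwork()]
#' @param dataset nonempty list of samples, each a list with \code{volume}
#'   ([VoxelVolume-class] or array), \code{lesionMask} ([BinaryMask-class] or
#'   logical array) and \code{label} (0/1 tooth-level pathology; default =
#'   any lesion voxel)
#' @param steps number of optimisation steps
#' @param seed RNG seed for batch sampling (default the config seed)
#' @param verbose print the loss every 25 steps
#' @return the trained network with a \code{history} data.frame (step,
#'   segLoss, clsLoss, loss) attached
#' @export
trainNetwork <- function(net, dataset, steps = 200L, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "cariesNet"))
  if (!is.list(dataset) || length(dataset) == 0L)
    stop("dataset must be a nonempty list of samples")
  seed <- seed %||% net$config@seed
  prep <- lapply(dataset, function(s) {
    vol <- if (methods::is(s$volume, "VoxelVolume")) s$volume@data else s$volume
    msk <- if (methods::is(s$lesionMask, "BinaryMask")) s$lesionMask@data else s$lesionMask
    if (!all(dim(vol) == net$inputShape) || !all(dim(msk) == net$inputShape))
      stop("every sample must match the network input shape")
    list(x = normalizeIntensities(vol), t = as.numeric(as.vector(msk)),
         label = as.numeric(s$label %||% any(msk != 0)))
  })
  lr <- net$config@learningRate
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8
  m <- lapply(net$params, function(p) p * 0)
  v <- lapply(net$params, function(p) p * 0)
  hist <- data.frame(step = integer(steps), segLoss = numeric(steps),
                     clsLoss = numeric(steps), loss = numeric(steps))
  bs <- min(net$config@batchSize, length(prep))
  .withSeed(seed, {
    for (s in seq_len(steps)) {
      batch <- sample.int(length(prep), bs, replace = length(prep) < bs)
      grads <- NULL
      segL <- 0; clsL <- 0
      for (i in batch) {
        fw <- .netForward(net, prep[[i]]$x, training = TRUE)
        lg <- .lossAndGrad(fw, prep[[i]]$t, prep[[i]]$label)
        segL <- segL + lg$segLoss / bs
        clsL <- clsL + lg$clsLoss / bs
        g <- .netBackward(net, fw, matrix(lg$dLogits / bs, ncol = 1L),
                          lg$dCls / bs)
        if (is.null(grads)) grads <- g
        else for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
      }
      loss <- segL + clsL
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at step %d (seg %.4g, cls %.4g): aborting",
                     s, segL, clsL))
      for (nm in names(net$params)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
        mh <- m[[nm]] / (1 - b1^s)
        vh <- v[[nm]] / (1 - b2^s)
        net$params[[nm]] <- net$params[[nm]] - lr * mh / (sqrt(vh) + adamEps)
      }
      hist$step[s] <- s; hist$segLoss[s] <- segL; hist$clsLoss[s] <- clsL
      hist$loss[s] <- loss
      if (verbose && (s %% 25L == 0L || s == 1L))
        message(sprintf("step %4d  loss %.4f (seg %.4f, cls %.4f)", s, loss, segL, clsL))
    }
  })
  net$history <- hist
  net
}

#' Soft Jaccard index between a probability grid and a binary mask
#'
#' @param predProb probability array (or [CariesPrediction-class])
#' @param target binary array or [BinaryMask-class]
#' @return scalar in [0, 1]
#' @export
softJaccard <- function(predProb, target) {
  if (methods::is(predProb, "CariesPrediction")) predProb <- predProb@lesionProb
  if (methods::is(target, "BinaryMask")) target <- target@data
  p <- as.vector(predProb); t <- as.numeric(as.vector(target))
  I <- sum(p * t); U <- sum(p) + sum(t) - I
  (I + .JACCARD_EPS) / (U + .JACCARD_EPS)
}

#' Dice coefficient between two binary masks
#'
#' @param a,b logical arrays or [BinaryMask-class] objects of equal shape
#' @return 2|A n B| / (|A| + |B|); 1 when both are empty
#' @export
diceCoefficient <- function(a, b) {
  if (methods::is(a, "BinaryMask")) a <- a@data
  if (methods::is(b, "BinaryMask")) b <- b@data
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
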