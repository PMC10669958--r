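# The modified fully-convolutional 3D U-Net: stride-2 3x3x3 encoder
# transitions, nearest-neighbour up-sampling, additive attention gates on the
# skip connections, decoder blocks of a 3x3x3 convolution followed by a 1x1x1
# convolution halving the feature maps, deep supervision by element-wise
# summation of per-level segmentation maps, instance normalisation and leaky
# ReLU throughout, plus a tooth-level classification head (global average pool
# of the bottleneck features -> dense -> sigmoid).

.netChannels <- function(config) config@baseChannels * 2L^(seq_len(config@nLevels) - 1L)

#' Build an attention 3D U-Net
#'
#' Freshly initialises all weights (He-scaled Gaussians, no pre-training)
#' under the config seed.  The input shape must be divisible by
#' 2^(nLevels - 1) per axis so every encoder level halves the resolution
#' exactly.
#'
#' @param config a [NetworkConfig-class]
#' @param inputShape integer length-3 network input shape
#'   (default c(96, 64, 64))
#' @return a network object (list with \code{config}, \code{inputShape},
#'   \code{params}) consumed by [predictCaries()] and [trainNetwork()]
#' @export
buildNetwork <- function(config = networkConfig(), inputShape = c(96L, 64L, 64L)) {
  methods::validObject(config)
  inputShape <- as.integer(inputShape)
  L <- config@nLevels
  div <- 2L^(L - 1L)
  if (any(inputShape %% div != 0L))
    stop(sprintf("configuration error: input shape %s not divisible by %d per axis",
                 paste(inputShape, collapse = "x"), div))
  ch <- .netChannels(config)
  params <- list()
  he <- function(nIn, dims) array(stats::rnorm(prod(dims), 0, sqrt(2 / nIn)), dims)
  # convolutions feeding instance norm carry no bias (the norm removes it)
  addConv3 <- function(prefix, cin, cout) {
    params[[paste0(prefix, ".W")]] <<- he(cin * 27, c(cin * 27L, cout))
    params[[paste0(prefix, ".g")]] <<- rep(1, cout)
    params[[paste0(prefix, ".be")]] <<- numeric(cout)
  }
  .withSeed(config@seed, {
    for (l in seq_len(L))
      addConv3(sprintf("enc%d", l), if (l == 1L) 1L else ch[l], ch[l])
    for (l in seq_len(L - 1L))
      addConv3(sprintf("down%d", l), ch[l], ch[l + 1L])
    for (l in seq_len(L - 1L)) {
      addConv3(sprintf("dec%d.c1", l), ch[l] + ch[l + 1L], 2L * ch[l])
      # 1x1x1 halving the feature maps
      params[[sprintf("dec%d.W2", l)]] <- he(2 * ch[l], c(2L * ch[l], ch[l]))
      params[[sprintf("dec%d.g2", l)]] <- rep(1, ch[l])
      params[[sprintf("dec%d.be2", l)]] <- numeric(ch[l])
      if (config@attentionGates) {
        ci <- ch[l]
        params[[sprintf("att%d.Wx", l)]] <- he(ch[l], c(ch[l], ci))
        params[[sprintf("att%d.Wg", l)]] <- he(ch[l + 1L], c(ch[l + 1L], ci))
        params[[sprintf("att%d.b", l)]] <- numeric(ci)
        params[[sprintf("att%d.psi", l)]] <- he(ci, c(ci, 1L))
        params[[sprintf("att%d.bp", l)]] <- 0
      }
    }
    dsLevels <- if (config@deepSupervision) seq_len(L - 1L) else 1L
    for (l in dsLevels) {
      params[[sprintf("ds%d.W", l)]] <- he(ch[l], c(ch[l], 1L))
      params[[sprintf("ds%d.b", l)]] <- 0
    }
    params[["cls.W"]] <- he(ch[L], c(ch[L], 1L))
    params[["cls.b"]] <- 0
  })
  structure(list(config = config, inputShape = inputShape, params = params),
            class = "cariesNet")
}

#' @export
print.cariesNet <- function(x, ...) {
  cat(sprintf("attention 3D U-Net: %d levels, base %d channels, input %s, %d parameters\n",
              x$config@nLevels, x$config@baseChannels,
              paste(x$inputShape, collapse = "x"),
              sum(vapply(x$params, length, numeric(1)))))
  invisible(x)
}

# conv3 -> instance norm -> leaky ReLU
.blockFwd <- function(x, shape, params, prefix, slope, stride = 1L, training = FALSE) {
  cv <- .conv3Fwd(x, shape, params[[paste0(prefix, ".W")]],
                  numeric(ncol(params[[paste0(prefix, ".W")]])), stride, training)
  no <- .inormFwd(cv$y, params[[paste0(prefix, ".g")]],
                  params[[paste0(prefix, ".be")]], training = training)
  ac <- .lreluFwd(no$y, slope, training)
  list(y = ac$y, shape = cv$shape,
       cache = if (training) list(cv = cv$cache, no = no$cache, ac = ac$cache) else NULL)
}

.blockBwd <- function(dY, cache, params, prefix, slope, G) {
  dY <- .lreluBwd(dY, cache$ac, slope)
  nb <- .inormBwd(dY, cache$no, params[[paste0(prefix, ".g")]])
  .gAcc(G, paste0(prefix, ".g"), nb$dgamma)
  .gAcc(G, paste0(prefix, ".be"), nb$dbeta)
  cb <- .conv3Bwd(nb$dx, cache$cv, params[[paste0(prefix, ".W")]])
  .gAcc(G, paste0(prefix, ".W"), cb$dW)
  cb$dx
}

.gAcc <- function(G, name, val) {
  cur <- G$g[[name]]
  G$g[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

# additive attention gate forward (skip at level l, gate at level l+1)
.attFwd <- function(skip, skipShape, gate, params, l, slope, training = FALSE) {
  Wx <- params[[sprintf("att%d.Wx", l)]]
  Wg <- params[[sprintf("att%d.Wg", l)]]
  b <- params[[sprintf("att%d.b", l)]]
  psi <- params[[sprintf("att%d.psi", l)]]
  bp <- params[[sprintf("att%d.bp", l)]]
  ds <- .downNearestFwd(skip, skipShape)
  if (nrow(ds$y) != nrow(gate))
    stop("shape error: gating features do not match the down-sampled skip grid")
  A <- sweep(ds$y %*% Wx + gate %*% Wg, 2L, b, "+")
  R <- .lreluFwd(A, slope, training = TRUE)
  E <- as.vector(R$y %*% psi) + bp
  S <- .sigmoid(E)
  up <- .triUpFwd(S, skipShape %/% 2L)
  coef <- up$y
  out <- skip * coef
  list(y = out, coef = coef,
       cache = if (training) list(skip = skip, skipShape = skipShape, Xd = ds$y,
                                  R = R, E = E, S = S, coef = coef) else NULL)
}

.attBwd <- function(dY, cache, params, l, slope, G) {
  Wx <- params[[sprintf("att%d.Wx", l)]]
  Wg <- params[[sprintf("att%d.Wg", l)]]
  psi <- params[[sprintf("att%d.psi", l)]]
  skip <- cache$skip
  coef <- cache$coef
  dskipDirect <- dY * coef
  dcoef <- rowSums(dY * skip)
  gateShape <- cache$skipShape %/% 2L
  dS <- .triUpBwd(dcoef, gateShape)
  dE <- dS * cache$S * (1 - cache$S)
  .gAcc(G, sprintf("att%d.psi", l), crossprod(cache$R$y, dE))
  .gAcc(G, sprintf("att%d.bp", l), sum(dE))
  dR <- dE %*% t(psi)
  dA <- .lreluBwd(dR, cache$R$cache, slope)
  .gAcc(G, sprintf("att%d.Wx", l), crossprod(cache$Xd, dA))
  .gAcc(G, sprintf("att%d.Wg", l), crossprod(cache$gate, dA))
  .gAcc(G, sprintf("att%d.b", l), colSums(dA))
  dGate <- dA %*% t(Wg)
  dXd <- dA %*% t(Wx)
  dskipGate <- .downNearestBwd(dXd, cache$skipShape, nrow(skip))
  list(dskip = dskipDirect + dskipGate, dgate = dGate)
}

# full forward pass.  x: 3D array already intensity-normalised.
.netForward <- function(net, x, training = FALSE) {
  cfg <- net$config
  L <- cfg@nLevels
  slope <- cfg@leakySlope
  shape <- dim(x)
  X <- matrix(as.vector(x), ncol = 1L)
  xs <- vector("list", L); shapes <- vector("list", L)
  encC <- vector("list", L); downC <- vector("list", L)
  cur <- X; curShape <- shape
  for (l in seq_len(L)) {
    bl <- .blockFwd(cur, curShape, net$params, sprintf("enc%d", l), slope,
                    1L, training)
    xs[[l]] <- bl$y; shapes[[l]] <- curShape
    encC[[l]] <- bl$cache
    if (l < L) {
      dn <- .blockFwd(bl$y, curShape, net$params, sprintf("down%d", l), slope,
                      2L, training)
      cur <- dn$y; curShape <- dn$shape
      downC[[l]] <- dn$cache
    }
  }
  # decoder
  dFeat <- vector("list", L); dFeat[[L]] <- xs[[L]]
  decC <- vector("list", L); attC <- vector("list", L)
  coefRange <- NULL
  for (l in seq.int(L - 1L, 1L)) {
    up <- .upNearestFwd(dFeat[[l + 1L]], shapes[[l + 1L]], 2L)
    if (cfg@attentionGates) {
      at <- .attFwd(xs[[l]], shapes[[l]], dFeat[[l + 1L]], net$params, l,
                    slope, training)
      if (training) { at$cache$gate <- dFeat[[l + 1L]]; attC[[l]] <- at$cache }
      skipIn <- at$y
      coefRange <- range(c(coefRange, range(at$coef)))
    } else skipIn <- xs[[l]]
    cat_ <- cbind(up$y, skipIn)
    b1 <- .blockFwd(cat_, shapes[[l]], net$params, sprintf("dec%d.c1", l),
                    slope, 1L, training)
    c2 <- .conv1Fwd(b1$y, net$params[[sprintf("dec%d.W2", l)]],
                    numeric(ncol(net$params[[sprintf("dec%d.W2", l)]])), training)
    n2 <- .inormFwd(c2$y, net$params[[sprintf("dec%d.g2", l)]],
                    net$params[[sprintf("dec%d.be2", l)]], training = training)
    a2 <- .lreluFwd(n2$y, slope, training)
    dFeat[[l]] <- a2$y
    decC[[l]] <- if (training) list(b1 = b1$cache, c2 = c2$cache, n2 = n2$cache,
                                    a2 = a2$cache, nUp = ncol(up$y)) else NULL
  }
  # deep supervision: sum per-level 1-channel maps up-sampled to full resolution
  dsLevels <- if (cfg@deepSupervision) seq_len(L - 1L) else 1L
  logits <- numeric(prod(shape))
  dsC <- vector("list", L)
  for (l in dsLevels) {
    aux <- .conv1Fwd(dFeat[[l]], net$params[[sprintf("ds%d.W", l)]],
                     net$params[[sprintf("ds%d.b", l)]], training)
    v <- aux$y
    if (l > 1L) v <- .upNearestFwd(v, shapes[[l]], 2L^(l - 1L))$y
    logits <- logits + as.vector(v)
    dsC[[l]] <- if (training) aux$cache else NULL
  }
  # classification head on the bottleneck (deepest) features
  z <- colMeans(xs[[L]])
  clsLogit <- sum(z * net$params[["cls.W"]][, 1]) + net$params[["cls.b"]]
  out <- list(
    lesionProb = array(.sigmoid(logits), shape),
    toothProb = .sigmoid(clsLogit),
    logits = logits, clsLogit = clsLogit,
    coefRange = coefRange)
  if (training)
    out$caches <- list(encC = encC, downC = downC, decC = decC, attC = attC,
                       dsC = dsC, xs = xs, shapes = shapes, dFeat = dFeat,
                       dsLevels = dsLevels)
  out
}

# full backward pass: gradients of (dLogits, dCls) wrt every parameter.
.netBackward <- function(net, fw, dLogits, dCls) {
  cfg <- net$config
  L <- cfg@nLevels
  slope <- cfg@leakySlope
  cc <- fw$caches
  G <- new.env(parent = emptyenv()); G$g <- list()

  dD <- vector("list", L)    # gradient wrt decoder features per level
  for (l in cc$dsLevels) {
    v <- dLogits
    if (l > 1L) v <- .upNearestBwd(matrix(v, ncol = 1L), cc$shapes[[l]],
                                   2L^(l - 1L))[, 1]
    cb <- .conv1Bwd(matrix(v, ncol = 1L), cc$dsC[[l]],
                    net$params[[sprintf("ds%d.W", l)]])
    .gAcc(G, sprintf("ds%d.W", l), cb$dW)
    .gAcc(G, sprintf("ds%d.b", l), cb$db)
    dD[[l]] <- if (is.null(dD[[l]])) cb$dx else dD[[l]] + cb$dx
  }
  dXs <- vector("list", L)   # gradient wrt encoder outputs per level
  for (l in seq_len(L - 1L)) {
    dY <- dD[[l]]
    if (is.null(dY)) dY <- matrix(0, nrow(cc$dFeat[[l]]), ncol(cc$dFeat[[l]]))
    # decoder block backward: lrelu <- inorm <- conv1 <- block(conv3+in+lrelu)
    dY <- .lreluBwd(dY, cc$decC[[l]]$a2, slope)
    nb <- .inormBwd(dY, cc$decC[[l]]$n2, net$params[[sprintf("dec%d.g2", l)]])
    .gAcc(G, sprintf("dec%d.g2", l), nb$dgamma)
    .gAcc(G, sprintf("dec%d.be2", l), nb$dbeta)
    c2b <- .conv1Bwd(nb$dx, cc$decC[[l]]$c2, net$params[[sprintf("dec%d.W2", l)]])
    .gAcc(G, sprintf("dec%d.W2", l), c2b$dW)
    dCat <- .blockBwd(c2b$dx, cc$decC[[l]]$b1, net$params,
                      sprintf("dec%d.c1", l), slope, G)
    nUp <- cc$decC[[l]]$nUp
    dUp <- dCat[, seq_len(nUp), drop = FALSE]
    dSkipIn <- dCat[, nUp + seq_len(ncol(dCat) - nUp), drop = FALSE]
    dNext <- .upNearestBwd(dUp, cc$shapes[[l + 1L]], 2L)
    if (cfg@attentionGates) {
      ab <- .attBwd(dSkipIn, cc$attC[[l]], net$params, l, slope, G)
      dXs[[l]] <- if (is.null(dXs[[l]])) ab$dskip else dXs[[l]] + ab$dskip
      dNext <- dNext + ab$dgate
    } else {
      dXs[[l]] <- if (is.null(dXs[[l]])) dSkipIn else dXs[[l]] + dSkipIn
    }
    dD[[l + 1L]] <- if (is.null(dD[[l + 1L]])) dNext else dD[[l + 1L]] + dNext
  }
  # bottleneck: decoder feature L == encoder output L, plus classification head
  dXL <- dD[[L]]
  if (is.null(dXL)) dXL <- matrix(0, nrow(cc$xs[[L]]), ncol(cc$xs[[L]]))
  nVoxL <- nrow(cc$xs[[L]])
  z <- colMeans(cc$xs[[L]])
  .gAcc(G, "cls.W", matrix(dCls * z, ncol = 1L))
  .gAcc(G, "cls.b", dCls)
  dXL <- dXL + matrix(rep(dCls * net$params[["cls.W"]][, 1] / nVoxL, each = nVoxL),
                      nrow = nVoxL)
  dXs[[L]] <- if (is.null(dXs[[L]])) dXL else dXs[[L]] + dXL
  # encoder backward
  dPrev <- NULL
  for (l in seq.int(L, 1L)) {
    dY <- dXs[[l]]
    if (!is.null(dPrev)) dY <- dY + dPrev
    dIn <- .blockBwd(dY, cc$encC[[l]], net$params, sprintf("enc%d", l), slope, G)
    if (l > 1L) {
      dPrev <- .blockBwd(dIn, cc$downC[[l - 1L]], net$params,
                         sprintf("down%d", l - 1L), slope, G)
    }
  }
  G$g
}

#' Apply an additive attention gate to skip features
#'
#' Functional form of the gate used inside the network: the skip features are
#' scaled voxel-wise by a single scalar coefficient per spatial location
#' (broadcast over channels), each coefficient in [0, 1].  Gating features
#' must live on the 2x-coarser grid.  Weights may be supplied; otherwise they
#' are initialised deterministically from \code{seed}.
#'
#' @param skip 4D array (D, H, W, C) of skip features
#' @param gate 4D array (D/2, H/2, W/2, Cg) of gating features
#' @param weights optional list with Wx, Wg, b, psi, bp
#' @param leakySlope leaky ReLU slope (default 0.01)
#' @param seed seed for the default weight initialisation
#' @return list with \code{gated} (4D array like \code{skip}) and
#'   \code{coefficients} (3D array in [0, 1])
#' @export
attentionGate <- function(skip, gate, weights = NULL, leakySlope = 0.01, seed = 1L) {
  ds <- dim(skip); dg <- dim(gate)
  if (length(ds) != 4L || length(dg) != 4L)
    stop("skip and gate must be 4D arrays (D, H, W, C)")
  if (!all(ds[1:3] == 2L * dg[1:3]))
    stop("shape error: gate grid must be half the skip grid per axis")
  cS <- ds[4]; cG <- dg[4]
  if (is.null(weights)) {
    weights <- .withSeed(seed, list(
      Wx = array(stats::rnorm(cS * cS, 0, sqrt(2 / cS)), c(cS, cS)),
      Wg = array(stats::rnorm(cG * cS, 0, sqrt(2 / cG)), c(cG, cS)),
      b = numeric(cS), psi = array(stats::rnorm(cS, 0, sqrt(2 / cS)), c(cS, 1L)),
      bp = 0))
  }
  params <- list()
  params[["att1.Wx"]] <- weights$Wx; params[["att1.Wg"]] <- weights$Wg
  params[["att1.b"]] <- weights$b; params[["att1.psi"]] <- weights$psi
  params[["att1.bp"]] <- weights$bp
  skipM <- matrix(skip, ncol = cS)
  gateM <- matrix(gate, ncol = cG)
  at <- .attFwd(skipM, ds[1:3], gateM, params, 1L, leakySlope)
  list(gated = array(at$y, ds), coefficients = array(at$coef, ds[1:3]))
}

#' Normalise volume intensities for the network
#'
#' Per-sample z-scoring (zero mean, unit variance); constant volumes map to 0.
#'
#' @param x 3D numeric array or [VoxelVolume-class]
#' @return 3D array
#' @export
normalizeIntensities <- function(x) {
  if (methods::is(x, "VoxelVolume")) x <- x@data
  s <- stats::sd(as.vector(x))
  if (!is.finite(s) || s == 0) return(array(0, dim(x)))
  (x - mean(x)) / s
}

#' Predict caries voxels and tooth-level pathology for one tooth volume
#'
#' @param net a network from [buildNetwork()] or [trainNetwork()]
#' @param toothVolume a [VoxelVolume-class] in network input geometry
#' @return a [CariesPrediction-class]
#' @export
predictCaries <- function(net, toothVolume) {
  stopifnot(inherits(net, "cariesNet"))
  x <- normalizeIntensities(toothVolume)
  if (!all(dim(x) == net$inputShape))
    stop(sprintf("tooth volume shape %s does not match the network input %s",
                 paste(dim(x), collapse = "x"),
                 paste(net$inputShape, collapse = "x")))
  fw <- .netForward(net, x, training = FALSE)
  methods::new("CariesPrediction", lesionProb = fw$lesionProb,
               toothProb = fw$toothProb)
}

#' Save / load a network checkpoint
#'
#' Weights are serialised to a single RDS file with the [NetworkConfig-class]
#' written alongside as a JSON sidecar.
#'
#' @param net a network object
#' @param path checkpoint file (.rds)
#' @return the path (\code{saveNetwork}) or the network (\code{loadNetwork})
#' @export
saveNetwork <- function(net, path) {
  saveRDS(net, path)
  cfg <- net$config
  side <- list(nLevels = cfg@nLevels, baseChannels = cfg@baseChannels,
               leakySlope = cfg@leakySlope, deepSupervision = cfg@deepSupervision,
               attentionGates = cfg@attentionGates, learningRate = cfg@learningRate,
               batchSize = cfg@batchSize, seed = cfg@seed,
               inputShape = net$inputShape)
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "cariesNet"))
  net
}
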