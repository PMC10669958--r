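# Independent brute-force oracles and fixture builders used across the suite.
# These deliberately share no code with the package implementation.

# flood-fill connected components by breadth-first search over an explicit
# neighbour enumeration
oracleFloodFill <- function(arr, connectivity = 26) {
  d <- dim(arr)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  l1 <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[switch(as.character(connectivity),
                      "6" = l1 == 1, "18" = l1 <= 2, "26" = rep(TRUE, nrow(offs))), ]
  labels <- array(0L, d)
  nextLab <- 0L
  for (start in which(arr)) {
    if (labels[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    labels[start] <- nextLab
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      i <- (v - 1) %% d[1] + 1
      j <- ((v - 1) %/% d[1]) %% d[2] + 1
      k <- (v - 1) %/% (d[1] * d[2]) + 1
      for (r in seq_len(nrow(offs))) {
        ni <- i + offs$dx[r]; nj <- j + offs$dy[r]; nk <- k + offs$dz[r]
        if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3]) next
        nv <- ni + d[1] * (nj - 1) + d[1] * d[2] * (nk - 1)
        if (arr[nv] && labels[nv] == 0L) {
          labels[nv] <- nextLab
          queue <- c(queue, nv)
        }
      }
    }
  }
  labels
}

# same partition of foreground voxels, up to label permutation
samePartition <- function(lab1, lab2) {
  f1 <- lab1[lab1 > 0]; f2 <- lab2[lab2 > 0]
  if (length(f1) != length(f2)) return(FALSE)
  if (!all((lab1 > 0) == (lab2 > 0))) return(FALSE)
  length(unique(paste(f1, f2))) == length(unique(f1)) &&
    length(unique(f1)) == length(unique(f2))
}

# brute-force dilation: voxel is set iff any source voxel lies within the
# radius-r ball of the given connectivity metric
oracleDilate <- function(arr, radius, connectivity = 26) {
  d <- dim(arr)
  out <- array(FALSE, d)
  src <- which(arr, arr.ind = TRUE)
  if (nrow(src) == 0) return(out)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dx <- abs(src[, 1] - i); dy <- abs(src[, 2] - j); dz <- abs(src[, 3] - k)
    within <- switch(as.character(connectivity),
      "6" = (dx + dy + dz) <= radius,
      "18" = pmax(dx, dy, dz) <= radius & (dx + dy + dz) <= 2 * radius,
      "26" = pmax(dx, dy, dz) <= radius)
    if (any(within)) out[i, j, k] <- TRUE
  }
  out
}

# weighted kappa by explicit double sums over the k x k weight matrix
oracleWeightedKappa <- function(tab, q) {
  k <- nrow(tab); n <- sum(tab)
  num <- 0; den <- 0
  r <- rowSums(tab); cl <- colSums(tab)
  for (i in 1:k) for (j in 1:k) {
    v <- (abs(i - j) / (k - 1))^q
    num <- num + v * tab[i, j] / n
    den <- den + v * r[i] * cl[j] / n^2
  }
  unname(1 - num / den)
}

# Fleiss kappa by the textbook double sums
oracleFleiss <- function(counts) {
  n <- nrow(counts); m <- sum(counts[1, ])
  Pi <- numeric(n)
  for (i in 1:n) Pi[i] <- (sum(counts[i, ]^2) - m) / (m * (m - 1))
  pj <- colSums(counts) / (n * m)
  (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
}

# tie-corrected pairwise concordance AUC
oracleAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# published reader-study contingency counts shipped with the package
readerCounts <- function() {
  utils::read.csv(system.file("extdata", "reader-study-confusion.csv",
                              package = "cbctCaries"), check.names = FALSE)
}

readerDistribution <- function() {
  utils::read.csv(system.file("extdata", "reader-study-distribution.csv",
                              package = "cbctCaries"), check.names = FALSE)
}

# Build a full three-observer, two-arm rating table + ground truth whose
# per-observer confusion counts equal the published table.  Ground truth is
# fixed (first nPos surfaces are "presence"), which is consistent because
# TP+FN and TN+FP agree across all observer x arm rows.
makeStudyFixture <- function(counts = readerCounts()) {
  nPos <- counts$TP[1] + counts$FN[1]
  nNeg <- counts$TN[1] + counts$FP[1]
  n <- nPos + nNeg
  stopifnot(all(counts$TP + counts$FN == nPos), all(counts$TN + counts$FP == nNeg))
  caseId <- sprintf("s%05d", seq_len(n))
  gt <- data.frame(case_id = caseId, tooth_fdi = "36",
                   surface = "mesial",
                   label = rep(c("presence", "absence"), c(nPos, nNeg)),
                   provenance = "unanimous")
  rows <- lapply(seq_len(nrow(counts)), function(r) {
    call <- c(rep(c(TRUE, FALSE), c(counts$TP[r], counts$FN[r])),
              rep(c(TRUE, FALSE), c(counts$FP[r], counts$TN[r])))
    data.frame(case_id = caseId, tooth_fdi = "36", surface = "mesial",
               condition = "intact", observer_id = counts$observer[r],
               arm = counts$arm[r], score = ifelse(call, 5L, 1L), session = 1L)
  })
  list(ratings = do.call(rbind, rows), groundTruth = gt)
}

# small phantom sample for network training tests
makeTrainingSample <- function(seed, lesion = TRUE, volMm3 = 35) {
  les <- if (lesion)
    data.frame(tooth_fdi = "31",
               surface = if (seed %% 2 == 0) "mesial" else "distal",
               targetVolumeMm3 = volMm3) else NULL
  spec <- phantomSpec(gridShape = c(32L, 32L, 32L), spacingMm = 0.4, nTeeth = 1L,
                      crownSemiAxesMm = c(3, 2.8, 2.8), rootSemiAxesMm = c(4, 2, 2),
                      intensity = list(background = 0, dentin = 1, enamel = 1.6,
                                       lesionContrast = 0.7),
                      lesions = les, noiseSigma = 0.02, seed = seed)
  ph <- generatePhantom(spec)
  lm <- if (lesion) ph$lesionMasks[[1]]
        else BinaryMask(array(FALSE, c(32L, 32L, 32L)), 0.4)
  list(volume = ph$volume, lesionMask = lm, label = as.numeric(lesion),
       phantom = ph)
}

tinyNetConfig <- function(...) {
  networkConfig(nLevels = 3L, baseChannels = 2L, learningRate = 0.01, ...)
}
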