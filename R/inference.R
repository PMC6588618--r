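## Voxelwise two-sample inference with TFCE and max-statistic permutation
## FWE correction.

# pooled-variance two-sample t for a matrix of subjects x voxels; returns
# a vector, zero (and flagged) where the pooled variance vanishes
pooledT <- function(Y, idxA) {
  n <- nrow(Y)
  nA <- length(idxA)
  nB <- n - nA
  A <- Y[idxA, , drop = FALSE]
  B <- Y[-idxA, , drop = FALSE]
  mA <- colMeans(A)
  mB <- colMeans(B)
  ssA <- colSums(A^2) - nA * mA^2
  ssB <- colSums(B^2) - nB * mB^2
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  zero <- !is.finite(t)
  t[zero] <- 0
  attr(t, "zeroVariance") <- which(zero)
  t
}

#' Voxelwise pooled-variance two-sample t-map
#'
#' @param mapsA,mapsB 4-D arrays (X x Y x Z x N_A / N_B) of per-subject maps
#'   on a common grid.
#' @return 3-D t-map with sign convention A - B; voxels with zero pooled
#'   variance get t = 0 and are listed in the \code{zeroVariance} attribute.
#' @export
twoSampleTMap <- function(mapsA, mapsB) {
  dA <- dim(mapsA); dB <- dim(mapsB)
  if (length(dA) != 4L || length(dB) != 4L || !identical(dA[1:3], dB[1:3]))
    stop("mapsA and mapsB must be 4-D arrays on a common grid")
  if (dA[4] < 2L || dB[4] < 2L) stop("need at least 2 subjects per group")
  Y <- rbind(t(matrix(mapsA, ncol = dA[4])), t(matrix(mapsB, ncol = dB[4])))
  t <- pooledT(Y, seq_len(dA[4]))
  out <- array(as.numeric(t), dA[1:3])
  attr(out, "zeroVariance") <- attr(t, "zeroVariance")
  out
}

#' 3-D connected components
#'
#' Labels maximal connected components of a binary volume under 6-, 18- or
#' 26-connectivity, labels dense from 1.
#'
#' @param binary 3-D logical (or 0/1) array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return list with \code{labels} (integer array, 0 = background) and
#'   \code{sizes} (voxel count per label).
#' @export
connectedComponents <- function(binary, connectivity = 26L) {
  d <- dim(binary)
  if (length(d) != 3L) stop("binary must be a 3-D array")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  res <- cpp_label_components(as.logical(binary), as.integer(d),
                              as.integer(connectivity))
  list(labels = array(res$labels, d), sizes = res$sizes)
}

#' Threshold-free cluster enhancement
#'
#' TFCE(v) = sum over thresholds h = dh, 2dh, ..., max of
#' e(h, v)^E * h^H * dh, where dh = max / nSteps and e(h, v) is the voxel
#' count of the connected component containing v among voxels with value
#' >= h. Voxels with non-positive input get 0; the negative direction is
#' handled by enhancing the negated map.
#'
#' @param statmap 3-D numeric array (finite).
#' @param params a \linkS4class{TfceParams}.
#' @return 3-D array of TFCE values.
#' @export
tfceEnhance <- function(statmap, params = TfceParams()) {
  d <- dim(statmap)
  if (length(d) != 3L) stop("statmap must be a 3-D array")
  if (!all(is.finite(range(statmap))))
    stop("statmap contains non-finite values")
  out <- cpp_tfce(as.numeric(statmap), as.integer(d), params@E, params@H,
                  params@nSteps, params@connectivity)
  array(out, d)
}

# all distinct assignments of nA out of n subjects to group A, as a matrix
# with one index-set per column; only called when choose(n, nA) is small
enumerateRelabelings <- function(n, nA) {
  utils::combn(n, nA)
}

#' Max-statistic permutation FWE inference
#'
#' Two-sample group inference on per-subject maps: pooled-variance t-map,
#' TFCE enhancement of both contrast directions, and family-wise error
#' corrected p-values from the permutation distribution of the image-wide
#' maximum TFCE value. The unpermuted labeling is included as one sample of
#' the null, so p-values are bounded below by 1/nPerm. When the number of
#' distinct relabelings does not exceed \code{nPerm} they are enumerated
#' exhaustively (and the \code{exhaustive} flag set); otherwise
#' \code{nPerm - 1} random relabelings are drawn.
#'
#' @param subjectMaps 4-D array X x Y x Z x N of per-subject maps.
#' @param labels length-N factor or character vector with two levels; the
#'   contrast is (first level) - (second level).
#' @param params a \linkS4class{TfceParams}.
#' @param nPerm number of permutations (default 5000, minimum 100 unless
#'   exhaustive enumeration applies).
#' @param seed RNG seed for Monte-Carlo relabelings.
#' @return an \linkS4class{InferenceResult}.
#' @export
permutationFWE <- function(subjectMaps, labels, params = TfceParams(),
                           nPerm = 5000L, seed = 1L) {
  d <- dim(subjectMaps)
  if (length(d) != 4L) stop("subjectMaps must be a 4-D array")
  n <- d[4]
  if (n < 4L) stop("need at least 4 subjects")
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must match subject count")
  lev <- unique(labels)
  if (length(lev) != 2L) stop("exactly two group labels are required")
  nA <- sum(labels == lev[1])
  if (nA < 2L || n - nA < 2L)
    stop("need at least 2 subjects per group")
  nDistinct <- choose(n, nA)
  exhaustive <- nDistinct <= nPerm
  if (!exhaustive && nPerm < 100L)
    stop("nPerm must be >= 100 unless exhaustive enumeration applies")

  Y <- t(matrix(subjectMaps, ncol = n))          # N x V
  obsIdx <- which(labels == lev[1])
  dims3 <- d[1:3]

  tfceMax <- function(idxA) {
    t <- pooledT(Y, idxA)
    tf <- array(as.numeric(t), dims3)
    pos <- tfceEnhance(tf, params)
    neg <- tfceEnhance(-tf, params)
    list(t = tf, pos = pos, neg = neg,
         maxPos = max(pos), maxNeg = max(neg))
  }

  obs <- tfceMax(obsIdx)

  if (exhaustive) {
    combos <- enumerateRelabelings(n, nA)
    nPermUsed <- ncol(combos)
    maxPos <- numeric(nPermUsed)
    maxNeg <- numeric(nPermUsed)
    for (p in seq_len(nPermUsed)) {
      r <- tfceMax(combos[, p])
      maxPos[p] <- r$maxPos
      maxNeg[p] <- r$maxNeg
    }
  } else {
    set.seed(seed)
    nPermUsed <- as.integer(nPerm)
    maxPos <- numeric(nPermUsed)
    maxNeg <- numeric(nPermUsed)
    maxPos[1] <- obs$maxPos                     # observed labeling included
    maxNeg[1] <- obs$maxNeg
    for (p in 2:nPermUsed) {
      r <- tfceMax(sample(n, nA))
      maxPos[p] <- r$maxPos
      maxNeg[p] <- r$maxNeg
    }
  }

  # p(v) = #{null max >= TFCE_obs(v)} / nPerm, via sorted lookup
  pMap <- function(tfceObs, nullMax) {
    s <- sort(nullMax)
    v <- as.numeric(tfceObs)
    cnt <- length(s) - findInterval(v, s, left.open = TRUE)
    array(pmin(cnt / nPermUsed, 1), dims3)
  }

  new("InferenceResult", tmap = obs$t, tfcePos = obs$pos, tfceNeg = obs$neg,
      pfwePos = pMap(obs$pos, maxPos), pfweNeg = pMap(obs$neg, maxNeg),
      nPerm = as.integer(nPermUsed), seed = as.integer(seed),
      exhaustive = exhaustive)
}
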