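## Confound cleaning: band-pass, Friston-24 expansion, CompCor, regression,
## spatial smoothing.

#' Temporal band-pass filter
#'
#' Zero-phase band-pass filtering of BOLD time series. The default design is
#' a forward-backward (two-pass) Butterworth filter of order 2 per pass, with
#' odd-reflection padding and steady-state initial conditions so that edge
#' transients are small even at the low 0.01 Hz edge. An ideal FFT filter
#' (hard spectral window) is available as an alternative design.
#'
#' @param series numeric vector or T x V matrix; columns are voxel series.
#' @param trSec repetition time in seconds.
#' @param lowHz,highHz band edges in Hz (defaults 0.01 and 0.08).
#' @param method \code{"butterworth"} (default) or \code{"fft"}.
#' @param order Butterworth order per pass.
#' @return filtered series, same shape as the input. Columns are demeaned
#'   before filtering (the pass band excludes DC).
#' @export
bandpassFilter <- function(series, trSec, lowHz = 0.01, highHz = 0.08,
                           method = c("butterworth", "fft"), order = 2L) {
  method <- match.arg(method)
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, ncol = 1) else as.matrix(series)
  n <- nrow(x)
  if (n < 30L) stop("need at least 30 time points for band-pass filtering")
  if (!all(is.finite(range(x)))) stop("series contains non-finite values")
  fs <- 1 / trSec
  nyq <- fs / 2
  if (highHz >= nyq)
    stop(sprintf("highHz (%.4g Hz) must be below the Nyquist frequency %.4g Hz",
                 highHz, nyq))
  if (lowHz < 0 || lowHz >= highHz)
    stop("need 0 <= lowHz < highHz")
  x <- sweep(x, 2, colMeans(x))
  if (method == "fft") {
    freqs <- (seq_len(n) - 1) / (n * trSec)
    freqs <- pmin(freqs, fs - freqs)        # two-sided spectrum
    keep <- freqs >= lowHz & freqs <= highHz
    xf <- stats::mvfft(x)
    xf[!keep, ] <- 0
    out <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  } else {
    bw <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
    b <- bw$b / bw$a[1]
    a <- bw$a / bw$a[1]
    zi <- lfilterZi(b, a)
    padlen <- min(n - 1L, max(3L * (length(a) - 1L), 24L))
    out <- cpp_filtfilt(b, a, zi, x, as.integer(padlen))
  }
  if (vec) drop(out) else out
}

# steady-state initial filter state (scipy lfilter_zi): solve
# (I - A^T) zi = b[-1] - b[1]*a[-1] with A the companion matrix of a
lfilterZi <- function(b, a) {
  m <- length(a) - 1L
  A <- matrix(0, m, m)
  A[1, ] <- -a[-1]
  if (m > 1) A[cbind(2:m, 1:(m - 1))] <- 1
  B <- b[-1] - b[1] * a[-1]
  solve(diag(m) - t(A), B)
}

#' Friston-24 motion confound expansion
#'
#' Expands 6 rigid-body motion parameters into 24 regressors: the parameters,
#' their one-step backward temporal differences (first row zero), and the
#' element-wise squares of both sets. Columns are demeaned.
#'
#' @param motion6 T x 6 numeric matrix (3 rotations then 3 translations).
#' @return T x 24 matrix with unique column labels
#'   (\code{mot1..6, dmot1..6, mot1_sq.., dmot1_sq..}).
#' @export
buildFriston24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("motion6 must have 6 columns")
  if (nrow(motion6) < 2L) stop("motion6 must have at least 2 rows")
  bad <- which(!apply(motion6, 1, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite motion parameters in row(s): ",
         paste(bad, collapse = ", "))
  d <- rbind(0, diff(motion6))
  out <- cbind(motion6, d, motion6^2, d^2)
  colnames(out) <- c(paste0("mot", 1:6), paste0("dmot", 1:6),
                     paste0("mot", 1:6, "_sq"), paste0("dmot", 1:6, "_sq"))
  sweep(out, 2, colMeans(out))
}

#' CompCor nuisance components
#'
#' Top principal-component time-courses of tissue (white matter + CSF) voxel
#' time series, anatomical-CompCor style: columns are demeaned and scaled to
#' unit variance before the PCA, components are returned in decreasing
#' explained-variance order with unit norm, and each component's sign is
#' fixed so that its largest-magnitude voxel loading is positive.
#'
#' @param tissueSeries T x M matrix of voxel time series from the tissue
#'   masks.
#' @param nComponents number of components requested (default 5).
#' @param varNormalize scale each voxel series to unit variance first.
#' @return T x n matrix of unit-norm component time-courses with attributes
#'   \code{explainedVariance} (full spectrum, fractions) and, if fewer than
#'   \code{nComponents} are available, \code{rankWarning}.
#' @export
compCorComponents <- function(tissueSeries, nComponents = 5L,
                              varNormalize = TRUE) {
  X <- as.matrix(tissueSeries)
  if (nrow(X) < nComponents || ncol(X) < nComponents)
    stop("tissue series must have at least nComponents rows and columns")
  X <- sweep(X, 2, colMeans(X))
  if (varNormalize) {
    s <- sqrt(colMeans(X^2))
    nz <- s > 0
    X[, nz] <- sweep(X[, nz, drop = FALSE], 2, s[nz], "/")
  }
  sv <- svd(X)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  n <- min(nComponents, rank)
  comps <- sv$u[, seq_len(n), drop = FALSE]
  for (j in seq_len(n)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) comps[, j] <- -comps[, j]
  }
  colnames(comps) <- paste0("compcor", seq_len(n))
  attr(comps, "explainedVariance") <- sv$d^2 / sum(sv$d^2)
  if (n < nComponents) {
    w <- sprintf("tissue matrix rank %d < %d requested components", rank,
                 nComponents)
    warning(w)
    attr(comps, "rankWarning") <- w
  }
  comps
}

#' Regress confounds out of voxel time series
#'
#' Ordinary least-squares residualisation of every voxel series on an
#' intercept plus the confound columns. Rank deficiency is handled by a
#' pseudoinverse (SVD), so collinear confounds do not abort the run.
#'
#' @param series T x V matrix.
#' @param confounds T x C confound matrix (see \code{\link{buildFriston24}},
#'   \code{\link{compCorComponents}}).
#' @return T x V residual matrix, orthogonal to every confound column.
#' @export
regressConfounds <- function(series, confounds) {
  Y <- as.matrix(series)
  C <- as.matrix(confounds)
  if (nrow(Y) != nrow(C))
    stop(sprintf("row mismatch: series has %d rows, confounds %d",
                 nrow(Y), nrow(C)))
  X <- cbind(intercept = 1, C)
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-12
  # residual = y - X pinv(X) y, computed through the thin SVD
  U <- sv$u[, pos, drop = FALSE]
  Y - U %*% crossprod(U, Y)
}

#' Separable Gaussian spatial smoothing
#'
#' Convolves each frame of a 3-D or 4-D volume with a separable Gaussian of
#' the given FWHM, with sigma (in voxels) = fwhm / (voxel_size * sqrt(8 ln 2))
#' per axis. Boundary handling: \code{"renormalize"} truncates the kernel at
#' the volume edge and rescales it to unit sum (spatial means are preserved),
#' \code{"periodic"} wraps, \code{"zero"} pads with zeros.
#'
#' @param volume 3-D or 4-D numeric array (last dimension = time if 4-D).
#' @param fwhmMm kernel full width at half maximum in mm.
#' @param voxelSizeMm numeric(3) voxel edge lengths in mm.
#' @param boundary boundary mode.
#' @return smoothed array of the same shape.
#' @export
gaussianSmooth <- function(volume, fwhmMm, voxelSizeMm = c(2, 2, 2),
                           boundary = c("renormalize", "periodic", "zero")) {
  boundary <- match.arg(boundary)
  if (fwhmMm < 0 || any(voxelSizeMm <= 0))
    stop("fwhmMm must be >= 0 and voxel sizes positive")
  d <- dim(volume)
  if (!length(d) %in% c(3L, 4L)) stop("volume must be 3-D or 4-D")
  sigmas <- fwhmMm / (voxelSizeMm * sqrt(8 * log(2)))
  if (all(sigmas < 0.01)) return(volume)
  out <- volume
  for (ax in 1:3) {
    if (sigmas[ax] < 0.01) next
    K <- gaussKernelMatrix(d[ax], sigmas[ax], boundary)
    out <- applyAlongDim(out, K, ax)
  }
  out
}

# n x n 1-D convolution matrix for a Gaussian of sd sigma (voxels)
gaussKernelMatrix <- function(n, sigma, boundary) {
  r <- max(1L, ceiling(4 * sigma))
  w <- dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + (-r:r)
    if (boundary == "periodic") {
      j <- ((idx - 1) %% n) + 1
      for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + w[t]
    } else {
      keep <- idx >= 1 & idx <= n
      ww <- w[keep]
      if (boundary == "renormalize") ww <- ww / sum(ww)
      K[i, idx[keep]] <- K[i, idx[keep]] + ww
    }
  }
  K
}

# multiply matrix K along dimension ax of a 3-D/4-D array
applyAlongDim <- function(arr, K, ax) {
  d <- dim(arr)
  perm <- c(ax, setdiff(seq_along(d), ax))
  m <- matrix(aperm(arr, perm), nrow = d[ax])
  m <- K %*% m
  arr2 <- array(m, dim = d[perm])
  aperm(arr2, order(perm))
}

#' Clean one subject's 4-D BOLD run
#'
#' Applies the in-scope preprocessing chain: temporal band-pass, nuisance
#' regression (Friston-24 motion expansion plus CompCor tissue components),
#' and Gaussian spatial smoothing, in the configured order. Confound columns
#' are passed through the same band-pass filter before the regression by
#' default, so residuals stay orthogonal to the *filtered* confounds.
#'
#' @param bold 4-D numeric array X x Y x Z x T.
#' @param trSec repetition time in seconds.
#' @param motion6 T x 6 motion-parameter matrix, or NULL to skip.
#' @param wmMask,csfMask 3-D logical arrays for CompCor, or NULL to skip.
#' @param bandHz numeric(2) band edges (default \code{c(0.01, 0.08)}).
#' @param fwhmMm smoothing FWHM in mm (default 6; 0 disables).
#' @param nCompCor number of CompCor components (default 5).
#' @param voxelSizeMm numeric(3).
#' @param steps character vector giving the processing order; any ordering of
#'   \code{"bandpass"}, \code{"confound_regression"}, \code{"smoothing"}.
#' @param bandpassConfounds filter confounds with the same band-pass before
#'   regression (default TRUE).
#' @param filterMethod passed to \code{\link{bandpassFilter}}.
#' @return a \linkS4class{CleanedBold}.
#' @export
cleanBold <- function(bold, trSec, motion6 = NULL, wmMask = NULL,
                      csfMask = NULL, bandHz = c(0.01, 0.08), fwhmMm = 6,
                      nCompCor = 5L, voxelSizeMm = c(2, 2, 2),
                      steps = c("bandpass", "confound_regression",
                                "smoothing"),
                      bandpassConfounds = TRUE,
                      filterMethod = "butterworth") {
  d <- dim(bold)
  stopifnot(length(d) == 4L)
  nt <- d[4]
  Y <- matrix(bold, nrow = prod(d[1:3]), ncol = nt)
  Y <- t(Y)                                   # T x V

  confounds <- NULL
  if (!is.null(motion6)) confounds <- buildFriston24(motion6)
  if (!is.null(wmMask) || !is.null(csfMask)) {
    tiss <- (if (is.null(wmMask)) array(FALSE, d[1:3]) else wmMask) |
            (if (is.null(csfMask)) array(FALSE, d[1:3]) else csfMask)
    ts <- Y[, as.vector(tiss), drop = FALSE]
    cc <- compCorComponents(ts, nComponents = nCompCor)
    confounds <- if (is.null(confounds)) cc else cbind(confounds, cc)
  }

  applied <- character()
  bandpassed <- FALSE
  for (st in steps) {
    if (st == "bandpass") {
      Y <- bandpassFilter(Y, trSec, bandHz[1], bandHz[2],
                          method = filterMethod)
      bandpassed <- TRUE
      applied <- c(applied, "bandpass")
    } else if (st == "confound_regression") {
      if (!is.null(confounds)) {
        Cf <- confounds
        if (bandpassConfounds && bandpassed)
          Cf <- bandpassFilter(Cf, trSec, bandHz[1], bandHz[2],
                               method = filterMethod)
        Y <- regressConfounds(Y, Cf)
      } else {
        Y <- sweep(Y, 2, colMeans(Y))          # at least demean
      }
      applied <- c(applied, "confound_regression")
    } else if (st == "smoothing") {
      if (fwhmMm > 0) {
        vol <- array(t(Y), dim = d)
        vol <- gaussianSmooth(vol, fwhmMm, voxelSizeMm)
        Y <- t(matrix(vol, nrow = prod(d[1:3])))
      }
      applied <- c(applied, "smoothing")
    } else stop("unknown cleaning step: ", st)
  }

  new("CleanedBold", data = array(t(Y), dim = d), trSec = trSec,
      bandHz = bandHz, fwhmMm = fwhmMm, provenance = applied,
      voxelSizeMm = voxelSizeMm)
}
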