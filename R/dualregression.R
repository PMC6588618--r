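## Dual regression: spatial stage (per-frame fit on template maps) and
## temporal stage (per-voxel fit on the recovered time-courses).

#' Stage-1 dual regression: network time-courses
#'
#' For every time point, fits that frame's masked voxel vector on all K
#' spatially-demeaned template maps jointly (one multiple regression per
#' frame). Time-courses are demeaned and, by default, scaled to unit
#' variance (the usual dual-regression design normalisation).
#'
#' @param cleaned a \linkS4class{CleanedBold} or a 4-D array.
#' @param template a \linkS4class{NetworkTemplate}.
#' @param mask 3-D logical analysis mask; default: all voxels.
#' @param normalize scale each time-course to unit variance (default TRUE).
#' @return T x K matrix of time-courses.
#' @export
stage1Timecourses <- function(cleaned, template, mask = NULL,
                              normalize = TRUE) {
  dat <- if (is(cleaned, "CleanedBold")) cleaned@data else cleaned
  d <- dim(dat)
  k <- length(template)
  if (!identical(d[1:3], dim(templateMaps(template))[1:3]))
    stop("data grid does not match template grid")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mv <- as.vector(mask)
  if (!any(mv)) stop("analysis mask is empty")
  D <- matrix(templateMaps(template), ncol = k)[mv, , drop = FALSE]
  D <- sweep(D, 2, colMeans(D))
  qrD <- qr(D)
  if (qrD$rank < k) {
    sv <- svd(D)
    bad <- which(sv$d <= max(sv$d) * 1e-10)
    stop("template design is rank-deficient within the mask; ",
         "collinear component subspace of dimension ", length(bad))
  }
  Y <- matrix(dat, ncol = d[4])[mv, , drop = FALSE]    # V x T
  tc <- t(qr.coef(qrD, Y))                             # T x K
  tc <- sweep(tc, 2, colMeans(tc))
  if (normalize) {
    s <- apply(tc, 2, sd)
    s[s == 0] <- 1
    tc <- sweep(tc, 2, s, "/")
  }
  colnames(tc) <- paste0("comp", seq_len(k))
  tc
}

#' Stage-2 dual regression: noise-normalised FC maps
#'
#' Multiple regression of each voxel's time series on all K stage-1
#' time-courses jointly (plus an intercept); the stored value for component
#' k is beta_k / SE(beta_k), a t-like statistic on T - K - 1 degrees of
#' freedom, interpreted as the voxel's functional-connectivity Z-value.
#' Voxels with zero residual variance get value 0 and are listed in the
#' \code{qcZeroVariance} attribute.
#'
#' @param cleaned a \linkS4class{CleanedBold} or 4-D array.
#' @param timecourses T x K matrix from \code{\link{stage1Timecourses}}.
#' @param mask 3-D logical analysis mask; voxels outside get 0.
#' @param gaussianize convert t statistics to standard-normal quantiles by
#'   matching cumulative probabilities (default FALSE).
#' @return 4-D array X x Y x Z x K with attribute \code{qcZeroVariance}
#'   (linear indices of degenerate voxels) and \code{dof}.
#' @export
stage2ZMaps <- function(cleaned, timecourses, mask = NULL,
                        gaussianize = FALSE) {
  dat <- if (is(cleaned, "CleanedBold")) cleaned@data else cleaned
  d <- dim(dat)
  tc <- as.matrix(timecourses)
  nt <- nrow(tc); k <- ncol(tc)
  if (d[4] != nt) stop("time-course length does not match data")
  dof <- nt - k - 1
  if (dof <= 0) stop("need T > K + 1 for residual degrees of freedom")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mv <- as.vector(mask)
  X <- cbind(1, tc)
  qrX <- qr(X)
  Y <- t(matrix(dat, ncol = nt)[mv, , drop = FALSE])   # T x Vm
  B <- qr.coef(qrX, Y)                                 # (K+1) x Vm
  res <- Y - X %*% B
  s2 <- colSums(res^2) / dof
  XtXinv <- chol2inv(qr.R(qrX))
  # degenerate voxels: the model explains essentially all variance
  vy <- colSums(sweep(Y, 2, colMeans(Y))^2) / (nt - 1)
  zeroVar <- which(vy == 0 | s2 <= vy * 1e-12)
  zmapsM <- matrix(0, sum(mv), k)
  for (j in seq_len(k)) {
    se <- sqrt(s2 * XtXinv[j + 1, j + 1])
    zj <- B[j + 1, ] / se
    zj[se == 0 | !is.finite(zj)] <- 0
    zmapsM[, j] <- zj
  }
  zmapsM[zeroVar, ] <- 0
  if (gaussianize) {
    # map through matching tail probabilities, sign-split for stability
    zmapsM <- sign(zmapsM) *
      qnorm(pt(abs(zmapsM), dof, lower.tail = FALSE, log.p = TRUE),
            lower.tail = FALSE, log.p = TRUE)
  }
  zmaps <- array(0, dim = c(d[1:3], k))
  flat <- matrix(zmaps, ncol = k)
  flat[mv, ] <- zmapsM
  zmaps <- array(flat, dim = c(d[1:3], k))
  attr(zmaps, "qcZeroVariance") <- which(mv)[zeroVar]
  attr(zmaps, "dof") <- dof
  zmaps
}

#' Run both dual-regression stages for one subject
#'
#' @param cleaned a \linkS4class{CleanedBold} or 4-D array.
#' @param template a \linkS4class{NetworkTemplate}.
#' @param mask optional 3-D logical analysis mask.
#' @param subjectId identifier stored in the result.
#' @param normalize,gaussianize passed to the two stages.
#' @return a \linkS4class{SubjectNetworkMaps}.
#' @export
runDualRegression <- function(cleaned, template, mask = NULL,
                              subjectId = "subject", normalize = TRUE,
                              gaussianize = FALSE) {
  tc <- stage1Timecourses(cleaned, template, mask, normalize = normalize)
  zm <- stage2ZMaps(cleaned, tc, mask, gaussianize = gaussianize)
  new("SubjectNetworkMaps", subjectId = subjectId,
      zmaps = array(zm, dim(zm)), timecourses = tc,
      templateId = template@templateId, dof = attr(zm, "dof"))
}

#' Non-zero-variance analysis mask across subjects
#'
#' Intersection over subjects of the voxels whose time series have non-zero
#' variance; the default analysis mask of the pipeline.
#'
#' @param boldList list of 4-D arrays or \linkS4class{CleanedBold} objects.
#' @return 3-D logical array.
#' @export
analysisMask <- function(boldList) {
  stopifnot(length(boldList) >= 1)
  mk <- NULL
  for (b in boldList) {
    dat <- if (is(b, "CleanedBold")) b@data else b
    d <- dim(dat)
    v <- matrix(dat, ncol = d[4])
    vr <- rowSums((v - rowMeans(v))^2)
    m <- array(vr > 0, d[1:3])
    mk <- if (is.null(mk)) m else (mk & m)
  }
  mk
}
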