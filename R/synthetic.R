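## Synthetic cohort generator: template, 4-D BOLD, motion, tissue masks,
## questionnaire scores, all with recorded ground truth.

# questionnaire score distributions used by the generator: group means/SDs of
# the SRS (total + 5 factors) and SNAP-IV (hyperactivity, inattention, ODD)
# in an ASD / typically-developing adolescent cohort, with plausible
# instrument ranges used for clipping
scoreNorms <- function() {
  data.frame(
    score = c("srs_total", "srs_awareness", "srs_cognition",
              "srs_communication", "srs_motivation", "srs_mannerisms",
              "snap_hyperactivity", "snap_inattention", "snap_odd"),
    asd_mean = c(108.95, 12.14, 21.43, 38.67, 17.14, 19.57, 14.19, 7.00, 6.81),
    asd_sd   = c(27.78, 3.72, 5.27, 10.46, 5.54, 7.25, 6.58, 4.57, 4.57),
    td_mean  = c(40.5, 6.63, 7.84, 11.53, 9.05, 5.00, 6.21, 2.89, 6.00),
    td_sd    = c(22.03, 2.71, 4.14, 9.11, 4.87, 3.73, 4.33, 2.11, 4.22),
    min      = rep(0, 9),
    max      = c(195, 24, 36, 66, 33, 36, 27, 27, 24),
    stringsAsFactors = FALSE)
}

#' Names of the nine questionnaire scores
#' @return character(9): SRS total + 5 factors, SNAP hyperactivity,
#'   inattention, oppositional symptoms.
#' @export
scoreNames <- function() scoreNorms()$score

#' Build a synthetic K-component network template
#'
#' Places K Gaussian blobs (peak Z drawn from \code{peakRange}, spatial SD
#' from \code{sigmaRange} voxels) at distinct interior voxels of the grid and
#' adds N(0, backgroundSd) background, producing Z-valued maps in which every
#' component has a supra-threshold (Z > 4) support by construction.
#'
#' @param gridShape integer(3), each dimension >= 12.
#' @param k number of components (default 10).
#' @param seed RNG seed; output is deterministic given the seed.
#' @param voxelSizeMm numeric(3) (default 2 mm isotropic).
#' @param peakRange,sigmaRange ranges for blob peak height (Z units) and
#'   width (voxels).
#' @param backgroundSd SD of the Z-valued background noise.
#' @return a \linkS4class{NetworkTemplate}.
#' @export
makeTemplate <- function(gridShape = c(16, 16, 16), k = 10L, seed = 1L,
                         voxelSizeMm = c(2, 2, 2), peakRange = c(6, 10),
                         sigmaRange = c(1.5, 2.5), backgroundSd = 0.5) {
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 3L || any(gridShape < 12L))
    stop("each grid dimension must be at least 12 voxels")
  if (k < 1L) stop("k must be >= 1")
  margin <- 3L
  interior <- expand.grid(x = (margin + 1):(gridShape[1] - margin),
                          y = (margin + 1):(gridShape[2] - margin),
                          z = (margin + 1):(gridShape[3] - margin))
  if (nrow(interior) < k)
    stop(sprintf(
      "grid too small to place %d blobs: only %d interior voxels at margin %d",
      k, nrow(interior), margin))
  set.seed(seed)
  centers <- interior[sample(nrow(interior), k), , drop = FALSE]
  ax <- lapply(gridShape, seq_len)
  maps <- array(0, dim = c(gridShape, k))
  blobCenters <- vector("list", k)
  for (j in seq_len(k)) {
    ctr <- as.numeric(centers[j, ])
    blobCenters[[j]] <- as.integer(ctr)
    peak <- runif(1, peakRange[1], peakRange[2])
    sig <- runif(1, sigmaRange[1], sigmaRange[2])
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
                (ax[[3]] - ctr[3])^2, "+")
    maps[, , , j] <- peak * exp(-d2 / (2 * sig^2)) +
      rnorm(prod(gridShape), sd = backgroundSd)
  }
  new("NetworkTemplate", maps = maps, voxelSizeMm = voxelSizeMm,
      blobCenters = blobCenters,
      templateId = sprintf("synthetic-k%d-seed%d", k, seed))
}

#' Define the ground truth of a synthetic cohort
#'
#' Chooses the effect regions (a high-Z core of each selected component, so
#' every region is nested in that component's Z > 4 support), the group
#' amplitude difference, the temporal noise model, and the phenotype-score
#' loadings.
#'
#' @param template a \linkS4class{NetworkTemplate}.
#' @param components integer vector of components carrying a group effect
#'   (default 4).
#' @param directions +1 (\code{ASD > TD}) or -1 per component (default +1).
#' @param effectSize group amplitude difference inside the effect region, in
#'   noise-SD units (default 1.5); 0 gives a null cohort.
#' @param noiseSd marginal SD of the AR(1) voxel noise (default 1).
#' @param ar1Coef AR(1) coefficient (default 0.3).
#' @param subjectAmpSd between-subject amplitude SD, noise-SD units
#'   (default 0.5).
#' @param signalScale BOLD amplitude per unit template Z (default 0.15, so
#'   a template peak of Z 6-10 carries signal of roughly one noise SD —
#'   resting-state network signal does not dwarf the noise).
#' @param regionZ Z threshold defining the effect region core (default 5;
#'   must exceed 4 so regions stay inside the R-masks).
#' @param phenotypeLoadings data.frame(score, component, r) of target
#'   population correlations between scores and true biomarkers; default one
#'   row tying \code{srs_total} to the first effect component at r = -0.4.
#'   Pass a zero-row data.frame for a fully null phenotype.
#' @return a \linkS4class{GroundTruth}.
#' @export
makeGroundTruth <- function(template, components = 4L, directions = NULL,
                            effectSize = 1.5, noiseSd = 1, ar1Coef = 0.3,
                            subjectAmpSd = 0.5, signalScale = 0.15,
                            regionZ = 5, phenotypeLoadings = NULL) {
  if (regionZ <= 4) stop("regionZ must exceed the R-mask threshold of 4")
  k <- length(template)
  components <- as.integer(components)
  if (any(components < 1L | components > k))
    stop("effect components out of range")
  if (is.null(directions)) directions <- rep(1L, length(components))
  if (is.null(phenotypeLoadings)) {
    phenotypeLoadings <- data.frame(score = "srs_total",
                                    component = components[1], r = -0.4,
                                    stringsAsFactors = FALSE)
  }
  regions <- list()
  for (i in seq_along(components)) {
    cmp <- components[i]
    map <- templateMaps(template)[, , , cmp]
    idx <- which(map > regionZ)
    if (!length(idx))
      stop(sprintf("component %d has no voxels above regionZ = %g", cmp,
                   regionZ))
    regions[[as.character(cmp)]] <-
      if (directions[i] > 0) list(pos = idx, neg = integer())
      else list(pos = integer(), neg = idx)
  }
  new("GroundTruth", effectRegions = regions, effectSize = effectSize,
      noiseSd = noiseSd, ar1Coef = ar1Coef, subjectAmpSd = subjectAmpSd,
      signalScale = signalScale, phenotypeLoadings = phenotypeLoadings)
}

# band-limited unit-variance component time-courses
makeTimecourses <- function(tPoints, k, trSec) {
  W <- matrix(rnorm(tPoints * k), tPoints, k)
  W <- bandpassFilter(W, trSec, method = "fft")
  sw <- apply(W, 2, sd)
  sw[sw == 0] <- 1
  sweep(W, 2, sw, "/")
}

# AR(1) noise with marginal SD sdMarg; stationary start drawn directly
ar1Noise <- function(tPoints, nVox, phi, sdMarg) {
  x <- matrix(rnorm(tPoints * nVox, sd = sdMarg * sqrt(1 - phi^2)),
              tPoints, nVox)
  x[1, ] <- rnorm(nVox, sd = sdMarg)
  if (phi > 0)
    for (t in 2:tPoints) x[t, ] <- x[t, ] + phi * x[t - 1, ]
  x
}

#' Simulate a two-group synthetic cohort
#'
#' Each subject's BOLD is built as (spatial maps x band-limited time-courses)
#' plus AR(1) Gaussian noise. Inside each ground-truth effect region the
#' component map is amplitude-modulated: the ASD group's mean amplitude is
#' offset by \code{direction * effectSize * noiseSd}, and every subject gets
#' an individual amplitude factor (SD \code{subjectAmpSd}, centred within
#' each group so the realised group difference equals the nominal effect
#' exactly). Motion parameters are smooth random walks; white-matter and CSF
#' masks are carved from template background voxels; questionnaire scores
#' follow the generator's group norms, or, for scores with a phenotype
#' loading, are tuned to the requested population correlation with the true
#' biomarker.
#'
#' @param template a \linkS4class{NetworkTemplate}.
#' @param nPerGroup integer(2): subjects in (ASD, TD); both must be >= 2.
#' @param truth a \linkS4class{GroundTruth}; default
#'   \code{makeGroundTruth(template)}.
#' @param tPoints time points per subject (default 150, matching a 5-minute
#'   TR = 2 s acquisition; minimum 30). Note that the 0.01-0.08 Hz band of a
#'   T-point series carries only about 0.14 T temporal degrees of freedom,
#'   so short runs leave little room for the 29 nuisance regressors.
#' @param trSec repetition time in seconds (default 2).
#' @param seed RNG seed; cohorts are bit-identical given (parameters, seed).
#' @param noiseless set TRUE to regenerate the noise-free signal (AR noise
#'   and score noise off) for ground-truth checks.
#' @return list with elements \code{subjects} (list of
#'   \linkS4class{SyntheticSubject}), \code{truth} (with per-subject
#'   time-courses and true biomarkers filled in), \code{trSec}, \code{seed},
#'   and \code{nClippedScores}.
#' @export
simulateCohort <- function(template, nPerGroup = c(15, 15), truth = NULL,
                           tPoints = 150L, trSec = 2, seed = 1L,
                           noiseless = FALSE) {
  if (length(nPerGroup) != 2L || any(nPerGroup < 2L))
    stop("need at least 2 subjects per group (two-sample tests are undefined below that)")
  if (tPoints < 30L) stop("tPoints must be >= 30")
  if (is.null(truth)) truth <- makeGroundTruth(template)
  d <- dim(templateMaps(template))[1:3]
  k <- length(template)
  nVox <- prod(d)
  M0 <- matrix(templateMaps(template), nrow = nVox, ncol = k) *
    truth@signalScale

  set.seed(seed)
  n <- sum(nPerGroup)
  groups <- rep(c("ASD", "TD"), nPerGroup)
  ids <- sprintf("sub-%03d", seq_len(n))

  # per-subject amplitude offsets (noise-SD units), jitter centred per group
  amp <- matrix(0, n, k, dimnames = list(ids, paste0("comp", seq_len(k))))
  for (cname in names(truth@effectRegions)) {
    cmp <- as.integer(cname)
    er <- truth@effectRegions[[cname]]
    dir <- if (length(er$pos)) 1 else -1
    jit <- rnorm(n, sd = truth@subjectAmpSd)
    for (g in c("ASD", "TD")) {
      sel <- groups == g
      jit[sel] <- jit[sel] - mean(jit[sel])
    }
    amp[, cmp] <- (dir * truth@effectSize * (groups == "ASD") + jit) *
      truth@noiseSd
  }

  # tissue masks from template background (deterministic, disjoint)
  bg <- which(apply(abs(M0), 1, max) < 1.5 * truth@signalScale)
  if (length(bg) < 12L) bg <- order(apply(abs(M0), 1, max))[1:40]
  half <- floor(length(bg) / 2)
  wmIdx <- bg[seq_len(min(60L, half))]
  csfIdx <- bg[half + seq_len(min(60L, length(bg) - half))]
  wmMask <- array(FALSE, d); wmMask[wmIdx] <- TRUE
  csfMask <- array(FALSE, d); csfMask[csfIdx] <- TRUE

  norms <- scoreNorms()
  loads <- truth@phenotypeLoadings
  pA <- nPerGroup[1] / n

  subjects <- vector("list", n)
  tcs <- vector("list", n)
  for (i in seq_len(n)) {
    W <- makeTimecourses(tPoints, k, trSec)
    tcs[[i]] <- W
    M <- M0
    for (cname in names(truth@effectRegions)) {
      cmp <- as.integer(cname)
      er <- truth@effectRegions[[cname]]
      idx <- c(er$pos, er$neg)
      mRegion <- mean(M0[idx, cmp])
      M[idx, cmp] <- M0[idx, cmp] * (1 + amp[i, cmp] / mRegion)
    }
    sig <- W %*% t(M)                       # T x V
    if (!noiseless && truth@noiseSd > 0)
      sig <- sig + ar1Noise(tPoints, nVox, truth@ar1Coef, truth@noiseSd)
    bold <- array(t(sig), dim = c(d, tPoints))
    motion <- cbind(
      apply(matrix(rnorm(tPoints * 3, sd = 2e-3), tPoints, 3), 2, cumsum),
      apply(matrix(rnorm(tPoints * 3, sd = 5e-2), tPoints, 3), 2, cumsum))
    subjects[[i]] <- new("SyntheticSubject", subjectId = ids[i],
                         group = groups[i], bold = bold, motion6 = motion,
                         wmMask = wmMask, csfMask = csfMask,
                         scores = setNames(numeric(9), norms$score))
  }

  # questionnaire scores
  nClipped <- 0L
  scoreMat <- matrix(NA_real_, n, 9, dimnames = list(ids, norms$score))
  for (j in seq_len(9)) {
    nm <- norms$score[j]
    li <- if (nrow(loads)) which(loads$score == nm & loads$r != 0) else
      integer()
    if (length(li)) {
      cmp <- as.integer(loads$component[li[1]])
      r <- loads$r[li[1]]
      er <- truth@effectRegions[[as.character(cmp)]]
      dir <- if (!is.null(er) && length(er$pos)) 1 else -1
      muA <- dir * truth@effectSize * truth@noiseSd
      mPop <- pA * muA
      vPop <- (truth@subjectAmpSd * truth@noiseSd)^2 +
        pA * (1 - pA) * muA^2
      zb <- (amp[, cmp] - mPop) / sqrt(max(vPop, 1e-12))
      muPool <- pA * norms$asd_mean[j] + (1 - pA) * norms$td_mean[j]
      sdPool <- pA * norms$asd_sd[j] + (1 - pA) * norms$td_sd[j]
      eps <- if (noiseless) numeric(n) else rnorm(n)
      scoreMat[, j] <- muPool + sdPool * (r * zb + sqrt(1 - r^2) * eps)
    } else {
      mu <- ifelse(groups == "ASD", norms$asd_mean[j], norms$td_mean[j])
      sdv <- ifelse(groups == "ASD", norms$asd_sd[j], norms$td_sd[j])
      scoreMat[, j] <- mu + (if (noiseless) 0 else rnorm(n)) * sdv
    }
    clip <- pmin(pmax(scoreMat[, j], norms$min[j]), norms$max[j])
    nClipped <- nClipped + sum(clip != scoreMat[, j])
    scoreMat[, j] <- clip
  }
  for (i in seq_len(n))
    subjects[[i]]@scores <- setNames(scoreMat[i, ], norms$score)

  truth@timecourses <- tcs
  truth@trueBiomarkers <- amp
  list(subjects = subjects, truth = truth, trSec = trSec, seed = seed,
       nClippedScores = nClipped)
}

#' Write a cohort to disk as a fixture set
#'
#' One 4-D NIfTI per subject plus the template, tissue masks, motion text
#' files (T rows x 6 whitespace-separated columns), a phenotype CSV and a
#' JSON manifest. Images are written at double precision so a read-back
#' reproduces the arrays bit-exactly.
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param template the \linkS4class{NetworkTemplate} used.
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
writeFixtureSet <- function(cohort, template, outDir) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  wr <- function(arr, path) {
    ok <- try(RNifti::writeNifti(RNifti::asNifti(arr), path,
                                 datatype = "double"), silent = TRUE)
    if (inherits(ok, "try-error")) stop("failed to write ", path)
    path
  }
  tpl <- file.path(outDir, "template.nii.gz")
  wr(templateMaps(template), tpl)
  subj <- cohort$subjects
  entries <- lapply(subj, function(s) {
    base <- file.path(outDir, s@subjectId)
    bold <- wr(s@bold, paste0(base, "_bold.nii.gz"))
    wm <- wr(s@wmMask + 0L, paste0(base, "_wm.nii.gz"))
    csf <- wr(s@csfMask + 0L, paste0(base, "_csf.nii.gz"))
    mot <- paste0(base, "_motion.txt")
    utils::write.table(format(s@motion6, digits = 17), mot,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    list(subject_id = s@subjectId, group = s@group, bold = bold,
         motion = mot, wm_mask = wm, csf_mask = csf)
  })
  pheno <- data.frame(subject_id = vapply(subj, function(s) s@subjectId, ""),
                      group = vapply(subj, function(s) s@group, ""),
                      do.call(rbind, lapply(subj, function(s)
                        as.data.frame(as.list(s@scores)))),
                      stringsAsFactors = FALSE)
  phenoPath <- file.path(outDir, "phenotype.csv")
  utils::write.csv(pheno, phenoPath, row.names = FALSE)
  manifest <- list(seed = cohort$seed, tr_s = cohort$trSec,
                   voxel_size_mm = voxelSize(template),
                   n_asd = sum(pheno$group == "ASD"),
                   n_td = sum(pheno$group == "TD"),
                   n_clipped_scores = cohort$nClippedScores,
                   template = tpl, phenotype = phenoPath,
                   subjects = entries)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture set back from its manifest
#'
#' @param manifestPath path to a \code{manifest.json} written by
#'   \code{\link{writeFixtureSet}}.
#' @return list with \code{subjects}, \code{template}, \code{trSec},
#'   \code{seed}.
#' @export
readFixtureSet <- function(manifestPath) {
  man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  tplArr <- as.array(RNifti::readNifti(man$template))
  template <- new("NetworkTemplate", maps = array(tplArr, dim(tplArr)),
                  voxelSizeMm = as.numeric(man$voxel_size_mm),
                  templateId = "from-fixture")
  pheno <- utils::read.csv(man$phenotype, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(man$subjects)), function(i) {
    e <- man$subjects[i, ]
    bold <- as.array(RNifti::readNifti(e$bold))
    wm <- as.array(RNifti::readNifti(e$wm_mask)) > 0
    csf <- as.array(RNifti::readNifti(e$csf_mask)) > 0
    mot <- as.matrix(utils::read.table(e$motion))
    dimnames(mot) <- NULL
    row <- pheno[pheno$subject_id == e$subject_id, ]
    sc <- as.numeric(row[1, scoreNames()])
    new("SyntheticSubject", subjectId = e$subject_id, group = e$group,
        bold = array(bold, dim(bold)), motion6 = mot,
        wmMask = array(wm, dim(wm)), csfMask = array(csf, dim(csf)),
        scores = setNames(sc, scoreNames()))
  })
  list(subjects = subjects, template = template, trSec = man$tr_s,
       seed = man$seed)
}
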