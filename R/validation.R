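## Validation battery: group t-tests, Pearson correlations under BH-FDR,
## ROC/AUC, and a paired test for correlated AUCs.

#' Per-biomarker group difference table
#'
#' Two-sided two-sample t-test (pooled variance by default, Welch by
#' configuration) of every biomarker between the ASD and TD groups. Columns
#' with fewer than 2 non-missing values in either group (e.g. from empty
#' masks) are reported as missing rows without a test.
#'
#' @param bm a \linkS4class{BiomarkerMatrix}.
#' @param varEqual pooled-variance t (default TRUE); FALSE gives Welch.
#' @return data.frame with per-biomarker group means/SDs, t, p, and
#'   significance flags at 0.05 and 0.01.
#' @export
groupTTestTable <- function(bm, varEqual = TRUE) {
  vals <- biomarkerValues(bm)            # subjects x masks
  grp <- groupLabels(bm)
  if (!all(c("ASD", "TD") %in% grp))
    stop("both ASD and TD groups must be present")
  asd <- grp == "ASD"
  out <- data.frame(biomarker = colnames(vals),
                    n_td = NA_integer_, n_asd = NA_integer_,
                    mean_td = NA_real_, sd_td = NA_real_,
                    mean_asd = NA_real_, sd_asd = NA_real_,
                    t = NA_real_, p = NA_real_,
                    sig05 = FALSE, sig01 = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(vals))) {
    xA <- vals[asd, j]; xT <- vals[!asd, j]
    xA <- xA[is.finite(xA)]; xT <- xT[is.finite(xT)]
    out$n_asd[j] <- length(xA); out$n_td[j] <- length(xT)
    if (length(xA) < 2 || length(xT) < 2) next
    out$mean_asd[j] <- mean(xA); out$sd_asd[j] <- sd(xA)
    out$mean_td[j] <- mean(xT); out$sd_td[j] <- sd(xT)
    tt <- t.test(xA, xT, var.equal = varEqual)
    out$t[j] <- unname(tt$statistic)
    out$p[j] <- tt$p.value
    out$sig05[j] <- tt$p.value < 0.05
    out$sig01[j] <- tt$p.value < 0.01
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: with p-values sorted ascending,
#' adj_(i) = min over j >= i of (m/j) p_(j), capped at 1 and restored to the
#' input order. NA entries are passed through.
#'
#' @param pvalues numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhFDR <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Biomarker-questionnaire correlation table
#'
#' Pearson correlation (with two-sided p) between every biomarker and every
#' questionnaire metric, pairwise-complete, followed by BH-FDR adjustment.
#' By default all biomarker x metric cells are adjusted as a single family;
#' \code{family = "per_metric"} adjusts each metric's column separately.
#' Biomarkers that are entirely missing (empty masks) yield missing rows;
#' zero-variance pairs are recorded as missing cells.
#'
#' @param bm a \linkS4class{BiomarkerMatrix} whose colData carries the score
#'   columns.
#' @param metrics character vector of score column names (default the nine
#'   questionnaire scores).
#' @param family \code{"global"} (default) or \code{"per_metric"}.
#' @param alpha significance level for the flag matrix (default 0.05).
#' @return list of matrices (biomarkers x metrics): \code{r}, \code{p},
#'   \code{padj}, \code{sig}, \code{n}; plus the \code{family} used.
#' @export
pearsonCorrelations <- function(bm, metrics = scoreNames(),
                                family = c("global", "per_metric"),
                                alpha = 0.05) {
  family <- match.arg(family)
  vals <- biomarkerValues(bm)
  cd <- as.data.frame(SummarizedExperiment::colData(bm))
  missingMetrics <- setdiff(metrics, colnames(cd))
  if (length(missingMetrics))
    stop("metrics not present in colData: ",
         paste(missingMetrics, collapse = ", "))
  nb <- ncol(vals); nm <- length(metrics)
  dn <- list(colnames(vals), metrics)
  r <- p <- matrix(NA_real_, nb, nm, dimnames = dn)
  nMat <- matrix(0L, nb, nm, dimnames = dn)
  for (i in seq_len(nb)) {
    for (j in seq_len(nm)) {
      x <- vals[, i]; y <- cd[[metrics[j]]]
      keep <- is.finite(x) & is.finite(y)
      nMat[i, j] <- sum(keep)
      if (sum(keep) < 3) next
      if (sd(x[keep]) == 0 || sd(y[keep]) == 0) next
      ct <- cor.test(x[keep], y[keep], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  padj <- matrix(NA_real_, nb, nm, dimnames = dn)
  if (family == "global") {
    padj[] <- bhFDR(as.vector(p))
  } else {
    for (j in seq_len(nm)) padj[, j] <- bhFDR(p[, j])
  }
  sig <- !is.na(padj) & padj < alpha
  list(r = r, p = p, padj = padj, sig = sig, n = nMat, family = family)
}

# exact all-pairs AUC: P(pos > neg) + 0.5 P(tie), via the rank-sum identity
allPairsAuc <- function(pos, neg) {
  rk <- rank(c(pos, neg), ties.method = "average")
  n1 <- length(pos); n2 <- length(neg)
  (sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve and AUC for one biomarker
#'
#' The positive class is ASD. Markers whose hypothesized direction is
#' "positive class lower" (\code{direction = "less"}) have their scores
#' sign-flipped before the analysis, so a reported AUC above 0.5 always
#' corresponds to the hypothesized direction; the flip is recorded. The
#' curve is a threshold sweep over the unique scores (ties collapse into
#' single sweep points, giving tie-consistent trapezoids); the AUC is the
#' exact all-pairs statistic P(score_pos > score_neg) + 0.5 P(tie), which
#' equals the trapezoidal area under that curve.
#'
#' @param scores numeric vector of marker values.
#' @param labels group labels, same length.
#' @param positive label of the positive class (default \code{"ASD"}).
#' @param direction \code{"greater"} (default: positive class expected
#'   higher) or \code{"less"} (scores flipped).
#' @return list of class \code{"RocResult"}: \code{auc}, \code{curve}
#'   (data.frame \code{fpr}, \code{tpr}, \code{threshold}),
#'   \code{orientation}, \code{n}.
#' @export
rocAuc <- function(scores, labels, positive = "ASD",
                   direction = c("greater", "less")) {
  direction <- match.arg(direction)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.character(labels)[keep]
  isPos <- labels == positive
  if (!any(isPos) || all(isPos))
    stop("both classes must be non-empty")
  flipped <- direction == "less"
  s <- if (flipped) -scores else scores
  pos <- s[isPos]; neg <- s[!isPos]
  n1 <- length(pos); n2 <- length(neg)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(h) sum(pos >= h), numeric(1)) / n1)
  fpr <- c(0, vapply(thr, function(h) sum(neg >= h), numeric(1)) / n2)
  curve <- data.frame(fpr = fpr, tpr = tpr,
                      threshold = c(Inf, thr))
  structure(list(auc = allPairsAuc(pos, neg), curve = curve,
                 orientation = list(positive = positive, flipped = flipped),
                 n = c(pos = n1, neg = n2)),
            class = "RocResult")
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve data.frame with \code{fpr}, \code{tpr} columns as produced
#'   by \code{\link{rocAuc}}.
#' @return the trapezoid-rule area.
#' @export
trapezoidAuc <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  x <- curve$fpr[o]; y <- curve$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# DeLong placement values: for each positive score, its mean win rate over
# the negatives (ties count half), and vice versa
placementValues <- function(pos, neg) {
  v10 <- vapply(pos, function(x)
    mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(y)
    mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' Paired test for the difference of two correlated AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects. The
#' analytic mode is DeLong's placement-value (structural-components) test:
#' the variance of the AUC difference is estimated from the empirical
#' covariance of the two markers' placement values, and a two-sided normal
#' p-value is reported. The permutation mode swaps the two markers' scores
#' within randomly chosen subjects and compares the observed |AUC
#' difference| against the permutation distribution (observed swap pattern
#' included). Zero estimated variance (e.g. a marker compared with itself)
#' returns p = 1 with a degeneracy flag.
#'
#' @param scores1,scores2 numeric vectors of the two markers, same subjects.
#' @param labels group labels, same length.
#' @param positive positive class label (default \code{"ASD"}).
#' @param mode \code{"analytic"} (default) or \code{"permutation"}.
#' @param nPerm permutations for permutation mode (default 2000).
#' @param seed RNG seed for permutation mode.
#' @param direction1,direction2 hypothesized directions passed to
#'   \code{\link{rocAuc}}.
#' @return list: \code{auc1}, \code{auc2}, \code{aucDiff},
#'   \code{statistic}, \code{p.value}, \code{mode}, \code{degenerate}.
#' @export
pairedAucTest <- function(scores1, scores2, labels, positive = "ASD",
                          mode = c("analytic", "permutation"),
                          nPerm = 2000L, seed = 1L,
                          direction1 = "greater", direction2 = "greater") {
  mode <- match.arg(mode)
  stopifnot(length(scores1) == length(scores2),
            length(scores1) == length(labels))
  keep <- is.finite(scores1) & is.finite(scores2) & !is.na(labels)
  s1 <- scores1[keep]; s2 <- scores2[keep]
  labels <- as.character(labels)[keep]
  if (direction1 == "less") s1 <- -s1
  if (direction2 == "less") s2 <- -s2
  isPos <- labels == positive
  if (sum(isPos) < 3 || sum(!isPos) < 3)
    stop("need at least 3 subjects per group")
  auc1 <- allPairsAuc(s1[isPos], s1[!isPos])
  auc2 <- allPairsAuc(s2[isPos], s2[!isPos])
  diff <- auc1 - auc2

  if (mode == "analytic") {
    pl1 <- placementValues(s1[isPos], s1[!isPos])
    pl2 <- placementValues(s2[isPos], s2[!isPos])
    n1 <- sum(isPos); n2 <- sum(!isPos)
    s10 <- stats::cov(cbind(pl1$v10, pl2$v10))
    s01 <- stats::cov(cbind(pl1$v01, pl2$v01))
    varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
               (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n2
    if (varDiff <= 1e-14) {
      return(list(auc1 = auc1, auc2 = auc2, aucDiff = diff,
                  statistic = 0, p.value = 1, mode = mode,
                  degenerate = TRUE))
    }
    z <- diff / sqrt(varDiff)
    list(auc1 = auc1, auc2 = auc2, aucDiff = diff, statistic = z,
         p.value = 2 * pnorm(-abs(z)), mode = mode, degenerate = FALSE)
  } else {
    if (all(s1 == s2)) {
      return(list(auc1 = auc1, auc2 = auc2, aucDiff = diff,
                  statistic = 0, p.value = 1, mode = mode,
                  degenerate = TRUE))
    }
    set.seed(seed)
    n <- length(s1)
    absObs <- abs(diff)
    exceed <- 1L                               # observed pattern included
    for (p in seq_len(nPerm - 1L)) {
      sw <- runif(n) < 0.5
      a <- ifelse(sw, s2, s1)
      b <- ifelse(sw, s1, s2)
      d <- allPairsAuc(a[isPos], a[!isPos]) -
           allPairsAuc(b[isPos], b[!isPos])
      if (abs(d) >= absObs - 1e-12) exceed <- exceed + 1L
    }
    list(auc1 = auc1, auc2 = auc2, aucDiff = diff, statistic = diff,
         p.value = exceed / nPerm, mode = mode, degenerate = FALSE)
  }
}
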