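# build a small BiomarkerMatrix directly from given columns
bmFromValues <- function(vals, groups, scores = NULL) {
  n <- nrow(vals)
  ids <- sprintf("sub-%03d", seq_len(n))
  rownames(vals) <- ids
  d <- c(2, 2, 2)
  k <- ncol(vals)
  rm <- setNames(lapply(seq_len(k), function(i) {
    m <- array(FALSE, d); m[i] <- TRUE; m
  }), paste0("R", seq_len(k)))
  attr(rm, "volumesMm3") <- setNames(rep(8, k), names(rm))
  am <- setNames(lapply(seq_len(2 * k), function(i) array(FALSE, d)),
                 paste0("A", seq_len(2 * k)))
  ms <- makeMaskSet(rm, am)
  pheno <- data.frame(subject_id = ids, group = groups,
                      stringsAsFactors = FALSE)
  for (nm in scoreNames())
    pheno[[nm]] <- if (!is.null(scores) && nm %in% colnames(scores))
      scores[, nm] else rnorm(n)
  full <- cbind(vals,
                matrix(NA_real_, n, 2 * k,
                       dimnames = list(ids, paste0("A", seq_len(2 * k)))))
  colnames(full)[seq_len(k)] <- paste0("R", seq_len(k))
  lst <- lapply(ids, function(i) full[i, ])
  names(lst) <- ids
  assembleBiomarkerMatrix(lst, pheno, ms)
}

test_that("group t-test table matches the hand pooled formula", {
  set.seed(30)
  vals <- cbind(c(1, 2, 3, 4, 2, 3, 4, 5))
  colnames(vals) <- "b"
  groups <- rep(c("ASD", "TD"), each = 4)
  bm <- bmFromValues(vals, groups)
  tab <- groupTTestTable(bm)
  xA <- vals[1:4, 1]; xT <- vals[5:8, 1]
  sp2 <- (3 * var(xA) + 3 * var(xT)) / 6
  tHand <- (mean(xA) - mean(xT)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(tab$t[1], tHand, tolerance = 1e-12)
  expect_equal(tab$p[1], 2 * pt(-abs(tHand), 6), tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  bm0 <- bmFromValues(cbind(b = rep(c(1, 2, 3, 4), 2)), groups)
  tab0 <- groupTTestTable(bm0)
  expect_equal(tab0$t[1], 0)
  expect_equal(tab0$p[1], 1)
  # missing (empty-mask) biomarkers are reported but untested
  expect_true(all(is.na(tab$t[-1])))
  expect_true(all(!tab$sig05[-1]))
})

test_that("correlation table matches the hand formula and flags FDR", {
  vals <- cbind(b = c(1, 3, 2, 5, 4, 6))
  groups <- rep(c("ASD", "TD"), 3)
  sc <- matrix(NA_real_, 6, 2,
               dimnames = list(NULL, c("srs_total", "srs_awareness")))
  sc[, "srs_total"] <- c(1, 3, 2, 5, 4, 6)        # identical: r = 1
  sc[, "srs_awareness"] <- -c(1, 3, 2, 5, 4, 6)   # negated: r = -1
  bm <- bmFromValues(vals, groups, scores = sc)
  ct <- pearsonCorrelations(bm)
  expect_equal(ct$r["R1", "srs_total"], 1)
  expect_equal(ct$r["R1", "srs_awareness"], -1)
  # 6-point pair against covariance / sd product
  y <- as.numeric(SummarizedExperiment::colData(bm)$snap_odd)
  rHand <- cov(vals[, 1], y) / (sd(vals[, 1]) * sd(y))
  expect_equal(ct$r["R1", "snap_odd"], rHand, tolerance = 1e-12)
  # missing biomarkers give missing rows; adjusted >= raw
  expect_true(all(is.na(ct$r["A1", ])))
  ok <- !is.na(ct$p)
  expect_true(all(ct$padj[ok] >= ct$p[ok] - 1e-15))
  expect_equal(dim(ct$r), c(3, 9))        # R1, A1, A2 x nine metrics
})

test_that("zero-variance pairs are recorded as missing", {
  vals <- cbind(b = rep(2.5, 6))
  bm <- bmFromValues(vals, rep(c("ASD", "TD"), 3))
  ct <- pearsonCorrelations(bm)
  expect_true(all(is.na(ct$r["R1", ])))
})

test_that("BH-FDR reproduces the step-up hand computation", {
  expect_equal(bhFDR(0.37), 0.37)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
  # step-up definition on a worked example
  p <- c(0.005, 0.04, 0.03, 0.8)
  ps <- sort(p)
  adj <- sapply(seq_along(ps), function(i)
    min(pmin(1, length(ps) / seq_along(ps) * ps)[i:length(ps)]))
  expect_equal(sort(bhFDR(p)), adj)
})

test_that("BH-FDR is monotone and never creates significance", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    adj <- bhFDR(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    expect_true(all(which(adj < 0.05) %in% which(p < 0.05)))
  }
})

test_that("ROC analysis counts pairs exactly", {
  r <- rocAuc(c(3, 5, 1, 4), c("ASD", "ASD", "TD", "TD"))
  expect_equal(r$auc, 3 / 4)                    # exhaustive pair counting
  expect_s3_class(r, "RocResult")
  # perfectly separated and all-tied cases
  expect_equal(rocAuc(c(5, 6, 1, 2), rep(c("ASD", "TD"), each = 2))$auc, 1)
  expect_equal(rocAuc(rep(2, 6), rep(c("ASD", "TD"), 3))$auc, 0.5)
  # curve endpoints and monotonicity
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  # direction flip is recorded and reverses the AUC
  rf <- rocAuc(c(3, 5, 1, 4), c("ASD", "ASD", "TD", "TD"),
               direction = "less")
  expect_true(rf$orientation$flipped)
  expect_equal(rf$auc, 1 - r$auc)
  expect_error(rocAuc(c(1, 2), c("ASD", "ASD")), "non-empty")
})

test_that("trapezoid AUC, all-pairs AUC and pROC agree", {
  set.seed(32)
  for (i in 1:25) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    pool <- if (i %% 2) rnorm(40) else sample(1:4, 40, replace = TRUE)
    s <- c(sample(pool, n1, TRUE) + 0.5, sample(pool, n2, TRUE))
    lab <- rep(c("ASD", "TD"), c(n1, n2))
    r <- rocAuc(s, lab)
    expect_equal(trapezoidAuc(r$curve), r$auc, tolerance = 1e-12)
    expect_equal(r$auc, oracleAllPairsAuc(s[1:n1], s[-(1:n1)]),
                 tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      pr <- suppressMessages(pROC::auc(pROC::roc(
        response = lab, predictor = s, levels = c("TD", "ASD"),
        direction = "<", quiet = TRUE)))
      expect_equal(r$auc, as.numeric(pr), tolerance = 1e-12)
    }
  }
})

test_that("the paired AUC test matches the placement-value oracle", {
  set.seed(33)
  lab <- rep(c("ASD", "TD"), c(5, 5))
  s1 <- c(rnorm(5, 1.2), rnorm(5))
  s2 <- 0.6 * s1 + c(rnorm(5, 0.3), rnorm(5))
  mine <- pairedAucTest(s1, s2, lab)
  orac <- oracleDelong(s1, s2, lab == "ASD")
  expect_equal(mine$aucDiff, orac$aucDiff, tolerance = 1e-12)
  expect_equal(mine$statistic, orac$z, tolerance = 1e-10)
  expect_equal(mine$p.value, orac$p, tolerance = 1e-10)
  if (requireNamespace("pROC", quietly = TRUE)) {
    rt <- pROC::roc.test(
      pROC::roc(lab, s1, levels = c("TD", "ASD"), direction = "<",
                quiet = TRUE),
      pROC::roc(lab, s2, levels = c("TD", "ASD"), direction = "<",
                quiet = TRUE),
      method = "delong", paired = TRUE)
    expect_equal(mine$p.value, rt$p.value, tolerance = 1e-8)
  }
  # self-comparison is degenerate with p = 1
  self <- pairedAucTest(s1, s1, lab)
  expect_true(self$degenerate)
  expect_equal(self$p.value, 1)
  expect_equal(self$aucDiff, 0)
  selfP <- pairedAucTest(s1, s1, lab, mode = "permutation")
  expect_true(selfP$degenerate)
  expect_equal(selfP$p.value, 1)
})

test_that("reports render deterministically with correct flags", {
  set.seed(34)
  vals <- cbind(b = rnorm(10))
  bm <- bmFromValues(vals, rep(c("ASD", "TD"), 5))
  tt <- groupTTestTable(bm)
  ct <- pearsonCorrelations(bm)
  rocs <- list(R1 = rocAuc(vals[, 1], rep(c("ASD", "TD"), 5)))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  renderReports(tt, ct, rocs, out1)
  renderReports(tt, ct, rocs, out2)
  for (f in c("group_tests.csv", "correlations.csv", "roc_auc.csv")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # asterisks appear exactly where adjusted p < 0.05
  cc <- read.csv(file.path(out1, "correlations.csv"), check.names = FALSE)
  starred <- matrix(grepl("\\*$", as.matrix(cc[, -1])), nrow = nrow(ct$sig))
  expect_equal(starred, unname(ct$sig))
  # correlation table shape matches biomarkers x metrics
  expect_equal(dim(cc[, -1]), dim(ct$r))
})
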