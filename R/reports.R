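## Report rendering: CSV tables (3-decimal presentation + full-precision
## sidecars), a color-coded |r| matrix figure and ROC curve figures.

fmt3 <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 3))

#' Write validation reports
#'
#' Writes the group-difference table and the correlation table as CSVs at
#' 3-decimal presentation precision (with full-precision sidecars), an AUC
#' table, a color-coded |r| matrix figure and ROC curve figures. CSV output
#' is deterministic given the inputs.
#'
#' @param ttestTable output of \code{\link{groupTTestTable}}.
#' @param corTable output of \code{\link{pearsonCorrelations}}.
#' @param rocList named list of \code{RocResult} objects (may be NULL).
#' @param outDir output directory (created if needed).
#' @param figureFormat \code{"pdf"} (default) or \code{"png"}.
#' @return character vector of written paths, invisibly.
#' @export
renderReports <- function(ttestTable, corTable, rocList = NULL, outDir,
                          figureFormat = c("pdf", "png")) {
  figureFormat <- match.arg(figureFormat)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  paths <- character()
  wcsv <- function(df, name) {
    pth <- file.path(outDir, name)
    utils::write.csv(df, pth, row.names = FALSE)
    paths <<- c(paths, pth)
  }

  # group-difference table, presentation precision
  gt <- ttestTable
  pres <- data.frame(
    biomarker = gt$biomarker,
    td = ifelse(is.na(gt$mean_td), "-",
                paste0(fmt3(gt$mean_td), " ± ", fmt3(gt$sd_td))),
    asd = ifelse(is.na(gt$mean_asd), "-",
                 paste0(fmt3(gt$mean_asd), " ± ", fmt3(gt$sd_asd))),
    t = fmt3(gt$t), p = fmt3(gt$p),
    flag = ifelse(is.na(gt$p), "",
                  ifelse(gt$p < 0.01, "**", ifelse(gt$p < 0.05, "*", ""))),
    stringsAsFactors = FALSE)
  wcsv(pres, "group_tests.csv")
  wcsv(gt, "group_tests_full.csv")

  # correlation table with significance asterisks at adjusted p < 0.05
  rmat <- corTable$r
  starred <- matrix(paste0(fmt3(rmat),
                           ifelse(corTable$sig, "*", "")),
                    nrow = nrow(rmat), dimnames = dimnames(rmat))
  starred[is.na(rmat)] <- "-"
  wcsv(data.frame(biomarker = rownames(rmat), starred,
                  check.names = FALSE, stringsAsFactors = FALSE),
       "correlations.csv")
  wcsv(data.frame(biomarker = rownames(rmat), corTable$r,
                  check.names = FALSE), "correlations_r_full.csv")
  wcsv(data.frame(biomarker = rownames(rmat), corTable$padj,
                  check.names = FALSE), "correlations_padj_full.csv")

  if (!is.null(rocList) && length(rocList)) {
    aucDf <- data.frame(
      biomarker = names(rocList),
      auc = vapply(rocList, function(r) r$auc, numeric(1)),
      flipped = vapply(rocList, function(r) r$orientation$flipped,
                       logical(1)),
      n_pos = vapply(rocList, function(r) unname(r$n["pos"]), numeric(1)),
      n_neg = vapply(rocList, function(r) unname(r$n["neg"]), numeric(1)),
      stringsAsFactors = FALSE)
    wcsv(aucDf, "roc_auc.csv")
  }

  # figures; any device failure (e.g. headless png) is non-fatal
  openDev <- function(name, w, h) {
    pth <- file.path(outDir, paste0(name, ".", figureFormat))
    ok <- try({
      if (figureFormat == "pdf") grDevices::pdf(pth, width = w, height = h)
      else grDevices::png(pth, width = w * 96, height = h * 96)
    }, silent = TRUE)
    if (inherits(ok, "try-error")) return(NULL)
    paths <<- c(paths, pth)
    pth
  }
  if (!is.null(openDev("correlation_matrix", 7, 7))) {
    absr <- abs(rmat)
    graphics::image(seq_len(ncol(absr)), seq_len(nrow(absr)), t(absr),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                    main = "|Pearson r|, * adjusted p < 0.05")
    graphics::axis(1, seq_len(ncol(absr)), colnames(absr), las = 2,
                   cex.axis = 0.6)
    graphics::axis(2, seq_len(nrow(absr)), rownames(absr), las = 2,
                   cex.axis = 0.5)
    sigIdx <- which(corTable$sig, arr.ind = TRUE)
    if (nrow(sigIdx))
      graphics::text(sigIdx[, 2], sigIdx[, 1], "*", cex = 1.2)
    grDevices::dev.off()
  }
  if (!is.null(rocList) && length(rocList) &&
      !is.null(openDev("roc_curves", 6, 6))) {
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                   xlab = "False positive rate",
                   ylab = "True positive rate", main = "ROC curves")
    cols <- grDevices::hcl.colors(max(3, length(rocList)), "Dark 3")
    for (i in seq_along(rocList)) {
      cv <- rocList[[i]]$curve
      graphics::lines(cv$fpr, cv$tpr, col = cols[i], lwd = 2)
    }
    graphics::legend("bottomright",
                     legend = sprintf("%s (AUC %.3f)", names(rocList),
                                      vapply(rocList, function(r) r$auc,
                                             numeric(1))),
                     col = cols[seq_along(rocList)], lwd = 2, cex = 0.7)
    grDevices::dev.off()
  }
  invisible(paths)
}
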