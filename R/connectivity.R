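## From per-domain ROI time series to correlation matrices: subject
## inclusion by scrubbing, run concatenation, task regression, Pearson
## correlation with explicit diagonal convention, signed decomposition.

#' Filter subjects by per-domain scrubbing fraction
#'
#' Retains subjects whose motion-scrubbing fraction is strictly below
#' \code{maxFraction} in every domain (the study's inclusion criterion: a
#' subject at or above the bound in any single domain is excluded).
#'
#' @param manifest Subject manifest with \code{scrub_<domain>} columns.
#' @param maxFraction Exclusion bound (default 0.30).
#' @param domains Domain names (default the four analysis domains).
#' @return List with \code{included} (character subject ids),
#'   \code{excluded} (data.frame subject_id, reason).
#' @export
filterSubjectsByScrubbing <- function(manifest, maxFraction = 0.30,
                                      domains = analysisDomains()) {
  cols <- paste0("scrub_", domains)
  missing <- setdiff(cols, names(manifest))
  if (length(missing))
    stop("manifest lacks scrub column(s): ", paste(missing, collapse = ", "))
  scrub <- as.matrix(manifest[, cols, drop = FALSE])
  ok <- apply(scrub < maxFraction, 1L, all)
  bad <- which(!ok)
  excluded <- data.frame(
    subject_id = manifest$subject_id[bad],
    reason = vapply(bad, function(i) {
      d <- domains[scrub[i, ] >= maxFraction]
      sprintf("scrub >= %.2f in %s", maxFraction, paste(d, collapse = ","))
    }, character(1)),
    stringsAsFactors = FALSE)
  list(included = manifest$subject_id[ok], excluded = excluded)
}

#' Concatenate task-run time series into one domain matrix
#'
#' Row-wise concatenation in the order given; all parts must share the ROI
#' columns (count and order).
#'
#' @param tsList List of volumes-by-ROIs matrices.
#' @return Single matrix with \code{sum(rows)} rows.
#' @export
concatenateDomain <- function(tsList) {
  if (!length(tsList)) stop("no time-series parts to concatenate")
  nc <- vapply(tsList, ncol, integer(1))
  if (length(unique(nc)) > 1L)
    stop("ROI column count differs across parts")
  cn <- lapply(tsList, colnames)
  if (!all(vapply(cn, identical, logical(1), y = cn[[1]])))
    stop("ROI column order differs across parts")
  do.call(rbind, tsList)
}

#' Regress the task design out of every ROI time series
#'
#' Replaces each ROI column by its least-squares residual against the task
#' design (an intercept is always included), removing block-evoked task
#' variance before correlation.
#'
#' @param ts Volumes-by-ROIs matrix.
#' @param design Volumes-by-regressors task design (see
#'   [domainTaskDesign()]); no intercept column needed.
#' @return Residual matrix, same shape and dimnames as \code{ts}.
#' @export
regressOutTask <- function(ts, design) {
  design <- as.matrix(design)
  if (nrow(design) != nrow(ts))
    stop("design rows (", nrow(design), ") must match time-series rows (",
         nrow(ts), ")")
  X <- cbind(intercept = 1, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("task design is rank deficient after adding the intercept")
  res <- qr.resid(qrX, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Pearson correlation matrix over ROI time series
#'
#' Correlates every ROI pair over time and applies the diagonal
#' convention: zero for graph analyses, missing for averaging analyses.
#' Constant (zero-variance) ROI columns yield missing correlations with a
#' warning rather than an error.
#'
#' @param ts Residualized volumes-by-ROIs matrix (at least 3 rows),
#'   columns named by roi_id.
#' @param diagonalMode \code{"missing"} (default) or \code{"zero"}.
#' @param domain,subjectId Optional labels stored on the result.
#' @return A [ConnectivityMatrix-class].
#' @export
correlationMatrix <- function(ts, diagonalMode = c("missing", "zero"),
                              domain = NA_character_,
                              subjectId = NA_character_) {
  diagonalMode <- match.arg(diagonalMode)
  if (nrow(ts) < 3L)
    stop("need at least 3 volumes to estimate correlations")
  sds <- apply(ts, 2L, sd)
  constant <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(ts))
  if (any(constant)) {
    warning(sum(constant), " constant ROI column(s); their correlations ",
            "set to missing")
    r[constant, ] <- NA_real_
    r[, constant] <- NA_real_
  }
  r <- (r + t(r)) / 2          # enforce exact symmetry
  r[r > 1] <- 1; r[r < -1] <- -1
  if (diagonalMode == "zero") diag(r) <- 0 else diag(r) <- NA_real_
  new("ConnectivityMatrix", values = r, diagonalMode = diagonalMode,
      domain = as.character(domain), subjectId = as.character(subjectId))
}

#' Split a connectivity matrix by correlation sign
#'
#' Positive matrix keeps r > 0 (others missing); negative matrix keeps
#' r < 0.  Exact zeros carry no sign and are missing in both.
#'
#' @param cm A [ConnectivityMatrix-class].
#' @return List with elements \code{positive} and \code{negative}, both
#'   [ConnectivityMatrix-class] with missing diagonal.
#' @export
splitPosNeg <- function(cm) {
  v <- cmValues(cm)
  diag(v) <- NA_real_
  pos <- v; pos[!is.na(pos) & pos <= 0] <- NA_real_
  neg <- v; neg[!is.na(neg) & neg >= 0] <- NA_real_
  list(positive = new("ConnectivityMatrix", values = pos,
                      diagonalMode = "missing", domain = cm@domain,
                      subjectId = cm@subjectId),
       negative = new("ConnectivityMatrix", values = neg,
                      diagonalMode = "missing", domain = cm@domain,
                      subjectId = cm@subjectId))
}

#' Switch the diagonal convention of a connectivity matrix
#'
#' @param cm A [ConnectivityMatrix-class].
#' @param diagonalMode \code{"zero"} or \code{"missing"}.
#' @return The matrix with the requested diagonal convention.
#' @export
setDiagonalMode <- function(cm, diagonalMode = c("zero", "missing")) {
  diagonalMode <- match.arg(diagonalMode)
  v <- cmValues(cm)
  if (diagonalMode == "zero") diag(v) <- 0 else diag(v) <- NA_real_
  new("ConnectivityMatrix", values = v, diagonalMode = diagonalMode,
      domain = cm@domain, subjectId = cm@subjectId)
}

#' Write / read a connectivity matrix
#'
#' Delimited square numeric table with a roi_id header row and column;
#' missing values encoded as \code{NA}.
#'
#' @param cm A [ConnectivityMatrix-class].
#' @param path File path.
#' @param diagonalMode,domain,subjectId Metadata restored on read.
#' @return \code{writeConnectivityMatrix}: the path, invisibly;
#'   \code{readConnectivityMatrix}: a [ConnectivityMatrix-class].
#' @export
writeConnectivityMatrix <- function(cm, path) {
  write.table(cmValues(cm), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname writeConnectivityMatrix
#' @export
readConnectivityMatrix <- function(path, diagonalMode = c("missing", "zero"),
                                   domain = NA_character_,
                                   subjectId = NA_character_) {
  diagonalMode <- match.arg(diagonalMode)
  tab <- read.table(path, header = TRUE, row.names = 1, check.names = FALSE)
  v <- as.matrix(tab)
  if (diagonalMode == "zero") diag(v) <- 0 else diag(v) <- NA_real_
  new("ConnectivityMatrix", values = v, diagonalMode = diagonalMode,
      domain = as.character(domain), subjectId = as.character(subjectId))
}

#' Full per-subject connectivity step
#'
#' Convenience wrapper: for each domain of a subject's time-series set,
#' regress out the task design and correlate, returning one
#' [ConnectivityMatrix-class] per domain (missing diagonal).
#'
#' @param tss A [ROITimeSeriesSet-class].
#' @param designs Named list of task design matrices, one per domain
#'   (omit for correlation on the raw series).
#' @return Named list of [ConnectivityMatrix-class] objects.
#' @export
subjectConnectivity <- function(tss, designs = NULL) {
  out <- list()
  for (d in names(tss@series)) {
    ts <- tss@series[[d]]
    if (!is.null(designs) && !is.null(designs[[d]]))
      ts <- regressOutTask(ts, designs[[d]])
    out[[d]] <- correlationMatrix(ts, diagonalMode = "missing",
                                  domain = d, subjectId = subjectId(tss))
  }
  out
}
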