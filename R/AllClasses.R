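## S4 data model: parcellation, per-subject time series, connectivity matrix.

#' NetworkParcellation: ROI definitions with network membership
#'
#' Holds an ordered ROI table (id, MNI centre in mm, network label), the
#' closed vocabulary of analysed network names, and the set of ROI ids
#' removed by filters (e.g. the centre-proximity exclusion).  ROI order is
#' fixed at load time and shared by every time series and connectivity
#' matrix derived from the parcellation.
#'
#' @slot rois data.frame with columns \code{roi_id}, \code{x}, \code{y},
#'   \code{z}, \code{network}; one row per ROI, input order preserved.
#'   Labels outside the network vocabulary are \code{"unassigned"}.
#' @slot networks character; the ordered vocabulary of analysed networks.
#' @slot excludedIds integer; roi_ids removed by filters.
#'
#' @seealso [loadParcellation()], [powerLikeParcellation()],
#'   [applyProximityExclusion()]
#' @export
setClass("NetworkParcellation",
         representation(rois = "data.frame",
                        networks = "character",
                        excludedIds = "integer"))

setValidity("NetworkParcellation", function(object) {
  req <- c("roi_id", "x", "y", "z", "network")
  if (!all(req %in% names(object@rois)))
    return(sprintf("rois must have columns %s", paste(req, collapse = ", ")))
  if (anyDuplicated(object@rois$roi_id))
    return("duplicate roi_id in parcellation")
  if (!all(object@rois$network %in% c(object@networks, "unassigned")))
    return("network labels outside the declared vocabulary")
  if (!is.numeric(object@rois$x) || !is.numeric(object@rois$y) ||
      !is.numeric(object@rois$z))
    return("coordinates must be numeric")
  if (!all(object@excludedIds %in% object@rois$roi_id))
    return("excludedIds contains unknown roi_id")
  TRUE
})

#' ROITimeSeriesSet: one subject's per-domain ROI time series
#'
#' @slot subjectId character scalar.
#' @slot series named list of numeric matrices (volumes x ROIs), one per
#'   domain; columns named by roi_id in parcellation order.
#'
#' @export
setClass("ROITimeSeriesSet",
         representation(subjectId = "character", series = "list"))

setValidity("ROITimeSeriesSet", function(object) {
  if (length(object@subjectId) != 1L) return("subjectId must be scalar")
  if (length(object@series)) {
    ok <- vapply(object@series, function(m)
      is.matrix(m) && is.numeric(m) && !anyNA(m), logical(1))
    if (!all(ok)) return("series must be numeric matrices without NA")
    nc <- vapply(object@series, ncol, integer(1))
    if (length(unique(nc)) > 1L)
      return("all domains must share the ROI column count")
  }
  TRUE
})

#' ConnectivityMatrix: symmetric ROI-by-ROI Pearson correlations
#'
#' Square symmetric matrix of Pearson correlations between ROI time series,
#' with an explicit diagonal convention: \code{"zero"} (graph analyses) or
#' \code{"missing"} (averaging analyses).
#'
#' @slot values numeric matrix, dimnames = roi_ids in parcellation order.
#' @slot diagonalMode \code{"zero"} or \code{"missing"}.
#' @slot domain domain label (may be \code{NA}).
#' @slot subjectId subject label (may be \code{NA}).
#'
#' @export
setClass("ConnectivityMatrix",
         representation(values = "matrix", diagonalMode = "character",
                        domain = "character", subjectId = "character"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (!identical(rownames(v), colnames(v)))
    return("row and column roi order must agree")
  d <- v - t(v)
  if (any(abs(d[!is.na(d)]) > 1e-12)) return("matrix must be symmetric")
  off <- v[row(v) != col(v)]
  off <- off[!is.na(off)]
  if (length(off) && (max(off) > 1 + 1e-12 || min(off) < -1 - 1e-12))
    return("off-diagonal correlations must lie in [-1, 1]")
  if (!object@diagonalMode %in% c("zero", "missing"))
    return("diagonalMode must be 'zero' or 'missing'")
  dg <- diag(v)
  if (object@diagonalMode == "zero" && (anyNA(dg) || any(dg != 0)))
    return("diagonal must be all zero under diagonalMode 'zero'")
  if (object@diagonalMode == "missing" && !all(is.na(dg)))
    return("diagonal must be all missing under diagonalMode 'missing'")
  TRUE
})

## Accessors ----------------------------------------------------------------

#' @describeIn NetworkParcellation full ROI table (all rows, input order).
#' @param x,object A \code{NetworkParcellation}.
#' @export
setMethod("roiTable", "NetworkParcellation", function(x, ...) x@rois)

#' @describeIn NetworkParcellation ROI table restricted to surviving
#'   (non-excluded) ROIs; with \code{assignedOnly = TRUE} also drops
#'   \code{"unassigned"} ROIs.  Input order is preserved.
#' @param assignedOnly logical; drop unassigned ROIs too.
#' @param ... unused.
#' @export
setMethod("survivingRois", "NetworkParcellation",
          function(x, assignedOnly = FALSE, ...) {
  keep <- !(x@rois$roi_id %in% x@excludedIds)
  if (assignedOnly) keep <- keep & x@rois$network != "unassigned"
  x@rois[keep, , drop = FALSE]
})

#' @describeIn NetworkParcellation the ordered network vocabulary.
#' @export
setMethod("networkNames", "NetworkParcellation", function(x) x@networks)

#' @describeIn NetworkParcellation roi_ids removed by filters.
#' @export
setMethod("excludedIds", "NetworkParcellation", function(x) x@excludedIds)

#' @describeIn NetworkParcellation surviving ROI count per network
#'   (named integer vector over the network vocabulary).
#' @export
setMethod("networkCounts", "NetworkParcellation", function(x, ...) {
  s <- survivingRois(x, assignedOnly = TRUE)
  cnt <- table(factor(s$network, levels = x@networks))
  setNames(as.integer(cnt), x@networks)
})

setMethod("show", "NetworkParcellation", function(object) {
  s <- survivingRois(object, assignedOnly = TRUE)
  cat(sprintf("NetworkParcellation: %d ROIs (%d assigned surviving, %d excluded)\n",
              nrow(object@rois), nrow(s), length(object@excludedIds)))
  cnt <- networkCounts(object)
  cat("  ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "), "\n")
})

#' @describeIn ROITimeSeriesSet subject label.
#' @param x,object A \code{ROITimeSeriesSet}.
#' @export
setMethod("subjectId", "ROITimeSeriesSet", function(x) x@subjectId)

#' @describeIn ROITimeSeriesSet the volumes-by-ROIs matrix for one domain.
#' @param domain Domain name.
#' @export
setMethod("domainSeries", "ROITimeSeriesSet", function(x, domain) {
  if (!domain %in% names(x@series))
    stop("no series for domain '", domain, "'")
  x@series[[domain]]
})

setMethod("show", "ROITimeSeriesSet", function(object) {
  dims <- vapply(object@series, function(m)
    sprintf("%dx%d", nrow(m), ncol(m)), character(1))
  cat(sprintf("ROITimeSeriesSet %s: %s\n", object@subjectId,
              paste(sprintf("%s[%s]", names(dims), dims), collapse = " ")))
})

#' @describeIn ConnectivityMatrix the correlation values matrix.
#' @param x,object A \code{ConnectivityMatrix}.
#' @export
setMethod("cmValues", "ConnectivityMatrix", function(x) x@values)

#' @describeIn ConnectivityMatrix the diagonal convention.
#' @export
setMethod("diagonalMode", "ConnectivityMatrix", function(x) x@diagonalMode)

#' @describeIn ConnectivityMatrix subject label.
#' @export
setMethod("subjectId", "ConnectivityMatrix", function(x) x@subjectId)

#' @describeIn ConnectivityMatrix domain label.
#' @export
setMethod("domainLabel", "ConnectivityMatrix", function(x) x@domain)

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix %s/%s: %d ROIs, diagonal '%s'\n",
              object@subjectId, object@domain, nrow(object@values),
              object@diagonalMode))
})
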