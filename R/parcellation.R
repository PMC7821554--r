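## Parcellation model: loading, the synthetic Power-style fixture, and the
## centre-proximity exclusion rule.

#' Construct a NetworkParcellation from an ROI table
#'
#' @param rois data.frame with columns \code{roi_id}, \code{x}, \code{y},
#'   \code{z}, \code{network}.
#' @param networks Network vocabulary (default the ten analysed networks).
#'   Labels outside the vocabulary are remapped to \code{"unassigned"} with
#'   a warning.
#' @param excludedIds Integer roi_ids already excluded.
#' @return A [NetworkParcellation-class] object.
#' @export
newParcellation <- function(rois, networks = analysisNetworks(),
                            excludedIds = integer(0)) {
  req <- c("roi_id", "x", "y", "z", "network")
  missing <- setdiff(req, names(rois))
  if (length(missing))
    stop("parcellation table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(rois) == 0L) stop("parcellation table has no ROIs")
  rois <- rois[, req]
  rois$roi_id <- as.integer(rois$roi_id)
  rois$network <- as.character(rois$network)
  if (anyDuplicated(rois$roi_id))
    stop("duplicate roi_id in parcellation table")
  unknown <- !(rois$network %in% c(networks, "unassigned"))
  if (any(unknown)) {
    warning(sum(unknown), " ROI(s) with unknown network label mapped to ",
            "'unassigned': ",
            paste(unique(rois$network[unknown]), collapse = ", "))
    rois$network[unknown] <- "unassigned"
  }
  rownames(rois) <- NULL
  new("NetworkParcellation", rois = rois, networks = networks,
      excludedIds = as.integer(excludedIds))
}

#' Read a parcellation table from delimited text
#'
#' Expects a whitespace- or tab-delimited file with header
#' \code{roi_id x y z network} and MNI mm coordinates.
#'
#' @param path File path.
#' @param networks Network vocabulary.
#' @return A [NetworkParcellation-class] object with ROIs in file order.
#' @export
loadParcellation <- function(path, networks = analysisNetworks()) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  newParcellation(tab, networks = networks)
}

#' Write a parcellation table
#'
#' Emits the same dialect [loadParcellation()] reads; only surviving
#' (non-excluded) ROIs are written.
#'
#' @param parc A [NetworkParcellation-class].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeParcellation <- function(parc, path) {
  write.table(survivingRois(parc), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Synthetic Power-style 264-node parcellation
#'
#' Builds a deterministic stand-in for the Power 264-node scheme: 214 ROIs
#' assigned to the ten analysed networks with the reference per-network
#' counts, plus (optionally) 50 \code{"unassigned"} ROIs.  Centres are laid
#' on a 24 mm grid spanning typical MNI ranges, so no pair falls inside the
#' default 20 mm exclusion radius.  This is a synthetic fixture, not the
#' published coordinate set.
#'
#' @param includeUnassigned logical; append 50 unassigned ROIs (total 264).
#' @return A [NetworkParcellation-class].
#' @export
#' @examples
#' parc <- powerLikeParcellation()
#' networkCounts(parc)
powerLikeParcellation <- function(includeUnassigned = TRUE) {
  counts <- referenceNetworkCounts()
  n <- if (includeUnassigned) 264L else 214L
  gx <- seq(-84, 84, by = 24)   # 8 positions per axis, 512 grid slots
  grid <- expand.grid(x = gx, y = gx, z = gx)
  grid <- grid[order(grid$z, grid$y, grid$x), ]
  labels <- c(rep(names(counts), counts),
              if (includeUnassigned) rep("unassigned", 50L))
  rois <- data.frame(roi_id = seq_len(n),
                     x = grid$x[seq_len(n)],
                     y = grid$y[seq_len(n)],
                     z = grid$z[seq_len(n)],
                     network = labels,
                     stringsAsFactors = FALSE)
  newParcellation(rois)
}

#' Exclude ROIs with centres closer than a minimum distance
#'
#' Any ROI belonging to at least one pair whose Euclidean centre distance is
#' strictly below \code{minDist} (in mm, standard space) is moved to the
#' excluded set; both members of an offending pair are removed.  A pair at
#' exactly \code{minDist} survives.  Distances are evaluated among the
#' currently surviving ROIs, so the operation is idempotent.
#'
#' @param parc A [NetworkParcellation-class].
#' @param minDist Minimum allowed centre distance in mm (default 20).
#' @return The filtered [NetworkParcellation-class].
#' @export
applyProximityExclusion <- function(parc, minDist = 20) {
  if (!is.numeric(minDist) || length(minDist) != 1L || minDist <= 0)
    stop("minDist must be a single positive number")
  s <- survivingRois(parc)
  if (anyNA(s[, c("x", "y", "z")]))
    stop("coordinates must be present for all ROIs")
  d <- as.matrix(dist(s[, c("x", "y", "z")]))
  diag(d) <- Inf
  offender <- apply(d < minDist, 1L, any)
  newExcluded <- s$roi_id[offender]
  parc@excludedIds <- sort(unique(c(parc@excludedIds,
                                    as.integer(newExcluded))))
  validObject(parc)
  parc
}
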