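## Connectivity metrics: signed within/between-network averages, system
## segregation, and proportionally thresholded weighted graph metrics.

## Network label per matrix row, from the parcellation, in matrix order.
.matrixNetworks <- function(cm, parc) {
  ids <- as.integer(rownames(cmValues(cm)))
  tab <- roiTable(parc)
  tab$network[match(ids, tab$roi_id)]
}

#' Mean within- or between-network correlation
#'
#' Averages the non-missing entries of a signed-split connectivity matrix
#' over ROI pairs inside network \code{network} (\code{scope = "within"};
#' upper triangle, each pair once) or over pairs joining \code{network}
#' with all other analysed networks pooled (\code{scope = "between"}).
#' Returns \code{NA} when no qualifying entry exists (e.g. no positive
#' within-network correlation in a small network).
#'
#' @param cm A positive-only or negative-only [ConnectivityMatrix-class]
#'   (see [splitPosNeg()]).
#' @param parc A [NetworkParcellation-class].
#' @param network Network name.
#' @param scope \code{"within"} or \code{"between"}.
#' @return Mean r, or \code{NA_real_}.
#' @export
networkMean <- function(cm, parc, network, scope = c("within", "between")) {
  scope <- match.arg(scope)
  if (!network %in% networkNames(parc))
    stop("unknown network '", network, "'")
  nets <- .matrixNetworks(cm, parc)
  v <- cmValues(cm)
  inK <- nets == network
  other <- nets != network & nets %in% networkNames(parc)
  if (scope == "within") {
    sub <- v[inK, inK, drop = FALSE]
    vals <- sub[upper.tri(sub)]
  } else {
    vals <- as.vector(v[inK, other])
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) NA_real_ else mean(vals)
}

#' System segregation
#'
#' Restricts the matrix to the ROIs of one system's networks (the other
#' system's ROIs are excluded entirely), sets negative correlations to
#' zero, optionally Fisher-z transforms (\code{atanh}), and computes
#' \deqn{SS = (\bar z_{within} - \bar z_{between}) / \bar z_{within}}
#' where the within mean pools all same-network ROI pairs of the system
#' and the between mean pools all cross-network pairs inside the system.
#' Zeroed negatives are included in both means (set-to-zero convention).
#' \code{ss} is missing when the within mean is not positive.
#'
#' @param cm A [ConnectivityMatrix-class] (missing diagonal).
#' @param parc A [NetworkParcellation-class].
#' @param system \code{"association"}, \code{"sensorimotor"} or
#'   \code{"whole_brain"}.
#' @param fisherZ logical; transform r with \code{atanh} before averaging
#'   (default TRUE).
#' @return List with \code{system}, \code{zWithin}, \code{zBetween},
#'   \code{ss}.
#' @export
systemSegregation <- function(cm, parc,
                              system = c("association", "sensorimotor",
                                         "whole_brain"),
                              fisherZ = TRUE) {
  system <- match.arg(system)
  nets <- .matrixNetworks(cm, parc)
  keep <- nets %in% systemNetworks(system)
  v <- cmValues(cm)[keep, keep, drop = FALSE]
  nk <- nets[keep]
  v[!is.na(v) & v < 0] <- 0
  if (fisherZ) v <- atanh(pmin(v, 1 - 1e-15))
  same <- outer(nk, nk, `==`)
  ut <- upper.tri(v)
  wvals <- v[ut & same]; wvals <- wvals[!is.na(wvals)]
  bvals <- v[ut & !same]; bvals <- bvals[!is.na(bvals)]
  zW <- if (length(wvals)) mean(wvals) else NA_real_
  zB <- if (length(bvals)) mean(bvals) else NA_real_
  ss <- if (!is.na(zW) && zW > 0 && !is.na(zB)) (zW - zB) / zW else NA_real_
  list(system = system, zWithin = zW, zBetween = zB, ss = ss)
}

#' Proportional threshold of a connectivity matrix
#'
#' Retains the strongest \code{ceiling(density * P)} positive off-diagonal
#' undirected edges (P = number of upper-triangle cells), zeroing all other
#' entries including every negative correlation.  Retained edges keep their
#' r weights; the result stays symmetric.  Ties at the cut are broken by
#' (weight, then smaller roi pair) lexicographic order for determinism.
#'
#' @param cm A [ConnectivityMatrix-class] with \code{diagonalMode "zero"}.
#' @param density Target edge density in (0, 1].
#' @return Symmetric non-negative weighted adjacency matrix.
#' @export
proportionalThreshold <- function(cm, density) {
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1)
    stop("density must be a single value in (0, 1]")
  if (diagonalMode(cm) != "zero")
    stop("proportional thresholding requires diagonalMode 'zero'")
  v <- cmValues(cm)
  n <- nrow(v)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  w <- v[ut]
  P <- nrow(ut)
  k <- ceiling(density * P)
  posIdx <- which(!is.na(w) & w > 0)
  if (!length(posIdx)) {
    warning("no positive correlations; thresholded adjacency is all zero")
    adj <- matrix(0, n, n, dimnames = dimnames(v))
    return(adj)
  }
  ord <- posIdx[order(-w[posIdx], ut[posIdx, 1L], ut[posIdx, 2L])]
  keep <- ord[seq_len(min(k, length(ord)))]
  adj <- matrix(0, n, n, dimnames = dimnames(v))
  adj[ut[keep, , drop = FALSE]] <- w[keep]
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

.adjGraph <- function(adj) {
  graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE,
                              diag = FALSE)
}

#' Weighted global efficiency
#'
#' Edge lengths are inverse weights; shortest-path distances come from
#' Dijkstra's algorithm, and efficiency is the average inverse distance
#' over ordered node pairs, with disconnected pairs contributing zero:
#' \deqn{E = \frac{1}{N(N-1)} \sum_{i \ne j} 1 / d_{ij}.}
#' For weights bounded by 1 the result lies in [0, 1].
#'
#' @param adj Symmetric non-negative weighted adjacency matrix.
#' @return Global efficiency value.
#' @export
globalEfficiency <- function(adj) {
  if (any(adj < 0)) stop("negative weights not allowed; zero them upstream")
  if (any(abs(adj - t(adj)) > 1e-12)) stop("adjacency must be symmetric")
  n <- nrow(adj)
  if (n < 2L) return(0)
  g <- .adjGraph(adj)
  wts <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(wts)) 1 / wts else NULL,
                         algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Newman-Girvan weighted modularity of a partition
#'
#' Evaluates \deqn{Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} -
#' \frac{k_i k_j}{2m}\right)\delta(c_i, c_j)} on a given node partition,
#' with strengths \eqn{k_i} and total weight \eqn{m}.
#'
#' @param adj Symmetric non-negative weighted adjacency matrix.
#' @param membership Integer community label per node.
#' @return Q value.
#' @export
modularityQ <- function(adj, membership) {
  stopifnot(length(membership) == nrow(adj))
  twoM <- sum(adj)
  if (twoM <= 0) return(NA_real_)
  k <- rowSums(adj)
  same <- outer(membership, membership, `==`)
  sum((adj - outer(k, k) / twoM) * same) / twoM
}

#' Louvain modularity
#'
#' Louvain optimisation of weighted Newman-Girvan Q at resolution 1, taking
#' the best partition over \code{nRestarts} deterministically seeded
#' restarts.  The returned Q is re-evaluated on the stored partition with
#' [modularityQ()], so it is always exactly reproducible from the
#' partition.
#'
#' @param adj Symmetric non-negative weighted adjacency matrix.
#' @param seed Integer seed for the restart sequence.
#' @param nRestarts Number of restarts (default 20).
#' @return List with \code{Q}, \code{membership} (integer per node),
#'   \code{seed}.
#' @export
louvainModularity <- function(adj, seed = 1L, nRestarts = 20L) {
  if (any(adj < 0)) stop("negative weights not allowed; zero them upstream")
  if (sum(adj) <= 0) {
    warning("total edge weight is zero; modularity undefined")
    return(list(Q = NA_real_, membership = rep(NA_integer_, nrow(adj)),
                seed = as.integer(seed)))
  }
  g <- .adjGraph(adj)
  ## one-block partition (Q = 0) as baseline candidate: the optimised Q can
  ## never fall below the trivial partition
  best <- rep(1L, nrow(adj))
  bestQ <- modularityQ(adj, best)
  for (r in seq_len(nRestarts)) {
    set.seed(as.integer(seed) + r - 1L)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                  resolution = 1)
    mem <- as.integer(igraph::membership(cl))
    q <- modularityQ(adj, mem)
    if (q > bestQ) { bestQ <- q; best <- mem }
  }
  list(Q = bestQ, membership = best, seed = as.integer(seed))
}

#' Compute the full tidy metric table for a cohort
#'
#' For every subject-by-domain connectivity matrix, computes the measures
#' requested: per-network positive within/between means and negative
#' between means (\code{"network"}), system segregation for the three
#' systems (\code{"segregation"}), and thresholded weighted graph metrics
#' (\code{"graph"}: global efficiency and Louvain modularity per edge
#' density).  Missing cells are preserved with a reason code.  Subjects
#' lacking a positive within- or between-network mean in any network in
#' any domain are flagged (attribute \code{"positiveSubset"} carries the
#' ids of subjects valid for the positive-correlation analysis).
#'
#' @param matrices Nested list: \code{matrices[[subject]][[domain]]} is a
#'   [ConnectivityMatrix-class] with missing diagonal.
#' @param parc A [NetworkParcellation-class].
#' @param manifest Subject manifest (for group labels); rows matched by
#'   \code{subject_id}.
#' @param measures Subset of \code{c("network", "segregation", "graph")}.
#' @param thresholds Edge densities for the graph metrics.
#' @param fisherZ Fisher-z averaging for segregation.
#' @param nRestarts,seed Louvain restart count and master seed.
#' @return data.frame with columns \code{subject_id}, \code{group},
#'   \code{domain}, \code{measure}, \code{network_or_system},
#'   \code{threshold}, \code{value}, \code{missing_reason}; attribute
#'   \code{"positiveSubset"} lists subjects with complete positive
#'   network means.
#' @export
computeMetricTable <- function(matrices, parc, manifest,
                               measures = c("network", "segregation",
                                            "graph"),
                               thresholds = seq(0.02, 0.10, by = 0.01),
                               fisherZ = TRUE, nRestarts = 20L,
                               seed = 1L) {
  measures <- match.arg(measures, several.ok = TRUE)
  nets <- networkNames(parc)
  chunks <- list()
  subjects <- names(matrices)
  groups <- manifest$group[match(subjects, manifest$subject_id)]
  for (si in seq_along(subjects)) {
    sid <- subjects[si]
    doms <- matrices[[sid]]
    for (di in seq_along(doms)) {
      d <- names(doms)[di]
      cm <- doms[[d]]
      msr <- character(0); nsys <- character(0); thr <- numeric(0)
      val <- numeric(0); why <- character(0)
      if ("network" %in% measures) {
        sp <- splitPosNeg(cm)
        for (k in nets) {
          v3 <- c(networkMean(sp$positive, parc, k, "within"),
                  networkMean(sp$positive, parc, k, "between"),
                  networkMean(sp$negative, parc, k, "between"))
          msr <- c(msr, "w_pos", "b_pos", "b_neg")
          nsys <- c(nsys, k, k, k)
          thr <- c(thr, NA_real_, NA_real_, NA_real_)
          val <- c(val, v3)
          why <- c(why, ifelse(is.na(v3), "no_qualifying_entries", ""))
        }
      }
      if ("segregation" %in% measures) {
        for (sys in c("association", "sensorimotor", "whole_brain")) {
          sg <- systemSegregation(cm, parc, sys, fisherZ = fisherZ)
          msr <- c(msr, "segregation"); nsys <- c(nsys, sys)
          thr <- c(thr, NA_real_); val <- c(val, sg$ss)
          why <- c(why, if (is.na(sg$ss)) "nonpositive_within_mean" else "")
        }
      }
      if ("graph" %in% measures && length(thresholds)) {
        cz <- setDiagonalMode(cm, "zero")
        for (ti in seq_along(thresholds)) {
          adj <- proportionalThreshold(cz, thresholds[ti])
          ge <- globalEfficiency(adj)
          lseed <- (as.integer(seed) + 131L * si + 17L * di + ti) %%
            2147483629L
          mo <- louvainModularity(adj, seed = lseed, nRestarts = nRestarts)
          msr <- c(msr, "global_efficiency", "modularity")
          nsys <- c(nsys, "whole_brain", "whole_brain")
          thr <- c(thr, thresholds[ti], thresholds[ti])
          val <- c(val, ge, mo$Q)
          why <- c(why, ifelse(is.na(c(ge, mo$Q)), "empty_graph", ""))
        }
      }
      chunks[[length(chunks) + 1L]] <-
        list(subject_id = rep(sid, length(msr)),
             group = rep(groups[si], length(msr)),
             domain = rep(d, length(msr)),
             measure = msr, network_or_system = nsys, threshold = thr,
             value = val, missing_reason = why)
    }
  }
  pull <- function(f) unlist(lapply(chunks, `[[`, f), use.names = FALSE)
  tab <- data.frame(subject_id = pull("subject_id"), group = pull("group"),
                    domain = pull("domain"), measure = pull("measure"),
                    network_or_system = pull("network_or_system"),
                    threshold = pull("threshold"), value = pull("value"),
                    missing_reason = pull("missing_reason"),
                    stringsAsFactors = FALSE)
  posTab <- tab[tab$measure %in% c("w_pos", "b_pos"), , drop = FALSE]
  if (nrow(posTab)) {
    badSubj <- unique(posTab$subject_id[is.na(posTab$value)])
    attr(tab, "positiveSubset") <- setdiff(subjects, badSubj)
  } else {
    attr(tab, "positiveSubset") <- subjects
  }
  tab
}

#' Write / read a metric table
#'
#' Tab-delimited long format with the header \code{subject_id group domain
#' measure network_or_system threshold value missing_reason}.
#'
#' @param table Metric table from [computeMetricTable()].
#' @param path File path.
#' @return \code{writeMetricTable}: the path, invisibly;
#'   \code{readMetricTable}: the data.frame.
#' @export
writeMetricTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetricTable
#' @export
readMetricTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA")
}
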