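test_that("network means reproduce simple arithmetic and missing rules", {
  parc <- toyParcellation(c(A = 3L, B = 2L))
  v <- matrix(NA_real_, 5, 5, dimnames = list(1:5, 1:5))
  v[1, 2] <- v[2, 1] <- 0.2
  v[1, 3] <- v[3, 1] <- 0.4
  v[2, 3] <- v[3, 2] <- 0.6
  v[4, 5] <- v[5, 4] <- 0.8
  v[1, 4] <- v[4, 1] <- 0.1
  cm <- asCM(v)
  expect_equal(networkMean(cm, parc, "A", "within"), 0.4)
  expect_equal(networkMean(cm, parc, "A", "between"), 0.1)
  expect_equal(networkMean(cm, parc, "B", "between"), 0.1)
  expect_error(networkMean(cm, parc, "Z"), "unknown network")
  ## all within entries negative in the positive-only matrix -> missing
  vneg <- v; vneg[1:3, 1:3] <- -abs(vneg[1:3, 1:3])
  sp <- splitPosNeg(asCM(vneg))
  expect_true(is.na(networkMean(sp$positive, parc, "A", "within")))
})

test_that("network means match a brute-force pair-enumeration oracle", {
  set.seed(91)
  parc <- powerLikeParcellation(includeUnassigned = FALSE)
  ids <- roiTable(parc)$roi_id
  nets <- roiTable(parc)$network
  m <- randomCorrMatrix(214, ids = ids)
  sp <- splitPosNeg(asCM(m))
  for (k in c("VAN", "DMN", "Mouth")) {
    for (side in c("positive", "negative")) {
      v <- cmValues(sp[[side]])
      wVals <- c(); bVals <- c()
      for (i in 1:213) for (j in (i + 1):214) {
        if (is.na(v[i, j])) next
        if (nets[i] == k && nets[j] == k) wVals <- c(wVals, v[i, j])
        if (xor(nets[i] == k, nets[j] == k)) bVals <- c(bVals, v[i, j])
      }
      expect_equal(networkMean(sp[[side]], parc, k, "within"),
                   if (length(wVals)) mean(wVals) else NA_real_,
                   tolerance = 1e-12)
      expect_equal(networkMean(sp[[side]], parc, k, "between"),
                   if (length(bVals)) mean(bVals) else NA_real_,
                   tolerance = 1e-12)
    }
  }
})

test_that("system segregation follows (zw - zb) / zw with set-to-zero negatives", {
  ## toy 3-network matrix, hand-enumerated oracle
  parc <- toyParcellation(c(DMN = 2L, FP = 2L, Vis = 2L))
  v <- matrix(NA_real_, 6, 6, dimnames = list(1:6, 1:6))
  fill <- function(i, j, r) v[i, j] <<- v[j, i] <<- r
  fill(1, 2, 0.6); fill(3, 4, 0.4)       # within DMN, within FP
  fill(1, 3, 0.2); fill(1, 4, -0.3)      # DMN-FP (one negative)
  fill(2, 3, 0.1); fill(2, 4, 0.25)
  fill(5, 6, 0.5)                        # within Vis
  for (i in 1:4) for (j in 5:6) fill(i, j, -0.2)  # association-Vis
  cm <- asCM(v)
  ## association system = DMN + FP here; Vis ROIs excluded entirely
  zw <- mean(atanh(c(0.6, 0.4)))
  zb <- mean(atanh(c(0.2, 0, 0.1, 0.25)))  # negative -0.3 set to zero
  sg <- systemSegregation(cm, parc, "association")
  expect_equal(sg$zWithin, zw, tolerance = 1e-12)
  expect_equal(sg$zBetween, zb, tolerance = 1e-12)
  expect_equal(sg$ss, (zw - zb) / zw, tolerance = 1e-12)
  ## raw-r averaging mode
  sgRaw <- systemSegregation(cm, parc, "association", fisherZ = FALSE)
  expect_equal(sgRaw$zWithin, 0.5, tolerance = 1e-12)
  ## formula arithmetic: ss(0.5, 0.25) = 0.5; ss = 0 when zw = zb
  expect_equal((0.5 - 0.25) / 0.5, 0.5)
  v2 <- v; v2[!is.na(v2)] <- 0.3
  sg2 <- systemSegregation(asCM(v2), parc, "association")
  expect_equal(sg2$ss, 0, tolerance = 1e-12)
  ## nonpositive within mean -> ss missing, no error
  v3 <- v; v3[1, 2] <- v3[2, 1] <- -0.6; v3[3, 4] <- v3[4, 3] <- -0.4
  expect_true(is.na(systemSegregation(asCM(v3), parc, "association")$ss))
})

test_that("segregation monotonically decreases in between-network coupling", {
  parc <- toyParcellation(c(DMN = 3L, FP = 3L))
  base <- matrix(0.2, 6, 6, dimnames = list(1:6, 1:6))
  base[1:3, 1:3] <- 0.6; base[4:6, 4:6] <- 0.6
  prev <- Inf
  for (b in c(0.1, 0.2, 0.3, 0.4)) {
    v <- base; v[1:3, 4:6] <- b; v[4:6, 1:3] <- b
    ss <- systemSegregation(asCM(v), parc, "association")$ss
    expect_lt(ss, prev)
    prev <- ss
  }
})

test_that("proportional threshold retains exactly ceiling(density * P) edges", {
  set.seed(101)
  ## 5-node example: P = 10, density 0.10 -> exactly 1 edge
  m5 <- randomCorrMatrix(5); m5 <- abs(m5)
  adj <- proportionalThreshold(asCM(m5, "zero"), 0.10)
  expect_equal(sum(adj[upper.tri(adj)] > 0), 1L)
  ## density 1.0: all positives retained, negatives zeroed
  m <- randomCorrMatrix(8)
  adjAll <- proportionalThreshold(asCM(m, "zero"), 1.0)
  ut <- upper.tri(m)
  expect_equal(sum(adjAll[ut] > 0), sum(m[ut] > 0))
  expect_true(all(adjAll >= 0))
  ## retained sets match a full sort-and-cut oracle across densities
  m30 <- randomCorrMatrix(30)
  cm30 <- asCM(m30, "zero")
  P <- 30 * 29 / 2
  pairs <- which(upper.tri(m30), arr.ind = TRUE)
  w <- m30[pairs]
  ord <- order(-w, pairs[, 1], pairs[, 2])
  ord <- ord[w[ord] > 0]
  for (dens in seq(0.02, 0.10, by = 0.01)) {
    adj <- proportionalThreshold(cm30, dens)
    k <- ceiling(dens * P)
    keep <- ord[seq_len(k)]
    expected <- matrix(0, 30, 30)
    expected[pairs[keep, , drop = FALSE]] <- w[keep]
    expected <- expected + t(expected)
    expect_equal(unname(adj), expected, tolerance = 1e-15)
    expect_equal(sum(adj[upper.tri(adj)] > 0), k)
  }
  ## degenerate: no positive entries
  expect_warning(z <- proportionalThreshold(asCM(-abs(m30), "zero"), 0.05),
                 "no positive")
  expect_true(all(z == 0))
  expect_error(proportionalThreshold(cm30, 0), "0, 1")
  expect_error(proportionalThreshold(asCM(m30, "missing"), 0.05), "zero")
})

test_that("global efficiency matches closed forms and the Floyd-Warshall oracle", {
  ## complete graph, unit weights
  K <- matrix(1, 6, 6); diag(K) <- 0
  expect_equal(globalEfficiency(K), 1)
  ## 3-node path: distances 1, 1, 2
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- 1; P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(globalEfficiency(P3), 5 / 6)
  ## weighted random graphs vs dynamic-programming oracle
  set.seed(111)
  for (rep in 1:5) {
    adj <- matrix(0, 10, 10)
    ut <- which(upper.tri(adj), arr.ind = TRUE)
    sel <- sample(nrow(ut), 20)
    adj[ut[sel, ]] <- runif(20, 0.1, 1)
    adj <- adj + t(adj)
    expect_equal(globalEfficiency(adj), oracleGlobalEfficiency(adj),
                 tolerance = 1e-12)
  }
  expect_error(globalEfficiency(matrix(c(0, -1, -1, 0), 2, 2)),
               "negative")
})

test_that("efficiency is non-decreasing in density for nested thresholds", {
  set.seed(121)
  m <- randomCorrMatrix(40)
  cm <- asCM(m, "zero")
  eff <- vapply(seq(0.02, 0.10, by = 0.01), function(d)
    globalEfficiency(proportionalThreshold(cm, d)), numeric(1))
  expect_true(all(diff(eff) >= -1e-12))
})

test_that("modularity reproduces closed-form partitions and bounds", {
  ## two disconnected unit-weight 3-cliques: Q = 0.5
  clique <- matrix(1, 3, 3); diag(clique) <- 0
  adj <- rbind(cbind(clique, matrix(0, 3, 3)),
               cbind(matrix(0, 3, 3), clique))
  res <- louvainModularity(adj, seed = 2, nRestarts = 5)
  expect_equal(res$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(res$membership)), 2L)
  ## Q recomputable from the stored partition
  expect_equal(res$Q, modularityQ(adj, res$membership), tolerance = 1e-12)
  expect_equal(res$Q, oracleQ(adj, res$membership), tolerance = 1e-12)
  ## one-block partition of a connected clique has Q = 0
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(modularityQ(K5, rep(1L, 5)), 0, tolerance = 1e-12)
  ## Louvain never returns below the one-block partition
  expect_gte(louvainModularity(K5, seed = 4)$Q, -1e-12)
  ## empty graph
  expect_warning(z <- louvainModularity(matrix(0, 3, 3)), "zero")
  expect_true(is.na(z$Q))
})

test_that("graph metrics are invariant under node permutation", {
  set.seed(131)
  adj <- matrix(0, 12, 12)
  ut <- which(upper.tri(adj), arr.ind = TRUE)
  sel <- sample(nrow(ut), 30)
  adj[ut[sel, ]] <- runif(30, 0.1, 1)
  adj <- adj + t(adj)
  perm <- sample(12)
  expect_equal(globalEfficiency(adj[perm, perm]), globalEfficiency(adj),
               tolerance = 1e-12)
  q1 <- louvainModularity(adj, seed = 7, nRestarts = 10)$Q
  q2 <- louvainModularity(adj[perm, perm], seed = 7, nRestarts = 10)$Q
  expect_equal(q2, q1, tolerance = 1e-9)
})

test_that("metric table row counts follow the closed-form product", {
  parc <- reducedParc()
  spec <- reducedSpec(groupSizes = c(YA = 1L, OA = 1L),
                      volumes = c(VOCAB = 40L, SPEED = 40L, FLUID = 40L,
                                  MEM = 40L), seed = 13L)
  co <- simulateCohort(spec, parc)
  mats <- lapply(co$series, subjectConnectivity)
  tab <- computeMetricTable(mats, parc, co$manifest,
                            thresholds = seq(0.02, 0.10, by = 0.01))
  ## 2 networks x 3 + 3 systems + 2 metrics x 9 thresholds = 27 per
  ## subject-domain; 2 subjects x 4 domains
  expect_equal(nrow(tab), 2L * 4L * (6L + 3L + 18L))
  expect_setequal(unique(tab$measure),
                  c("w_pos", "b_pos", "b_neg", "segregation",
                    "global_efficiency", "modularity"))
  ## round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMetricTable(tab, path)
  tab2 <- readMetricTable(path)
  expect_equal(tab2$value, tab$value, tolerance = 1e-10)
})

test_that("subjects without positive within-network entries are flagged", {
  parc <- toyParcellation(c(DMN = 3L, Vis = 3L))
  goodV <- randomCorrMatrix(6)
  badV <- goodV
  badV[1:3, 1:3] <- -abs(badV[1:3, 1:3])  # DMN all-negative within
  mats <- list(S1 = list(VOCAB = asCM(goodV)),
               S2 = list(VOCAB = asCM(badV)))
  man <- data.frame(subject_id = c("S1", "S2"), group = c("YA", "OA"))
  tab <- computeMetricTable(mats, parc, man, measures = "network")
  expect_equal(attr(tab, "positiveSubset"), "S1")
  expect_true(any(tab$missing_reason == "no_qualifying_entries"))
})
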