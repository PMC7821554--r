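## Independent brute-force oracles used across the suite.  These stay
## deliberately naive (loops, enumeration, closed forms) and never call the
## implementation paths they check.

## All-pairs shortest path by Floyd-Warshall on inverse-weight lengths.
oracleFloydWarshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && adj[i, j] > 0) d[i, j] <- 1 / adj[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracleGlobalEfficiency <- function(adj) {
  d <- oracleFloydWarshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- nrow(adj)
  sum(inv) / (n * (n - 1))
}

## All set partitions of 1..n (Bell number growth; keep n small).
oraclePartitions <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- oraclePartitions(n - 1L)
  out <- list()
  for (p in smaller) {
    k <- max(p)
    for (b in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, b)
  }
  out
}

## Newman-Girvan weighted Q evaluated naively, pair by pair.
oracleQ <- function(adj, membership) {
  twoM <- sum(adj)
  k <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(ncol(adj)))
    if (membership[i] == membership[j])
      q <- q + adj[i, j] - k[i] * k[j] / twoM
  q / twoM
}

oracleMaxQ <- function(adj) {
  best <- -Inf
  for (p in oraclePartitions(nrow(adj))) {
    q <- oracleQ(adj, p)
    if (q > best) best <- q
  }
  best
}

## Textbook Pearson r for two vectors, via explicit covariance / sd.
oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## Least-squares residuals via explicit normal equations (X'X)^-1 X'Y.
oracleResiduals <- function(Y, X) {
  B <- solve(t(X) %*% X) %*% t(X) %*% Y
  Y - X %*% B
}

## First-order partial correlation by the standard recursion, applied
## iteratively over the covariate list.
oraclePartialCor <- function(x, y, Z) {
  vars <- cbind(x = x, y = y, Z)
  R <- stats::cor(vars)
  idx <- seq_len(ncol(vars))
  recur <- function(i, j, rest) {
    if (!length(rest)) return(R[i, j])
    k <- rest[1]; rem <- rest[-1]
    rij <- recur(i, j, rem); rik <- recur(i, k, rem); rjk <- recur(j, k, rem)
    (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
  }
  recur(1L, 2L, seq(3L, length.out = ncol(vars) - 2L))
}

## Small helper fixtures -----------------------------------------------------

## Parcellation with arbitrary per-network sizes, well-separated centres.
toyParcellation <- function(sizes, spacing = 30) {
  n <- sum(sizes)
  gx <- seq(0, by = spacing, length.out = ceiling(n^(1 / 3)) + 1)
  grid <- expand.grid(x = gx, y = gx, z = gx)
  data.frame(roi_id = seq_len(n), x = grid$x[seq_len(n)],
             y = grid$y[seq_len(n)], z = grid$z[seq_len(n)],
             network = rep(names(sizes), sizes),
             stringsAsFactors = FALSE) |>
    newParcellation(networks = names(sizes))
}

## Symmetric correlation-like matrix with roi_id dimnames.
randomCorrMatrix <- function(n, ids = seq_len(n)) {
  m <- matrix(runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  dimnames(m) <- list(ids, ids)
  m
}

## ConnectivityMatrix straight from a values matrix.
asCM <- function(v, diagonalMode = "missing") {
  if (diagonalMode == "zero") diag(v) <- 0 else diag(v) <- NA_real_
  new("ConnectivityMatrix", values = v, diagonalMode = diagonalMode,
      domain = NA_character_, subjectId = NA_character_)
}

## Reduced cohort spec used by the heavier simulation tests: two networks,
## short series, small parcellation.
reducedSpec <- function(groupSizes = c(YA = 72L, yMA = 60L, oMA = 86L,
                                       OA = 84L),
                        w = NULL, nets = c("DMN", "Vis"),
                        volumes = c(VOCAB = 120L, SPEED = 120L,
                                    FLUID = 120L, MEM = 120L),
                        rho = 0.2, seed = 1L, ...) {
  coupling <- matrix(rho, length(nets), length(nets),
                     dimnames = list(nets, nets))
  diag(coupling) <- 1
  cohortSpec(groupSizes = groupSizes, networks = nets, w = w,
             coupling = coupling, couplingAgeStep = 0, volumes = volumes,
             seed = seed, ...)
}

reducedParc <- function(nets = c(DMN = 6L, Vis = 6L)) {
  toyParcellation(nets)
}
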