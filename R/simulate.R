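## Synthetic cohort generator.  ROI signals follow a network factor model
##   x_i(t) = sqrt(w_k) g_k(t) + sqrt(1 - w_k) * noiseSd * e_i(t) + beta s(t)
## with network factors g_k correlated according to a coupling matrix rho,
## unit white noise e_i, and a block task regressor s(t) (boxcar convolved
## with a canonical double-gamma haemodynamic response).  The model gives
## closed-form expected Pearson correlations, used as recovery oracles.

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style double gamma: peak at ~5 s, undershoot at ~15 s
#' (shape1 = 6, shape2 = 16, rates 1, undershoot ratio 1/6).
#'
#' @param t Time in seconds (vector).
#' @return HRF values at \code{t}.
#' @export
hrfDoubleGamma <- function(t) {
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  out[pos] <- tp^5 * exp(-tp) / gamma(6) - tp^15 * exp(-tp) / (6 * gamma(16))
  out
}

## Convolve a boxcar (volume units) with the HRF sampled at TR; truncate.
.convolveBoxcar <- function(box, tr = 2) {
  h <- hrfDoubleGamma(seq(0, 30, by = tr))
  full <- convolve(box, rev(h), type = "open")
  full[seq_along(box)]
}

#' Block task design for one domain
#'
#' Builds the volumes-by-tasks regressor matrix for a domain: one regressor
#' per constituent task run, a boxcar of alternating off/on blocks
#' (starting off) convolved with the double-gamma response, supported only
#' on that run's segment of the concatenated series.  No intercept column;
#' [regressOutTask()] adds one.
#'
#' @param domain Domain name (used only for labelling).
#' @param runs Named integer vector of per-run volume counts; their sum is
#'   the domain's concatenated volume count.
#' @param blockLen Block length in volumes (default 15, i.e. 30 s at TR 2 s).
#' @param tr Repetition time in seconds.
#' @return Numeric matrix (total volumes x number of runs), columns named
#'   by run.
#' @export
#' @examples
#' d <- domainTaskDesign("VOCAB", domainTaskRuns()$VOCAB)
#' dim(d)  # 388 x 2
domainTaskDesign <- function(domain, runs, blockLen = 15L, tr = 2) {
  stopifnot(length(runs) >= 1L, all(runs >= 1L))
  total <- sum(runs)
  X <- matrix(0, nrow = total, ncol = length(runs),
              dimnames = list(NULL, names(runs)))
  offset <- 0L
  for (j in seq_along(runs)) {
    Tr <- runs[[j]]
    box <- as.numeric((((seq_len(Tr) - 1L) %/% blockLen) %% 2L) == 1L)
    X[offset + seq_len(Tr), j] <- .convolveBoxcar(box, tr = tr)
    offset <- offset + Tr
  }
  attr(X, "domain") <- domain
  X
}

#' Default network coupling matrix
#'
#' Symmetric positive-semidefinite correlation matrix of the network
#' factors: 0.3 among sensorimotor networks, 0.2 among association
#' networks, and -0.15 between the two systems, so the generator plants
#' the negative inter-system coupling the between-network negative
#' correlation analysis relies on.
#'
#' @param networks Network vocabulary.
#' @return Named square matrix with unit diagonal.
#' @export
defaultCoupling <- function(networks = analysisNetworks()) {
  sm <- networks %in% systemNetworks("sensorimotor")
  rho <- matrix(0, length(networks), length(networks),
                dimnames = list(networks, networks))
  rho[sm, sm] <- 0.3
  rho[!sm, !sm] <- 0.2
  rho[sm, !sm] <- -0.15
  rho[!sm, sm] <- -0.15
  diag(rho) <- 1
  rho
}

#' Specify a synthetic cohort
#'
#' Collects every generator parameter: group sizes, per-group/per-network
#' within-network loadings \code{w}, network-factor coupling, domain
#' volumes and task-run structure, noise and task-signal scales, the
#' scrubbing-fraction distribution, the behaviour model, demographics, and
#' the master seed.  Defaults reproduce the study conditions: four age
#' groups of 72/60/86/84 subjects (N = 302), domain volumes 388/595/1290/517,
#' and within-network loadings declining 0.45 to 0.36 across age groups
#' (the qualitative age effect the analysis is designed to detect).
#'
#' @param groupSizes Named integer vector of subjects per age group.
#' @param networks Network vocabulary.
#' @param w Numeric matrix (groups x networks) of within-network factor
#'   loadings in (0, 1]; default \code{wBase - (groupIndex-1) * ageEffect}
#'   for every network.
#' @param wBase,ageEffect Scalars building the default \code{w}.
#' @param coupling Coupling matrix, or a list of matrices, one per group.
#'   Must be symmetric PSD with unit diagonal.  When a single matrix is
#'   given it is age-graded by \code{couplingAgeStep} (below).
#' @param couplingAgeStep Per-group-step scaling of the coupling when one
#'   base matrix is supplied: for group index \eqn{g} (1 = youngest),
#'   positive off-diagonal couplings are multiplied by
#'   \code{1 + couplingAgeStep * (g - 1)} and negative couplings by
#'   \code{max(0, 1 - couplingAgeStep * (g - 1))}.  Together with the
#'   declining \code{w}, this plants the aged brain's dedifferentiation:
#'   relatively stronger positive between-network coupling and attenuated
#'   (eventually abolished) negative coupling in older groups.  Scaling
#'   \code{w} alone cannot express this contrast — it leaves the
#'   between/within correlation ratio, and hence segregation and the
#'   weighted modularity of the proportionally thresholded graph,
#'   asymptotically unchanged.  The default 0.5 produces young-minus-old
#'   modularity differences of the order the emulated study reports.
#'   Set to 0 for age-constant coupling.  Ignored when \code{coupling} is
#'   a per-group list.
#' @param volumes Named integer vector of per-domain concatenated volumes.
#' @param taskRuns Named list of per-domain run structures (see
#'   [domainTaskRuns()]); defaults to a single run per domain when
#'   \code{volumes} deviates from the reference values.
#' @param noiseSd ROI white-noise scale (1 keeps unit signal variance).
#' @param betaTask Task regressor amplitude (default 1/3, putting roughly
#'   10\% of total variance in the task signal).
#' @param blockLen Task block length in volumes.
#' @param scrubShape length-2 Beta shape parameters for per-domain scrub
#'   fractions (default Beta(2, 15): mean 0.12, with a tail above 0.30
#'   that excludes roughly a tenth of subjects over the four domains).
#' @param behaviorMeans Matrix (groups x domains) of behavioural z-score
#'   means; defaults mirror the demographic table's group pattern.
#' @param behaviorSd Behavioural noise SD.
#' @param genderPF Probability of female.
#' @param educationMean,educationSd Education (years) distribution.
#' @param seed Master random seed (integer).
#' @return A list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(groupSizes = c(YA = 72L, yMA = 60L, oMA = 86L, OA = 84L),
                       networks = analysisNetworks(),
                       w = NULL, wBase = 0.45, ageEffect = 0.03,
                       coupling = defaultCoupling(networks),
                       couplingAgeStep = 0.5,
                       volumes = domainVolumes(),
                       taskRuns = NULL,
                       noiseSd = 1, betaTask = 1 / 3, blockLen = 15L,
                       scrubShape = c(2, 15),
                       behaviorMeans = NULL, behaviorSd = 0.8,
                       genderPF = 0.52,
                       educationMean = 16, educationSd = 2.4,
                       seed = 20201118L) {
  groups <- names(groupSizes)
  if (is.null(groups)) groups <- c("YA", "yMA", "oMA", "OA")[seq_along(groupSizes)]
  if (any(groupSizes < 1L)) stop("groupSizes must be positive")
  domains <- names(volumes)
  if (any(volumes < 10L)) stop("domain volumes must be at least 10")
  if (is.null(w)) {
    w <- outer(wBase - (seq_along(groups) - 1L) * ageEffect,
               rep(1, length(networks)))
    dimnames(w) <- list(groups, networks)
  }
  if (any(w <= 0) || any(w > 1)) stop("w loadings must lie in (0, 1]")
  if (!is.list(coupling)) {
    base <- coupling
    coupling <- setNames(lapply(seq_along(groups), function(gi) {
      rho <- base
      off <- row(rho) != col(rho)
      rho[off & rho > 0] <- rho[off & rho > 0] *
        (1 + couplingAgeStep * (gi - 1))
      rho[off & rho < 0] <- rho[off & rho < 0] *
        max(0, 1 - couplingAgeStep * (gi - 1))
      rho
    }), groups)
  }
  for (rho in coupling) {
    if (any(abs(rho - t(rho)) > 1e-12) || any(abs(diag(rho) - 1) > 1e-12))
      stop("coupling must be symmetric with unit diagonal")
    if (min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("coupling must be positive semidefinite")
  }
  if (is.null(taskRuns)) {
    ref <- domainTaskRuns()
    taskRuns <- lapply(domains, function(d) {
      if (d %in% names(ref) && sum(ref[[d]]) == volumes[[d]]) ref[[d]]
      else setNames(as.integer(volumes[[d]]), paste0(tolower(d), "_task"))
    })
    names(taskRuns) <- domains
  }
  if (is.null(behaviorMeans)) {
    ref <- rbind(VOCAB = c(-0.143, -0.161, 0.029, 0.099),
                 SPEED = c(-0.359, -0.178, -0.049, 0.300),
                 FLUID = c(0.280, 0.001, -0.054, -0.088),
                 MEM   = c(0.268, 0.054, -0.047, -0.193))
    behaviorMeans <- matrix(0, length(groups), length(domains),
                            dimnames = list(groups, domains))
    for (d in domains)
      if (d %in% rownames(ref) && length(groups) == 4L)
        behaviorMeans[, d] <- ref[d, ]
  }
  structure(list(groupSizes = groupSizes, groups = groups,
                 networks = networks, w = w, coupling = coupling,
                 volumes = volumes, domains = domains, taskRuns = taskRuns,
                 noiseSd = noiseSd, betaTask = betaTask,
                 blockLen = as.integer(blockLen),
                 scrubShape = scrubShape, behaviorMeans = behaviorMeans,
                 behaviorSd = behaviorSd, genderPF = genderPF,
                 educationMean = educationMean, educationSd = educationSd,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' @export
print.CohortSpec <- function(x, ...) {
  cat(sprintf("CohortSpec: %d subjects (%s), %d networks, domains %s, seed %d\n",
              sum(x$groupSizes),
              paste(sprintf("%s=%d", x$groups, x$groupSizes), collapse = " "),
              length(x$networks),
              paste(sprintf("%s=%d", x$domains, x$volumes), collapse = " "),
              x$seed))
  invisible(x)
}

#' Expected Pearson correlation under the factor model
#'
#' Within one network the expected ROI-pair correlation is
#' \code{w / (w + (1-w) noiseSd^2)} (equal to \code{w} for the unit-variance
#' default \code{noiseSd = 1}); across networks k and l it is
#' \code{sqrt(wK wL) * rho} rescaled by the same variance terms.  Used by
#' the tests as the parameter-recovery target.
#'
#' @param wK Within-network loading of network k, in (0, 1].
#' @param wL Loading of network l; omit (NULL) for the within-network case.
#' @param rho Factor correlation between k and l, in (-1, 1).
#' @param noiseSd Noise scale of the generator.
#' @return Expected Pearson r.
#' @export
#' @examples
#' expectedCorrelation(0.4)                      # 0.4
#' expectedCorrelation(0.5, 0.32, rho = -0.5)    # -0.2
expectedCorrelation <- function(wK, wL = NULL, rho = NULL, noiseSd = 1) {
  if (any(wK <= 0) || any(wK > 1)) stop("w must lie in (0, 1]")
  v <- function(w) w + (1 - w) * noiseSd^2
  if (is.null(wL)) return(wK / v(wK))
  if (is.null(rho)) stop("rho required for the cross-network expectation")
  if (any(wL <= 0) || any(wL > 1)) stop("w must lie in (0, 1]")
  if (any(rho <= -1) || any(rho >= 1)) stop("rho must lie in (-1, 1)")
  sqrt(wK * wL) * rho / sqrt(v(wK) * v(wL))
}

## Per-subject seeds drawn from a dedicated stream of the master seed.
## Sampling the seeds (rather than deriving them arithmetically from the
## subject index) keeps the subject streams free of index-linked structure:
## seeds in arithmetic progression fill the generator state linearly and
## can leave a weak trend in subject index, which a between-group test on
## index-blocked groups would pick up.  Deterministic given masterSeed;
## all seeds stay below 2^31.
.cohortSeeds <- function(masterSeed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.integer(masterSeed) %% 2147480000L) + 101L)
  sample.int(2147483646L, n)
}

#' Simulate one subject's per-domain ROI time series
#'
#' @param spec A [cohortSpec()].
#' @param subject List or one-row data.frame with at least \code{subject_id}
#'   and \code{group}.
#' @param parc A [NetworkParcellation-class]; assigned surviving ROIs are
#'   simulated, in parcellation order.
#' @param seed Integer seed (reproducibility contract: identical
#'   \code{(seed, subject)} gives identical output).
#' @return A [ROITimeSeriesSet-class].
#' @export
simulateSubject <- function(spec, subject, parc, seed) {
  group <- as.character(subject$group)
  if (!group %in% rownames(spec$w))
    stop("no network parameters configured for group '", group, "'")
  rois <- survivingRois(parc, assignedOnly = TRUE)
  if (!all(rois$network %in% spec$networks))
    stop("parcellation networks not covered by the cohort spec")
  netIdx <- match(rois$network, spec$networks)
  wNet <- spec$w[group, ]
  rho <- spec$coupling[[group]]
  Lt <- chol(rho + diag(1e-12, nrow(rho)))
  set.seed(as.integer(seed))
  series <- list()
  for (d in spec$domains) {
    Tn <- spec$volumes[[d]]
    G <- matrix(rnorm(Tn * length(spec$networks)), Tn) %*% Lt
    Emat <- matrix(rnorm(Tn * nrow(rois)), Tn)
    wi <- wNet[netIdx]
    X <- sweep(G[, netIdx, drop = FALSE], 2L, sqrt(wi), `*`) +
      sweep(Emat, 2L, sqrt(1 - wi) * spec$noiseSd, `*`)
    if (spec$betaTask != 0) {
      des <- domainTaskDesign(d, spec$taskRuns[[d]], blockLen = spec$blockLen)
      s <- rowSums(des)
      if (sd(s) > 0) s <- (s - mean(s)) / sd(s)
      X <- X + spec$betaTask * s
    }
    colnames(X) <- rois$roi_id
    series[[d]] <- X
  }
  new("ROITimeSeriesSet", subjectId = as.character(subject$subject_id),
      series = series)
}

#' Simulate a full cohort: manifest plus time series
#'
#' Deterministic under \code{spec$seed}: demographics, scrub fractions and
#' behaviour are drawn from the master seed; each subject's time series use
#' a per-subject seed derived from it, so subjects can be regenerated
#' independently with [simulateSubject()].
#'
#' @param spec A [cohortSpec()].
#' @param parc A [NetworkParcellation-class].
#' @param dir Optional output directory; when given, writes
#'   \code{manifest.tsv} and one \code{ts/<subject>_<domain>.tsv} file per
#'   subject per domain.
#' @param returnSeries logical; keep the generated [ROITimeSeriesSet-class]
#'   objects in the return value (disable for large cohorts).
#' @param overwrite logical; allow overwriting an existing manifest.
#' @return List with \code{manifest} (data.frame), \code{series} (list or
#'   NULL) and \code{subjectSeeds} (named integer vector).
#' @export
simulateCohort <- function(spec, parc, dir = NULL, returnSeries = TRUE,
                           overwrite = FALSE) {
  manifest <- simulateManifest(spec)
  seeds <- setNames(.cohortSeeds(spec$seed, nrow(manifest)),
                    manifest$subject_id)
  if (!is.null(dir)) {
    mpath <- file.path(dir, "manifest.tsv")
    if (file.exists(mpath) && !overwrite)
      stop("manifest already exists at ", mpath, " (set overwrite = TRUE)")
    dir.create(file.path(dir, "ts"), recursive = TRUE, showWarnings = FALSE)
    writeManifest(manifest, mpath)
  }
  series <- if (returnSeries) vector("list", nrow(manifest)) else NULL
  for (i in seq_len(nrow(manifest))) {
    tss <- simulateSubject(spec, manifest[i, ], parc, seed = seeds[[i]])
    if (!is.null(dir)) {
      for (d in names(tss@series))
        writeTimeSeries(tss@series[[d]],
                        file.path(dir, "ts",
                                  sprintf("%s_%s.tsv", subjectId(tss), d)))
    }
    if (returnSeries) series[[i]] <- tss
  }
  if (returnSeries) names(series) <- manifest$subject_id
  list(manifest = manifest, series = series, subjectSeeds = seeds)
}

#' Simulate the subject manifest only
#'
#' Demographics (age within group band, gender, education), per-domain
#' scrub fractions (Beta distributed) and behavioural z-scores (group mean
#' plus noise), deterministic under \code{spec$seed}.
#'
#' @param spec A [cohortSpec()].
#' @return data.frame with columns \code{subject_id}, \code{group},
#'   \code{age}, \code{gender}, \code{education}, \code{scrub_<domain>} and
#'   \code{z_<domain>}.
#' @export
simulateManifest <- function(spec) {
  set.seed(spec$seed)
  bands <- ageGroups()
  n <- sum(spec$groupSizes)
  group <- rep(spec$groups, spec$groupSizes)
  band <- bands[match(group, bands$group), ]
  if (anyNA(band$lo)) band$lo <- 20; if (anyNA(band$hi)) band$hi <- 80
  manifest <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group,
    age = round(runif(n, band$lo, band$hi), 1),
    gender = ifelse(rbinom(n, 1L, spec$genderPF) == 1L, "F", "M"),
    education = pmin(pmax(round(rnorm(n, spec$educationMean,
                                      spec$educationSd), 1), 8), 24),
    stringsAsFactors = FALSE)
  for (d in spec$domains)
    manifest[[paste0("scrub_", d)]] <-
      round(rbeta(n, spec$scrubShape[1], spec$scrubShape[2]), 4)
  for (d in spec$domains)
    manifest[[paste0("z_", d)]] <-
      round(spec$behaviorMeans[match(group, spec$groups), d] +
              rnorm(n, 0, spec$behaviorSd), 4)
  manifest
}

#' Write / read the subject manifest
#'
#' Tab-delimited with the header
#' \code{subject_id group age gender education scrub_* z_*}.
#'
#' @param manifest data.frame from [simulateManifest()].
#' @param path File path.
#' @return \code{writeManifest}: the path, invisibly; \code{readManifest}:
#'   the data.frame.
#' @export
writeManifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read one volumes-by-ROIs time-series matrix
#'
#' Tab-delimited numeric table with a header row of roi_ids.
#'
#' @param mat Numeric matrix (volumes x ROIs), columns named by roi_id.
#' @param path File path.
#' @return \code{writeTimeSeries}: the path, invisibly;
#'   \code{readTimeSeries}: the matrix.
#' @export
writeTimeSeries <- function(mat, path) {
  write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  tab <- read.table(path, header = TRUE, check.names = FALSE)
  as.matrix(tab)
}
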