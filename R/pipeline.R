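## End-to-end orchestration: simulate -> connect -> metrics -> stats ->
## report, deterministic under a single master seed.

#' Pipeline configuration
#'
#' Collects every pipeline toggle in one object: the cohort spec (simulate
#' mode), the proximity-exclusion radius, scrubbing bound, graph-metric
#' thresholds, Fisher-z and statistic-family switches, Louvain restarts,
#' the master seed and an optional output directory.
#'
#' @param spec A [cohortSpec()]; its seed is the pipeline master seed.
#' @param parc A [NetworkParcellation-class] (default the synthetic
#'   Power-style fixture) — the proximity exclusion is applied to it.
#' @param minDist Centre-proximity exclusion radius in mm.
#' @param maxScrub Scrubbing inclusion bound.
#' @param thresholds Edge densities for the graph metrics (strictly
#'   increasing, in (0, 1]); may be empty to skip graph metrics.
#' @param fisherZ Fisher-z averaging in system segregation.
#' @param test \code{"Wilks"} or \code{"Pillai"}.
#' @param nRestarts Louvain restarts.
#' @param measures Metric families to compute.
#' @param outputDir Optional directory for artifacts.
#' @return List of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(spec = cohortSpec(),
                           parc = powerLikeParcellation(),
                           minDist = 20, maxScrub = 0.30,
                           thresholds = seq(0.02, 0.10, by = 0.01),
                           fisherZ = TRUE, test = "Wilks",
                           nRestarts = 20L,
                           measures = c("network", "segregation", "graph"),
                           outputDir = NULL) {
  if (length(thresholds)) {
    if (any(diff(thresholds) <= 0) || any(thresholds <= 0) ||
        any(thresholds > 1))
      stop("thresholds must be strictly increasing within (0, 1]")
  }
  structure(list(spec = spec, parc = parc, minDist = minDist,
                 maxScrub = maxScrub, thresholds = thresholds,
                 fisherZ = fisherZ, test = test,
                 nRestarts = as.integer(nRestarts), measures = measures,
                 outputDir = outputDir),
            class = "PipelineConfig")
}

## Stable config hash for provenance (serialize deterministically to text).
.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[setdiff(names(config), "outputDir")], file = tmp,
       control = c("keepNA", "keepInteger"))
  unname(tools::md5sum(tmp))
}

## Long analysis frames from the metric table + manifest covariates.
.analysisData <- function(metricTable, manifest, analysis) {
  manifest$scrub_mean <- rowMeans(
    manifest[, grep("^scrub_", names(manifest)), drop = FALSE])
  meta <- manifest[, c("subject_id", "scrub_mean")]
  merge2 <- function(tab) merge(tab, meta, by = "subject_id", sort = FALSE)
  switch(analysis,
    pos_corr = {
      tab <- metricTable[metricTable$measure %in% c("w_pos", "b_pos"), ]
      ps <- attr(metricTable, "positiveSubset")
      if (!is.null(ps)) tab <- tab[tab$subject_id %in% ps, ]
      tab$direction <- ifelse(tab$measure == "w_pos", "within", "between")
      tab$network <- tab$network_or_system
      merge2(tab[, c("subject_id", "group", "domain", "network",
                     "direction", "value")])
    },
    neg_corr = {
      tab <- metricTable[metricTable$measure == "b_neg", ]
      tab$network <- tab$network_or_system
      merge2(tab[, c("subject_id", "group", "domain", "network", "value")])
    },
    segregation = {
      tab <- metricTable[metricTable$measure == "segregation" &
                           metricTable$network_or_system != "whole_brain", ]
      tab$system <- tab$network_or_system
      merge2(tab[, c("subject_id", "group", "domain", "system", "value")])
    },
    efficiency = ,
    modularity = {
      ms <- if (analysis == "efficiency") "global_efficiency" else
        "modularity"
      tab <- metricTable[metricTable$measure == ms, ]
      merge2(tab[, c("subject_id", "group", "domain", "threshold",
                     "value")])
    },
    stop("unknown analysis '", analysis, "'"))
}

#' Factorial analysis presets over the metric table
#'
#' Runs one of the study's five repeated-measures MANCOVA designs on a
#' metric table: \code{"pos_corr"} (domain x network x direction x group,
#' positive-subset subjects only), \code{"neg_corr"} (domain x network x
#' group), \code{"segregation"} (domain x system x group),
#' \code{"efficiency"} / \code{"modularity"} (domain x threshold x group),
#' all with the mean scrubbing fraction as covariate.
#'
#' @param metricTable From [computeMetricTable()].
#' @param manifest Subject manifest.
#' @param analysis Analysis name (see above).
#' @param test \code{"Wilks"} or \code{"Pillai"}.
#' @return [rmMancova()] result table.
#' @export
analysisMancova <- function(metricTable, manifest,
                            analysis = c("pos_corr", "neg_corr",
                                         "segregation", "efficiency",
                                         "modularity"),
                            test = "Wilks") {
  analysis <- match.arg(analysis)
  dat <- .analysisData(metricTable, manifest, analysis)
  within <- switch(analysis,
                   pos_corr = c("domain", "network", "direction"),
                   neg_corr = c("domain", "network"),
                   segregation = c("domain", "system"),
                   c("domain", "threshold"))
  rmMancova(dat, within = within, between = "group",
            covariates = "scrub_mean", test = test)
}

#' Brain-behaviour partial correlations
#'
#' For each connectivity metric and its matching-domain behavioural
#' z-score, computes the Pearson partial correlation controlling for years
#' of education and gender (numeric dummy), and a second set additionally
#' controlling for age.  No multiple-comparison correction is applied
#' (exploratory analysis).
#'
#' @param metricTable From [computeMetricTable()].
#' @param manifest Subject manifest with \code{z_<domain>}, \code{age},
#'   \code{gender}, \code{education}.
#' @return data.frame: \code{domain}, \code{measure},
#'   \code{network_or_system}, \code{threshold}, \code{r}, \code{p},
#'   \code{r_agectl}, \code{p_agectl}, \code{n}.
#' @export
behaviorCorrelations <- function(metricTable, manifest) {
  manifest$gender_num <- as.numeric(manifest$gender == "F")
  keys <- unique(metricTable[, c("domain", "measure", "network_or_system",
                                 "threshold")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- metricTable$domain == k$domain &
      metricTable$measure == k$measure &
      metricTable$network_or_system == k$network_or_system &
      (is.na(k$threshold) | (!is.na(metricTable$threshold) &
                               metricTable$threshold == k$threshold))
    tab <- metricTable[sel, c("subject_id", "value")]
    m <- merge(tab, manifest, by = "subject_id", sort = FALSE)
    z <- m[[paste0("z_", k$domain)]]
    ok <- stats::complete.cases(m$value, z)
    if (sum(ok) < 10L) return(NULL)
    base <- partialCorrelation(m$value[ok], z[ok],
                               m[ok, c("education", "gender_num")])
    agec <- partialCorrelation(m$value[ok], z[ok],
                               m[ok, c("education", "gender_num", "age")])
    data.frame(k, r = base$r, p = base$p, r_agectl = agec$r,
               p_agectl = agec$p, n = base$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' Executes simulate -> connect -> metrics -> stats on a configuration:
#' applies the proximity exclusion to the parcellation, simulates the
#' cohort manifest, filters subjects by scrubbing, simulates and
#' residualizes each included subject's time series, builds the metric
#' table, fits the five factorial analyses plus the brain-behaviour
#' correlations, and (optionally) writes every artifact with the config
#' hash and seed recorded.  Rerunning the same configuration reproduces
#' the manifest and metric table bit-identically.
#'
#' @param config A [pipelineConfig()].
#' @return List of class \code{"PipelineRun"}: \code{parc},
#'   \code{manifest}, \code{included}, \code{excluded},
#'   \code{metricTable}, \code{stats} (named list of MANCOVA tables),
#'   \code{behavior}, \code{demographics}, \code{provenance}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  spec <- config$spec
  parc <- applyProximityExclusion(config$parc, config$minDist)
  manifest <- simulateManifest(spec)
  filt <- filterSubjectsByScrubbing(manifest, config$maxScrub,
                                    domains = spec$domains)
  inc <- manifest[manifest$subject_id %in% filt$included, , drop = FALSE]
  designs <- lapply(setNames(spec$domains, spec$domains), function(d)
    domainTaskDesign(d, spec$taskRuns[[d]], blockLen = spec$blockLen))
  matrices <- vector("list", nrow(inc))
  names(matrices) <- inc$subject_id
  allSeeds <- .cohortSeeds(spec$seed, nrow(manifest))
  idxAll <- match(inc$subject_id, manifest$subject_id)
  for (i in seq_len(nrow(inc))) {
    tss <- tryCatch(
      simulateSubject(spec, inc[i, ], parc,
                      seed = allSeeds[idxAll[i]]),
      error = function(e) stop("stage simulate failed for subject ",
                               inc$subject_id[i], ": ",
                               conditionMessage(e)))
    matrices[[i]] <- tryCatch(
      subjectConnectivity(tss, designs),
      error = function(e) stop("stage connect failed for subject ",
                               inc$subject_id[i], ": ",
                               conditionMessage(e)))
  }
  metricTable <- computeMetricTable(matrices, parc, inc,
                                    measures = config$measures,
                                    thresholds = config$thresholds,
                                    fisherZ = config$fisherZ,
                                    nRestarts = config$nRestarts,
                                    seed = spec$seed)
  analyses <- c("pos_corr", "neg_corr", "segregation")
  if ("graph" %in% config$measures && length(config$thresholds))
    analyses <- c(analyses, "efficiency", "modularity")
  analyses <- analyses[vapply(analyses, function(a)
    switch(a,
           pos_corr = , neg_corr = "network" %in% config$measures,
           segregation = "segregation" %in% config$measures,
           TRUE), logical(1))]
  statsOut <- lapply(setNames(analyses, analyses), function(a)
    tryCatch(analysisMancova(metricTable, inc, a, test = config$test),
             error = function(e) stop("stage stats (", a, ") failed: ",
                                      conditionMessage(e))))
  behavior <- behaviorCorrelations(metricTable, inc)
  run <- list(parc = parc, manifest = manifest, included = filt$included,
              excluded = filt$excluded, metricTable = metricTable,
              stats = statsOut, behavior = behavior,
              demographics = demographicTable(inc),
              provenance = list(configHash = .configHash(config),
                                seed = spec$seed,
                                skippedGraph = !("graph" %in%
                                                   config$measures) ||
                                  !length(config$thresholds)))
  class(run) <- "PipelineRun"
  if (!is.null(config$outputDir)) .writeRunArtifacts(run, config)
  run
}

.writeRunArtifacts <- function(run, config) {
  dir <- config$outputDir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("# config_hash: %s seed: %d", run$provenance$configHash,
                  run$provenance$seed)
  writeLines(prov, file.path(dir, "provenance.txt"))
  writeManifest(run$manifest, file.path(dir, "manifest.tsv"))
  writeMetricTable(run$metricTable, file.path(dir, "metric_table.tsv"))
  for (a in names(run$stats))
    write.table(run$stats[[a]], file.path(dir, sprintf("stats_%s.tsv", a)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$behavior, file.path(dir, "behavior_correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(makeReport(run), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Human-readable summary report of a pipeline run
#'
#' Per-analysis effect tables (effect, F, dfs, p, significance mark) and
#' group-mean-by-network summaries of the positive/negative correlation
#' metrics and segregation.
#'
#' @param run A \code{"PipelineRun"} from [runPipeline()].
#' @param alpha Significance level for marking effects.
#' @return Character vector of report lines.
#' @export
makeReport <- function(run, alpha = 0.05) {
  lines <- c(sprintf("taskFC pipeline report (seed %d, config %s)",
                     run$provenance$seed, run$provenance$configHash),
             sprintf("Subjects: %d simulated, %d included, %d excluded by scrubbing",
                     nrow(run$manifest), length(run$included),
                     nrow(run$excluded)))
  if (is.null(run$metricTable) || !nrow(run$metricTable))
    return(c(lines, "no metrics computed"))
  if (isTRUE(run$provenance$skippedGraph))
    lines <- c(lines, "graph-metric stages skipped (no thresholds configured)")
  for (a in names(run$stats)) {
    st <- run$stats[[a]]
    lines <- c(lines, "", sprintf("== Analysis: %s (n = %d) ==", a,
                                  attr(st, "n")))
    for (i in seq_len(nrow(st))) {
      lines <- c(lines, if (is.na(st$p[i]))
        sprintf("  %-28s (not testable in this design)", st$effect[i])
        else sprintf("  %-28s F(%g, %.1f) = %8.3f  p = %.4g%s",
                     st$effect[i], st$df_num[i], st$df_den[i],
                     st$F[i], st$p[i], if (st$p[i] < alpha) "  *" else ""))
    }
  }
  mt <- run$metricTable
  netTab <- mt[mt$measure %in% c("w_pos", "b_pos", "b_neg"), ]
  if (nrow(netTab)) {
    lines <- c(lines, "", "== Group mean by network (averaged over domains) ==")
    agg <- aggregate(value ~ group + measure + network_or_system,
                     data = netTab, FUN = mean, na.rm = TRUE)
    for (msr in unique(agg$measure)) {
      sub <- agg[agg$measure == msr, ]
      wide <- reshape(sub, idvar = "network_or_system", timevar = "group",
                      direction = "wide", drop = "measure")
      names(wide) <- sub("^value\\.", "", names(wide))
      lines <- c(lines, sprintf("  [%s]", msr),
                 paste0("    ", capture.output(print(wide,
                                                     row.names = FALSE))))
    }
  }
  seg <- mt[mt$measure == "segregation", ]
  if (nrow(seg)) {
    agg <- aggregate(value ~ group + network_or_system, data = seg,
                     FUN = mean, na.rm = TRUE)
    lines <- c(lines, "", "== Mean system segregation by group ==",
               paste0("  ", capture.output(print(agg, row.names = FALSE))))
  }
  lines
}
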