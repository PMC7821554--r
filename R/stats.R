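## Follow-up univariate statistics, Bonferroni contrasts, partial
## correlations with behaviour, and the demographics summary table.

#' Follow-up one-way ANCOVA on a metric slice
#'
#' Univariate ANCOVA of a sliced metric (e.g. one network within one
#' domain) on the age-group factor, adjusting for the covariate; used to
#' probe significant interactions from [rmMancova()].
#'
#' @param data data.frame with columns \code{value}, the group column and
#'   optionally the covariate column; one row per subject.
#' @param between Group column name (default \code{"group"}).
#' @param covariate Covariate column name, or NULL for a plain one-way
#'   ANOVA.
#' @return One-row data.frame: \code{effect}, \code{F}, \code{df_num},
#'   \code{df_den}, \code{p}, \code{statistic_family}.
#' @export
followupAnova <- function(data, between = "group", covariate = "scrub_mean") {
  if (!nrow(data)) stop("empty slice")
  grp <- factor(data[[between]])
  if (any(table(grp) == 0L) || nlevels(grp) < 2L)
    stop("every group must be represented in the slice")
  if (!is.null(covariate) && covariate %in% names(data) &&
      sd(as.numeric(data[[covariate]])) > 0) {
    cv <- as.numeric(data[[covariate]])
    fit0 <- lm(data$value ~ cv)
    fit1 <- lm(data$value ~ cv + grp)
  } else {
    fit0 <- lm(data$value ~ 1)
    fit1 <- lm(data$value ~ grp)
  }
  av <- anova(fit0, fit1)
  data.frame(effect = between, F = av$F[2], df_num = av$Df[2],
             df_den = av$Res.Df[2], p = av$`Pr(>F)`[2],
             statistic_family = "univariate", stringsAsFactors = FALSE)
}

#' Covariate-adjusted pairwise group contrast with Bonferroni correction
#'
#' Tests the adjusted mean difference between two groups (linear model on
#' the covariate plus a group indicator) and Bonferroni-corrects over the
#' \code{m} contrasts examined within a domain (default: one per network).
#'
#' @param data data.frame with \code{value}, the group column and the
#'   covariate column.
#' @param groups Length-2 character vector, e.g. \code{c("YA", "OA")}.
#' @param m Number of comparisons corrected over (default 10).
#' @param between,covariate Column names.
#' @return One-row data.frame: \code{contrast}, \code{estimate}, \code{t},
#'   \code{df}, \code{p}, \code{corrected_p}, \code{m}.
#' @export
pairwiseGroupContrast <- function(data, groups, m = 10L, between = "group",
                                  covariate = "scrub_mean") {
  if (!is.numeric(m) || m < 1) stop("m must be at least 1")
  sub <- data[data[[between]] %in% groups, , drop = FALSE]
  if (!all(groups %in% sub[[between]]))
    stop("both groups must be present in the slice")
  ind <- as.numeric(sub[[between]] == groups[2])
  if (!is.null(covariate) && covariate %in% names(sub) &&
      sd(as.numeric(sub[[covariate]])) > 0) {
    fit <- lm(sub$value ~ as.numeric(sub[[covariate]]) + ind)
  } else {
    fit <- lm(sub$value ~ ind)
  }
  co <- summary(fit)$coefficients["ind", ]
  praw <- co["Pr(>|t|)"]
  data.frame(contrast = paste(groups, collapse = " vs "),
             estimate = unname(co["Estimate"]), t = unname(co["t value"]),
             df = fit$df.residual, p = unname(praw),
             corrected_p = min(1, m * unname(praw)), m = m,
             stringsAsFactors = FALSE)
}

#' Pearson partial correlation
#'
#' Correlates the least-squares residuals of \code{x} and \code{y} after
#' removing the covariates (intercept always included); with an empty
#' covariate set this is exactly the plain Pearson correlation.  The
#' p-value uses a t statistic with \code{n - 2 - k} degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix / data.frame of covariates, or NULL.
#' @return data.frame: \code{r}, \code{p}, \code{n}, \code{df},
#'   \code{n_covariates}; \code{r} is \code{NA} with a reason attribute
#'   when a residual variance is zero.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  ok <- if (is.null(covariates)) stats::complete.cases(x, y) else
    stats::complete.cases(x, y, covariates)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sx0 <- sd(x); sy0 <- sd(y)
  k <- 0L
  if (!is.null(covariates)) {
    Z <- as.matrix(as.data.frame(covariates))[ok, , drop = FALSE]
    storage.mode(Z) <- "double"
    k <- ncol(Z)
    qrZ <- qr(cbind(1, Z))
    x <- qr.resid(qrZ, x)
    y <- qr.resid(qrZ, y)
  }
  if (n <= k + 2L) stop("need n > number of covariates + 2")
  if (sd(x) <= 1e-10 * max(sx0, 1) || sd(y) <= 1e-10 * max(sy0, 1)) {
    out <- data.frame(r = NA_real_, p = NA_real_, n = n, df = n - 2L - k,
                      n_covariates = k)
    attr(out, "reason") <- "zero residual variance"
    return(out)
  }
  r <- cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  data.frame(r = r, p = 2 * pt(-abs(tval), df), n = n, df = df,
             n_covariates = k)
}

#' Demographics and behaviour summary by age group
#'
#' Per-group means and SDs for age, education and the per-domain behaviour
#' z-scores with one-way ANOVA p-values, plus percentage female with a
#' chi-square test of homogeneity.
#'
#' @param manifest Subject manifest (see [simulateManifest()]).
#' @return data.frame: one row per variable, columns \code{variable},
#'   one \code{<group>} column per group (formatted mean (SD), or \%F for
#'   gender) and \code{p}.
#' @export
demographicTable <- function(manifest) {
  grp <- factor(manifest$group, levels = unique(manifest$group))
  contVars <- c("age", "education",
                grep("^z_", names(manifest), value = TRUE))
  rows <- lapply(contVars, function(v) {
    x <- as.numeric(manifest[[v]])
    m <- tapply(x, grp, mean)
    s <- tapply(x, grp, sd)
    p <- anova(lm(x ~ grp))$`Pr(>F)`[1]
    out <- data.frame(variable = v, stringsAsFactors = FALSE)
    for (g in levels(grp))
      out[[g]] <- sprintf("%.3f (%.3f)", m[[g]], s[[g]])
    out$p <- p
    out
  })
  pf <- tapply(manifest$gender == "F", grp, mean) * 100
  gtab <- table(grp, manifest$gender)
  gp <- if (ncol(gtab) > 1L)
    suppressWarnings(chisq.test(gtab)$p.value) else NA_real_
  grow <- data.frame(variable = "gender_pct_female",
                     stringsAsFactors = FALSE)
  for (g in levels(grp)) grow[[g]] <- sprintf("%.2f%%", pf[[g]])
  grow$p <- gp
  out <- rbind(do.call(rbind, rows), grow)
  rownames(out) <- NULL
  out
}
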