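## Fixture: long metric data with configurable group effect on the cells.
makeLongData <- function(n = 40, cells = expand.grid(
                           domain = c("D1", "D2", "D3"),
                           network = c("N1", "N2"),
                           stringsAsFactors = FALSE),
                         groupShift = 0, seed = 1) {
  set.seed(seed)
  groups <- c("YA", "yMA", "oMA", "OA")
  subj <- sprintf("P%03d", seq_len(n))
  grp <- rep(groups, length.out = n)
  cov <- runif(n, 0, 0.3)
  shift <- groupShift * (match(grp, groups) - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(subject_id = subj[i], group = grp[i], scrub_mean = cov[i],
               cells, value = rnorm(nrow(cells), mean = shift[i]),
               stringsAsFactors = FALSE)))
}

test_that("MANCOVA Wilks statistics agree with the car::Anova oracle", {
  skip_if_not_installed("car")
  long <- makeLongData(40, groupShift = 0.3, seed = 5)
  res <- rmMancova(long, within = c("domain", "network"))
  ## independent multivariate fit via car
  cells <- unique(long[, c("domain", "network")])
  key <- paste(long$domain, long$network)
  ckey <- paste(cells$domain, cells$network)
  subj <- unique(long$subject_id)
  Y <- matrix(NA, length(subj), nrow(cells))
  Y[cbind(match(long$subject_id, subj), match(key, ckey))] <- long$value
  meta <- long[!duplicated(long$subject_id), ]
  g <- factor(meta$group, levels = unique(meta$group))
  cov <- meta$scrub_mean
  mod <- lm(Y ~ g + cov, contrasts = list(g = "contr.sum"))
  idata <- cells
  idata$domain <- factor(idata$domain, levels = unique(idata$domain))
  idata$network <- factor(idata$network, levels = unique(idata$network))
  av <- suppressWarnings(summary(car::Anova(
    mod, idata = idata, idesign = ~ domain * network, type = 3,
    test.statistic = "Wilks"), multivariate = TRUE))$multivariate.tests
  lam <- function(nm) {
    o <- av[[nm]]
    det(o$SSPE) / det(o$SSPE + o$SSPH)
  }
  getStat <- function(effect) res$statistic[res$effect == effect]
  expect_equal(getStat("group"), lam("g"), tolerance = 1e-10)
  expect_equal(getStat("scrub_mean"), lam("cov"), tolerance = 1e-10)
  expect_equal(getStat("domain"), lam("domain"), tolerance = 1e-10)
  expect_equal(getStat("domain:group"), lam("g:domain"), tolerance = 1e-10)
  expect_equal(getStat("network:group"), lam("g:network"),
               tolerance = 1e-10)
  expect_equal(getStat("domain:network:group"), lam("g:domain:network"),
               tolerance = 1e-10)
})

test_that("MANCOVA between-group test collapses to the univariate ANCOVA F", {
  long <- makeLongData(36, groupShift = 0.4, seed = 7)
  res <- rmMancova(long, within = c("domain", "network"))
  ## subject means tested against group + covariate: exact F identity
  avg <- aggregate(value ~ subject_id + group + scrub_mean, data = long,
                   FUN = mean)
  fu <- followupAnova(avg, covariate = "scrub_mean")
  rg <- res[res$effect == "group", ]
  expect_equal(rg$F, fu$F, tolerance = 1e-10)
  expect_equal(rg$p, fu$p, tolerance = 1e-10)
  expect_equal(c(rg$df_num, rg$df_den), c(fu$df_num, fu$df_den))
})

test_that("a zero covariate reproduces the covariate-free model exactly", {
  long <- makeLongData(32, groupShift = 0.2, seed = 9)
  long$scrub_mean <- 0
  res0 <- rmMancova(long, within = c("domain", "network"),
                    covariates = "scrub_mean")
  res1 <- rmMancova(long, within = c("domain", "network"),
                    covariates = character(0))
  shared <- intersect(res0$effect, res1$effect)
  expect_equal(res0$F[match(shared, res0$effect)],
               res1$F[match(shared, res1$effect)], tolerance = 1e-10)
})

test_that("MANCOVA results are invariant to subject and row ordering", {
  long <- makeLongData(32, groupShift = 0.3, seed = 11)
  res <- rmMancova(long, within = c("domain", "network"))
  perm <- sample(nrow(long))
  res2 <- rmMancova(long[perm, ], within = c("domain", "network"))
  expect_equal(res2$F[match(res$effect, res2$effect)], res$F,
               tolerance = 1e-9)
})

test_that("Pillai option runs and matches Wilks for single-df hypotheses", {
  long <- makeLongData(32, seed = 13)
  w <- rmMancova(long, within = c("domain", "network"), test = "Wilks")
  p <- rmMancova(long, within = c("domain", "network"), test = "Pillai")
  ## covariate test has q = 1: Wilks and Pillai F coincide
  expect_equal(p$F[p$effect == "scrub_mean"],
               w$F[w$effect == "scrub_mean"], tolerance = 1e-9)
})

test_that("follow-up ANOVA reduces to known identities", {
  set.seed(15)
  ## null slice: group means forced equal
  d <- data.frame(group = rep(c("YA", "OA"), each = 20),
                  value = rep(rnorm(20), 2))
  fu <- followupAnova(d, covariate = NULL)
  expect_lt(fu$F, 1e-12)
  ## two groups, no covariate: F = t^2
  d2 <- data.frame(group = rep(c("YA", "OA"), each = 15),
                   value = rnorm(30, mean = rep(c(0, 0.8), each = 15)))
  fu2 <- followupAnova(d2, covariate = NULL)
  tt <- t.test(value ~ group, data = d2, var.equal = TRUE)
  expect_equal(fu2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(followupAnova(d2[d2$group == "YA", ]), "group")
})

test_that("pairwise contrasts apply the Bonferroni correction with cap", {
  set.seed(17)
  d <- data.frame(group = rep(c("YA", "OA"), each = 30),
                  scrub_mean = runif(60),
                  value = rnorm(60, rep(c(0, 1), each = 30)))
  pc <- pairwiseGroupContrast(d, c("YA", "OA"), m = 10)
  expect_equal(pc$corrected_p, min(1, 10 * pc$p))
  ## explicit arithmetic on the correction rule
  expect_equal(min(1, 10 * 0.004), 0.04)
  expect_equal(min(1, 10 * 0.2), 1.0)
  expect_error(pairwiseGroupContrast(d, c("YA", "OA"), m = 0), "m must")
  expect_error(pairwiseGroupContrast(d[d$group == "YA", ], c("YA", "OA")),
               "present")
})

test_that("partial correlation equals plain Pearson with no covariates", {
  set.seed(19)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  pc <- partialCorrelation(x, y)
  expect_identical(pc$r, cor(x, y))
  expect_equal(pc$df, 48L)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("partial correlation matches the recursive formula oracle", {
  set.seed(23)
  for (rep in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    Z <- cbind(z1 = rnorm(12), z2 = rnorm(12))
    pc <- partialCorrelation(x, y, Z)
    expect_equal(pc$r, oraclePartialCor(x, y, Z), tolerance = 1e-12)
  }
  ## affine rescaling of covariates leaves r unchanged
  x <- rnorm(30); y <- rnorm(30); Z <- cbind(rnorm(30))
  expect_equal(partialCorrelation(x, y, 5 * Z + 2)$r,
               partialCorrelation(x, y, Z)$r, tolerance = 1e-12)
  ## degenerate: y equals a covariate exactly
  z <- rnorm(20)
  res <- partialCorrelation(rnorm(20), z, cbind(z))
  expect_true(is.na(res$r))
  expect_error(partialCorrelation(rnorm(3), rnorm(3), cbind(rnorm(3))),
               "n >")
})

test_that("demographics table summarises groups and flags planted trends", {
  spec <- cohortSpec(groupSizes = c(YA = 40L, yMA = 40L, oMA = 40L,
                                    OA = 40L),
                     volumes = c(VOCAB = 20L, SPEED = 20L, FLUID = 20L,
                                 MEM = 20L),
                     behaviorMeans = matrix(c(0, 0, 0, 0,
                                              -0.6, -0.2, 0.2, 0.6,
                                              0, 0, 0, 0, 0, 0, 0, 0),
                                            4, 4,
                                            dimnames = list(
                                              c("YA", "yMA", "oMA", "OA"),
                                              analysisDomains())),
                     seed = 29L)
  man <- simulateManifest(spec)
  tab <- demographicTable(man)
  expect_setequal(tab$variable,
                  c("age", "education", "gender_pct_female",
                    paste0("z_", analysisDomains())))
  ## age separates by construction; planted SPEED trend detected
  expect_lt(tab$p[tab$variable == "age"], 1e-10)
  expect_lt(tab$p[tab$variable == "z_SPEED"], 0.001)
  ## identically generated gender proportions: no systematic rejection
  expect_gt(tab$p[tab$variable == "gender_pct_female"], 0.001)
  ## education generated identically across groups
  expect_gt(tab$p[tab$variable == "education"], 0.001)
})
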