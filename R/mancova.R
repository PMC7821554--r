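## Repeated-measures factorial MANCOVA via the multivariate linear model:
## wide response matrix Y (subjects x within-cells), design X = intercept +
## sum-to-zero group dummies + covariate(s).  Each within effect is tested
## by post-multiplying Y with a Kronecker contrast matrix M and testing
## coefficient rows L of the transformed model (type III), using Wilks'
## lambda with Rao's F approximation (Pillai's trace available).

## Orthonormal polynomial-style contrasts (l x (l-1)) or averaging vector.
.withinContrast <- function(nLevels, effect = TRUE) {
  if (!effect) return(matrix(1 / nLevels, nLevels, 1L))
  C <- stats::contr.helmert(nLevels)
  qr.Q(qr(C))          # orthonormal columns, each orthogonal to constant
}

## M for a subset S of within factors, cells ordered by expand.grid
## (first factor varies fastest => Kronecker runs last factor leftmost).
.kronContrast <- function(withinLevels, subset) {
  mats <- lapply(names(withinLevels), function(f)
    .withinContrast(length(withinLevels[[f]]), f %in% subset))
  Reduce(kronecker, rev(mats))
}

## Wilks lambda + Rao F for hypothesis rows L on transformed responses YM.
.multivariateTest <- function(Y, X, L, test = "Wilks") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design matrix in MANCOVA")
  B <- qr.coef(qrX, Y)
  Ehat <- crossprod(qr.resid(qrX, Y))
  XtXinv <- chol2inv(qr.R(qrX))
  LB <- L %*% B
  Hhat <- t(LB) %*% solve(L %*% XtXinv %*% t(L), LB)
  p <- ncol(Y)
  q <- nrow(L)
  v <- nrow(Y) - qrX$rank
  if (v < p) stop("not enough error df for ", p, " transformed responses")
  if (rcond(Ehat) < 1e-12)
    stop("collinear responses within the transformed cells ",
         "(singular error SSCP); effect not testable")
  if (test == "Wilks") {
    lam <- det(Ehat) / det(Ehat + Hhat)
    s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
    m <- v - (p - q + 1) / 2
    df1 <- p * q
    df2 <- m * s - (p * q) / 2 + 1
    Fstat <- ((1 - lam^(1 / s)) / lam^(1 / s)) * df2 / df1
    stat <- lam
  } else {
    ev <- Re(eigen(solve(Ehat, Hhat), only.values = TRUE)$values)
    ev <- pmax(ev, 0)
    V <- sum(ev / (1 + ev))
    s <- min(p, q)
    mm <- (abs(p - q) - 1) / 2
    nn <- (v - p - 1) / 2
    df1 <- s * (2 * mm + s + 1)
    df2 <- s * (2 * nn + s + 1)
    Fstat <- ((2 * nn + s + 1) / (2 * mm + s + 1)) * V / (s - V)
    stat <- V
  }
  pval <- pf(Fstat, df1, df2, lower.tail = FALSE)
  data.frame(statistic = stat, F = Fstat, df_num = df1, df_den = df2,
             p = pval)
}

#' Repeated-measures factorial MANCOVA
#'
#' Reshapes a long metric table (one row per subject per within-factor
#' cell) to a subject-by-cell response matrix, fits a multivariate linear
#' model on the between-subject factor (sum-to-zero coding) plus
#' covariates, and tests, via Wilks' lambda with Rao's F approximation
#' (type III): the between-factor main effect, each covariate, every
#' within-factor effect and within-by-between interaction.  Subjects with
#' any missing cell are dropped (complete-case) with a message.
#'
#' @param data Long data.frame with columns \code{subject_id},
#'   \code{value}, the within-factor columns, the between column and any
#'   covariate columns (constant within subject).
#' @param within Character vector naming the within-subject factor
#'   columns (cell levels taken in order of first appearance).
#' @param between Name of the between-subjects factor column (default
#'   \code{"group"}).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param test \code{"Wilks"} (default) or \code{"Pillai"}.
#' @return data.frame of test results: \code{effect}, \code{statistic}
#'   (lambda or trace), \code{F}, \code{df_num}, \code{df_den}, \code{p},
#'   \code{statistic_family}, plus attributes \code{"n"} (subjects used)
#'   and \code{"dropped"}.
#' @export
rmMancova <- function(data, within, between = "group",
                      covariates = "scrub_mean",
                      test = c("Wilks", "Pillai")) {
  test <- match.arg(test)
  covariates <- covariates[covariates %in% names(data)]
  withinLevels <- lapply(within, function(f) unique(data[[f]]))
  names(withinLevels) <- within
  cells <- expand.grid(withinLevels, stringsAsFactors = FALSE)
  cellKey <- do.call(paste, c(cells, sep = "\r"))
  rowKey <- do.call(paste, c(data[within], sep = "\r"))
  subjects <- unique(data$subject_id)
  Y <- matrix(NA_real_, length(subjects), nrow(cells),
              dimnames = list(subjects, NULL))
  Y[cbind(match(data$subject_id, subjects), match(rowKey, cellKey))] <-
    data$value
  keep <- stats::complete.cases(Y)
  dropped <- subjects[!keep]
  if (length(dropped))
    message(length(dropped), " subject(s) dropped (incomplete cells)")
  Y <- Y[keep, , drop = FALSE]
  subjects <- subjects[keep]
  if (nrow(Y) < 4L) stop("too few complete subjects for the MANCOVA")
  meta <- data[!duplicated(data$subject_id),
               c("subject_id", between, covariates), drop = FALSE]
  meta <- meta[match(subjects, meta$subject_id), , drop = FALSE]
  grp <- factor(meta[[between]], levels = unique(meta[[between]]))
  X <- model.matrix(~ grp, contrasts.arg = list(grp = "contr.sum"))
  colnames(X) <- c("(Intercept)", paste0(between, seq_len(nlevels(grp) - 1)))
  for (cv in covariates) {
    x <- as.numeric(meta[[cv]])
    if (sd(x) > 0) X <- cbind(X, setNames(data.frame(x), cv)[[1]])
    else next
    colnames(X)[ncol(X)] <- cv
  }
  betweenRows <- which(startsWith(colnames(X), between))
  results <- list()
  addResult <- function(effect, res) {
    results[[length(results) + 1L]] <<-
      cbind(data.frame(effect = effect, stringsAsFactors = FALSE), res)
  }
  runTest <- function(M, rows, effect) {
    L <- diag(ncol(X))[rows, , drop = FALSE]
    res <- tryCatch(.multivariateTest(Y %*% M, X, L, test = test),
                    error = function(e) {
                      message("effect '", effect, "' not testable: ",
                              conditionMessage(e))
                      data.frame(statistic = NA_real_, F = NA_real_,
                                 df_num = NA_real_, df_den = NA_real_,
                                 p = NA_real_)
                    })
    addResult(effect, res)
  }
  Mavg <- .kronContrast(withinLevels, character(0))
  runTest(Mavg, betweenRows, between)
  for (cv in intersect(covariates, colnames(X)))
    runTest(Mavg, which(colnames(X) == cv), cv)
  subsets <- unlist(lapply(seq_along(within), function(k)
    combn(within, k, simplify = FALSE)), recursive = FALSE)
  for (S in subsets) {
    M <- .kronContrast(withinLevels, S)
    nm <- paste(S, collapse = ":")
    runTest(M, 1L, nm)
    runTest(M, betweenRows, paste(nm, between, sep = ":"))
  }
  out <- do.call(rbind, results)
  out$statistic_family <- "multivariate"
  attr(out, "n") <- nrow(Y)
  attr(out, "dropped") <- dropped
  attr(out, "test") <- test
  rownames(out) <- NULL
  out
}
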