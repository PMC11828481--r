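.testResult <- function(test, statistic, df, p.value, ...) {
  structure(c(list(test = test, statistic = statistic, df = df,
                   p.value = p.value), list(...)),
            class = "synphen_test")
}

#' @export
print.synphen_test <- function(x, ...) {
  dfTxt <- paste(signif(unlist(x$df), 6), collapse = ", ")
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.4g\n",
              x$test, x$statistic, dfTxt, x$p.value))
  invisible(x)
}

#' Mixed two-way ANOVA with a matched within-subject factor
#'
#' The design used for matched EPSC measures: each cell contributes one value
#' per level of a within-subject factor (e.g. the -90 mV and +50 mV
#' measurements), and cells are nested in a between-subject sleep condition.
#' Reports the condition main effect (between stratum), the within-factor
#' main effect and the condition-by-factor interaction (within stratum), with
#' an optional Greenhouse-Geisser sphericity correction producing fractional
#' degrees of freedom (for a two-level within factor epsilon is exactly 1).
#'
#' @param data data.frame with one row per cell and within-level.
#' @param value,cell,within,between column names (character) of the response,
#'   cell identifier, within-subject factor and between-subject factor.
#' @param ggCorrection apply the Greenhouse-Geisser epsilon to the
#'   within-stratum degrees of freedom.
#' @return data.frame with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `p`, `epsilon`.
#' @export
twoWayMixedAnova <- function(data, value = "value", cell = "cell_id",
                             within = "measurement", between = "condition",
                             ggCorrection = FALSE) {
  d <- data.frame(
    value = data[[value]],
    cell = factor(data[[cell]]),
    within = factor(data[[within]]),
    between = factor(data[[between]]))
  if (anyNA(d)) stop("missing values in the ANOVA input")
  tab <- table(d$cell, d$within)
  bad <- rownames(tab)[rowSums(tab != 1L) > 0L]
  if (length(bad)) {
    stop("unbalanced within-subject data for cells: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::aov(value ~ between * within + Error(cell / within), data = d)
  sm <- summary(fit)
  betweenTab <- as.data.frame(sm[["Error: cell"]][[1L]])
  withinTab <- as.data.frame(sm[["Error: cell:within"]][[1L]])
  grab <- function(tab, pattern) {
    i <- grep(pattern, trimws(rownames(tab)))[1L]
    as.numeric(tab[i, c("Df", "F value")])
  }
  resid <- function(tab) {
    i <- grep("Residuals", trimws(rownames(tab)))[1L]
    as.numeric(tab[i, "Df"])
  }
  eps <- 1
  if (ggCorrection) eps <- .ggEpsilon(d)
  mk <- function(effect, tab, pattern, correct) {
    x <- grab(tab, pattern)
    df1 <- x[1L]
    df2 <- resid(tab)
    f <- x[2L]
    e <- if (correct) eps else 1
    data.frame(effect = effect, F = f, df1 = df1 * e, df2 = df2 * e,
               p = stats::pf(f, df1 * e, df2 * e, lower.tail = FALSE),
               epsilon = if (correct) eps else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    mk("between", betweenTab, "^between$", FALSE),
    mk("within", withinTab, "^within$", ggCorrection),
    mk("interaction", withinTab, "^between:within$", ggCorrection))
  rownames(out) <- NULL
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# repeated measures; 1 when the within factor has two levels.
.ggEpsilon <- function(d) {
  wide <- stats::reshape(d, idvar = "cell", timevar = "within",
                         direction = "wide",
                         v.names = "value", drop = "between")
  grp <- d$between[match(wide$cell, d$cell)]
  Y <- as.matrix(wide[, -1L, drop = FALSE])
  k <- ncol(Y)
  if (k < 3L) return(1)
  S <- matrix(0, k, k)
  df <- 0
  for (g in levels(grp)) {
    Yg <- Y[grp == g, , drop = FALSE]
    if (nrow(Yg) > 1L) {
      S <- S + stats::cov(Yg) * (nrow(Yg) - 1L)
      df <- df + nrow(Yg) - 1L
    }
  }
  S <- S / df
  # orthonormal contrasts
  C <- t(stats::contr.helmert(k)) / sqrt(colSums(stats::contr.helmert(k)^2))
  M <- C %*% S %*% t(C)
  (sum(diag(M)))^2 / ((k - 1) * sum(M * M))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation, for
#' comparing a measure (e.g. AMPA/NMDA ratio or failure-rate ratio) across
#' the sleep-condition cohorts.
#'
#' @param values numeric vector, or a list of group samples.
#' @param groups group labels (ignored when `values` is a list).
#' @return a `synphen_test` with `statistic` (H), `df` and `p.value`.
#' @export
kruskalWallis <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  kt <- stats::kruskal.test(values, factor(groups))
  if (!is.finite(kt$statistic)) {
    # all values identical: H is 0 by convention
    return(.testResult("Kruskal-Wallis", 0, as.numeric(kt$parameter), 1))
  }
  .testResult("Kruskal-Wallis", as.numeric(kt$statistic),
              as.numeric(kt$parameter), kt$p.value)
}

#' Two-stage linear step-up FDR procedure (Benjamini-Krieger-Yekutieli)
#'
#' Stage 1 runs a Benjamini-Hochberg step-up at level q' = q/(1+q); the
#' number of non-rejections estimates the number of true nulls m0. If nothing
#' is rejected the procedure stops with no discoveries, if everything is
#' rejected all hypotheses are discovered; otherwise stage 2 reruns the
#' step-up at level q'·m/m0. Because the stage-2 level is at least q', the
#' rejection set always contains the plain BH rejections at level q' (it
#' usually, but not always, contains the BH rejections at level q: when
#' stage 1 rejects nothing the procedure stops even if BH at the slightly
#' higher level q would have fired).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param q target false-discovery rate (default 0.05).
#' @return list with `rejected` (logical, original order), `m0` (estimated
#'   true nulls), `adjusted` (stage-2 step-up adjusted values, comparable to
#'   q/(1+q)) and `qPrime`.
#' @export
bkyTwoStage <- function(p, q = 0.05) {
  stopifnot(q > 0, q < 1)
  m <- length(p)
  if (m == 0L) {
    return(list(rejected = logical(), m0 = 0L,
                adjusted = numeric(), qPrime = q / (1 + q)))
  }
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  qPrime <- q / (1 + q)
  stepUp <- function(p, level) {
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= seq_len(m) * level / m)
    rej <- logical(m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  r1 <- sum(stepUp(p, qPrime))
  m0 <- m - r1
  if (r1 == 0L) {
    rejected <- logical(m)
  } else if (r1 == m) {
    rejected <- rep(TRUE, m)
  } else {
    rejected <- stepUp(p, qPrime * m / m0)
  }
  # reject  <=>  adjusted <= q/(1+q), in every branch
  adj <- stats::p.adjust(p, method = "BH") * m0 / m
  list(rejected = rejected, m0 = as.integer(m0),
       adjusted = pmin(1, adj), qPrime = qPrime)
}

#' Sidak multiple-comparison adjustment
#'
#' @param p numeric vector of p-values.
#' @param m family size (default `length(p)`).
#' @return adjusted p-values, 1 - (1 - p)^m.
#' @export
sidakAdjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  1 - (1 - p)^m
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired signed-rank test (e.g. per-cell-type median UMIs, control sleep vs
#' sleep deprivation). Zero differences are dropped; the exact null
#' distribution is used up to `exactMax` pairs (when the ranks are untied),
#' the normal approximation beyond.
#'
#' @param x,y paired numeric vectors.
#' @param exactMax switch to the normal approximation above this n
#'   (default 25).
#' @param alternative passed to [stats::wilcox.test()].
#' @return a `synphen_test` with `statistic` (V, sum of positive ranks),
#'   `minStatistic` (the smaller of the positive/negative rank sums), `n`
#'   (pairs after dropping zero differences) and `p.value`.
#' @export
wilcoxonMatchedPairs <- function(x, y, exactMax = 25,
                                 alternative = "two.sided") {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) stop("AllTies: all paired differences are zero")
  n <- length(d)
  wt <- suppressWarnings(stats::wilcox.test(
    d, exact = n <= exactMax, correct = n > exactMax,
    alternative = alternative))
  v <- as.numeric(wt$statistic)
  res <- .testResult("Wilcoxon matched-pairs", v, NA_real_, wt$p.value)
  res$minStatistic <- min(v, n * (n + 1) / 2 - v)
  res$n <- n
  res
}

#' Chi-square test with Yates continuity correction on a 2x2 table
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return a `synphen_test` with the corrected chi-square statistic, 1
#'   degree of freedom and the p-value.
#' @export
chiSquareYates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  .testResult("Chi-square (Yates)", as.numeric(ct$statistic),
              as.numeric(ct$parameter), ct$p.value)
}
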