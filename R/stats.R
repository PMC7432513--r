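## The statistical battery applied to movement values and observer counts:
## Levene's homogeneity test (mean-centred), a Levene-gated two-sample t-test
## (pooled Student's form when variances are homogeneous, Welch's form when
## not), Cohen's d with the conventional magnitude bands, rank-based ROC AUC
## with accuracy bands, and unweighted Cohen's kappa for two observers'
## behaviour counts.

#' Levene's test for homogeneity of variances (two samples)
#'
#' One-way ANOVA on absolute deviations from the group means (mean-centred
#' Levene). Used to gate the choice between the pooled Student's t and
#' Welch's t in [twoSampleT()].
#'
#' @param x,y Numeric samples with at least 2 finite values each.
#' @return List with elements \code{F} and \code{p}. Fully degenerate input
#'   (all deviations equal in both groups) returns \code{F = 0, p = 1}.
#' @examples
#' leveneTest2(c(1, 2, 3, 4), c(1, 1, 1, 9))
#' @export
leveneTest2 <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 finite values")
  zx <- abs(x - mean(x)); zy <- abs(y - mean(y))
  ## degenerate cases: equal mean deviations (e.g. identical samples) carry
  ## no evidence against homogeneity; zero within-group spread with unequal
  ## mean deviations is infinite evidence
  if (mean(zx) == mean(zy)) return(list(F = 0, p = 1))
  withinSS <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  if (withinSS == 0) return(list(F = Inf, p = 0))
  z <- c(zx, zy)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  a <- suppressWarnings(anova(lm(z ~ g)))  # tiny-n fits can be near-perfect
  Fv <- unname(a[["F value"]][1L]); pv <- unname(a[["Pr(>F)"]][1L])
  if (is.infinite(Fv)) pv <- 0
  list(F = Fv, p = pv)
}

#' Levene-gated two-sample t-test
#'
#' Student's two-sample t-test with the variance rule used throughout the
#' report tables: \code{"auto"} applies mean-centred Levene at level
#' \code{alpha} and uses the pooled-variance Student's t when homogeneity is
#' not rejected, Welch's t (Welch-Satterthwaite df) when it is. \code{t > 0}
#' when \code{mean(x) > mean(y)}.
#'
#' @param x,y Numeric samples (>= 2 finite values each).
#' @param varianceRule \code{"auto"}, \code{"pooled"} or \code{"welch"}.
#' @param alpha Gate level for the Levene test under \code{"auto"}.
#' @return List with \code{t}, \code{df}, \code{p}, \code{method}
#'   (\code{"pooled"} or \code{"welch"}) and the gating \code{levene_F},
#'   \code{levene_p}. Zero pooled variance with unequal means yields
#'   \code{t = +/-Inf, p = 0} (explicit infinite separation).
#' @examples
#' twoSampleT(rnorm(20), rnorm(20, 1))
#' @export
twoSampleT <- function(x, y, varianceRule = c("auto", "pooled", "welch"),
                       alpha = 0.05) {
  varianceRule <- match.arg(varianceRule)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 finite values")
  lv <- leveneTest2(x, y)
  method <- switch(varianceRule,
                   pooled = "pooled", welch = "welch",
                   auto = if (lv$p < alpha) "welch" else "pooled")
  if (var(x) == 0 && var(y) == 0) {
    df <- length(x) + length(y) - 2
    res <- if (mean(x) == mean(y)) list(t = 0, df = df, p = 1)
           else list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0)
  } else {
    tt <- t.test(x, y, var.equal = (method == "pooled"))
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  c(res, list(method = method, levene_F = lv$F, levene_p = lv$p))
}

#' Two-sample t-test from summary statistics
#'
#' The same test computed from printed group summaries (means, SDs, sizes),
#' as needed to re-derive the values of published tables.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (\code{n >= 2},
#'   \code{sd >= 0}).
#' @param varianceRule \code{"pooled"} (Student) or \code{"welch"}.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @examples
#' # pooled t for experimental (M 8.50, SD 4.71, n 32)
#' # vs control (M 5.27, SD 4.65, n 33):
#' twoSampleTSummary(8.50, 4.71, 32, 5.27, 4.65, 33)$t  # ~2.78
#' @export
twoSampleTSummary <- function(mean1, sd1, n1, mean2, sd2, n2,
                              varianceRule = c("pooled", "welch")) {
  varianceRule <- match.arg(varianceRule)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (varianceRule == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    a <- sd1^2 / n1; b <- sd2^2 / n2
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
    se <- sqrt(a + b)
  }
  if (se == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean1 - mean2) * Inf, df = df, p = 0))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cohen's d from group summaries
#'
#' Unsigned standardized mean difference
#' \eqn{d = |m_1 - m_2| / s_{pool}}. With \code{weighting = "df"} the pooled
#' SD weights the group variances by their degrees of freedom,
#' \eqn{s^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}; with
#' \code{"equal"} the two variances are averaged,
#' \eqn{s^2 = (s_1^2+s_2^2)/2}, the form needed when the per-group sizes
#' behind a printed table are unknown.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries. \code{n1}, \code{n2} are
#'   ignored under \code{"equal"} weighting.
#' @param weighting \code{"df"} (default) or \code{"equal"}.
#' @return Non-negative number. Zero pooled SD returns 0 for equal means and
#'   \code{Inf} (explicit infinite effect) for unequal means.
#' @examples
#' cohensD(8.50, 4.71, 32, 5.27, 4.65, 33)                     # 0.69
#' cohensD(8.92, 4.88, 25, 16.52, 12.54, 25, weighting = "equal")  # 0.80
#' @export
cohensD <- function(mean1, sd1, n1, mean2, sd2, n2,
                    weighting = c("df", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(sd1 >= 0, sd2 >= 0)
  if (weighting == "df") {
    stopifnot(n1 >= 2, n2 >= 2)
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  } else {
    sp2 <- (sd1^2 + sd2^2) / 2
  }
  if (sp2 == 0) {
    if (mean1 == mean2) return(0)
    return(Inf)
  }
  abs(mean1 - mean2) / sqrt(sp2)
}

#' Magnitude band of a Cohen's d
#'
#' Conventional interpretation bands: \code{d < 0.20} is below the threshold
#' of a relevant effect; \code{0.20 <= d <= 0.50} small; \code{0.50 < d <=
#' 0.80} moderate; \code{d > 0.80} large.
#'
#' @param d Non-negative effect size(s).
#' @return Character vector of band labels.
#' @examples
#' classifyD(c(0.18, 0.37, 0.69, 1.12))
#' @export
classifyD <- function(d) {
  stopifnot(all(d >= 0, na.rm = TRUE))
  out <- rep(NA_character_, length(d))
  out[d < 0.20] <- "below_threshold"
  out[d >= 0.20 & d <= 0.50] <- "small"
  out[d > 0.50 & d <= 0.80] <- "moderate"
  out[d > 0.80] <- "large"
  out
}

#' ROC area under the curve (rank form)
#'
#' The probability that a random draw from \code{positives} exceeds a random
#' draw from \code{negatives}, counting ties as one half: the normalized
#' Mann-Whitney U statistic, computed from midranks. Identical to the area
#' under the empirical ROC curve, with exact tie handling.
#'
#' @param positives,negatives Non-empty numeric samples.
#' @return Number in \code{[0, 1]}.
#' @examples
#' rocAuc(c(2, 3, 4), c(1, 2, 3))  # 7/9
#' @export
rocAuc <- function(positives, negatives) {
  positives <- positives[is.finite(positives)]
  negatives <- negatives[is.finite(negatives)]
  if (!length(positives) || !length(negatives))
    stop("both samples must be non-empty")
  n1 <- length(positives); n2 <- length(negatives)
  r <- rank(c(positives, negatives))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Accuracy band of an AUC
#'
#' \code{0.5} is a chance result; above 0.5 up to (excluding) 0.7 indicates
#' lower accuracy; 0.7 to 0.9 moderate accuracy; above 0.9 higher accuracy.
#' An AUC below 0.5 (the groups separate in the opposite direction) is
#' labelled \code{"chance"} and flagged via the \code{"inverted"} attribute.
#'
#' @param auc Number in \code{[0, 1]}.
#' @return Band label (\code{"chance"}, \code{"lower"}, \code{"moderate"} or
#'   \code{"higher"}) with attribute \code{inverted}.
#' @examples
#' classifyAuc(0.79)  # moderate
#' @export
classifyAuc <- function(auc) {
  stopifnot(length(auc) == 1L, auc >= 0, auc <= 1)
  inverted <- auc < 0.5
  band <- if (auc <= 0.5) "chance"
          else if (auc < 0.7) "lower"
          else if (auc <= 0.9) "moderate"
          else "higher"
  structure(band, inverted = inverted)
}

#' Cohen's kappa for two observers
#'
#' Chance-corrected exact agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} on a
#' K x K contingency table of the two observers' category assignments, with
#' \eqn{p_o} the diagonal fraction and \eqn{p_e} the product of the margins.
#' Unweighted: behaviour counts are compared as exact-agreement categories.
#'
#' @param table Square matrix of non-negative integer counts, total >= 1.
#' @return Number in \code{[-1, 1]}. The degenerate case \eqn{p_e = 1} (both
#'   observers constant) returns 1 with attribute \code{degenerate = TRUE}
#'   when agreement is perfect.
#' @examples
#' cohensKappa(matrix(c(20, 10, 5, 15), 2))  # 0.4
#' @export
cohensKappa <- function(table) {
  table <- as.matrix(table)
  if (!nrow(table) || nrow(table) != ncol(table))
    stop("table must be a non-empty square matrix")
  if (any(table < 0) || sum(table) < 1)
    stop("table must hold non-negative counts with total >= 1")
  n <- sum(table)
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  if (isTRUE(all.equal(pe, 1))) {
    return(structure(if (isTRUE(all.equal(po, 1))) 1 else 0,
                     degenerate = TRUE))
  }
  (po - pe) / (1 - pe)
}

## Tabulate two observers' per-subject counts into the contingency table of
## exact-agreement categories and run cohensKappa.
#' @rdname cohensKappa
#' @param counts Data frame with columns \code{observer_a}, \code{observer_b}
#'   (e.g. from [simulateObserverCounts()]).
#' @export
observerKappa <- function(counts) {
  stopifnot(all(c("observer_a", "observer_b") %in% names(counts)))
  lev <- sort(unique(c(counts$observer_a, counts$observer_b)))
  tab <- table(factor(counts$observer_a, levels = lev),
               factor(counts$observer_b, levels = lev))
  cohensKappa(unclass(tab))
}

## ---- group comparison battery ----------------------------------------------

## Pool a joint's observations from a list of MovementMatrix objects.
.jointObservations <- function(matrices, joint, unit) {
  obs <- lapply(matrices, function(m) {
    v <- pathLength(m)
    if (!joint %in% rownames(v)) return(NULL)
    row <- v[joint, ]
    if (unit == "minute") row[!is.na(row)]
    else if (all(is.na(row))) NULL
    else mean(row, na.rm = TRUE)
  })
  unlist(obs, use.names = FALSE)
}

#' Compare two groups of movement matrices
#'
#' For every analysis joint, pools the per-minute path lengths of each group
#' (\code{unit = "minute"}, one observation per non-missing subject-minute --
#' the unit giving the large df seen in published per-minute tables) or the
#' per-subject session means (\code{unit = "subject"}, the conservative
#' alternative), then runs the battery: mean-centred Levene, Levene-gated
#' t-test, Cohen's d with magnitude band. Missing minutes are excluded, never
#' zero-filled. No multiple-testing correction is applied across joints by
#' default, matching the reporting convention of the source tables;
#' \code{holm = TRUE} adds a Holm-adjusted column as a clearly separate
#' extension.
#'
#' @param matricesGroup1,matricesGroup2 Lists of [MovementMatrix()].
#' @param unit \code{"minute"} (default) or \code{"subject"}.
#' @param alpha Levene gate level.
#' @param weighting Cohen's d pooling, see [cohensD()].
#' @param holm Add a Holm-corrected p-value column?
#' @return Data frame with one row per analysis joint (report order) and
#'   columns \code{joint, levene_F, levene_p, mean1, sd1, n1, mean2, sd2, n2,
#'   t, df, p, d, magnitude, flag}; \code{flag} is \code{"insufficient_data"}
#'   when a joint has fewer than 2 observations in either group (row kept,
#'   statistics NA).
#' @seealso [rocTable()], [renderMinuteCurves()]
#' @export
compareGroups <- function(matricesGroup1, matricesGroup2,
                          unit = c("minute", "subject"), alpha = 0.05,
                          weighting = c("df", "equal"), holm = FALSE) {
  unit <- match.arg(unit)
  weighting <- match.arg(weighting)
  rows <- lapply(.JOINTS_17, function(j) {
    x <- .jointObservations(matricesGroup1, j, unit)
    y <- .jointObservations(matricesGroup2, j, unit)
    base <- data.frame(joint = j, levene_F = NA_real_, levene_p = NA_real_,
                       mean1 = NA_real_, sd1 = NA_real_, n1 = length(x),
                       mean2 = NA_real_, sd2 = NA_real_, n2 = length(y),
                       t = NA_real_, df = NA_real_, p = NA_real_,
                       d = NA_real_, magnitude = NA_character_,
                       flag = "", stringsAsFactors = FALSE)
    if (length(x) < 2L || length(y) < 2L) {
      base$flag <- "insufficient_data"
      return(base)
    }
    tt <- twoSampleT(x, y, varianceRule = "auto", alpha = alpha)
    d <- cohensD(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                 weighting = weighting)
    base$levene_F <- tt$levene_F; base$levene_p <- tt$levene_p
    base$mean1 <- mean(x); base$sd1 <- sd(x)
    base$mean2 <- mean(y); base$sd2 <- sd(y)
    base$t <- tt$t; base$df <- tt$df; base$p <- tt$p
    base$d <- d; base$magnitude <- classifyD(d)
    base
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' ROC table across joints
#'
#' [rocAuc()] per analysis joint, with group 1 as the positive class, plus
#' the accuracy band of each AUC.
#'
#' @inheritParams compareGroups
#' @return Data frame with columns \code{joint, auc, band, inverted}.
#' @export
rocTable <- function(matricesGroup1, matricesGroup2,
                     unit = c("minute", "subject")) {
  unit <- match.arg(unit)
  rows <- lapply(.JOINTS_17, function(j) {
    x <- .jointObservations(matricesGroup1, j, unit)
    y <- .jointObservations(matricesGroup2, j, unit)
    if (!length(x) || !length(y))
      return(data.frame(joint = j, auc = NA_real_, band = NA_character_,
                        inverted = NA, stringsAsFactors = FALSE))
    a <- rocAuc(x, y)
    b <- classifyAuc(a)
    data.frame(joint = j, auc = a, band = as.character(b),
               inverted = attr(b, "inverted"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
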