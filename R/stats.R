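#' @include AllClasses.R utils.R
NULL

#' Coefficient of variation of repeated evoked amplitudes
#'
#' Sample SD divided by the mean of the trial peak amplitudes of one cell.
#' The CV of evoked EPSCs is inversely related to release probability and
#' release-site number: for binomial release over `N` sites with release
#' probability `p` and fixed quantal size, CV tends to `sqrt((1-p)/(N*p))`.
#'
#' @param amplitudes numeric vector of trial peak amplitudes, pA (>= 3
#'   trials, positive mean).
#' @return Dimensionless CV.
#' @export
#' @examples
#' coefficientOfVariation(c(5, 5, 5))  # 0
coefficientOfVariation <- function(amplitudes) {
  assertThat(length(amplitudes) >= 3, "optomap_invalid_input",
             "CV needs at least 3 trials")
  m <- mean(amplitudes)
  assertThat(is.finite(m) && m > 0, "optomap_invalid_input",
             "CV needs a positive mean amplitude")
  sd(amplitudes) / m
}

#' Percent reduction of a test value relative to a reference
#'
#' `100 * (1 - test/reference)`, optionally rounded to the nearest
#' `roundingStep` percent (the convention used when summarizing group-mean
#' reductions as round percentages).
#'
#' @param reference reference (e.g. WT) value, > 0.
#' @param test test (e.g. KO) value.
#' @param roundingStep round to the nearest this many percent; NULL for no
#'   rounding.
#' @return Percent reduction (negative for an increase).
#' @export
#' @examples
#' percentChange(172, 105, roundingStep = 5)
percentChange <- function(reference, test, roundingStep = NULL) {
  assertThat(all(reference > 0), "optomap_invalid_input",
             "reference must be > 0")
  pc <- 100 * (1 - test / reference)
  if (!is.null(roundingStep)) pc <- round(pc / roundingStep) * roundingStep
  pc
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the normalized skewness and kurtosis statistics into
#' `K2 = Z(b1)^2 + Z(b2)^2`, referred to a chi-squared distribution with 2
#' degrees of freedom. Requires n >= 8.
#'
#' @param x numeric sample.
#' @return list with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostinoPearsonTest <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  assertThat(n >= 8, "optomap_invalid_input",
             "D'Agostino-Pearson test needs n >= 8 (got %d)", n)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  assertThat(m2 > 0, "optomap_invalid_input",
             "sample has zero variance")
  # skewness transform (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  ya <- y / alpha
  zs <- delta * log(ya + sqrt(ya^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  zk <- (term1 - term2) / sqrt(2 / (9 * A))
  k2 <- zs^2 + zk^2
  list(statistic = k2, p.value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = zs, z_kurt = zk, n = n)
}

#' Choose the paired test by the double normality gate
#'
#' Runs the D'Agostino-Pearson and Anderson-Darling normality tests on the
#' paired differences; only when both pass at `alpha` is the parametric
#' paired t test selected, otherwise the Wilcoxon matched-pairs test.
#' Samples smaller than 8 (where omnibus normality tests are uninformative)
#' and degenerate zero-variance samples fall back to Wilcoxon with a
#' warning.
#'
#' @param differences numeric vector of paired differences.
#' @param alpha significance level of each normality test.
#' @return list: `test` ("paired t" or "Wilcoxon"), `normality` (the two p
#'   values and the gate verdict).
#' @export
choosePairedTest <- function(differences, alpha = 0.05) {
  d <- differences[is.finite(differences)]
  n <- length(d)
  if (n < 8) {
    warning(sprintf(
      "only %d pairs: normality tests are unreliable below n = 8; using Wilcoxon",
      n), call. = FALSE)
    return(list(test = "Wilcoxon",
                normality = list(dagostino_pearson = NA_real_,
                                 anderson_darling = NA_real_,
                                 normal = FALSE)))
  }
  if (sd(d) == 0) {
    return(list(test = "Wilcoxon",
                normality = list(dagostino_pearson = NA_real_,
                                 anderson_darling = NA_real_,
                                 normal = FALSE)))
  }
  pDP <- dagostinoPearsonTest(d)$p.value
  pAD <- nortest::ad.test(d)$p.value
  normal <- pDP > alpha && pAD > alpha
  list(test = if (normal) "paired t" else "Wilcoxon",
       normality = list(dagostino_pearson = pDP, anderson_darling = pAD,
                        normal = normal))
}

#' Normality-gated paired comparison
#'
#' Drops incomplete pairs, gates with [choosePairedTest()], and runs the
#' selected two-sided paired test.
#'
#' @param pairs data.frame with columns `wt` and `ko` (optionally
#'   `pair_id`), one row per neighbor pair.
#' @param alpha significance level of the normality gate.
#' @return A [TestResult-class].
#' @export
pairedCompare <- function(pairs, alpha = 0.05) {
  assertThat(all(c("wt", "ko") %in% names(pairs)), "optomap_invalid_input",
             "pairs needs 'wt' and 'ko' columns")
  ok <- is.finite(pairs$wt) & is.finite(pairs$ko)
  if (any(!ok))
    message(sprintf("dropping %d incomplete pair(s)", sum(!ok)))
  pairs <- pairs[ok, , drop = FALSE]
  n <- nrow(pairs)
  assertThat(n >= 3, "optomap_invalid_input",
             "need at least 3 complete pairs (got %d)", n)
  d <- pairs$wt - pairs$ko
  if (all(d == 0))
    return(new("TestResult", test = "Wilcoxon", statistic = 0,
               df = NA_real_, p = 1, n = as.integer(n),
               normality = list(dagostino_pearson = NA_real_,
                                anderson_darling = NA_real_, normal = FALSE)))
  gate <- choosePairedTest(d, alpha = alpha)
  if (gate$test == "paired t") {
    tt <- t.test(pairs$wt, pairs$ko, paired = TRUE)
    new("TestResult", test = "paired t",
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, n = as.integer(n), normality = gate$normality)
  } else {
    wt <- suppressWarnings(wilcox.test(pairs$wt, pairs$ko, paired = TRUE,
                                       exact = FALSE, correct = TRUE))
    new("TestResult", test = "Wilcoxon",
        statistic = unname(wt$statistic), df = NA_real_,
        p = wt$p.value, n = as.integer(n), normality = gate$normality)
  }
}

#' Sign-flip permutation test for paired differences
#'
#' Independent check of the gated paired procedure: the mean difference is
#' referred to its sign-flip permutation distribution (two-sided).
#'
#' @param differences numeric vector of paired differences.
#' @param nPerm number of random sign assignments.
#' @return list: `statistic` (mean difference), `p.value`, `nPerm`.
#' @export
signFlipTest <- function(differences, nPerm = 10000) {
  d <- differences[is.finite(differences)]
  n <- length(d)
  assertThat(n >= 3, "optomap_invalid_input", "need at least 3 differences")
  obs <- mean(d)
  signs <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
  perm <- as.numeric(signs %*% d) / n
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (nPerm + 1)
  list(statistic = obs, p.value = p, nPerm = nPerm)
}

#' Genotype x condition interaction ANOVA
#'
#' Classical two-way ANOVA with interaction for two crossed two-level
#' factors (e.g. genotype x age or genotype x deprivation), returning the
#' interaction F with its degrees of freedom; optionally Sidak-corrected
#' pairwise comparisons of the four design cells.
#'
#' @param data data.frame with one row per cell (observation).
#' @param value,factorA,factorB column names of the response and the two
#'   factors.
#' @param sidak also return Sidak-adjusted pairwise comparisons.
#' @return A [TestResult-class]; with `sidak = TRUE` a list of the
#'   TestResult and a `pairwise` data.frame.
#' @export
interactionAnova <- function(data, value = "value", factorA = "genotype",
                             factorB = "condition", sidak = FALSE) {
  assertThat(all(c(value, factorA, factorB) %in% names(data)),
             "optomap_invalid_input", "missing columns in data")
  df <- data.frame(y = data[[value]],
                   A = factor(data[[factorA]]), B = factor(data[[factorB]]))
  df <- df[complete.cases(df), , drop = FALSE]
  tabn <- table(df$A, df$B)
  assertThat(all(tabn > 0), "optomap_invalid_design",
             "every factor-level combination needs observations")
  fit <- aov(y ~ A * B, data = df)
  sm <- summary(fit)[[1]]
  ia <- grep("A:B", rownames(sm))
  Fv <- sm[ia, "F value"]
  df1 <- sm[ia, "Df"]
  df2 <- sm[nrow(sm), "Df"]
  p <- sm[ia, "Pr(>F)"]
  if (!is.finite(Fv) || var(df$y) == 0) { Fv <- 0; p <- 1 }  # degenerate
  res <- new("TestResult", test = "ANOVA interaction", statistic = Fv,
             df = c(df1, df2), p = p, n = as.integer(nrow(df)),
             normality = list())
  if (!sidak) return(res)
  em <- emmeans::emmeans(fit, ~ A * B)
  pw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "sidak"))
  list(result = res, pairwise = pw)
}
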