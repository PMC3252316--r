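#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard implementation, with the classical
#' sample-size limits made explicit.
#'
#' @param sample numeric vector, 3 <= n <= 5000, not constant.
#' @return named list: W, p.
#' @export
shapiroWilk <- function(sample) {
  n <- length(sample)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (length(unique(sample)) == 1L)
    stop("Shapiro-Wilk is undefined for a constant sample")
  sw <- stats::shapiro.test(sample)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square ratio with the F-distribution
#' p-value; returns the decomposition so pairwise Scheffe contrasts can
#' reuse the pooled error term.
#'
#' @param groups list of 2 or more numeric vectors, each with n >= 2.
#' @return named list: F, p, df1, df2, msw (within mean square), means,
#'   sizes. \code{F} is NA when both between- and within-group variance
#'   vanish.
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))$F   # 3
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  ns <- lengths(groups)
  N <- sum(ns)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0 && ssb == 0)
    return(list(F = NA_real_, p = NA_real_, df1 = df1, df2 = df2,
                msw = 0, means = means, sizes = ns))
  msb <- ssb / df1
  msw <- ssw / df2
  Fstat <- if (msw == 0) Inf else msb / msw
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, msw = msw, means = means, sizes = ns)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based omnibus H statistic with tie correction and the chi-square
#' approximation (wraps the standard implementation).
#'
#' @param groups list of numeric vectors, total n >= 5.
#' @return named list: H, p, df.
#' @examples
#' kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))$H   # 32/7
#' @export
kruskalWallis <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 5) stop("Kruskal-Wallis requires total n >= 5")
  if (length(unique(x)) == 1L) stop("all values tied: H is undefined")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kw <- stats::kruskal.test(x, g)
  list(H = unname(kw$statistic), p = kw$p.value,
       df = unname(kw$parameter))
}

# Scheffe-corrected pairwise p-value on the ANOVA path: the pairwise
# F-contrast divided by (k-1) referred to F(k-1, N-k).
scheffePairP <- function(fit, i, j) {
  Fs <- (fit$means[i] - fit$means[j])^2 /
    (fit$msw * (1 / fit$sizes[i] + 1 / fit$sizes[j]))
  stats::pf(Fs / fit$df1, fit$df1, fit$df2, lower.tail = FALSE)
}

# Scheffe-style pairwise p-value on the Kruskal-Wallis path: a Dunn-type
# rank contrast whose squared z is referred to chi-square with k-1 degrees
# of freedom (the rank analogue of projecting onto the omnibus criterion).
rankScheffePairP <- function(groups, i, j) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tieCorr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  s2 <- N * (N + 1) / 12 * tieCorr
  ri <- mean(r[g == i])
  rj <- mean(r[g == j])
  z2 <- (ri - rj)^2 / (s2 * (1 / sum(g == i) + 1 / sum(g == j)))
  stats::pchisq(z2, df = length(groups) - 1, lower.tail = FALSE)
}

#' Screen features for discriminatory power across three populations
#'
#' Reproduces the published decision procedure per feature: Shapiro-Wilk
#' normality per group (at 0.05); one-way ANOVA when all three groups pass,
#' Kruskal-Wallis otherwise; pairwise contrasts with Scheffe correction
#' (F-projection on the ANOVA path, chi-square-referred Dunn contrasts on
#' the rank path); significance flags at \code{alpha} (default 0.0025). The
#' normal-vs-abnormal flag requires BOTH normal-vs-X contrasts significant.
#'
#' @param feature_table data.frame: \code{cell_id} column plus feature
#'   columns (usually the 42 registry features).
#' @param group_labels factor/character of populations, one per row; must
#'   have exactly 3 levels, in the order (normal, fibrocystic, metastatic)
#'   of \code{levels()} or of first appearance.
#' @param alpha corrected significance level.
#' @return data.frame (one row per feature): the chosen test, omnibus p,
#'   the three pairwise corrected p-values, and logical flags
#'   \code{normal_vs_abnormal}, \code{fibrocystic_vs_metastatic}. Features
#'   with missing values are skipped with a message and reported with NA.
#' @export
screenFeatures <- function(feature_table, group_labels, alpha = 0.0025) {
  stopifnot(is.data.frame(feature_table))
  groups <- if (is.factor(group_labels)) levels(group_labels) else
    unique(group_labels)
  if (length(groups) != 3L) stop("need exactly 3 populations")
  featNames <- setdiff(names(feature_table), "cell_id")
  if (min(table(factor(group_labels, levels = groups))) < 3)
    stop("need at least 3 cells per group")
  rows <- lapply(featNames, function(fn) {
    x <- feature_table[[fn]]
    base <- data.frame(feature = fn, test = NA_character_, p_omnibus = NA_real_,
                       p_normal_fibrocystic = NA_real_,
                       p_normal_metastatic = NA_real_,
                       p_fibrocystic_metastatic = NA_real_,
                       normal_vs_abnormal = NA,
                       fibrocystic_vs_metastatic = NA)
    if (anyNA(x)) {
      message("feature '", fn, "' skipped: missing values")
      return(base)
    }
    gl <- lapply(groups, function(g) x[group_labels == g])
    allNormal <- all(vapply(gl, function(v) {
      if (length(unique(v)) == 1L) return(FALSE)
      shapiroWilk(v)$p >= 0.05
    }, logical(1)))
    if (length(unique(x)) == 1L) {
      message("feature '", fn, "' skipped: constant across all cells")
      return(base)
    }
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    if (allNormal) {
      fit <- oneWayAnova(gl)
      pp <- vapply(pairs, function(ij) scheffePairP(fit, ij[1], ij[2]),
                   numeric(1))
      base$test <- "anova"
      base$p_omnibus <- fit$p
    } else {
      kw <- kruskalWallis(gl)
      pp <- vapply(pairs, function(ij) rankScheffePairP(gl, ij[1], ij[2]),
                   numeric(1))
      base$test <- "kruskal-wallis"
      base$p_omnibus <- kw$p
    }
    base$p_normal_fibrocystic <- pp[1]
    base$p_normal_metastatic <- pp[2]
    base$p_fibrocystic_metastatic <- pp[3]
    base$normal_vs_abnormal <- (pp[1] < alpha) && (pp[2] < alpha)
    base$fibrocystic_vs_metastatic <- pp[3] < alpha
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- groups
  out
}

#' Summarize discriminatory power
#'
#' Counts significant features per comparison column and expresses them as
#' a percentage of the 42-feature registry (rounded to the nearest
#' integer), as in the published summary.
#'
#' @param table a \code{\link{screenFeatures}} result, or any data.frame
#'   with logical/"Yes"/"No" columns \code{normal_vs_abnormal} and
#'   \code{fibrocystic_vs_metastatic} and one row per registry feature.
#' @return data.frame: comparison, n_significant, n_features, percent.
#' @export
summarizeDiscriminatory <- function(table) {
  nreg <- nrow(featureRegistry())
  if (nrow(table) != nreg)
    stop("expected ", nreg, " feature rows, got ", nrow(table))
  asFlag <- function(x) {
    if (is.logical(x)) return(x)
    tolower(trimws(as.character(x))) %in% c("yes", "true", "1")
  }
  cols <- c("normal_vs_abnormal", "fibrocystic_vs_metastatic")
  missing <- setdiff(cols, names(table))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  counts <- vapply(cols, function(cn) sum(asFlag(table[[cn]]), na.rm = TRUE),
                   numeric(1))
  data.frame(comparison = cols, n_significant = as.integer(counts),
             n_features = nreg,
             percent = as.integer(round(counts / nreg * 100)))
}

#' Published per-feature significance calls
#'
#' Loads the machine-readable transcription of the published
#' discriminatory-power table (42 features, Yes/No calls for the
#' normal-vs-abnormal and fibrocystic-vs-metastatic comparisons at
#' p < 0.0025 with multiple-comparison correction) shipped with the
#' package.
#'
#' @return data.frame: feature, normal_vs_abnormal,
#'   fibrocystic_vs_metastatic.
#' @export
table2Calls <- function() {
  path <- system.file("extdata", "table2_significance.csv",
                      package = "nucleomorph3d", mustWork = TRUE)
  utils::read.csv(path)
}
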