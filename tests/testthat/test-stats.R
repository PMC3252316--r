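test_that("Shapiro-Wilk wrapper matches the frozen reference values", {
  # deterministic quantile samples; W frozen from an independent
  # implementation (agrees to 1e-10)
  xn <- qnorm((1:50 - 0.5) / 50)
  sw <- shapiroWilk(xn)
  expect_equal(sw$W, 0.9992035684, tolerance = 1e-6)
  xe <- qexp((1:50 - 0.5) / 50)
  swe <- shapiroWilk(xe)
  expect_equal(swe$W, 0.8375865216, tolerance = 1e-6)
  expect_lt(swe$p, 0.01)
  expect_error(shapiroWilk(rep(1, 10)), "constant")
  expect_error(shapiroWilk(c(1, 2)), "3 <= n")
})

test_that("one-way ANOVA reproduces closed forms and the t-test identity", {
  fit <- oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(fit$F, 3)
  expect_equal(fit$p, pf(3, 2, 6, lower.tail = FALSE))
  # cross-check against the standard implementation
  x <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- factor(rep(1:3, each = 3))
  ow <- oneway.test(x ~ g, var.equal = TRUE)
  expect_equal(fit$F, unname(ow$statistic))
  expect_equal(fit$p, ow$p.value)
  # identical groups: F = 0, p = 1
  same <- oneWayAnova(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # two groups: F equals the square of the pooled t statistic
  set.seed(3)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  f2 <- oneWayAnova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(f2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  # constant identical data: flagged not applicable
  expect_true(is.na(oneWayAnova(list(c(1, 1), c(1, 1)))$F))
})

test_that("Kruskal-Wallis reproduces the rank closed form and invariances", {
  kw <- kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, 32 / 7, tolerance = 1e-12)
  # monotone transforms leave H unchanged
  kw2 <- kruskalWallis(list(exp(c(1, 2)), exp(c(3, 4)), exp(c(5, 6))))
  expect_equal(kw2$H, kw$H)
  # consistent permutation of values leaves H unchanged
  kw3 <- kruskalWallis(list(c(2, 1), c(4, 3), c(6, 5)))
  expect_equal(kw3$H, kw$H)
  expect_error(kruskalWallis(list(1, 2)), "n >= 5")
  expect_error(kruskalWallis(list(c(1, 1, 1), c(1, 1, 1))), "tied")
})

test_that("test selection is gated by per-group normality", {
  set.seed(8)
  n <- 30
  normal <- lapply(1:3, function(i) rnorm(n, i * 0.1))
  skewed <- lapply(1:3, function(i) rexp(n) + i * 0.1)
  mk <- function(gl) {
    data.frame(cell_id = seq_len(3 * n), f = unlist(gl))
  }
  labs <- rep(c("normal", "fibrocystic", "metastatic"), each = n)
  sN <- screenFeatures(mk(normal), labs, alpha = 0.05)
  expect_equal(sN$test, "anova")
  sK <- screenFeatures(mk(skewed), labs, alpha = 0.05)
  expect_equal(sK$test, "kruskal-wallis")
})

test_that("the screen recovers planted shifts with few false positives", {
  set.seed(42)
  n <- 50
  reg <- featureRegistry()$name
  mk <- function(shiftIdx, shift) {
    X <- matrix(rnorm(n * 42), n, 42)
    X[, shiftIdx] <- X[, shiftIdx] + shift
    X
  }
  tab <- data.frame(cell_id = sprintf("c%03d", 1:(3 * n)),
                    rbind(mk(integer(0), 0), mk(1:10, 2), mk(1:10, 2)),
                    check.names = FALSE)
  names(tab)[-1] <- reg
  labs <- rep(c("normal", "fibrocystic", "metastatic"), each = n)
  sig <- screenFeatures(tab, labs)
  expect_equal(sum(sig$normal_vs_abnormal[1:10]), 10L)
  expect_lte(sum(sig$normal_vs_abnormal[-(1:10)]), 2L)
})

test_that("identical groups produce no flags at the study alpha", {
  set.seed(10)
  flagged <- 0L
  for (r in 1:60) {
    tab <- data.frame(cell_id = 1:90, f = rnorm(90))
    s <- screenFeatures(tab, rep(c("a", "b", "c"), each = 30))
    flagged <- flagged + (isTRUE(s$normal_vs_abnormal) ||
                            isTRUE(s$fibrocystic_vs_metastatic))
  }
  expect_gte(1 - flagged / 60, 0.95)
})

test_that("boundary alphas and missing data behave as documented", {
  set.seed(12)
  tab <- data.frame(cell_id = 1:30, f = rnorm(30), g = rnorm(30))
  labs <- rep(c("a", "b", "c"), each = 10)
  sAll <- screenFeatures(tab, labs, alpha = 1)
  expect_true(all(sAll$normal_vs_abnormal))
  expect_true(all(sAll$fibrocystic_vs_metastatic))
  tab$g[3] <- NA
  expect_message(sNA <- screenFeatures(tab, labs), "skipped")
  expect_true(is.na(sNA$normal_vs_abnormal[sNA$feature == "g"]))
  expect_error(screenFeatures(tab, rep(c("a", "b"), 15)), "3 populations")
})

test_that("the shipped discriminatory table summarizes to 38/42 and 29/42", {
  calls <- table2Calls()
  expect_equal(nrow(calls), 42L)
  expect_identical(calls$feature, featureRegistry()$name)
  s <- summarizeDiscriminatory(calls)
  expect_equal(s$n_significant[s$comparison == "normal_vs_abnormal"], 38L)
  expect_equal(s$percent[s$comparison == "normal_vs_abnormal"], 90L)
  expect_equal(s$n_significant[s$comparison == "fibrocystic_vs_metastatic"],
               29L)
  expect_equal(s$percent[s$comparison == "fibrocystic_vs_metastatic"], 69L)
  # all-false table -> zero
  none <- calls
  none$normal_vs_abnormal <- "No"
  none$fibrocystic_vs_metastatic <- FALSE
  s0 <- summarizeDiscriminatory(none)
  expect_equal(s0$n_significant, c(0L, 0L))
  expect_error(summarizeDiscriminatory(calls[1:10, ]), "42")
})
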