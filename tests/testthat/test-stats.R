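# Oracle: Kruskal-Wallis H computed from first principles (mid-ranks).
kw_oracle_h <- function(a, b) {
  x <- c(a, b)
  g <- rep(1:2, c(length(a), length(b)))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

test_that("PCA handles collinear, duplicated and random matrices", {
  # three samples along one axis: first component carries all variance
  base <- rnorm(10)
  m <- cbind(s1 = base, s2 = base * 2, s3 = base * 3.5) # features x samples
  p <- pca_samples(m)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-10)
  # duplicated sample columns land on identical score coordinates
  m2 <- cbind(m, s4 = m[, "s3"])
  p2 <- pca_samples(m2)
  expect_equal(p2$scores["s3", ], p2$scores["s4", ], tolerance = 1e-9,
               ignore_attr = TRUE)
  # full-rank reconstruction of the centered matrix
  set.seed(5)
  x <- matrix(rnorm(200), nrow = 20, ncol = 10,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  p3 <- pca_samples(x)
  centered <- scale(t(x), center = TRUE, scale = FALSE)
  rebuilt <- p3$scores %*% t(p3$loadings)
  expect_lt(max(abs(rebuilt - centered)), 1e-8)
  # loadings orthonormal, variances non-increasing
  expect_equal(crossprod(p3$loadings), diag(ncol(p3$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(p3$explained_variance) <= 1e-12))
  # constant matrix must not crash
  expect_equal(sum(pca_samples(matrix(3, 4, 5))$explained_variance), 0)
})

test_that("RM-ANOVA F matches the aov error-stratum fit on random grids", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(3:5, 1)
    k <- sample(3:6, 1)
    y <- matrix(rnorm(n * k, mean = 10), n, k)
    got <- rm_anova(y)
    df <- data.frame(y = as.vector(y),
                     subject = factor(rep(seq_len(n), k)),
                     cond = factor(rep(seq_len(k), each = n)))
    fit <- stats::aov(y ~ cond + Error(subject), data = df)
    tab <- summary(fit)[["Error: Within"]][[1]]
    expect_equal(got$statistic, tab["cond", "F value"], tolerance = 1e-10)
    expect_equal(got$p_value, tab["cond", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(got$df1, k - 1)
    expect_equal(got$df2, (k - 1) * (n - 1))
  }
})

test_that("with two conditions RM-ANOVA F equals the squared paired t", {
  set.seed(23)
  for (i in 1:10) {
    y <- matrix(rnorm(8, mean = 5), 4, 2)
    got <- rm_anova(y)
    tt <- t.test(y[, 1], y[, 2], paired = TRUE)
    expect_equal(got$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(got$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate RM-ANOVA grids are flagged, not crashed", {
  flat <- rm_anova(matrix(4, 3, 5))
  expect_equal(flat$statistic, 0)
  expect_true(flat$degenerate)
  expect_true(is.na(rm_anova(matrix(rnorm(4), 1, 4))$statistic))
  # incomplete subjects are dropped with a message
  y <- matrix(rnorm(12), 4, 3)
  y[2, 3] <- NA
  expect_message(got <- rm_anova(y), "incomplete")
  expect_equal(got$df2, 2 * 2)
})

test_that("Kruskal-Wallis matches hand ranks and handles total ties", {
  kw <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  expect_equal(kruskal_wallis(c(1, 2), c(1, 2))$statistic, 0)
  expect_equal(kruskal_wallis(c(7, 7, 7), c(7, 7))$p_value, 1)
  expect_error(kruskal_wallis(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis agrees with the exhaustive 3-vs-3 permutation law", {
  combos <- utils::combn(6, 3)
  set.seed(41)
  max_h <- kw_oracle_h(1:3, 4:6)
  # chi-squared p at the rank-extreme arrangement: the discreteness floor
  expect_equal(stats::pchisq(max_h, 1, lower.tail = FALSE), 0.0495,
               tolerance = 1e-2)
  for (i in 1:8) {
    x <- round(runif(6, 0, 100), 3) # continuous: ties almost surely absent
    split_at <- combos[, sample(ncol(combos), 1)]
    a <- x[split_at]; b <- x[-split_at]
    got <- kruskal_wallis(a, b)
    expect_equal(got$statistic, kw_oracle_h(a, b), tolerance = 1e-10)
    # exhaustive permutation distribution of H over all 20 assignments:
    # the chi-squared p must fall between the strict and inclusive
    # permutation tail probabilities (the bracket discreteness allows)
    h_perm <- apply(combos, 2, function(idx) kw_oracle_h(x[idx], x[-idx]))
    p_incl <- mean(h_perm >= got$statistic - 1e-12)
    p_strict <- mean(h_perm > got$statistic + 1e-12)
    expect_gte(got$p_value, p_strict - 1e-9)
    expect_lte(got$p_value, p_incl + 1e-9)
    expect_gte(p_incl, stats::pchisq(max_h, 1, lower.tail = FALSE))
  }
})

test_that("Bonferroni adjustment multiplies, clamps and preserves order", {
  expect_equal(bonferroni(1e-5, m = 1852), 0.01852)
  expect_equal(bonferroni(0.5, m = 1852), 1)
  expect_equal(bonferroni(c(0.01, 0.2, 0.03)), c(0.03, 0.6, 0.09))
  expect_error(bonferroni(1.2), "0, 1")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
  # agrees with p.adjust when m equals the list length
  p <- runif(20)
  expect_equal(bonferroni(p), p.adjust(p, "bonferroni"))
})

test_that("feature_tests runs both tests per feature with the right family", {
  lib <- tiny_library(8, 2)
  des <- generate_design(3, ft_grid(3), replicates = 3)
  pk <- simulate_peak_tables(lib, des, effect_spec(noise_sigma = 0.08, seed = 30))
  am <- annotate_peaks(pk, lib, des)
  ft <- feature_tests(am, "freeze_thaw")
  expect_equal(nrow(ft), 6L) # sILCs are not features
  expect_equal(attr(ft, "family_size"), 6L)
  expect_true(all(ft$p_anova >= 0 & ft$p_anova <= 1))
  expect_equal(ft$p_anova_bonf, pmin(1, 6 * ft$p_anova))
  expect_true(all(ft$f_statistic >= 0))
  expect_true(all(ft$h_statistic >= 0))
  expect_error(feature_tests(am, "lyophilised"), "unknown series")
})
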