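# hand-computed Pearson chi-square and standardized residuals
chisq_oracle <- function(tab) {
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - E)^2 / E)
  z <- (tab - E) / sqrt(E * outer(1 - rowSums(tab) / n, 1 - colSums(tab) / n))
  list(chi2 = chi2, stdres = z)
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_oracle_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  sum(probs[probs <= dhyper(x_obs, m, n, k) * (1 + 1e-7)])
}

# textbook Welch statistic and Satterthwaite df
welch_oracle <- function(groups) {
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, var, 0)
  w <- n / v
  mw <- sum(w * m) / sum(w)
  k <- length(groups)
  A <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  df2 <- (k^2 - 1) / (3 * lam)
  list(F = A / B, df1 = k - 1, df2 = df2,
       p = pf(A / B, k - 1, df2, lower.tail = FALSE))
}

# Kruskal-Wallis H with tie correction, from the rank formula
kw_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

test_that("a balanced sex table gives a null chi-square and no flags", {
  tab <- cbind(male = rep(15L, 5), female = rep(15L, 5))
  rownames(tab) <- c("Dm", "D0", "D1", "D3", "D4")
  res <- sex_ratio_test(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 4)
  expect_false(any(res$posthoc$significant))
})

test_that("chi-square statistic and residuals match the hand oracle", {
  tab <- rbind(A = c(10L, 10L), B = c(30L, 10L))
  colnames(tab) <- c("male", "female")
  res <- sex_ratio_test(tab)
  ora <- chisq_oracle(tab)
  expect_equal(res$statistic, ora$chi2, tolerance = 1e-12)
  expect_equal(matrix(res$posthoc$residual, nrow = 2), unclass(ora$stdres),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a strongly female-skewed diet is the only flagged one", {
  # adult sex counts echoing a trial where one artificial diet came out
  # ~17% male / 83% female while the others stayed near balance
  tab <- rbind(Dm = c(18L, 11L), D0 = c(5L, 24L), D1 = c(14L, 14L),
               D3 = c(12L, 17L), D4 = c(17L, 10L))
  colnames(tab) <- c("male", "female")
  res <- sex_ratio_test(tab)
  ora <- chisq_oracle(tab)
  expect_equal(res$statistic, ora$chi2, tolerance = 1e-12)
  flagged <- unique(res$posthoc$diet[res$posthoc$significant])
  expect_equal(flagged, "D0")
  # bonferroni never lowers a p-value and flags agree with adjusted p
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p_raw - 1e-15))
  expect_equal(res$posthoc$significant, res$posthoc$p_adj <= 0.05)
})

test_that("identical mortality across diets is not significant", {
  tab <- cbind(died = rep(6L, 5), survived = rep(27L, 5))
  rownames(tab) <- c("Dm", "D0", "D1", "D3", "D4")
  res <- mortality_test(tab)
  expect_equal(res$p_value, 1)
  expect_false(any(res$posthoc$significant))
})

test_that("2x2 exact p-values match hypergeometric enumeration to 1e-12", {
  with_seed(77, {
    for (r in 1:50) {
      tab <- matrix(rbinom(4, 25, runif(1, 0.1, 0.9)) + 1L, 2,
                    dimnames = list(c("a", "b"), c("died", "survived")))
      res <- mortality_test(tab)
      expect_equal(res$p_value, fisher_oracle_2x2(tab), tolerance = 1e-12)
    }
  })
})

test_that("a fully lethal diet separates from every other diet", {
  tab <- rbind(Dm = c(2L, 31L), D0 = c(6L, 27L), D1 = c(5L, 28L),
               D2 = c(33L, 0L), D3 = c(6L, 27L), D4 = c(6L, 27L))
  colnames(tab) <- c("died", "survived")
  res <- mortality_test(tab)
  expect_lt(res$p_value, 0.001)
  has_d2 <- grepl("D2", res$posthoc$pair)
  expect_true(all(res$posthoc$significant[has_d2]))
  expect_false(any(res$posthoc$significant[!has_d2]))
})

test_that("Welch statistic and fractional df match the textbook formula", {
  with_seed(101, {
    for (r in 1:10) {
      groups <- lapply(1:4, function(i) rnorm(sample(8:40, 1), i * 0.3,
                                              runif(1, 0.5, 3)))
      names(groups) <- paste0("g", 1:4)
      res <- welch_anova(groups)
      ora <- welch_oracle(groups)
      expect_equal(res$statistic, ora$F, tolerance = 1e-10)
      expect_equal(res$df[1], ora$df1)
      expect_equal(res$df[2], ora$df2, tolerance = 1e-10)
      expect_equal(res$p_value, ora$p, tolerance = 1e-10)
    }
  })
})

test_that("Welch approaches the classical F when variances are equal", {
  with_seed(103, {
    g <- lapply(1:3, function(i) {
      x <- rnorm(5000)
      (x - mean(x)) / sd(x) + i * 0.05  # exactly unit sample variance
    })
    names(g) <- paste0("g", 1:3)
    w <- welch_anova(g)
    cl <- stats::oneway.test(unlist(g) ~ factor(rep(1:3, each = 5000)),
                             var.equal = TRUE)
    expect_equal(w$statistic, unname(cl$statistic), tolerance = 1e-3)
  })
  expect_error(welch_anova(list(a = c(1, 1), b = c(1, 1))), "degenerate")
})

test_that("Games-Howell at two groups equals the Welch t-test", {
  with_seed(105, {
    for (r in 1:10) {
      x <- rnorm(sample(5:30, 1), 0, 1)
      y <- rnorm(sample(5:30, 1), runif(1, 0, 2), runif(1, 0.5, 3))
      gh <- games_howell(list(a = x, b = y))
      tt <- stats::t.test(x, y)
      # ptukey carries ~1e-8 quadrature error, hence the tolerance
      expect_equal(gh$p, tt$p.value, tolerance = 1e-6)
      expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-10)
    }
  })
})

test_that("Games-Howell flags only pairs containing a far-shifted group", {
  with_seed(107, {
    groups <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30),
                   d = rnorm(30) + 10)
    gh <- games_howell(groups)
    has_d <- grepl("d", gh$pair)
    expect_true(all(gh$significant[has_d]))
    expect_false(any(gh$significant[!has_d]))
    same <- games_howell(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
    expect_gt(same$p, 0.999)
  })
})

test_that("identical per-diet samples give a null Kruskal-Wallis", {
  df <- data.frame(stage = "N1", diet = rep(c("Dm", "D0", "D1"), each = 3),
                   add = rep(c(10, 20, 30), times = 3))
  res <- kruskal_wallis_per_instar(df)
  expect_equal(res$N1$statistic, 0, tolerance = 1e-12)
  expect_equal(res$N1$p_value, 1, tolerance = 1e-12)
})

test_that("the H statistic matches the rank formula oracle with ties", {
  with_seed(109, {
    for (r in 1:10) {
      values <- sample(1:4, 12, replace = TRUE)  # heavy ties
      groups <- rep(c("a", "b"), each = 6)
      df <- data.frame(stage = "N2", diet = groups, add = values)
      if (var(values) == 0) next
      res <- kruskal_wallis_per_instar(df)
      expect_equal(res$N2$statistic, kw_oracle(values, groups),
                   tolerance = 1e-12)
    }
  })
})

test_that("per-instar tests run independently and skip sparse instars", {
  df <- data.frame(stage = rep(c("N1", "N2"), c(8, 3)),
                   diet = c(rep(c("Dm", "D0"), each = 4), rep("Dm", 3)),
                   add = c(rnorm(8), rnorm(3)))
  expect_warning(res <- kruskal_wallis_per_instar(df), "N2.*skipped")
  expect_named(res, "N1")
})

test_that("Kruskal-Wallis rejection rises with a location shift", {
  rate_at <- function(shift) {
    with_seed(111 + round(shift * 10), {
      mean(replicate(150, {
        df <- data.frame(stage = "N3", diet = rep(c("a", "b"), each = 12),
                         add = c(rnorm(12), rnorm(12) + shift))
        kruskal_wallis_per_instar(df)$N3$p_value <= 0.05
      }))
    })
  }
  rates <- vapply(c(0, 1, 2), rate_at, 0)
  expect_lt(rates[1], 0.15)
  expect_gt(rates[3], rates[1])
  expect_gt(rates[3], 0.9)
})

test_that("two-way fecundity ANOVA matches type-II sums of squares", {
  with_seed(113, {
    females <- data.frame(
      diet = rep(c("Dm", "D0", "D1"), each = 20),
      generation = rep(rep(1:2, each = 10), times = 3),
      eggs_laid = round(rnorm(60, 26, 5)) +
        rep(c(0, 1, 0), each = 20) + rep(rep(c(0, 2), each = 10), 3)
    )
    res <- fecundity_anova(females)
    # independent route: type-II F from residual sums of squares
    f2 <- function(d) {
      full <- lm(eggs_laid ~ factor(diet) + factor(generation), data = d)
      nog <- lm(eggs_laid ~ factor(diet), data = d)
      rss <- sum(residuals(full)^2)
      dfr <- df.residual(full)
      ((sum(residuals(nog)^2) - rss) / 1) / (rss / dfr)
    }
    expect_equal(res$eggs$generation$statistic, f2(females),
                 tolerance = 1e-10)
    # perturbing one observation moves both routes identically
    females2 <- females
    females2$eggs_laid[1] <- females2$eggs_laid[1] + 10
    res2 <- fecundity_anova(females2)
    expect_equal(res2$eggs$generation$statistic, f2(females2),
                 tolerance = 1e-10)
    expect_false(isTRUE(all.equal(res$eggs$generation$statistic,
                                  res2$eggs$generation$statistic)))
    # companions are reported
    expect_true(res$normality$p_value >= 0 && res$normality$p_value <= 1)
    expect_true(res$levene$p_value >= 0 && res$levene$p_value <= 1)
  })
})

test_that("degenerate and incomplete fecundity designs are handled", {
  females <- data.frame(diet = rep(c("a", "b"), each = 4),
                        generation = rep(1:2, 4), eggs_laid = 26)
  expect_error(fecundity_anova(females), "degenerate")
  females2 <- data.frame(
    diet = c(rep("a", 6), rep("b", 3)),
    generation = c(rep(1:2, 3), rep(1, 3)),
    eggs_laid = c(20, 25, 30, 22, 27, 24, 21, 26, 23)
  )
  expect_warning(fecundity_anova(females2), "empty")
})
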