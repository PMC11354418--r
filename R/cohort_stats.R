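#' @title Diet-comparison statistics for rearing cohorts
#' @description Helpers that tabulate cohorts and the test battery run on
#'   them: sex-ratio chi-square with a standardized-residual post hoc,
#'   exact mortality tests with pairwise Bonferroni comparisons, Welch's
#'   heteroscedastic ANOVA with the Games-Howell post hoc on cumulative
#'   degree-days, per-instar Kruskal-Wallis tests, and a two-way ANOVA on
#'   fecundity and hatch rate with residual-normality and
#'   variance-homogeneity companions.
#' @name cohort_stats
NULL

.test_result <- function(statistic_name, statistic, df, p_value,
                         posthoc = NULL, extra = list()) {
  structure(c(list(statistic_name = statistic_name, statistic = statistic,
                   df = df, p_value = p_value, posthoc = posthoc), extra),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  df <- paste(signif(unlist(x$df), 4), collapse = ", ")
  cat(sprintf("%s = %.4g, df = %s, p = %.4g\n",
              x$statistic_name, x$statistic, df, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Tabulate adult sexes by diet
#'
#' @param log a `rearing_log`, possibly spanning several diets (one
#'   generation). Individuals of undetermined or unassigned sex are
#'   excluded.
#' @return integer matrix, diets in rows, columns `male`, `female`.
#' @export
sex_table <- function(log) {
  keep <- !is.na(log$sex) & log$sex %in% c("male", "female")
  tab <- table(factor(log$diet[keep]),
               factor(log$sex[keep], levels = c("male", "female")))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Tabulate pre-adult mortality by diet
#'
#' Mortality is death before entering the adult stage, out of the initial
#' cohort.
#'
#' @param log a `rearing_log` (one generation).
#' @return integer matrix, diets in rows, columns `died`, `survived`.
#' @export
mortality_table <- function(log) {
  died <- tapply(is.na(log$date_AD), log$diet, sum)
  total <- tapply(log$individual_id, log$diet, length)
  m <- cbind(died = as.integer(died), survived = as.integer(total - died))
  rownames(m) <- names(died)
  m
}

.drop_zero_rows <- function(counts) {
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning("dropping diet(s) with no observations: ",
            paste(rownames(counts)[zero], collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
  }
  counts
}

#' Sex-ratio homogeneity test with residual post hoc
#'
#' Pearson's chi-square test (no continuity correction) of homogeneity of
#' sex composition across diets, followed by a cell-level post hoc on the
#' standardized Pearson residuals: each residual is referred to the
#' standard normal, two-sided, with Bonferroni adjustment over all cells.
#'
#' @param counts diet x sex integer matrix (see [sex_table()]).
#' @param alpha significance level for the post hoc flags.
#' @return a `cohort_test` with a per-cell `posthoc` data frame
#'   (`diet`, `sex`, `residual`, `p_raw`, `p_adj`, `significant`).
#' @export
sex_ratio_test <- function(counts, alpha = 0.05) {
  if (all(counts == 0)) stop("all-zero sex table")
  counts <- .drop_zero_rows(counts)
  if (nrow(counts) < 2) stop("need at least two diets")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  z <- ct$stdres
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- pmin(1, p_raw * length(z))
  posthoc <- data.frame(
    diet = rep(rownames(counts), times = ncol(counts)),
    sex = rep(colnames(counts), each = nrow(counts)),
    residual = as.vector(z),
    p_raw = as.vector(p_raw),
    p_adj = as.vector(p_adj),
    significant = as.vector(p_adj <= alpha),
    stringsAsFactors = FALSE
  )
  .test_result("chi2", unname(ct$statistic), unname(ct$parameter),
               ct$p.value, posthoc)
}

#' Mortality comparison by exact tests
#'
#' Fisher's exact test on the full diet x (died, survived) table, followed
#' by all pairwise 2x2 exact tests with Bonferroni adjustment.
#'
#' @param counts diet x outcome integer matrix (see [mortality_table()]).
#' @param alpha significance level for the pairwise flags.
#' @return a `cohort_test`; `posthoc` has one row per diet pair.
#' @export
mortality_test <- function(counts, alpha = 0.05) {
  if (all(counts == 0)) stop("all-zero mortality table")
  counts <- .drop_zero_rows(counts)
  if (nrow(counts) < 2) stop("need at least two diets")
  overall <- stats::fisher.test(counts, workspace = 2e7)
  pairs <- utils::combn(rownames(counts), 2)
  p_raw <- apply(pairs, 2, function(pr) {
    stats::fisher.test(counts[pr, , drop = FALSE])$p.value
  })
  p_adj <- pmin(1, p_raw * ncol(pairs))
  posthoc <- data.frame(
    pair = apply(pairs, 2, paste, collapse = "-"),
    p_raw = p_raw, p_adj = p_adj,
    significant = p_adj <= alpha,
    stringsAsFactors = FALSE
  )
  .test_result("exact", NA_real_, NA_real_, overall$p.value, posthoc)
}

.check_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("every group needs at least two observations")
  }
  if (stats::var(unlist(groups)) == 0) {
    stop("degenerate input: all observations identical")
  }
  groups
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' One-way analysis of variance without the equal-variance assumption
#' (Welch's F with a Satterthwaite fractional denominator df), the
#' appropriate omnibus test for cumulative degree-days whose dispersion
#' differs strongly between diets.
#'
#' @param groups named list of numeric vectors (one per diet), each with at
#'   least two observations and not all observations identical overall.
#' @return a `cohort_test` with statistic `F` and `df = c(df1, df2)`.
#' @export
welch_anova <- function(groups) {
  groups <- .check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)))
  ht <- stats::oneway.test(values ~ g, var.equal = FALSE)
  .test_result("F", unname(ht$statistic), unname(ht$parameter), ht$p.value)
}

#' Games-Howell pairwise comparisons
#'
#' Pairwise mean comparisons that assume neither equal variances nor equal
#' sample sizes: for groups i and j the statistic
#' `q = |m_i - m_j| / sqrt((s_i^2/n_i + s_j^2/n_j) / 2)` is referred to the
#' studentized range with the total number of groups and the
#' Welch-Satterthwaite degrees of freedom of the pair.
#'
#' @inheritParams welch_anova
#' @param alpha significance level for the flags.
#' @return data frame with one row per pair: `pair`, `diff`, `se`, `df`,
#'   `q`, `p`, `significant`.
#' @export
games_howell <- function(groups, alpha = 0.05) {
  groups <- .check_groups(groups)
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, stats::var, 0)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    q <- abs(m[i] - m[j]) / sqrt(se2 / 2)
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    c(diff = unname(m[i] - m[j]), se = unname(sqrt(se2)), df = unname(df),
      q = unname(q), p = unname(p))
  })
  data.frame(
    pair = apply(pairs, 2, function(ij) {
      paste(names(groups)[ij], collapse = "-")
    }),
    t(out),
    significant = out["p", ] <= alpha,
    stringsAsFactors = FALSE
  )
}

#' Per-instar Kruskal-Wallis tests of diet effect on degree-days
#'
#' For each instar independently, a Kruskal-Wallis rank test (with the
#' usual tie correction) of the diet effect on the degree-days accumulated
#' in that instar. Instars represented in fewer than two diets are skipped
#' with a warning.
#'
#' @param df data frame with columns `stage`, `diet`, `add` (one row per
#'   individual per instar, e.g. a ledger joined to diet labels).
#' @return named list of `cohort_test` objects, one per tested instar.
#' @export
kruskal_wallis_per_instar <- function(df) {
  stopifnot(all(c("stage", "diet", "add") %in% names(df)))
  out <- list()
  for (s in intersect(stage_codes(), unique(df$stage))) {
    sub <- df[df$stage == s, ]
    if (length(unique(sub$diet)) < 2) {
      warning("instar ", s, " observed in fewer than two diets; skipped")
      next
    }
    kt <- stats::kruskal.test(sub$add, factor(sub$diet))
    out[[s]] <- .test_result("H", unname(kt$statistic),
                             unname(kt$parameter), kt$p.value)
  }
  out
}

#' Two-way ANOVA on fecundity and hatch rate
#'
#' Fits eggs per female (and, when hatch counts are present, the hatched
#' fraction) against diet and generation as fixed factors, reporting
#' type-II sums of squares so unbalanced designs (e.g. a diet lost in one
#' generation) are handled; companion diagnostics are the Lilliefors test
#' on the model residuals and Levene's test across diet x generation
#' groups.
#'
#' @param females data frame with one row per female: `diet`, `generation`,
#'   `eggs_laid` and optionally `eggs_hatched`.
#' @return list with elements `eggs` (per-factor `cohort_test`s),
#'   `hatch` (idem, or NULL), `normality`, `levene`.
#' @export
fecundity_anova <- function(females) {
  stopifnot(all(c("diet", "generation", "eggs_laid") %in% names(females)))
  if (length(unique(females$diet)) < 2 ||
      length(unique(females$generation)) < 2) {
    stop("need at least two diets and two generations")
  }
  females$diet <- factor(females$diet)
  females$generation <- factor(females$generation)
  if (any(table(females$diet, females$generation) == 0)) {
    warning("empty diet x generation cell; type-II sums of squares used")
  }
  fit_one <- function(y) {
    if (stats::var(y) == 0) stop("degenerate response: all values identical")
    fit <- stats::lm(y ~ diet + generation, data = females)
    aq <- car::Anova(fit, type = 2)
    terms <- rownames(aq)
    res <- list()
    for (tm in c("diet", "generation")) {
      i <- match(tm, terms)
      res[[tm]] <- .test_result(
        "F", aq$`F value`[i], c(aq$Df[i], aq$Df[match("Residuals", terms)]),
        aq$`Pr(>F)`[i])
    }
    res$fit <- fit
    res
  }
  eggs <- fit_one(females$eggs_laid)
  hatch <- NULL
  if ("eggs_hatched" %in% names(females) && any(!is.na(females$eggs_hatched))) {
    frac <- females$eggs_hatched / females$eggs_laid
    hatch <- fit_one(frac)
  }
  resid <- stats::residuals(eggs$fit)
  lt <- nortest::lillie.test(resid)
  lev <- car::leveneTest(stats::formula(eggs_laid ~ diet:generation),
                         data = females)
  list(
    eggs = eggs[c("diet", "generation")],
    hatch = if (!is.null(hatch)) hatch[c("diet", "generation")],
    normality = .test_result("D", unname(lt$statistic), NA_real_, lt$p.value),
    levene = .test_result("F", lev$`F value`[1],
                          c(lev$Df[1], lev$Df[2]), lev$`Pr(>F)`[1])
  )
}
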