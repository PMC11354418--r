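#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.875 -> 0.88 at two digits), the
#' convention of published rearing tables, rather than the round-half-even
#' rule of [base::round()]. A small absolute guard absorbs binary
#' representation error so that values intended as exact halves (e.g. the
#' mean of two 2-decimal numbers) round up reliably.
#'
#' @param x numeric vector (nonnegative in all table uses; negatives round
#'   half away from zero).
#' @param digits decimal digits.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-8) / f
}

.fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", round_half_up(x, 2)))
.fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", round_half_up(x, 1)))

#' Render a life table as text
#'
#' Produces the published table layout: one row per stage with the number
#' living and the survival columns rounded half-up to two decimals (computed
#' from raw counts first, rounded only here), the degree-day expectation of
#' life to one decimal, then the subsequent brood's egg count and the
#' population trend to two decimals. Rendering is deterministic: the same
#' table yields byte-identical text.
#'
#' @param table a `life_table`.
#' @return character vector of tab-separated lines.
#' @export
render_life_table <- function(table) {
  header <- paste("Instar (x)", "Number Living (N)", "Fraction Surviving (lx)",
                  "Period Survival (px)", "Period Mortality (qx)",
                  "Frequence of Deaths (dx)", "Expectation of Life (ADD) (ex)",
                  sep = "\t")
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(table$stage[i], table$n[i],
          .fmt2(table$lx[i]), .fmt2(table$px[i]), .fmt2(table$qx[i]),
          .fmt2(table$dx[i]), .fmt1(table$ex[i]), sep = "\t")
  }, "")
  c(header, rows,
    paste("EG", attr(table, "eggs_next"), sep = "\t"),
    paste0("T = ", sprintf("%.2f", round_half_up(attr(table, "trend"), 2))))
}

#' @export
print.life_table <- function(x, ...) {
  diet <- attr(x, "diet"); gen <- attr(x, "generation")
  if (!is.na(diet)) cat(sprintf("Cohort: diet %s, generation %s\n", diet, gen))
  cat(render_life_table(x), sep = "\n")
  invisible(x)
}

#' Tidy life-table export
#'
#' One row per stage with cohort labels and unrounded columns, suitable for
#' CSV export or binding across cohorts.
#'
#' @param table a `life_table`.
#' @return plain data frame `diet, generation, stage, n, lx, px, qx, dx, ex`.
#' @export
tidy_life_table <- function(table) {
  data.frame(diet = attr(table, "diet"),
             generation = attr(table, "generation"),
             as.data.frame(table),
             stringsAsFactors = FALSE)
}
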