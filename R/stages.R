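#' Developmental stage codes
#'
#' The post-embryonic development of the reared bugs is tracked through seven
#' ordered stages: the egg (`EG`, the biofix from which degree-days are
#' accumulated), five nymphal instars (`N1`--`N5`) and the adult (`AD`).
#'
#' @return Character vector of the seven stage codes in developmental order.
#' @export
stage_codes <- function() {
  c("EG", "N1", "N2", "N3", "N4", "N5", "AD")
}

#' @rdname stage_codes
#' @param stage character vector of stage codes.
#' @return `stage_index()` returns the 1-based position of each code in the
#'   developmental order (EG = 1, AD = 7).
#' @export
stage_index <- function(stage) {
  i <- match(stage, stage_codes())
  if (anyNA(i) && !all(is.na(stage))) {
    bad <- unique(stage[is.na(i) & !is.na(stage)])
    stop("unknown stage code(s): ", paste(bad, collapse = ", "))
  }
  i
}

# column names holding stage entry dates in a rearing log
stage_date_cols <- function() paste0("date_", stage_codes())
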