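#' Daqu quality grades
#'
#' Light-flavor Daqu blocks are graded into three quality classes from their
#' cross-section: premium (`"P"`, grayish-blue center, thin Pizhang rim),
#' first grade (`"F"`, red spot or line in the center, small dark edge areas)
#' and second grade (`"S"`, cracks or black rings, larger dark areas, thick
#' rim). The order `P < F < S` is used only for stratification bookkeeping.
#'
#' @return Character vector `c("P", "F", "S")`.
#' @export
#' @examples
#' daqu_grades()
daqu_grades <- function() c("P", "F", "S")

#' @rdname daqu_grades
#' @param x character vector of grade codes.
#' @return `as_grade()` returns a factor with levels `P < F < S`.
#' @export
as_grade <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), daqu_grades())
  if (length(bad) > 0) {
    abort(paste0("unknown grade label(s): ", paste(bad, collapse = ", "),
                 " (valid: P, F, S)"))
  }
  factor(x, levels = daqu_grades(), ordered = TRUE)
}

check_grade <- function(grade) {
  if (length(grade) != 1L || !is.character(grade) || !grade %in% daqu_grades()) {
    abort("`grade` must be one of \"P\", \"F\", \"S\"")
  }
  grade
}
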