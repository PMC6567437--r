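#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

emmr_log <- function(..., verbose = getOption("emmr.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[emmr] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Multiset containment for character vectors
#' @noRd
multiset_contains <- function(big, small) {
  if (length(small) == 0L) return(TRUE)
  tb <- table(big)
  ts <- table(small)
  all(names(ts) %in% names(tb)) && all(ts <= tb[names(ts)])
}

#' Split a "a;b;c" field into a character vector
#' @noRd
split_field <- function(x) {
  if (length(x) == 0L || is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "[;|]")[[1]])
}

join_field <- function(x) paste(x, collapse = ";")

#' Parse a molecular formula string like "C21H27N7O14P2"
#'
#' Returns a named integer vector of element counts. Elements are one capital
#' letter optionally followed by one lowercase letter, with an optional count.
#'
#' @param formula formula string
#' @param charge net charge (kept as the "charge" attribute)
#' @return named integer vector with a `charge` attribute
#' @export
parse_formula <- function(formula, charge = 0L) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (paste(toks, collapse = "") != formula) {
    stop("unparsable formula: ", formula)
  }
  counts <- integer(0)
  for (t in toks) {
    el <- sub("[0-9]+$", "", t)
    n <- sub("^[A-Za-z]+", "", t)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  attr(counts, "charge") <- as.integer(charge)
  counts
}

#' Format an element-count vector back into a formula string
#' @noRd
format_formula <- function(counts) {
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    n <- counts[[e]]
    if (n == 0L) "" else if (n == 1L) e else paste0(e, n)
  }, ""), collapse = "")
}
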