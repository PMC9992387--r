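# Small shared helpers: logging, list-cell (de)serialisation, checks.

the <- new.env(parent = emptyenv())
the$verbose <- FALSE

#' Toggle stage logging
#'
#' Every analysis stage can log its input counts, exclusions and
#' parameter values. Logging is off by default; turn it on for audit
#' trails of long pipeline runs.
#'
#' @param on Logical; `TRUE` enables logging via `message()`.
#' @return The previous setting, invisibly.
#' @export
osteokit_verbose <- function(on = TRUE) {
  old <- the$verbose
  the$verbose <- isTRUE(on)
  invisible(old)
}

ok_log <- function(stage, ...) {
  if (isTRUE(the$verbose)) {
    message(sprintf("[osteokit:%s] %s", stage, sprintf(...)))
  }
  invisible(NULL)
}

# "1;4;17" -> c(1L, 4L, 17L); "" / NA -> integer(0)
parse_int_list <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(integer(0))
  out <- suppressWarnings(as.integer(strsplit(trimws(x), ";", fixed = TRUE)[[1]]))
  if (anyNA(out)) return(NULL)
  out
}

format_int_list <- function(x) paste(x, collapse = ";")

# "cut_defleshing:2;scrape:1" -> named integer vector; "" -> empty vector
parse_mark_list <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(stats::setNames(integer(0), character(0)))
  }
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  kinds <- vapply(kv, `[`, character(1), 1)
  counts <- vapply(kv, function(p) {
    if (length(p) < 2) 1L else suppressWarnings(as.integer(p[2]))
  }, integer(1))
  if (anyNA(counts)) return(NULL)
  stats::setNames(counts, kinds)
}

format_mark_list <- function(x) {
  if (length(x) == 0) return("")
  paste(sprintf("%s:%d", names(x), as.integer(x)), collapse = ";")
}

# round half away from zero to `digits` decimals (printed-table convention)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(row, field, why) {
  stop(sprintf("row %d, field '%s': %s", row, field, why), call. = FALSE)
}
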