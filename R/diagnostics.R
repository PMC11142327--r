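#' Diagnostic records
#'
#' Every stage of the compiler (lexing, parsing, semantic resolution,
#' restriction checks, SBML import) reports problems as diagnostic records
#' rather than bare strings, so callers can filter by severity and tools can
#' print machine-parseable `SEVERITY file:line:col message` lines.
#'
#' @param severity `"error"` or `"warning"`.
#' @param message Human-readable description.
#' @param line,col 1-based source position, `NA` when not applicable.
#' @return A list of class `ant_diagnostic`.
#' @keywords internal
ant_diagnostic <- function(severity, message, line = NA_integer_, col = NA_integer_) {
  stopifnot(severity %in% c("error", "warning"))
  structure(
    list(severity = severity, message = message,
         line = as.integer(line), col = as.integer(col)),
    class = "ant_diagnostic"
  )
}

#' @export
print.ant_diagnostic <- function(x, ...) {
  cat(format_diagnostic(x), "\n", sep = "")
  invisible(x)
}

#' Format diagnostics as `SEVERITY line:col message` lines
#'
#' @param diags A single diagnostic or a list of them.
#' @param file Optional file name to prefix positions with.
#' @return Character vector, one line per diagnostic.
#' @export
format_diagnostic <- function(diags, file = NULL) {
  if (inherits(diags, "ant_diagnostic")) diags <- list(diags)
  vapply(diags, function(d) {
    pos <- if (is.na(d$line)) "-" else paste0(d$line, ":", ifelse(is.na(d$col), 1L, d$col))
    loc <- if (is.null(file)) pos else paste0(file, ":", pos)
    paste(toupper(d$severity), loc, d$message)
  }, character(1))
}

diag_errors <- function(diags) {
  Filter(function(d) d$severity == "error", diags)
}

diag_warnings <- function(diags) {
  Filter(function(d) d$severity == "warning", diags)
}

#' Stop with a source-located compiler error
#'
#' Raises a condition of class `ant_error` carrying the source location, so
#' tests and the command-line driver can recover the position.
#' @keywords internal
ant_stop <- function(message, line = NA_integer_, col = NA_integer_,
                     class = "ant_error") {
  pos <- if (!is.na(line)) sprintf(" [line %d, col %d]", line, ifelse(is.na(col), 1L, col)) else ""
  cond <- structure(
    class = c(class, "ant_error", "error", "condition"),
    list(message = paste0(message, pos), call = NULL,
         line = as.integer(line), col = as.integer(col))
  )
  stop(cond)
}
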