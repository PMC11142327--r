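# Lexer for the reaction-network model language.
#
# Lexical conventions:
#   * `//` starts a comment running to end of line.
#   * statements are separated by newline or `;` (the parser decides which
#     `;` separate statements and which introduce a kinetic law).
#   * `:=` is one token, distinct from `=`.
#   * `'` directly after an identifier is a PRIME (rate-of-change marker).
#   * `$` directly before an identifier marks a boundary species.
#   * typeset punctuation (Unicode minus, en/em dash, curly quotes) is
#     normalised to its ASCII equivalent before scanning, so text copied out
#     of formatted documents lexes identically to plain ASCII.

# one-to-one character normalisation: keeps line/column positions intact
normalize_source <- function(text) {
  from <- c("−", "–", "—", "“", "”", "‘", "’")
  to <- c("-", "-", "-", "\"", "\"", "'", "'")
  for (i in seq_along(from)) text <- gsub(from[i], to[i], text, fixed = TRUE)
  text
}

ant_token <- function(kind, text, line, col, value = NULL) {
  list(kind = kind, text = text, line = line, col = col, value = value)
}

#' Tokenize model-language text
#'
#' Splits source text into a flat token sequence with 1-based line/column
#' positions. Comments (`//` to end of line) are dropped; newlines are kept
#' as `NEWLINE` tokens because they separate statements.
#'
#' @param text A length-one character scalar (UTF-8).
#' @return A list of tokens; each token is a list with fields `kind`, `text`,
#'   `line`, `col` and (for numbers) `value`.
#' @examples
#' toks <- ant_tokenize("A -> B; k1*A")
#' vapply(toks, `[[`, "", "kind")
#' @export
ant_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- normalize_source(enc2utf8(text))
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  n <- length(chars)
  toks <- vector("list", 64L)
  ntok <- 0L
  push <- function(tok) {
    ntok <<- ntok + 1L
    if (ntok > length(toks)) length(toks) <<- 2L * ntok
    toks[[ntok]] <<- tok
  }
  i <- 1L
  line <- 1L
  col <- 1L
  is_id_start <- function(ch) grepl("^[A-Za-z_]$", ch)
  is_id_char <- function(ch) grepl("^[A-Za-z0-9_]$", ch)
  is_digit <- function(ch) grepl("^[0-9]$", ch)

  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") {
      push(ant_token("NEWLINE", "\n", line, col))
      i <- i + 1L
      line <- line + 1L
      col <- 1L
      next
    }
    if (ch %in% c(" ", "\t", "\r")) {
      i <- i + 1L
      col <- col + 1L
      next
    }
    if (ch == "/" && i < n && chars[i + 1L] == "/") {
      while (i <= n && chars[i] != "\n") {
        i <- i + 1L
        col <- col + 1L
      }
      next
    }
    start_col <- col
    if (is_id_start(ch)) {
      j <- i
      while (j <= n && is_id_char(chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      col <- col + (j - i)
      i <- j
      # a prime directly after an identifier (no space) is its own token
      push(ant_token("ID", word, line, start_col))
      if (i <= n && chars[i] == "'") {
        push(ant_token("PRIME", "'", line, col))
        i <- i + 1L
        col <- col + 1L
      }
      next
    }
    if (is_digit(ch)) {
      j <- i
      while (j <= n && is_digit(chars[j])) j <- j + 1L
      if (j <= n && chars[j] == "." && j < n && is_digit(chars[j + 1L])) {
        j <- j + 1L
        while (j <= n && is_digit(chars[j])) j <- j + 1L
      }
      if (j <= n && chars[j] %in% c("e", "E")) {
        k <- j + 1L
        if (k <= n && chars[k] %in% c("+", "-")) k <- k + 1L
        if (k <= n && is_digit(chars[k])) {
          j <- k
          while (j <= n && is_digit(chars[j])) j <- j + 1L
        }
      }
      numtext <- paste(chars[i:(j - 1L)], collapse = "")
      col <- col + (j - i)
      i <- j
      push(ant_token("NUMBER", numtext, line, start_col, value = as.numeric(numtext)))
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      buf <- character(0)
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\n") {
          ant_stop("unterminated string literal", line, start_col, "ant_lex_error")
        }
        buf <- c(buf, chars[j])
        j <- j + 1L
      }
      if (j > n) ant_stop("unterminated string literal", line, start_col, "ant_lex_error")
      push(ant_token("STRING", paste(buf, collapse = ""), line, start_col,
                     value = paste(buf, collapse = "")))
      col <- col + (j - i + 1L)
      i <- j + 1L
      next
    }
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    kind2 <- switch(two,
      "->" = "ARROW", ":=" = "WALRUS", ">=" = "GE", "<=" = "LE",
      "==" = "EQEQ", "!=" = "NEQ", NULL)
    if (!is.null(kind2)) {
      push(ant_token(kind2, two, line, start_col))
      i <- i + 2L
      col <- col + 2L
      next
    }
    if (ch == "$") {
      if (i < n && is_id_start(chars[i + 1L])) {
        push(ant_token("DOLLAR", "$", line, start_col))
        i <- i + 1L
        col <- col + 1L
        next
      }
      ant_stop("'$' must directly precede an identifier", line, start_col, "ant_lex_error")
    }
    kind1 <- switch(ch,
      "=" = "ASSIGN", "(" = "LPAREN", ")" = "RPAREN", "{" = "LBRACE",
      "}" = "RBRACE", "," = "COMMA", ";" = "SEMI", ":" = "COLON",
      "+" = "PLUS", "-" = "MINUS", "*" = "STAR", "/" = "SLASH",
      "^" = "CARET", ">" = "GT", "<" = "LT", "." = "DOT", NULL)
    if (!is.null(kind1)) {
      push(ant_token(kind1, ch, line, start_col))
      i <- i + 1L
      col <- col + 1L
      next
    }
    ant_stop(sprintf("illegal character '%s'", ch), line, start_col, "ant_lex_error")
  }
  toks[seq_len(ntok)]
}
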