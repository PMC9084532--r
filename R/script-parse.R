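# Parser for the rule-script dialect: sequential statements, if-blocks over
# genotype equality tests combined with and/or, assignments to `risk` and
# `comment`, and an optional early `return risk, comment`.

KEYWORDS <- c("if", "then", "end", "and", "or", "return")

# --- tokenizer -------------------------------------------------------------

# Tokens are lists(type, value, line, col). Types: ident, number, string,
# eqeq, assign, lparen, rparen, comma, keyword.
tokenize_script <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  tokens <- list()
  push <- function(type, value, line, col) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           line = line, col = col)
  }
  for (li in seq_along(lines)) {
    s <- lines[li]
    i <- 1L
    nc <- nchar(s)
    while (i <= nc) {
      rest <- substr(s, i, nc)
      ws <- regmatches(rest, regexpr("^[ \t\r]+", rest))
      if (length(ws)) { i <- i + nchar(ws); next }
      rest <- substr(s, i, nc)

      # string literal: straight or typographic double quotes, no escapes
      m <- regmatches(rest, regexpr("^(\"[^\"]*\"|“[^”]*”)", rest))
      if (length(m)) {
        inner <- substr(m, 2L, nchar(m) - 1L)
        push("string", inner, li, i)
        i <- i + nchar(m); next
      }
      if (startsWith(rest, "==")) { push("eqeq", "==", li, i); i <- i + 2L; next }
      ch <- substr(rest, 1L, 1L)
      if (ch == "=") { push("assign", "=", li, i); i <- i + 1L; next }
      if (ch == "(") { push("lparen", "(", li, i); i <- i + 1L; next }
      if (ch == ")") { push("rparen", ")", li, i); i <- i + 1L; next }
      if (ch == ",") { push("comma", ",", li, i); i <- i + 1L; next }
      m <- regmatches(rest, regexpr("^-?[0-9]+(\\.[0-9]+)?", rest))
      if (length(m)) {
        push("number", as.numeric(m), li, i)
        i <- i + nchar(m); next
      }
      # identifier, optionally in positional colon form (chr1:16949)
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*(:[0-9]+)?", rest))
      if (length(m)) {
        if (m %in% KEYWORDS) push("keyword", m, li, i) else push("ident", m, li, i)
        i <- i + nchar(m); next
      }
      stop("syntax error at line ", li, ", col ", i,
           ": unexpected character ", sQuote(ch))
    }
  }
  tokens
}

# --- recursive-descent parser ---------------------------------------------

new_token_stream <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env
}

ts_peek <- function(ts) if (ts$i <= length(ts$tokens)) ts$tokens[[ts$i]] else NULL

ts_next <- function(ts) {
  tok <- ts_peek(ts)
  if (!is.null(tok)) ts$i <- ts$i + 1L
  tok
}

tok_desc <- function(tok) {
  if (is.null(tok)) return("end of input")
  paste0(sQuote(as.character(tok$value)), " at line ", tok$line,
         ", col ", tok$col)
}

ts_expect <- function(ts, type, value = NULL) {
  tok <- ts_next(ts)
  ok <- !is.null(tok) && tok$type == type &&
    (is.null(value) || identical(as.character(tok$value), value))
  if (!ok) {
    want <- if (is.null(value)) type else sQuote(value)
    stop("syntax error: expected ", want, ", got ", tok_desc(tok))
  }
  tok
}

ts_at_keyword <- function(ts, kw) {
  tok <- ts_peek(ts)
  !is.null(tok) && tok$type == "keyword" && tok$value == kw
}

#' Parse rule-script text into a program AST
#'
#' The accepted grammar is the dialect the rule engine evaluates:
#' `if <expr> then <statements> end` blocks; equality atoms
#' `<variant> == "<genotype>"` where the variant is an rsID-style identifier
#' or a positional reference (`chr1:16949`, sanitized to `chr1_16949`);
#' `and`/`or` connectives with `and` binding tighter than `or`, plus
#' parentheses; `risk = <number>`; `comment = "<string>"`; and
#' `return risk, comment`, which may only close a block body or the program.
#' Top-level bindings of the form `<variant> = "<genotype>"` — the scaffolding
#' an upstream tool would prepend — are accepted and ignored with a warning,
#' since genotypes are bound from the store at evaluation time.
#'
#' @param text the script source.
#' @return an object of class `rule_program` with fields `statements` (the
#'   AST) and `referenced_vars` (every variable appearing in a condition).
#' @export
parse_script <- function(text) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  if (!nzchar(trimws(text))) stop("empty script")
  ts <- new_token_stream(tokenize_script(text))
  statements <- parse_stmt_list(ts, top_level = TRUE)
  tok <- ts_peek(ts)
  if (!is.null(tok)) stop("syntax error: unexpected ", tok_desc(tok))
  new_rule_program(statements)
}

new_rule_program <- function(statements) {
  structure(list(statements = statements,
                 referenced_vars = collect_vars(statements)),
            class = "rule_program")
}

#' @export
print.rule_program <- function(x, ...) {
  cat("<rule_program: ", length(x$statements), " top-level statement(s), ",
      length(x$referenced_vars), " referenced variant(s)>\n", sep = "")
  invisible(x)
}

# Parses statements until `end` (inside an if body) or end of input.
# A `return` must be the final statement of the sequence.
parse_stmt_list <- function(ts, top_level) {
  stmts <- list()
  saw_return <- FALSE
  repeat {
    tok <- ts_peek(ts)
    done <- is.null(tok) || (!top_level && ts_at_keyword(ts, "end"))
    if (done) break
    if (saw_return) {
      stop("syntax error: `return risk, comment` must be the last statement ",
           "of its block, got ", tok_desc(tok))
    }
    stmt <- parse_stmt(ts, top_level)
    if (is.null(stmt)) next       # ignored top-level binding
    if (stmt$type == "return") saw_return <- TRUE
    stmts[[length(stmts) + 1L]] <- stmt
  }
  stmts
}

parse_stmt <- function(ts, top_level) {
  tok <- ts_peek(ts)
  if (is.null(tok)) stop("syntax error: unexpected end of input")
  if (tok$type == "keyword") {
    if (tok$value == "if") return(parse_if(ts))
    if (tok$value == "return") {
      ts_next(ts)
      ts_expect(ts, "ident", "risk")
      ts_expect(ts, "comma")
      ts_expect(ts, "ident", "comment")
      return(list(type = "return"))
    }
    stop("syntax error: unexpected keyword ", tok_desc(tok))
  }
  if (tok$type != "ident") stop("syntax error: unexpected ", tok_desc(tok))
  name <- tok$value
  ts_next(ts)
  if (name == "risk") {
    ts_expect(ts, "assign")
    num <- ts_expect(ts, "number")
    return(list(type = "assign_risk", value = as.numeric(num$value)))
  }
  if (name == "comment") {
    ts_expect(ts, "assign")
    str <- ts_expect(ts, "string")
    return(list(type = "assign_comment", value = as.character(str$value)))
  }
  nxt <- ts_peek(ts)
  if (!is.null(nxt) && nxt$type == "assign") {
    ts_next(ts)
    val <- ts_next(ts)
    if (is.null(val) || val$type != "string") {
      stop("assignment to ", sQuote(name), " at line ", tok$line,
           ": only `risk` and `comment` may be assigned")
    }
    if (!top_level) {
      stop("assignment to ", sQuote(name), " at line ", tok$line,
           ": only `risk` and `comment` may be assigned inside a block")
    }
    warning("ignoring top-level genotype binding ", sQuote(name),
            " = \"", val$value, "\" (line ", tok$line,
            "); genotypes are taken from the store",
            call. = FALSE)
    return(NULL)
  }
  stop("syntax error: unexpected ", tok_desc(tok),
       " (a bare condition is not a statement)")
}

parse_if <- function(ts) {
  ts_expect(ts, "keyword", "if")
  cond <- parse_or(ts)
  ts_expect(ts, "keyword", "then")
  body <- parse_stmt_list(ts, top_level = FALSE)
  tok <- ts_next(ts)
  if (is.null(tok) || tok$type != "keyword" || tok$value != "end") {
    stop("syntax error: `if` without matching `end` (got ", tok_desc(tok), ")")
  }
  list(type = "if", cond = cond, body = body)
}

# `and` binds tighter than `or`; both left-associative.
parse_or <- function(ts) {
  left <- parse_and(ts)
  while (ts_at_keyword(ts, "or")) {
    ts_next(ts)
    left <- list(type = "or", left = left, right = parse_and(ts))
  }
  left
}

parse_and <- function(ts) {
  left <- parse_atom(ts)
  while (ts_at_keyword(ts, "and")) {
    ts_next(ts)
    left <- list(type = "and", left = left, right = parse_atom(ts))
  }
  left
}

parse_atom <- function(ts) {
  tok <- ts_peek(ts)
  if (is.null(tok)) stop("syntax error: unexpected end of input in condition")
  if (tok$type == "lparen") {
    ts_next(ts)
    e <- parse_or(ts)
    ts_expect(ts, "rparen")
    return(e)
  }
  if (tok$type != "ident") {
    stop("syntax error: expected a variant identifier in condition, got ",
         tok_desc(tok))
  }
  ts_next(ts)
  var <- tok$value
  if (grepl(":", var, fixed = TRUE)) var <- sanitize_identifier(var)
  ts_expect(ts, "eqeq")
  str <- ts_expect(ts, "string")
  literal <- tryCatch(parse_genotype_literal(str$value), error = function(e) {
    stop("invalid genotype literal in condition at line ", str$line, ": ",
         conditionMessage(e), call. = FALSE)
  })
  list(type = "eq", var = var, literal = literal,
       raw_literal = as.character(str$value))
}

collect_vars <- function(stmts) {
  vars <- character(0)
  walk_expr <- function(e) {
    if (e$type == "eq") {
      vars <<- c(vars, e$var)
    } else {
      walk_expr(e$left); walk_expr(e$right)
    }
  }
  walk_stmts <- function(ss) {
    for (s in ss) {
      if (s$type == "if") { walk_expr(s$cond); walk_stmts(s$body) }
    }
  }
  walk_stmts(stmts)
  unique(vars)
}
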