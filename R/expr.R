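# Safe arithmetic expressions
#
# Generic rate laws and non-uniform density placements carry small arithmetic
# expressions in the document. These are parsed with a dedicated recursive-
# descent grammar -- +, -, *, /, ^, exp(), pow(), parentheses, numbers and a
# fixed variable set -- and never handed to R's evaluator, so a document can
# not execute host code.

#' Parse a safe arithmetic expression
#'
#' Grammar: numbers (decimal or scientific), variables (`v`, `ca`, `celsius`,
#' `d`, `r`), binary `+ - * / ^`, unary minus, parentheses, and the functions
#' `exp(x)` and `pow(x, y)`. Anything else is a parse error.
#'
#' @param text expression source, e.g. `"1e-4 + 2e-6 * d"`.
#' @param vars character vector of variable names allowed to appear.
#' @return an object of class `"nml_expr"`; evaluate it with [eval_expr()].
#' @examples
#' e <- parse_expr("0.1 * exp(-v / 20)", vars = "v")
#' eval_expr(e, list(v = 0))
#' @export
parse_expr <- function(text, vars = c("v", "ca", "celsius", "d", "r")) {
  toks <- expr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$vars <- vars; st$src <- text
  node <- expr_parse_sum(st)
  if (st$pos <= length(st$toks))
    stop("trailing input in expression: ", text)
  structure(list(ast = node, source = text, vars = vars),
            class = "nml_expr")
}

#' @param expr an `nml_expr`.
#' @param env named list of variable values (vectors recycle as usual).
#' @rdname parse_expr
#' @export
eval_expr <- function(expr, env = list()) {
  stopifnot(inherits(expr, "nml_expr"))
  expr_eval_node(expr$ast, env)
}

#' @export
print.nml_expr <- function(x, ...) {
  cat("<expression>", x$source, "\n"); invisible(x)
}

expr_tokenize <- function(text) {
  pat <- "\\s*([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?|[A-Za-z_][A-Za-z_0-9]*|[-+*/^(),])"
  toks <- character(0); rest <- text
  while (nzchar(trimws(rest))) {
    m <- regexpr(pat, rest, perl = TRUE)
    if (m != 1L) stop("cannot tokenize expression near: ", rest)
    tok <- trimws(regmatches(rest, m))
    toks <- c(toks, tok)
    rest <- substring(rest, attr(m, "match.length") + 1L)
  }
  toks
}

expr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
expr_take <- function(st) { t <- expr_peek(st); st$pos <- st$pos + 1L; t }
expr_expect <- function(st, what) {
  t <- expr_take(st)
  if (!identical(t, what))
    stop("expected '", what, "' in expression: ", st$src)
  t
}

expr_parse_sum <- function(st) {
  node <- expr_parse_product(st)
  repeat {
    op <- expr_peek(st)
    if (identical(op, "+") || identical(op, "-")) {
      expr_take(st)
      node <- list(op = op, a = node, b = expr_parse_product(st))
    } else return(node)
  }
}

expr_parse_product <- function(st) {
  node <- expr_parse_power(st)
  repeat {
    op <- expr_peek(st)
    if (identical(op, "*") || identical(op, "/")) {
      expr_take(st)
      node <- list(op = op, a = node, b = expr_parse_power(st))
    } else return(node)
  }
}

expr_parse_power <- function(st) {
  base <- expr_parse_unary(st)
  if (identical(expr_peek(st), "^")) {
    expr_take(st)
    return(list(op = "^", a = base, b = expr_parse_power(st)))  # right assoc
  }
  base
}

expr_parse_unary <- function(st) {
  if (identical(expr_peek(st), "-")) {
    expr_take(st)
    return(list(op = "neg", a = expr_parse_unary(st)))
  }
  if (identical(expr_peek(st), "+")) expr_take(st)
  expr_parse_atom(st)
}

expr_parse_atom <- function(st) {
  t <- expr_take(st)
  if (is.na(t)) stop("unexpected end of expression: ", st$src)
  if (grepl("^[0-9.]", t)) return(list(op = "num", value = as.numeric(t)))
  if (identical(t, "(")) {
    node <- expr_parse_sum(st); expr_expect(st, ")"); return(node)
  }
  if (identical(t, "exp")) {
    expr_expect(st, "("); a <- expr_parse_sum(st); expr_expect(st, ")")
    return(list(op = "exp", a = a))
  }
  if (identical(t, "pow")) {
    expr_expect(st, "("); a <- expr_parse_sum(st); expr_expect(st, ",")
    b <- expr_parse_sum(st); expr_expect(st, ")")
    return(list(op = "^", a = a, b = b))
  }
  if (grepl("^[A-Za-z_]", t)) {
    if (!t %in% st$vars)
      stop("unknown variable '", t, "' in expression: ", st$src)
    return(list(op = "var", name = t))
  }
  stop("unexpected token '", t, "' in expression: ", st$src)
}

expr_eval_node <- function(node, env) {
  switch(node$op,
    num = node$value,
    var = {
      v <- env[[node$name]]
      if (is.null(v)) stop("no value supplied for variable '", node$name, "'")
      v
    },
    neg = -expr_eval_node(node$a, env),
    exp = exp(expr_eval_node(node$a, env)),
    "+" = expr_eval_node(node$a, env) + expr_eval_node(node$b, env),
    "-" = expr_eval_node(node$a, env) - expr_eval_node(node$b, env),
    "*" = expr_eval_node(node$a, env) * expr_eval_node(node$b, env),
    "/" = expr_eval_node(node$a, env) / expr_eval_node(node$b, env),
    "^" = expr_eval_node(node$a, env) ^ expr_eval_node(node$b, env),
    stop("corrupt expression node")
  )
}
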