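## Boolean expression engine for gate truth tables.
##
## Grammar (precedence low to high):  OR ("+" or "|")  <  XOR ("^")
## <  AND ("&", "*", or the typographic dot)  <  NOT ("!").
## Variables are A1..A9; constants 0 and 1; parentheses as usual.

bool_tokenise <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  toks <- list()
  i <- 1L
  push <- function(type, value, pos)
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  while (i <= length(chars)) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("A", "a")) {
      j <- i + 1L
      num <- ""
      while (j <= length(chars) && grepl("[0-9]", chars[j])) {
        num <- paste0(num, chars[j]); j <- j + 1L
      }
      if (num == "")
        stop("parse error at position ", i, ": variable needs an index",
             call. = FALSE)
      push("var", as.integer(num), i)
      i <- j
      next
    }
    if (ch %in% c("0", "1")) { push("const", as.integer(ch), i); i <- i + 1L; next }
    op <- switch(ch,
                 "+" = "or", "|" = "or",
                 "^" = "xor",
                 "&" = "and", "*" = "and", "·" = "and", "∙" = "and",
                 "!" = "not",
                 "(" = "lpar", ")" = "rpar",
                 NULL)
    if (is.null(op))
      stop("parse error at position ", i, ": unexpected character '", ch, "'",
           call. = FALSE)
    push(op, ch, i)
    i <- i + 1L
  }
  toks
}

## recursive-descent parser -> nested list AST
bool_parse <- function(text) {
  toks <- bool_tokenise(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect_more <- function(what) {
    if (is.null(peek()))
      stop("parse error at end of input: expected ", what, call. = FALSE)
  }
  parse_or <- function() {
    left <- parse_xor()
    while (!is.null(peek()) && peek()$type == "or") {
      take(); right <- parse_xor()
      left <- list(op = "or", left, right)
    }
    left
  }
  parse_xor <- function() {
    left <- parse_and()
    while (!is.null(peek()) && peek()$type == "xor") {
      take(); right <- parse_and()
      left <- list(op = "xor", left, right)
    }
    left
  }
  parse_and <- function() {
    left <- parse_unary()
    while (!is.null(peek()) && peek()$type == "and") {
      take(); right <- parse_unary()
      left <- list(op = "and", left, right)
    }
    left
  }
  parse_unary <- function() {
    expect_more("an operand")
    t <- peek()
    if (t$type == "not") { take(); return(list(op = "not", parse_unary())) }
    if (t$type == "var") { take(); return(list(op = "var", t$value)) }
    if (t$type == "const") { take(); return(list(op = "const", t$value)) }
    if (t$type == "lpar") {
      take()
      inner <- parse_or()
      if (is.null(peek()) || peek()$type != "rpar")
        stop("parse error at position ", t$pos, ": unmatched '('", call. = FALSE)
      take()
      return(inner)
    }
    stop("parse error at position ", t$pos, ": unexpected '", t$value, "'",
         call. = FALSE)
  }
  ast <- parse_or()
  if (!is.null(peek()))
    stop("parse error at position ", peek()$pos, ": trailing input",
         call. = FALSE)
  ast
}

bool_eval_ast <- function(ast, inputs) {
  switch(ast$op,
         var = {
           if (ast[[2L]] > length(inputs))
             stop("expression uses A", ast[[2L]], " but only ",
                  length(inputs), " inputs were given", call. = FALSE)
           inputs[ast[[2L]]]
         },
         const = ast[[2L]],
         not = 1L - bool_eval_ast(ast[[2L]], inputs),
         and = bool_eval_ast(ast[[2L]], inputs) & bool_eval_ast(ast[[3L]], inputs),
         or = bool_eval_ast(ast[[2L]], inputs) | bool_eval_ast(ast[[3L]], inputs),
         xor = xor(bool_eval_ast(ast[[2L]], inputs),
                   bool_eval_ast(ast[[3L]], inputs)))
}

#' Evaluate a Boolean expression on an input word
#'
#' Expressions use variables `A1`, `A2`, ... with `!` (NOT), `&` or `*`
#' (AND), `+` or `|` (OR) and `^` (XOR), parenthesised freely;
#' precedence from high to low is NOT, AND, XOR, OR.  `A1 ^ A2` equals
#' `A1 & !A2 | !A1 & A2`.
#'
#' @param expr expression string (or a pre-parsed object from
#'   [parse_boolean()]).
#' @param inputs integer (0/1) vector of input bits; `inputs[i]` is
#'   `Ai`.
#' @return A single bit (integer 0 or 1).
#' @examples
#' eval_boolean("A1 ^ A2", c(1, 1))     # 0
#' eval_boolean("!(A1 & A2)", c(0, 0))  # NAND -> 1
#' @export
eval_boolean <- function(expr, inputs) {
  ast <- if (is.character(expr)) bool_parse(expr) else expr
  as.integer(bool_eval_ast(ast, as.integer(inputs)))
}

#' @rdname eval_boolean
#' @export
parse_boolean <- function(expr) bool_parse(expr)

#' Truth vector of an expression over all input words
#'
#' @param expr expression string.
#' @param n_inputs number of input variables.
#' @param words optional matrix of input words (rows); defaults to all
#'   `2^n_inputs` words in binary order.
#' @return Integer vector of outputs, one per word.
#' @export
boolean_truth_vector <- function(expr, n_inputs, words = NULL) {
  if (is.null(words)) words <- all_input_words(n_inputs)
  ast <- bool_parse(expr)
  apply(words, 1L, function(w) as.integer(bool_eval_ast(ast, w)))
}

## all 2^n input words, binary order (A1 is the most significant bit)
all_input_words <- function(n) {
  m <- vapply(0:(2^n - 1L),
              function(k) as.integer(intToBits(k))[n:1],
              integer(n))
  m <- t(matrix(m, nrow = n))
  dimnames(m) <- NULL
  m
}

#' Infer a minimal Boolean expression matching an output column
#'
#' Bounded exhaustive search: starting from literals (`Ai`, `!Ai`, 0,
#' 1), expressions are combined pairwise with AND, OR and XOR, keeping
#' the smallest expression found for each distinct truth vector, until
#' either the target vector is reached or the size bound is exhausted.
#'
#' @param outputs integer 0/1 vector over the rows of `words`.
#' @param words input-word matrix (one row per entry of `outputs`).
#' @param max_size maximal number of literals in the expression.
#' @return The expression string, or `NA_character_` if no expression
#'   within the bound matches.
#' @export
infer_expression <- function(outputs, words, max_size = 4L) {
  n <- ncol(words)
  key <- function(v) paste(v, collapse = "")
  target <- key(outputs)
  pool <- new.env(parent = emptyenv())
  add <- function(v, expr, size) {
    k <- key(v)
    cur <- pool[[k]]
    if (is.null(cur) || cur$size > size)
      pool[[k]] <- list(expr = expr, size = size, v = v)
  }
  for (i in seq_len(n)) {
    vi <- words[, i]
    add(vi, paste0("A", i), 1L)
    add(1L - vi, paste0("!A", i), 1L)
  }
  add(rep(0L, nrow(words)), "0", 1L)
  add(rep(1L, nrow(words)), "1", 1L)
  for (round in seq_len(max_size - 1L)) {
    if (!is.null(pool[[target]])) break
    entries <- as.list(pool)
    for (a in entries) for (b in entries) {
      if (a$size + b$size > max_size) next
      add(a$v & b$v, paste0("(", a$expr, ") & (", b$expr, ")"), a$size + b$size)
      add(a$v | b$v, paste0("(", a$expr, ") + (", b$expr, ")"), a$size + b$size)
      add(as.integer(xor(a$v, b$v)), paste0("(", a$expr, ") ^ (", b$expr, ")"),
          a$size + b$size)
    }
  }
  hit <- pool[[target]]
  if (is.null(hit)) NA_character_ else hit$expr
}
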