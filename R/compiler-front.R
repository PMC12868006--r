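# Front end of the high-level language compiler: lexer, recursive-descent
# parser, and semantic analysis (symbol resolution, type checking, overload
# dispatch).  The language is a small C-like layer over the VM: `let`
# declarations, 1-D heap arrays, `if`/`else`, `while`, `for`, user functions
# with arity+type overloading (inlined at call sites), `env` buffer
# declarations, `print`/`printc`, and built-in math functions mapping 1:1 to
# math operations.

LANG_KEYWORDS <- c("let", "env", "fn", "if", "else", "while", "for", "return",
                   "print", "printc")
LANG_BUILTINS <- c(sqrt = "SQRT", sin = "SIN", cos = "COS", tan = "TAN",
                   asin = "ASIN", acos = "ACOS", atan = "ATAN", exp = "EXP",
                   log = "LOG", erf = "ERF", abs = "ABS", floor = "FLOOR")
LANG_BUILTINS2 <- c(pow = "POW")   # two-argument built-ins

diag_stop <- function(line, col, msg) {
  d <- data.frame(severity = "error", line = line, col = col, message = msg,
                  stringsAsFactors = FALSE)
  cond <- structure(
    class = c("vm_diag_error", "error", "condition"),
    list(message = sprintf("line %d:%d: %s", line, col, msg),
         call = NULL, diagnostics = d))
  stop(cond)
}

# ---------------------------------------------------------------------------
# lexer

lex_source <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  toks <- vector("list", 256); nt <- 0
  add <- function(type, txt, line, col) {
    nt <<- nt + 1
    if (nt > length(toks)) length(toks) <<- 2L * nt
    toks[[nt]] <<- list(type = type, text = txt, line = line, col = col)
  }
  num_re <- "^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?"
  id_re <- "^[A-Za-z_][A-Za-z0-9_]*"
  two_char <- c("==", "!=", "<=", ">=", "&&", "||")
  one_char <- c("+", "-", "*", "/", "%", "!", "=", "<", ">", "(", ")",
                "{", "}", "[", "]", ";", ",", ":")
  for (ln in seq_along(lines)) {
    s <- lines[ln]; col <- 1L
    while (nchar(s) > 0) {
      ws <- regmatches(s, regexpr("^[ \t\r]+", s))
      if (length(ws)) { col <- col + nchar(ws); s <- substring(s, nchar(ws) + 1); next }
      if (substring(s, 1, 1) == "#") break
      m <- regmatches(s, regexpr(num_re, s))
      if (length(m) && nchar(m)) {
        add("num", m, ln, col); col <- col + nchar(m); s <- substring(s, nchar(m) + 1); next
      }
      m <- regmatches(s, regexpr(id_re, s))
      if (length(m) && nchar(m)) {
        add(if (m %in% LANG_KEYWORDS) m else "ident", m, ln, col)
        col <- col + nchar(m); s <- substring(s, nchar(m) + 1); next
      }
      p2 <- substring(s, 1, 2)
      if (p2 %in% two_char) {
        add("op", p2, ln, col); col <- col + 2L; s <- substring(s, 3); next
      }
      p1 <- substring(s, 1, 1)
      if (p1 %in% one_char) {
        add("op", p1, ln, col); col <- col + 1L; s <- substring(s, 2); next
      }
      diag_stop(ln, col, paste0("unexpected character '", p1, "'"))
    }
  }
  add("eof", "", length(lines), nchar(lines[length(lines)]) + 1L)
  toks[seq_len(nt)]
}

# ---------------------------------------------------------------------------
# parser

new_parser <- function(toks) {
  e <- new.env(parent = emptyenv())
  e$toks <- toks; e$i <- 1L
  e
}
p_peek <- function(ps) ps$toks[[ps$i]]
p_next <- function(ps) { t <- ps$toks[[ps$i]]; ps$i <- ps$i + 1L; t }
p_at <- function(ps, type, text = NULL) {
  t <- p_peek(ps)
  t$type == type && (is.null(text) || t$text == text)
}
p_expect <- function(ps, type, text = NULL) {
  t <- p_peek(ps)
  if (!p_at(ps, type, text)) {
    what <- if (is.null(text)) type else paste0("'", text, "'")
    diag_stop(t$line, t$col, paste0("expected ", what, ", found '",
                                    if (t$type == "eof") "end of input" else t$text, "'"))
  }
  p_next(ps)
}

node <- function(k, tok, ...) c(list(k = k, line = tok$line, col = tok$col), list(...))

#' Parse a source unit
#'
#' Parses program text in the package's small language into an abstract
#' syntax tree.  Syntax errors stop with a classed condition
#' (`vm_diag_error`) carrying a `diagnostics` data frame with line/column.
#'
#' @param text Program source text.
#' @param name Identifier used in diagnostics.
#' @return A list of top-level AST nodes (class `vm_ast`).
#' @export
parse_source <- function(text, name = "<source>") {
  ps <- new_parser(lex_source(text))
  items <- list()
  while (!p_at(ps, "eof")) items[[length(items) + 1]] <- parse_item(ps)
  structure(items, class = "vm_ast", source_name = name)
}

parse_item <- function(ps) {
  if (p_at(ps, "env")) return(parse_env_decl(ps))
  if (p_at(ps, "fn")) return(parse_fn(ps))
  parse_stmt(ps)
}

parse_env_decl <- function(ps) {
  tok <- p_expect(ps, "env")
  nm <- p_expect(ps, "ident")$text
  p_expect(ps, "op", ":")
  ty <- p_expect(ps, "ident")$text
  if (!(ty %in% ENV_TYPES)) diag_stop(tok$line, tok$col,
                                      paste0("unknown environment type '", ty, "'"))
  p_expect(ps, "op", "[")
  len_tok <- p_expect(ps, "num")
  p_expect(ps, "op", "]")
  p_expect(ps, "op", ";")
  node("envdecl", tok, name = nm, type = ty, len = as.integer(as.numeric(len_tok$text)))
}

parse_fn <- function(ps) {
  tok <- p_expect(ps, "fn")
  nm <- p_expect(ps, "ident")$text
  p_expect(ps, "op", "(")
  params <- list()
  while (!p_at(ps, "op", ")")) {
    if (length(params)) p_expect(ps, "op", ",")
    pn <- p_expect(ps, "ident")$text
    pt <- "num"
    if (p_at(ps, "op", ":")) {
      p_next(ps)
      ann <- p_expect(ps, "ident")$text
      if (!(ann %in% c("num", "array")))
        diag_stop(tok$line, tok$col, paste0("unknown parameter type '", ann, "'"))
      pt <- ann
    }
    params[[length(params) + 1]] <- list(name = pn, type = pt)
  }
  p_expect(ps, "op", ")")
  body <- parse_block(ps)
  node("fndef", tok, name = nm, params = params, body = body)
}

parse_block <- function(ps) {
  p_expect(ps, "op", "{")
  out <- list()
  while (!p_at(ps, "op", "}")) out[[length(out) + 1]] <- parse_stmt(ps)
  p_expect(ps, "op", "}")
  out
}

parse_simple <- function(ps) {
  # assignment or let without trailing ';' (for-loop header clauses)
  if (p_at(ps, "let")) {
    tok <- p_next(ps)
    nm <- p_expect(ps, "ident")$text
    p_expect(ps, "op", "=")
    node("let", tok, name = nm, expr = parse_expr(ps))
  } else {
    tok <- p_expect(ps, "ident")
    p_expect(ps, "op", "=")
    node("assign", tok, name = tok$text, expr = parse_expr(ps))
  }
}

parse_stmt <- function(ps) {
  t <- p_peek(ps)
  if (t$type == "let") {
    p_next(ps)
    nm_tok <- p_expect(ps, "ident")
    if (p_at(ps, "op", "[")) {
      p_next(ps)
      len <- parse_expr(ps)
      p_expect(ps, "op", "]")
      p_expect(ps, "op", ";")
      return(node("letarr", t, name = nm_tok$text, len = len))
    }
    p_expect(ps, "op", "=")
    e <- parse_expr(ps)
    p_expect(ps, "op", ";")
    return(node("let", t, name = nm_tok$text, expr = e))
  }
  if (t$type == "if") {
    p_next(ps)
    p_expect(ps, "op", "(")
    cond <- parse_expr(ps)
    p_expect(ps, "op", ")")
    then <- parse_block(ps)
    els <- NULL
    if (p_at(ps, "else")) {
      p_next(ps)
      els <- if (p_at(ps, "if")) list(parse_stmt(ps)) else parse_block(ps)
    }
    return(node("if", t, cond = cond, then = then, els = els))
  }
  if (t$type == "while") {
    p_next(ps)
    p_expect(ps, "op", "(")
    cond <- parse_expr(ps)
    p_expect(ps, "op", ")")
    return(node("while", t, cond = cond, body = parse_block(ps)))
  }
  if (t$type == "for") {
    p_next(ps)
    p_expect(ps, "op", "(")
    init <- parse_simple(ps)
    p_expect(ps, "op", ";")
    cond <- parse_expr(ps)
    p_expect(ps, "op", ";")
    step <- parse_simple(ps)
    p_expect(ps, "op", ")")
    return(node("for", t, init = init, cond = cond, step = step,
                body = parse_block(ps)))
  }
  if (t$type %in% c("print", "printc")) {
    p_next(ps)
    p_expect(ps, "op", "(")
    e <- parse_expr(ps)
    p_expect(ps, "op", ")")
    p_expect(ps, "op", ";")
    return(node(t$type, t, expr = e))
  }
  if (t$type == "return") {
    p_next(ps)
    e <- NULL
    if (!p_at(ps, "op", ";")) e <- parse_expr(ps)
    p_expect(ps, "op", ";")
    return(node("return", t, expr = e))
  }
  if (t$type == "ident") {
    # lookahead: assignment, indexed assignment, or expression statement
    save <- ps$i
    nm_tok <- p_next(ps)
    if (p_at(ps, "op", "=")) {
      p_next(ps)
      e <- parse_expr(ps)
      p_expect(ps, "op", ";")
      return(node("assign", nm_tok, name = nm_tok$text, expr = e))
    }
    if (p_at(ps, "op", "[")) {
      p_next(ps)
      idx <- parse_expr(ps)
      p_expect(ps, "op", "]")
      if (p_at(ps, "op", "=")) {
        p_next(ps)
        e <- parse_expr(ps)
        p_expect(ps, "op", ";")
        return(node("assign_index", nm_tok, name = nm_tok$text, idx = idx, expr = e))
      }
    }
    ps$i <- save
  }
  e <- parse_expr(ps)
  p_expect(ps, "op", ";")
  node("exprstmt", t, expr = e)
}

# precedence climbing
BINOP_LEVELS <- list(
  c("||"), c("&&"), c("==", "!="), c("<", ">", "<=", ">="),
  c("+", "-"), c("*", "/", "%"))

parse_expr <- function(ps, level = 1L) {
  if (level > length(BINOP_LEVELS)) return(parse_unary(ps))
  lhs <- parse_expr(ps, level + 1L)
  repeat {
    t <- p_peek(ps)
    if (t$type == "op" && t$text %in% BINOP_LEVELS[[level]]) {
      p_next(ps)
      rhs <- parse_expr(ps, level + 1L)
      lhs <- node("bin", t, op = t$text, lhs = lhs, rhs = rhs)
    } else break
  }
  lhs
}

parse_unary <- function(ps) {
  t <- p_peek(ps)
  if (t$type == "op" && t$text %in% c("-", "!")) {
    p_next(ps)
    return(node("un", t, op = t$text, expr = parse_unary(ps)))
  }
  parse_primary(ps)
}

parse_primary <- function(ps) {
  t <- p_peek(ps)
  if (t$type == "num") { p_next(ps); return(node("num", t, value = as.numeric(t$text))) }
  if (t$type == "op" && t$text == "(") {
    p_next(ps)
    e <- parse_expr(ps)
    p_expect(ps, "op", ")")
    return(e)
  }
  if (t$type == "ident") {
    p_next(ps)
    if (p_at(ps, "op", "(")) {
      p_next(ps)
      args <- list()
      while (!p_at(ps, "op", ")")) {
        if (length(args)) p_expect(ps, "op", ",")
        args[[length(args) + 1]] <- parse_expr(ps)
      }
      p_expect(ps, "op", ")")
      return(node("call", t, name = t$text, args = args))
    }
    if (p_at(ps, "op", "[")) {
      p_next(ps)
      idx <- parse_expr(ps)
      p_expect(ps, "op", "]")
      return(node("index", t, name = t$text, idx = idx))
    }
    return(node("var", t, name = t$text))
  }
  diag_stop(t$line, t$col, paste0("unexpected '",
                                  if (t$type == "eof") "end of input" else t$text, "'"))
}

# ---------------------------------------------------------------------------
# semantic analysis

#' Analyze a parsed program
#'
#' Resolves every identifier to a declaration, type-checks expressions
#' (`num` vs `array`), binds environment identifiers to buffer-table slots,
#' and dispatches function calls by arity and argument type (overloads on
#' `num` vs `array` parameters resolve to distinct definitions).  Calls are
#' inlined by the back end, so recursive (direct or mutual) calls are
#' rejected here.
#'
#' @param ast Result of [parse_source()].
#' @return A list with the annotated AST (`main` statements, `fns` table,
#'   `env_table`).
#' @export
analyze <- function(ast) {
  env_rows <- list()
  fns <- list()        # signature key -> fndef node
  # collect declarations first
  for (it in ast) {
    if (it$k == "envdecl") {
      if (it$name %in% vapply(env_rows, function(r) r$name, ""))
        diag_stop(it$line, it$col, paste0("duplicate env name '", it$name, "'"))
      env_rows[[length(env_rows) + 1]] <- it
    } else if (it$k == "fndef") {
      key <- fn_key(it$name, vapply(it$params, function(p) p$type, ""))
      if (!is.null(fns[[key]]))
        diag_stop(it$line, it$col, paste0("duplicate definition of ", key))
      fns[[key]] <- it
    }
  }
  env_names <- vapply(env_rows, function(r) r$name, "")
  ctx <- new.env(parent = emptyenv())
  ctx$env_rows <- env_rows; ctx$env_names <- env_names
  ctx$fns <- fns; ctx$fn_stack <- character(0)
  ctx$fns_annotated <- list()
  # analyze function bodies (in an arbitrary but fixed order)
  for (key in names(fns)) annotate_fn(ctx, key)
  # analyze top level as main
  scope <- list(list())
  main <- list()
  for (it in ast) {
    if (it$k %in% c("envdecl", "fndef")) next
    res <- ana_stmt(ctx, it, scope, in_fn = FALSE)
    main[[length(main) + 1]] <- res$node
    scope <- res$scope
  }
  et <- if (length(env_rows)) data.frame(
    name = env_names,
    type = vapply(env_rows, function(r) r$type, ""),
    len = vapply(env_rows, function(r) r$len, 0L),
    stringsAsFactors = FALSE) else NULL
  list(main = main, fns = ctx$fns_annotated, env_table = et,
       source_name = attr(ast, "source_name"))
}

fn_key <- function(name, types) paste0(name, "(", paste(types, collapse = ","), ")")

annotate_fn <- function(ctx, key) {
  if (!is.null(ctx$fns_annotated[[key]])) return(invisible(NULL))
  if (key %in% ctx$fn_stack) {
    fd <- ctx$fns[[key]]
    diag_stop(fd$line, fd$col,
              paste0("recursive call involving ", key, " is not supported"))
  }
  ctx$fn_stack <- c(ctx$fn_stack, key)
  fd <- ctx$fns[[key]]
  frame <- list()
  for (p in fd$params) frame[[p$name]] <- list(type = p$type)
  scope <- list(frame)
  body <- list()
  n <- length(fd$body)
  for (i in seq_along(fd$body)) {
    s <- fd$body[[i]]
    if (s$k == "return" && i != n)
      diag_stop(s$line, s$col, "return must be the final statement of a function body")
    res <- ana_stmt(ctx, s, scope, in_fn = TRUE)
    body[[length(body) + 1]] <- res$node
    scope <- res$scope
  }
  fd$body <- body
  ctx$fns_annotated[[key]] <- fd
  ctx$fn_stack <- setdiff(ctx$fn_stack, key)
  invisible(NULL)
}

scope_lookup <- function(scope, name) {
  for (f in rev(seq_along(scope))) {
    v <- scope[[f]][[name]]
    if (!is.null(v)) return(v)
  }
  NULL
}

ana_stmt <- function(ctx, s, scope, in_fn) {
  k <- s$k
  if (k == "let") {
    e <- ana_expr(ctx, s$expr, scope)
    scope[[length(scope)]][[s$name]] <- list(type = e$type)
    s$expr <- e; s$type <- e$type
    return(list(node = s, scope = scope))
  }
  if (k == "letarr") {
    le <- ana_expr(ctx, s$len, scope)
    if (le$type != "num") diag_stop(s$line, s$col, "array length must be a number")
    scope[[length(scope)]][[s$name]] <- list(type = "array")
    s$len <- le
    return(list(node = s, scope = scope))
  }
  if (k == "assign") {
    v <- scope_lookup(scope, s$name)
    if (is.null(v)) diag_stop(s$line, s$col, paste0("unresolved symbol ", s$name))
    e <- ana_expr(ctx, s$expr, scope)
    if (e$type != v$type)
      diag_stop(s$line, s$col, paste0("type error: cannot assign ", e$type,
                                      " to ", v$type, " variable '", s$name, "'"))
    s$expr <- e
    return(list(node = s, scope = scope))
  }
  if (k == "assign_index") {
    tgt <- resolve_indexable(ctx, s, scope)
    s$target <- tgt$target; s$env_slot <- tgt$env_slot; s$env_type <- tgt$env_type
    idx <- ana_expr(ctx, s$idx, scope)
    e <- ana_expr(ctx, s$expr, scope)
    if (idx$type != "num" || e$type != "num")
      diag_stop(s$line, s$col, "type error: indices and stored values must be numbers")
    s$idx <- idx; s$expr <- e
    return(list(node = s, scope = scope))
  }
  if (k == "if") {
    cond <- ana_expr(ctx, s$cond, scope); require_num(cond, s)
    s$cond <- cond
    s$then <- ana_block(ctx, s$then, scope, in_fn)
    if (!is.null(s$els)) s$els <- ana_block(ctx, s$els, scope, in_fn)
    return(list(node = s, scope = scope))
  }
  if (k == "while") {
    cond <- ana_expr(ctx, s$cond, scope); require_num(cond, s)
    s$cond <- cond
    s$body <- ana_block(ctx, s$body, scope, in_fn)
    return(list(node = s, scope = scope))
  }
  if (k == "for") {
    inner <- c(scope, list(list()))
    # `for (i = 0; ...)` with undeclared i declares it for the loop's scope
    if (s$init$k == "assign" && is.null(scope_lookup(inner, s$init$name)))
      s$init$k <- "let"
    ri <- ana_stmt(ctx, s$init, inner, in_fn)
    inner <- ri$scope; s$init <- ri$node
    cond <- ana_expr(ctx, s$cond, inner); require_num(cond, s)
    s$cond <- cond
    rs <- ana_stmt(ctx, s$step, inner, in_fn)
    s$step <- rs$node
    s$body <- ana_block(ctx, s$body, inner, in_fn)
    return(list(node = s, scope = scope))
  }
  if (k %in% c("print", "printc")) {
    e <- ana_expr(ctx, s$expr, scope); require_num(e, s)
    s$expr <- e
    return(list(node = s, scope = scope))
  }
  if (k == "return") {
    if (!in_fn) diag_stop(s$line, s$col, "return outside of a function")
    if (!is.null(s$expr)) {
      e <- ana_expr(ctx, s$expr, scope); require_num(e, s)
      s$expr <- e
    }
    return(list(node = s, scope = scope))
  }
  if (k == "exprstmt") {
    s$expr <- ana_expr(ctx, s$expr, scope)
    return(list(node = s, scope = scope))
  }
  diag_stop(s$line, s$col, paste0("internal: unknown statement kind ", k))
}

ana_block <- function(ctx, stmts, scope, in_fn) {
  inner <- c(scope, list(list()))
  out <- list()
  for (s in stmts) {
    res <- ana_stmt(ctx, s, inner, in_fn)
    out[[length(out) + 1]] <- res$node
    inner <- res$scope
  }
  out
}

require_num <- function(e, s) {
  if (e$type != "num")
    diag_stop(s$line, s$col, "type error: expected a number")
}

resolve_indexable <- function(ctx, s, scope) {
  v <- scope_lookup(scope, s$name)
  if (!is.null(v)) {
    if (v$type != "array")
      diag_stop(s$line, s$col, paste0("type error: '", s$name, "' is not an array"))
    return(list(target = "array", env_slot = NA_integer_, env_type = NA_character_))
  }
  i <- match(s$name, ctx$env_names)
  if (!is.na(i)) {
    return(list(target = "env", env_slot = i - 1L, env_type = ctx$env_rows[[i]]$type))
  }
  diag_stop(s$line, s$col, paste0("unresolved symbol ", s$name))
}

ana_expr <- function(ctx, e, scope) {
  k <- e$k
  if (k == "num") { e$type <- "num"; return(e) }
  if (k == "var") {
    v <- scope_lookup(scope, e$name)
    if (is.null(v)) diag_stop(e$line, e$col, paste0("unresolved symbol ", e$name))
    e$type <- v$type
    return(e)
  }
  if (k == "index") {
    tgt <- resolve_indexable(ctx, e, scope)
    e$target <- tgt$target; e$env_slot <- tgt$env_slot; e$env_type <- tgt$env_type
    idx <- ana_expr(ctx, e$idx, scope)
    if (idx$type != "num") diag_stop(e$line, e$col, "type error: index must be a number")
    e$idx <- idx; e$type <- "num"
    return(e)
  }
  if (k == "un") {
    x <- ana_expr(ctx, e$expr, scope)
    if (x$type != "num") diag_stop(e$line, e$col, "type error: operand must be a number")
    e$expr <- x; e$type <- "num"
    return(e)
  }
  if (k == "bin") {
    l <- ana_expr(ctx, e$lhs, scope)
    r <- ana_expr(ctx, e$rhs, scope)
    if (l$type != "num" || r$type != "num")
      diag_stop(e$line, e$col, paste0("type error: operator '", e$op,
                                      "' needs number operands"))
    e$lhs <- l; e$rhs <- r; e$type <- "num"
    return(e)
  }
  if (k == "call") {
    args <- lapply(e$args, function(a) ana_expr(ctx, a, scope))
    if (e$name == "tid") {
      if (length(args)) diag_stop(e$line, e$col, "tid() takes no arguments")
      e$builtin <- "LDTID"; e$args <- args; e$type <- "num"
      return(e)
    }
    if (e$name %in% names(LANG_BUILTINS)) {
      if (length(args) != 1 || args[[1]]$type != "num")
        diag_stop(e$line, e$col, paste0(e$name, "() takes one number argument"))
      e$builtin <- LANG_BUILTINS[[e$name]]; e$args <- args; e$type <- "num"
      return(e)
    }
    if (e$name %in% names(LANG_BUILTINS2)) {
      if (length(args) != 2 || !all(vapply(args, function(a) a$type, "") == "num"))
        diag_stop(e$line, e$col, paste0(e$name, "() takes two number arguments"))
      e$builtin <- LANG_BUILTINS2[[e$name]]; e$args <- args; e$type <- "num"
      return(e)
    }
    key <- fn_key(e$name, vapply(args, function(a) a$type, ""))
    if (is.null(ctx$fns[[key]])) {
      diag_stop(e$line, e$col, paste0("unresolved symbol ", e$name,
                                      " (no definition matching ", key, ")"))
    }
    annotate_fn(ctx, key)
    e$sig <- key; e$args <- args; e$type <- "num"
    return(e)
  }
  diag_stop(e$line, e$col, paste0("internal: unknown expression kind ", k))
}
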