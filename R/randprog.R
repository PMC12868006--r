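# Random well-formed program generator for differential testing of the
# optimizer (optimized vs unoptimized bytecode must behave identically).
# Generated programs always terminate (loops are bounded counters), never
# fault structurally (array indices are literal and in range), and write
# observable output (console prints and an `out` environment buffer).

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random source program
#'
#' Produces a random, terminating, fault-free program exercising arithmetic,
#' comparisons, math built-ins, conditionals, bounded loops, small heap
#' arrays, user function calls and prints.  Used for differential testing:
#' the program's observable behavior must be identical when compiled with
#' and without the fusion pass.
#'
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @param n_stmts Number of top-level statements.
#' @return Source text.
#' @export
random_source <- function(seed, n_stmts = 8L) {
  with_local_seed(seed, {
    st <- new.env(parent = emptyenv())
    st$vars <- character(0)     # numeric variables in scope
    st$arrays <- list()         # name -> length
    st$counter <- 0L
    fresh <- function(prefix) {
      st$counter <- st$counter + 1L
      paste0(prefix, st$counter)
    }
    gen_expr <- function(depth) {
      pool <- c("lit", "lit", "var", "bin", "bin", "unary", "math", "cmp", "aread", "call")
      pick <- if (depth <= 0) sample(c("lit", "var"), 1) else sample(pool, 1)
      if (pick == "var" && !length(st$vars)) pick <- "lit"
      if (pick == "aread" && !length(st$arrays)) pick <- "bin"
      switch(pick,
        lit = formatC(sample(c(-9:9, 0.5, 1.5, 2.25, 100), 1), format = "fg"),
        var = sample(st$vars, 1),
        bin = {
          op <- sample(c("+", "-", "*", "/"), 1, prob = c(3, 3, 2, 1))
          paste0("(", gen_expr(depth - 1), " ", op, " ", gen_expr(depth - 1), ")")
        },
        unary = paste0("(-", gen_expr(depth - 1), ")"),
        math = {
          f <- sample(c("sin", "cos", "sqrt", "exp", "abs", "floor"), 1)
          arg <- gen_expr(depth - 1)
          if (f == "sqrt") arg <- paste0("abs(", arg, ")")
          if (f == "exp") arg <- paste0("(", arg, " % 20)")
          paste0(f, "(", arg, ")")
        },
        cmp = {
          op <- sample(c("<", ">", "==", "!=", "<=", ">="), 1)
          paste0("(", gen_expr(depth - 1), " ", op, " ", gen_expr(depth - 1), ")")
        },
        aread = {
          nm <- sample(names(st$arrays), 1)
          idx <- sample(st$arrays[[nm]], 1) - 1L
          paste0(nm, "[", idx, "]")
        },
        call = paste0("mix2(", gen_expr(depth - 1), ", ", gen_expr(depth - 1), ")")
      )
    }
    gen_stmt <- function(budget, indent) {
      pad <- strrep("  ", indent)
      kind <- sample(c("let", "assign", "print", "if", "while", "awrite", "envout"),
                     1, prob = c(3, 2, 2, if (budget > 1) 2 else 0,
                                 if (budget > 1) 2 else 0, 2, 1))
      if (kind == "assign" && !length(st$vars)) kind <- "let"
      if (kind == "awrite" && !length(st$arrays)) kind <- "let"
      switch(kind,
        let = {
          if (length(st$arrays) < 2 && stats::runif(1) < 0.2) {
            nm <- fresh("a")
            len <- sample(2:6, 1)
            st$arrays[[nm]] <- len
            paste0(pad, "let ", nm, "[", len, "];")
          } else {
            nm <- fresh("v")
            line <- paste0(pad, "let ", nm, " = ", gen_expr(2), ";")
            st$vars <- c(st$vars, nm)
            line
          }
        },
        assign = paste0(pad, sample(st$vars, 1), " = ", gen_expr(2), ";"),
        print = paste0(pad, "print(", gen_expr(2), ");"),
        awrite = {
          nm <- sample(names(st$arrays), 1)
          idx <- sample(st$arrays[[nm]], 1) - 1L
          paste0(pad, nm, "[", idx, "] = ", gen_expr(2), ";")
        },
        envout = paste0(pad, "out[", sample(0:3, 1), "] = ", gen_expr(2), ";"),
        "if" = {
          body <- gen_stmts(budget - 1, indent + 1)
          els <- if (stats::runif(1) < 0.5)
            paste0(" else {\n", gen_stmts(budget - 1, indent + 1), "\n", pad, "}")
          else ""
          paste0(pad, "if (", gen_expr(2), ") {\n", body, "\n", pad, "}", els)
        },
        "while" = {
          cv <- fresh("k")
          n <- sample(1:4, 1)
          body <- gen_stmts(budget - 1, indent + 1)
          paste0(pad, "let ", cv, " = 0;\n",
                 pad, "while (", cv, " < ", n, ") {\n", body, "\n",
                 strrep("  ", indent + 1), cv, " = ", cv, " + 1;\n", pad, "}")
        })
    }
    gen_stmts <- function(budget, indent) {
      saved_vars <- st$vars; saved_arrays <- st$arrays
      k <- sample(1:2, 1)
      out <- vapply(seq_len(k), function(i) gen_stmt(budget, indent), "")
      # names declared in a block go out of scope with it
      st$vars <- saved_vars; st$arrays <- saved_arrays
      paste(out, collapse = "\n")
    }
    header <- paste(
      "env out: f64[4];",
      "fn mix2(x, y) {",
      "  let z = x * 2 + y;",
      "  return z - x;",
      "}",
      sep = "\n")
    body <- vapply(seq_len(n_stmts), function(i) gen_stmt(2L, 0L), "")
    paste(c(header, body), collapse = "\n")
  })
}

#' Differential check of the fusion optimizer on one random program
#'
#' Compiles the program with and without fusion, runs both, and compares
#' console output, environment snapshot and lane statuses.
#'
#' @param seed Seed passed to [random_source()].
#' @return `TRUE` if behavior matched; otherwise a character description.
#' @export
check_optimizer_parity <- function(seed) {
  src <- random_source(seed)
  p0 <- compile_source(src, name = "rand", optimize = FALSE)
  p1 <- compile_source(src, name = "rand", optimize = TRUE)
  r0 <- run_program(p0, limits = list(max_steps = 1e7))
  r1 <- run_program(p1, limits = list(max_steps = 1e7))
  if (!identical(r0$console, r1$console)) return("console output differs")
  if (!identical(r0$env, r1$env)) return("environment snapshot differs")
  if (!identical(r0$status, r1$status)) return("lane status differs")
  if (!fusion_complete(p1)) return("fusion incomplete")
  TRUE
}
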