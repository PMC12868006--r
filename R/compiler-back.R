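# Back end: lowers the annotated AST to the aligned-array bytecode.  Local
# variables live in reserved stack slots addressed with SREAD/SWRITE relative
# to the tracked stack depth; arrays live on the per-lane heap via MALLOC and
# are freed when their scope exits; control flow lowers to JUMP/JUMPIFZERO
# with the condition-then-target stack protocol (target on top); jump targets
# are absolute instruction indices patched in a single backpatch pass.
# Function calls are inlined (overloads were resolved during analysis).

new_emitter <- function() {
  em <- new.env(parent = emptyenv())
  em$ins <- character(1024); em$ops <- rep(NA_character_, 1024)
  em$vals <- numeric(1024); em$n <- 0L
  em$label_addr <- integer(0)     # label id -> instruction index (1-based stored)
  em$label_slots <- integer(0)    # 0-based value-slot indices holding label ids
  em$depth <- 0L
  em
}

em_grow <- function(em, need) {
  while (need > length(em$ins)) {
    k <- length(em$ins)
    em$ins <- c(em$ins, character(k))
    em$ops <- c(em$ops, rep(NA_character_, k))
    em$vals <- c(em$vals, numeric(k))
  }
}

emit <- function(em, instr, op = NA_character_, val = 0) {
  n <- em$n + 1L
  em_grow(em, n)
  em$ins[n] <- instr; em$ops[n] <- op; em$vals[n] <- val
  em$n <- n
  invisible(n)
}

em_new_label <- function(em) {
  em$label_addr <- c(em$label_addr, NA_integer_)
  length(em$label_addr)
}
em_place_label <- function(em, id) em$label_addr[id] <- em$n       # next instr index (0-based = n)
em_push_label <- function(em, id) {
  i <- emit(em, "VALUE", val = id)
  em$label_slots <- c(em$label_slots, i - 1L)
  em$depth <- em$depth + 1L
}

# emit helpers that keep the static depth in sync
e_value <- function(em, v) { emit(em, "VALUE", val = v); em$depth <- em$depth + 1L }
e_op <- function(em, name) {
  tab <- op_table()
  i <- match(name, tab$name)
  emit(em, "OP", op = name)
  em$depth <- em$depth - tab$arity_in[i] + tab$arity_out[i]
}

# ---------------------------------------------------------------------------
# code generation state: scopes map names to absolute stack slot indices

cg_new_state <- function(an) {
  st <- new.env(parent = emptyenv())
  st$em <- new_emitter()
  st$an <- an
  st$scopes <- list()       # frames: list(vars = list(name -> list(slot, type)), arrays = slots, depth0)
  st
}

cg_push_frame <- function(st) {
  st$scopes[[length(st$scopes) + 1]] <- list(vars = list(), arrays = integer(0),
                                             depth0 = st$em$depth)
}

cg_register <- function(st, name, slot, type, is_heap_array = FALSE) {
  f <- st$scopes[[length(st$scopes)]]
  f$vars[[name]] <- list(slot = slot, type = type)
  if (is_heap_array) f$arrays <- c(f$arrays, slot)
  st$scopes[[length(st$scopes)]] <- f
}

cg_lookup <- function(st, name) {
  for (i in rev(seq_along(st$scopes))) {
    v <- st$scopes[[i]]$vars[[name]]
    if (!is.null(v)) return(v)
  }
  stop("internal compiler error: unresolved '", name, "' reached codegen")
}

# leave the frame: free heap arrays declared here, drop its slots
cg_pop_frame <- function(st, drop_to = NULL) {
  em <- st$em
  f <- st$scopes[[length(st$scopes)]]
  target <- if (is.null(drop_to)) f$depth0 else drop_to
  for (slot in rev(f$arrays)) {
    e_value(em, em$depth - slot)   # offset to the pointer slot
    e_op(em, "SREAD")
    e_op(em, "FREE")
  }
  while (em$depth > target) e_op(em, "DROP")
  st$scopes[[length(st$scopes)]] <- NULL
}

cg_read_var <- function(st, name) {
  em <- st$em
  v <- cg_lookup(st, name)
  e_value(em, em$depth + 1L - 1L - v$slot)  # offset computed after the push is popped
  e_op(em, "SREAD")
}

cg_write_var <- function(st, name) {
  # value to store is on top of stack
  em <- st$em
  v <- cg_lookup(st, name)
  e_value(em, em$depth + 1L - 2L - v$slot)
  e_op(em, "SWRITE")
}

env_read_op <- c(f64 = "READ_F64", f32 = "READ_F32", i32 = "READ_I32", char = "READ_CHAR")
env_write_op <- c(f64 = "WRITE_F64", f32 = "WRITE_F32", i32 = "WRITE_I32", char = "WRITE_CHAR")

cg_expr <- function(st, e) {
  em <- st$em
  k <- e$k
  if (k == "num") { e_value(em, e$value); return(invisible(NULL)) }
  if (k == "var") { cg_read_var(st, e$name); return(invisible(NULL)) }
  if (k == "index") {
    if (e$target == "env") {
      cg_expr(st, e$idx)
      e_value(em, e$env_slot)
      e_op(em, env_read_op[[e$env_type]])
    } else {
      cg_read_var(st, e$name)     # base pointer
      cg_expr(st, e$idx)
      e_op(em, "SADD_P")
      e_op(em, "PTR_DEREF")
    }
    return(invisible(NULL))
  }
  if (k == "un") {
    cg_expr(st, e$expr)
    e_op(em, if (e$op == "-") "NEG" else "NOT")
    return(invisible(NULL))
  }
  if (k == "bin") {
    cg_expr(st, e$lhs)
    cg_expr(st, e$rhs)
    opname <- switch(e$op,
      "+" = "ADD", "-" = "SUB", "*" = "MUL", "/" = "DIV", "%" = "FMOD",
      "==" = "EQ", "!=" = "NEQ", ">" = "GT", "<" = "LT",
      ">=" = "GTEQ", "<=" = "LTEQ", "&&" = "AND", "||" = "OR",
      stop("internal: unknown operator ", e$op))
    e_op(em, opname)
    return(invisible(NULL))
  }
  if (k == "call") {
    if (!is.null(e$builtin)) {
      for (a in e$args) cg_expr(st, a)
      e_op(em, e$builtin)
      return(invisible(NULL))
    }
    cg_inline_call(st, e)
    return(invisible(NULL))
  }
  stop("internal: unknown expression kind ", k)
}

cg_inline_call <- function(st, e) {
  em <- st$em
  fd <- st$an$fns[[e$sig]]
  result_slot <- em$depth
  e_value(em, 0)                      # result slot
  for (a in e$args) cg_expr(st, a)
  nargs <- length(e$args)
  cg_push_frame(st)
  for (i in seq_along(fd$params)) {
    cg_register(st, fd$params[[i]]$name, result_slot + i, fd$params[[i]]$type)
  }
  body <- fd$body
  n <- length(body)
  has_ret <- n > 0 && body[[n]]$k == "return"
  main_stmts <- if (has_ret) body[seq_len(n - 1L)] else body
  for (s in main_stmts) cg_stmt(st, s)
  if (has_ret && !is.null(body[[n]]$expr)) {
    cg_expr(st, body[[n]]$expr)
    e_value(em, em$depth - 1L - result_slot)
    e_op(em, "SWRITE")
  }
  cg_pop_frame(st)                    # frees fn-local arrays, drops fn locals
  while (em$depth > result_slot + 1L) e_op(em, "DROP")  # drop the arguments
}

cg_stmt <- function(st, s) {
  em <- st$em
  k <- s$k
  if (k == "let") {
    cg_expr(st, s$expr)
    cg_register(st, s$name, em$depth - 1L, s$type)
    return(invisible(NULL))
  }
  if (k == "letarr") {
    cg_expr(st, s$len)
    e_op(em, "MALLOC")
    cg_register(st, s$name, em$depth - 1L, "array", is_heap_array = TRUE)
    return(invisible(NULL))
  }
  if (k == "assign") {
    cg_expr(st, s$expr)
    cg_write_var(st, s$name)
    return(invisible(NULL))
  }
  if (k == "assign_index") {
    if (s$target == "env") {
      cg_expr(st, s$expr)
      cg_expr(st, s$idx)
      e_value(em, s$env_slot)
      e_op(em, env_write_op[[s$env_type]])
    } else {
      cg_expr(st, s$expr)
      cg_read_var(st, s$name)
      cg_expr(st, s$idx)
      e_op(em, "SADD_P")
      e_op(em, "PTR_STORE")
    }
    return(invisible(NULL))
  }
  if (k == "if") {
    l_else <- em_new_label(em)
    cg_expr(st, s$cond)
    em_push_label(em, l_else)
    emit(em, "JUMPIFZERO"); em$depth <- em$depth - 2L
    cg_block(st, s$then)
    if (is.null(s$els)) {
      em_place_label(em, l_else)
    } else {
      l_end <- em_new_label(em)
      em_push_label(em, l_end)
      emit(em, "JUMP"); em$depth <- em$depth - 1L
      em_place_label(em, l_else)
      cg_block(st, s$els)
      em_place_label(em, l_end)
    }
    return(invisible(NULL))
  }
  if (k == "while") {
    l_cond <- em_new_label(em); l_end <- em_new_label(em)
    em_place_label(em, l_cond)
    cg_expr(st, s$cond)
    em_push_label(em, l_end)
    emit(em, "JUMPIFZERO"); em$depth <- em$depth - 2L
    cg_block(st, s$body)
    em_push_label(em, l_cond)
    emit(em, "JUMP"); em$depth <- em$depth - 1L
    em_place_label(em, l_end)
    return(invisible(NULL))
  }
  if (k == "for") {
    cg_push_frame(st)
    cg_stmt(st, s$init)
    l_cond <- em_new_label(em); l_end <- em_new_label(em)
    em_place_label(em, l_cond)
    cg_expr(st, s$cond)
    em_push_label(em, l_end)
    emit(em, "JUMPIFZERO"); em$depth <- em$depth - 2L
    cg_block(st, s$body)
    cg_stmt(st, s$step)
    em_push_label(em, l_cond)
    emit(em, "JUMP"); em$depth <- em$depth - 1L
    em_place_label(em, l_end)
    cg_pop_frame(st)
    return(invisible(NULL))
  }
  if (k == "print") {
    cg_expr(st, s$expr)
    e_op(em, "PRINTF")
    e_value(em, 10)
    e_op(em, "PRINTC")
    return(invisible(NULL))
  }
  if (k == "printc") {
    cg_expr(st, s$expr)
    e_op(em, "PRINTC")
    return(invisible(NULL))
  }
  if (k == "exprstmt") {
    cg_expr(st, s$expr)
    e_op(em, "DROP")
    return(invisible(NULL))
  }
  if (k == "return") stop("internal: return outside inline expansion")
  stop("internal: unknown statement kind ", k)
}

cg_block <- function(st, stmts) {
  cg_push_frame(st)
  for (s in stmts) cg_stmt(st, s)
  cg_pop_frame(st)
}

#' Generate bytecode from an analyzed program
#'
#' @param an Result of [analyze()].
#' @return A validated `vm_program` with jump-address bookkeeping in `meta`
#'   (`label_slots`, `jump_targets`) used by [optimize_program()].
#' @export
codegen <- function(an) {
  st <- cg_new_state(an)
  cg_push_frame(st)
  for (s in an$main) cg_stmt(st, s)
  cg_pop_frame(st)
  em <- st$em
  if (em$depth != 0L) stop("internal compiler error: unbalanced stack depth ", em$depth)
  n <- em$n
  if (n == 0L) { e_op(em, "OPNULL"); n <- em$n }   # empty source still yields a program
  ins <- em$ins[seq_len(n)]; ops <- em$ops[seq_len(n)]; vals <- em$vals[seq_len(n)]
  # backpatch label ids with absolute instruction indices
  addr <- em$label_addr
  if (length(em$label_slots)) {
    ids <- vals[em$label_slots + 1L]
    vals[em$label_slots + 1L] <- addr[ids]
  }
  targets <- sort(unique(as.integer(addr)))
  bc_program(ins, ops, vals, env_table = an$env_table,
             meta = list(source = an$source_name,
                         compiler = as.character(utils::packageVersion("blochvm")),
                         label_slots = as.integer(em$label_slots),
                         jump_targets = targets))
}

# ---------------------------------------------------------------------------
# optimizer: VALUE+OP fusion

#' Fuse adjacent VALUE/OP pairs into single instructions
#'
#' Every adjacent `VALUE` followed by `OP` whose second element is not a jump
#' target fuses into `SI_VALUE_OP` (and `OP` followed by `VALUE` into
#' `SI_OP_VALUE`), halving the dispatch cost of the commonest sequences while
#' preserving observable behavior exactly.  Fusion shifts instruction
#' indices, so absolute jump addresses (recorded by the compiler in
#' `meta$label_slots`) are remapped; a program with jumps but without that
#' bookkeeping is returned unchanged.
#'
#' @param program A validated `vm_program`.
#' @return The optimized `vm_program`.
#' @export
optimize_program <- function(program) {
  validate_program(program)
  ins <- program$instructions; ops <- program$operations; vals <- program$values
  n <- length(ins)
  has_jumps <- any(ins %in% c("JUMP", "JUMPIFZERO"))
  label_slots <- program$meta$label_slots
  if (has_jumps && is.null(label_slots)) return(program)
  targets <- program$meta$jump_targets
  if (is.null(targets)) targets <- integer(0)
  is_target <- rep(FALSE, n + 1L)
  is_target[targets + 1L] <- TRUE
  new_ins <- character(0); new_ops <- character(0); new_vals <- numeric(0)
  # map[i+1] = new 0-based index of old instruction i (second of a fused pair
  # maps to the pair's index; jump targets are never such a second element)
  map <- integer(n + 1L)
  i <- 1L
  while (i <= n) {
    ni <- length(new_ins)            # next new 0-based index
    fuse <- FALSE
    if (i < n && !is_target[i + 1L]) {
      if (ins[i] == "VALUE" && ins[i + 1L] == "OP") {
        new_ins <- c(new_ins, "SI_VALUE_OP")
        new_ops <- c(new_ops, ops[i + 1L])
        new_vals <- c(new_vals, vals[i])
        fuse <- TRUE
      } else if (ins[i] == "OP" && ins[i + 1L] == "VALUE") {
        new_ins <- c(new_ins, "SI_OP_VALUE")
        new_ops <- c(new_ops, ops[i])
        new_vals <- c(new_vals, vals[i + 1L])
        fuse <- TRUE
      }
    }
    if (fuse) {
      map[i] <- ni; map[i + 1L] <- ni
      i <- i + 2L
    } else {
      new_ins <- c(new_ins, ins[i]); new_ops <- c(new_ops, ops[i])
      new_vals <- c(new_vals, vals[i])
      map[i] <- ni
      i <- i + 1L
    }
  }
  map[n + 1L] <- length(new_ins)     # one-past-the-end target (normal halt)
  meta <- program$meta
  if (!is.null(label_slots) && length(label_slots)) {
    # where did each old value slot land, and what address does it now hold?
    new_slots <- map[label_slots + 1L]
    old_addr <- vals[label_slots + 1L]
    new_vals[new_slots + 1L] <- map[as.integer(old_addr) + 1L]
    meta$label_slots <- as.integer(new_slots)
  }
  if (length(targets)) meta$jump_targets <- as.integer(sort(unique(map[targets + 1L])))
  bc_program(new_ins, new_ops, new_vals, env_table = program$env_table, meta = meta)
}

# check used by tests: after optimization no fusable adjacent pair remains
fusion_complete <- function(program) {
  ins <- program$instructions
  n <- length(ins)
  if (n < 2) return(TRUE)
  targets <- program$meta$jump_targets
  if (is.null(targets)) targets <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (i %in% targets) next         # i is the 0-based index of ins[i + 1]
    if ((ins[i] == "VALUE" && ins[i + 1L] == "OP") ||
        (ins[i] == "OP" && ins[i + 1L] == "VALUE")) return(FALSE)
  }
  TRUE
}

#' Compile source text to a bytecode program
#'
#' Runs the full pipeline parse, analyze, codegen and (by default) the
#' VALUE/OP fusion pass.  Deterministic: identical source and options yield
#' a byte-identical program.  The first failing stage stops with a
#' `vm_diag_error` condition carrying a diagnostics data frame.
#'
#' @param text Source text (or use `file`).
#' @param file Path to a source file (UTF-8); overrides `text`.
#' @param name Name used in diagnostics and program metadata.
#' @param optimize Apply [optimize_program()] (default `TRUE`).
#' @return A validated `vm_program`.
#' @export
compile_source <- function(text = NULL, file = NULL, name = NULL, optimize = TRUE) {
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
    if (is.null(name)) name <- basename(file)
  }
  if (is.null(text)) stop("either text or file must be given")
  if (is.null(name)) name <- "<source>"
  p <- codegen(analyze(parse_source(text, name = name)))
  if (optimize) p <- optimize_program(p)
  p
}
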