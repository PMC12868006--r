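#' @useDynLib blochvm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Instruction tokens; order mirrors the interpreter's instruction codes.
BC_INSTRUCTIONS <- c("OP", "VALUE", "JUMP", "JUMPIFZERO", "SI_VALUE_OP", "SI_OP_VALUE")

# instructions that carry an operation / a value in their aligned slot
BC_HAS_OP <- c("OP", "SI_VALUE_OP", "SI_OP_VALUE")
BC_HAS_VALUE <- c("VALUE", "SI_VALUE_OP", "SI_OP_VALUE")

ENV_TYPES <- c("f64", "f32", "i32", "char")

.op_table_cache <- new.env(parent = emptyenv())

#' Operation table of the virtual machine
#'
#' Returns the full table of implemented operations: symbolic name, category,
#' and fixed stack arities (words consumed / produced).  Categories follow the
#' VM's operation library layout: null, stack access and pointer arithmetic,
#' basic arithmetic and logic, memory management and ternary, comparison,
#' extra memory access, floating-point/integer/character environment I/O,
#' mathematical functions, system calls, type casting, environment registers,
#' and synchronization barriers.
#'
#' @return A data.frame with columns `id`, `name`, `category`, `arity_in`,
#'   `arity_out`.
#' @export
op_table <- function() {
  if (is.null(.op_table_cache$tab)) .op_table_cache$tab <- cpp_op_table()
  .op_table_cache$tab
}

op_id <- function(name) {
  tab <- op_table()
  i <- match(name, tab$name)
  if (anyNA(i)) stop("unknown operation: ", paste(name[is.na(i)], collapse = ", "))
  tab$id[i]
}

#' Construct a bytecode program
#'
#' A program is the aligned-array triple interpreted by the VM: an instruction
#' array, an operation array and a value array of identical length, indexed by
#' a single program counter.  Slots that an instruction does not consume hold
#' `NA` (operations) or `0` (values).
#'
#' @param instructions Character vector of instruction tokens
#'   (`OP`, `VALUE`, `JUMP`, `JUMPIFZERO`, `SI_VALUE_OP`, `SI_OP_VALUE`).
#' @param operations Character vector of operation names (`NA` where unused),
#'   same length as `instructions`.
#' @param values Numeric vector, same length as `instructions`.
#' @param env_table Data frame with columns `name`, `type`
#'   (`f64`/`f32`/`i32`/`char`) and `len`: the host buffers the program binds.
#' @param meta Free-form provenance list (source name, compiler version,
#'   jump-address slots used by the optimizer).
#' @param validate Run [validate_program()] before returning.
#' @return An object of class `vm_program`.
#' @export
bc_program <- function(instructions, operations = NULL, values = NULL,
                       env_table = NULL, meta = list(), validate = TRUE) {
  n <- length(instructions)
  if (is.null(operations)) operations <- rep(NA_character_, n)
  if (is.null(values)) values <- numeric(n)
  if (is.null(env_table)) {
    env_table <- data.frame(name = character(), type = character(),
                            len = integer(), stringsAsFactors = FALSE)
  }
  p <- structure(list(
    instructions = as.character(instructions),
    operations = as.character(operations),
    values = as.numeric(values),
    env_table = env_table,
    meta = meta
  ), class = "vm_program")
  if (validate) validate_program(p)
  p
}

#' Validate a bytecode program
#'
#' Checks the aligned-array invariants: the three arrays share one length,
#' every `OP`/`SI_*` slot names a known operation, every value-carrying slot
#' holds a finite-or-NaN numeric, and environment declarations are well formed
#' with unique names.  Errors name the first failing index.
#'
#' @param program A `vm_program`.
#' @return Invisibly `TRUE`; stops with a validation error otherwise.
#' @export
validate_program <- function(program) {
  if (!inherits(program, "vm_program")) stop("not a vm_program object")
  ins <- program$instructions
  n <- length(ins)
  if (n == 0L) stop("validation error: empty program")
  if (length(program$operations) != n || length(program$values) != n)
    stop("validation error: instruction/operation/value arrays differ in length (",
         n, ", ", length(program$operations), ", ", length(program$values), ")")
  bad <- which(!(ins %in% BC_INSTRUCTIONS))
  if (length(bad))
    stop("validation error at index ", bad[1] - 1L,
         ": unknown instruction '", ins[bad[1]], "'")
  needs_op <- ins %in% BC_HAS_OP
  miss <- which(needs_op & is.na(program$operations))
  if (length(miss))
    stop("validation error at index ", miss[1] - 1L,
         ": instruction ", ins[miss[1]], " has a null operation slot")
  known <- program$operations[needs_op] %in% op_table()$name
  if (!all(known)) {
    idx <- which(needs_op)[which(!known)[1]]
    stop("validation error at index ", idx - 1L,
         ": unknown operation '", program$operations[idx], "'")
  }
  has_val <- ins %in% BC_HAS_VALUE
  badv <- which(has_val & is.na(program$values))
  if (length(badv))
    stop("validation error at index ", badv[1] - 1L, ": missing value")
  et <- program$env_table
  if (!is.data.frame(et) || !all(c("name", "type", "len") %in% names(et)))
    stop("validation error: env_table must have columns name, type, len")
  if (anyDuplicated(et$name))
    stop("validation error: duplicate environment name '",
         et$name[duplicated(et$name)][1], "'")
  if (nrow(et) && !all(et$type %in% ENV_TYPES))
    stop("validation error: unknown environment type '",
         setdiff(et$type, ENV_TYPES)[1], "'")
  if (nrow(et) && any(et$len < 1))
    stop("validation error: environment buffer length must be >= 1")
  invisible(TRUE)
}

#' @export
print.vm_program <- function(x, ...) {
  cat("<vm_program> ", length(x$instructions), " instructions, ",
      nrow(x$env_table), " environment buffer(s)\n", sep = "")
  if (!is.null(x$meta$source)) cat("  source: ", x$meta$source, "\n", sep = "")
  invisible(x)
}

#' Serialize a program to its JSON dialect
#'
#' Deterministic (fixed key order, full double precision) so that identical
#' programs serialize to identical text and `decode_program(encode_program(p))`
#' reproduces `p` exactly.
#'
#' @param program A validated `vm_program`.
#' @return A single JSON string.
#' @export
encode_program <- function(program) {
  validate_program(program)
  obj <- list(
    version = 1L,
    instructions = program$instructions,
    operations = program$operations,
    values = program$values,
    env = if (nrow(program$env_table)) {
      lapply(seq_len(nrow(program$env_table)), function(i)
        list(name = program$env_table$name[i],
             type = program$env_table$type[i],
             len = as.integer(program$env_table$len[i])))
    } else list(),
    meta = program$meta
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

#' Deserialize a program from its JSON dialect
#'
#' @param text JSON text produced by [encode_program()] (or path handling is
#'   left to the caller; this takes the text itself).
#' @return A validated `vm_program`.
#' @export
decode_program <- function(text) {
  obj <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop("parse error: ", conditionMessage(e)))
  if (is.null(obj$version) || obj$version != 1)
    stop("decode error: unsupported bytecode version")
  ins <- vapply(obj$instructions, function(x) as.character(x)[1], "")
  bad <- setdiff(unique(ins), BC_INSTRUCTIONS)
  if (length(bad)) stop("decode error: unknown instruction '", bad[1], "'")
  ops <- vapply(obj$operations, function(x)
    if (is.null(x)) NA_character_ else as.character(x)[1], "")
  unknown <- setdiff(ops[!is.na(ops)], op_table()$name)
  if (length(unknown)) stop("decode error: unknown operation '", unknown[1], "'")
  vals <- vapply(obj$values, function(x)
    if (is.null(x)) NA_real_ else as.numeric(x)[1], 0)
  et <- if (length(obj$env)) {
    data.frame(
      name = vapply(obj$env, function(e) as.character(e$name), ""),
      type = vapply(obj$env, function(e) as.character(e$type), ""),
      len = vapply(obj$env, function(e) as.integer(e$len), 0L),
      stringsAsFactors = FALSE)
  } else NULL
  meta <- obj$meta
  if (!is.null(meta$label_slots)) meta$label_slots <- as.integer(unlist(meta$label_slots))
  if (!is.null(meta$jump_targets)) meta$jump_targets <- as.integer(unlist(meta$jump_targets))
  bc_program(ins, ops, vals, env_table = et, meta = if (is.null(meta)) list() else meta)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Disassemble a program to a textual listing
#'
#' One line per index: index, instruction token, then the operation name
#' and/or value where the instruction carries one.  Environment declarations
#' and metadata are emitted as `.env` / `.meta` header lines so the listing is
#' fully re-parseable by [assemble()].
#'
#' @param program A validated `vm_program`.
#' @return A single string (lines separated by `\n`).
#' @export
disassemble <- function(program) {
  validate_program(program)
  lines <- character(0)
  et <- program$env_table
  for (i in seq_len(nrow(et))) {
    lines <- c(lines, paste(".env", et$name[i], et$type[i], et$len[i]))
  }
  if (length(program$meta)) {
    lines <- c(lines, paste(".meta", as.character(
      jsonlite::toJSON(program$meta, auto_unbox = TRUE, digits = NA))))
  }
  n <- length(program$instructions)
  for (i in seq_len(n)) {
    ins <- program$instructions[i]
    part <- c(i - 1L, ins)
    if (ins == "VALUE") part <- c(part, fmt_num(program$values[i]))
    if (ins == "OP") part <- c(part, program$operations[i])
    if (ins == "SI_VALUE_OP")
      part <- c(part, fmt_num(program$values[i]), program$operations[i])
    if (ins == "SI_OP_VALUE")
      part <- c(part, program$operations[i], fmt_num(program$values[i]))
    lines <- c(lines, paste(part, collapse = " "))
  }
  paste(lines, collapse = "\n")
}

#' Assemble a textual listing back into a program
#'
#' Inverse of [disassemble()]: `assemble(disassemble(p))` reproduces `p`.
#'
#' @param text Assembly listing text.
#' @return A validated `vm_program`.
#' @export
assemble <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  env_rows <- list()
  meta <- list()
  ins <- character(0); ops <- character(0); vals <- numeric(0)
  for (ln in lines) {
    if (startsWith(ln, ".env ")) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) != 4) stop("assembly error: bad .env line: ", ln)
      env_rows[[length(env_rows) + 1]] <-
        data.frame(name = f[2], type = f[3], len = as.integer(f[4]),
                   stringsAsFactors = FALSE)
      next
    }
    if (startsWith(ln, ".meta ")) {
      meta <- jsonlite::fromJSON(sub("^\\.meta ", "", ln), simplifyVector = FALSE)
      if (!is.null(meta$label_slots))
        meta$label_slots <- as.integer(unlist(meta$label_slots))
      if (!is.null(meta$jump_targets))
        meta$jump_targets <- as.integer(unlist(meta$jump_targets))
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 2) stop("assembly error: bad line: ", ln)
    tok <- f[2]
    if (!(tok %in% BC_INSTRUCTIONS)) stop("assembly error: unknown instruction '", tok, "'")
    op <- NA_character_; val <- 0
    if (tok == "VALUE") val <- as.numeric(f[3])
    else if (tok == "OP") op <- f[3]
    else if (tok == "SI_VALUE_OP") { val <- as.numeric(f[3]); op <- f[4] }
    else if (tok == "SI_OP_VALUE") { op <- f[3]; val <- as.numeric(f[4]) }
    ins <- c(ins, tok); ops <- c(ops, op); vals <- c(vals, val)
  }
  et <- if (length(env_rows)) do.call(rbind, env_rows) else NULL
  bc_program(ins, ops, vals, env_table = et, meta = meta)
}
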