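#' Load a program into a virtual machine instance
#'
#' Initializes `n_lanes` parallel lanes (emulated GPU threads), each with
#' program counter 0, an empty fixed-capacity stack, a private heap arena and
#' a distinct thread id in `[0, n_lanes)`.  Environment buffers are the
#' host-side data-exchange contract: their order, types and lengths must match
#' the program's environment table exactly.
#'
#' @param program A validated `vm_program`.
#' @param n_lanes Number of lanes (>= 1).
#' @param env Named list of buffer contents matching `program$env_table`
#'   (`f64`/`f32` buffers as numeric, `i32` as integer, `char` as raw).
#'   Missing buffers are zero-initialized.
#' @param limits List overriding `stack_capacity` (words, default 4096),
#'   `heap_words` per lane (default 2^16), `max_steps` per lane (default 1e8) and
#'   `warp_size` (contiguous lanes per warp barrier scope, default 32).
#' @return A `vm_instance` handle usable with [vm_step()] and [vm_run()].
#' @export
vm_load <- function(program, n_lanes = 1L, env = list(), limits = list()) {
  validate_program(program)
  if (!is.numeric(n_lanes) || n_lanes < 1) stop("argument error: n_lanes must be >= 1")
  lim <- list(stack_capacity = 4096, heap_words = 2^16, max_steps = 1e8, warp_size = 32)
  lim[names(limits)] <- limits
  if (lim$stack_capacity < 1) stop("argument error: stack_capacity must be >= 1")
  et <- program$env_table
  vals <- vector("list", nrow(et))
  for (i in seq_len(nrow(et))) {
    nm <- et$name[i]; ty <- et$type[i]; len <- et$len[i]
    v <- env[[nm]]
    if (is.null(v)) {
      v <- switch(ty, f64 = numeric(len), f32 = numeric(len),
                  i32 = integer(len), char = raw(len))
    }
    if (length(v) != len)
      stop("binding error: buffer '", nm, "' has length ", length(v),
           ", declared ", len)
    v <- switch(ty,
      f64 = as.numeric(v), f32 = as.numeric(v),
      i32 = {
        if (is.double(v) && any(v != trunc(v))) stop("binding error: buffer '",
          nm, "' declared i32 but holds non-integer values")
        as.integer(v)
      },
      char = as.raw(v))
    vals[[i]] <- v
  }
  extra <- setdiff(names(env), et$name)
  if (length(extra))
    stop("binding error: buffer '", extra[1], "' not declared by the program")
  ptr <- cpp_vm_load(
    instr = match(program$instructions, BC_INSTRUCTIONS) - 1L,
    ops = ifelse(is.na(program$operations), -1L,
                 op_id(ifelse(is.na(program$operations), "OPNULL", program$operations))),
    vals = program$values,
    env_names = et$name, env_types = et$type, env_values = vals,
    n_lanes = as.integer(n_lanes),
    stack_capacity = lim$stack_capacity, heap_words = lim$heap_words,
    max_steps = lim$max_steps, warp_size = as.integer(lim$warp_size))
  structure(list(ptr = ptr, program = program, n_lanes = as.integer(n_lanes),
                 limits = lim), class = "vm_instance")
}

#' Advance one lane by one instruction
#'
#' Applies exactly one instruction's semantics to the given lane: `OP`
#' executes the aligned operation; `VALUE` pushes the aligned value; `JUMP`
#' pops an absolute target; `JUMPIFZERO` pops the target then the condition
#' and jumps iff the condition word is exactly 0; the fused `SI_VALUE_OP` /
#' `SI_OP_VALUE` forms perform both halves in one step.
#'
#' @param instance A `vm_instance`.
#' @param lane Lane id in `[0, n_lanes)`.
#' @return The lane state after the step: `pc`, `tid`, `sp`, `stack`
#'   (as doubles), `status`, `fault`, `steps`.
#' @export
vm_step <- function(instance, lane = 0L) {
  stopifnot(inherits(instance, "vm_instance"))
  cpp_vm_step(instance$ptr, as.integer(lane))
}

#' Inspect a lane without stepping
#' @param instance A `vm_instance`.
#' @param lane Lane id.
#' @return Lane state list as in [vm_step()].
#' @export
vm_lane <- function(instance, lane = 0L) {
  stopifnot(inherits(instance, "vm_instance"))
  cpp_vm_lane(instance$ptr, as.integer(lane))
}

#' Run a loaded instance to completion
#'
#' Interleaves lanes deterministically (round-robin, one instruction per
#' running lane per round) until every lane halts, faults, or reaches the
#' per-lane step limit.  Synchronization operations block a lane until all
#' lanes of the barrier's scope arrive; if some lanes finish while others
#' wait, the waiting lanes fault with a barrier deadlock.
#'
#' @param instance A `vm_instance`.
#' @return An `execution_report`: per-lane `steps`, `status` and `fault`,
#'   captured `console` output, and the final `env` buffer snapshot.
#' @export
vm_run <- function(instance) {
  stopifnot(inherits(instance, "vm_instance"))
  rep <- cpp_vm_run(instance$ptr)
  structure(rep, class = "execution_report")
}

#' @export
print.execution_report <- function(x, ...) {
  cat("<execution_report> ", length(x$steps), " lane(s)\n", sep = "")
  tab <- table(x$status)
  cat("  status: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  total steps: ", format(sum(x$steps), big.mark = ","), "\n", sep = "")
  if (nzchar(x$console))
    cat("  console: ", nchar(x$console), " characters\n", sep = "")
  invisible(x)
}

#' Compile-free convenience runner
#'
#' Loads and runs a program in one call.
#'
#' @inheritParams vm_load
#' @return An `execution_report`.
#' @export
run_program <- function(program, n_lanes = 1L, env = list(), limits = list()) {
  vm_run(vm_load(program, n_lanes = n_lanes, env = env, limits = limits))
}

#' Execute a single operation on a prepared stack
#'
#' Test/inspection helper: builds a one-off single-lane program that pushes
#' `stack` (bottom first), executes `op` once, and returns the resulting
#' stack.  Structural faults (underflow, range errors) surface as errors.
#'
#' @param op Operation name from [op_table()].
#' @param stack Numeric vector, bottom of stack first.
#' @param env Optional named environment buffers (with `env_table` rows
#'   inferred as f64 from the values).
#' @return Numeric vector: the stack after the operation, bottom first.
#' @export
exec_op <- function(op, stack = numeric(), env = list()) {
  et <- if (length(env)) {
    data.frame(name = names(env), type = "f64",
               len = lengths(env), stringsAsFactors = FALSE)
  } else NULL
  ins <- c(rep("VALUE", length(stack)), "OP")
  ops <- c(rep(NA_character_, length(stack)), op)
  vals <- c(as.numeric(stack), 0)
  p <- bc_program(ins, ops, vals, env_table = et)
  inst <- vm_load(p, env = env)
  st <- NULL
  for (i in seq_along(ins)) st <- vm_step(inst, 0L)
  if (st$status == "faulted") stop("lane faulted: ", st$fault)
  st$stack
}
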