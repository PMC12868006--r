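# Randomized differential fuzz of every VM operation against independent R
# reference semantics.  Pure stack-transform ops run as one large unrolled
# single-lane program (inputs as VALUE instructions, outputs drained to an
# f64 env buffer, top of stack first); memory, env-I/O, register and barrier
# ops use dedicated randomized builders.  Returns per-op mismatch counts.

fz_out_table <- function(n) {
  data.frame(name = "out", type = "f64", len = as.integer(max(n, 1)),
             stringsAsFactors = FALSE)
}

fz_read_op <- c(f64 = "READ_F64", f32 = "READ_F32", i32 = "READ_I32",
                char = "READ_CHAR")
fz_write_op <- c(f64 = "WRITE_F64", f32 = "WRITE_F32", i32 = "WRITE_I32",
                 char = "WRITE_CHAR")

# --- pattern tiling -------------------------------------------------------
# A case pattern is a fixed instruction template with some value slots
# parameterized per case.  fz_tile() replicates it n times and fills the
# parameter slots column-wise from `params` (n x p), giving one large
# program that exercises n independent cases.

fz_pat <- function() {
  e <- new.env(parent = emptyenv())
  e$ins <- character(0); e$ops <- character(0); e$vals <- numeric(0)
  e$slots <- integer(0)
  e
}
pat_value <- function(e, v = 0, param = FALSE) {
  e$ins <- c(e$ins, "VALUE"); e$ops <- c(e$ops, NA_character_)
  e$vals <- c(e$vals, v)
  if (param) e$slots <- c(e$slots, length(e$vals))
}
pat_op <- function(e, nm) {
  e$ins <- c(e$ins, "OP"); e$ops <- c(e$ops, nm); e$vals <- c(e$vals, 0)
}
# write top of stack to out[case_base + k]; the slot is patched during tiling
pat_write_out <- function(e, k, bufid = 0) {
  pat_value(e, k, param = FALSE)
  e$out_slots <- c(e$out_slots, length(e$vals))
  e$out_offsets <- c(e$out_offsets, k)
  pat_value(e, bufid)
  pat_op(e, "WRITE_F64")
}

fz_tile_run <- function(e, n, params = NULL, outs_per_case = 0L,
                        extra_env = NULL, heap_words = 64) {
  L <- length(e$ins)
  ins <- rep(e$ins, n); ops <- rep(e$ops, n); vals <- rep(e$vals, n)
  if (!is.null(params)) {
    for (j in seq_along(e$slots)) {
      vals[seq(e$slots[j], by = L, length.out = n)] <- params[, j]
    }
  }
  if (outs_per_case > 0) {
    base <- (0:(n - 1)) * outs_per_case
    for (j in seq_along(e$out_slots)) {
      vals[seq(e$out_slots[j], by = L, length.out = n)] <-
        base + e$out_offsets[j]
    }
  }
  et <- fz_out_table(n * outs_per_case)
  if (!is.null(extra_env)) et <- rbind(extra_env, et)
  p <- bc_program(ins, ops, vals, env_table = et)
  rep <- run_program(p, limits = list(max_steps = (L + 2) * n + 10,
                                      heap_words = heap_words))
  stopifnot(all(rep$status == "halted"))
  rep
}

# --- pure stack-transform ops ---------------------------------------------

fuzz_run_pure <- function(opname, inputs, m) {
  n <- nrow(inputs); k <- ncol(inputs)
  e <- fz_pat(); e$out_slots <- integer(0); e$out_offsets <- integer(0)
  for (j in seq_len(k)) pat_value(e, 0, param = TRUE)
  pat_op(e, opname)
  for (jm in seq_len(m)) pat_write_out(e, jm - 1L)
  rep <- fz_tile_run(e, n, params = inputs, outs_per_case = m)
  if (m == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  matrix(rep$env$out, ncol = m, byrow = TRUE)
}

# op specs: input generator (n -> matrix) and reference (matrix -> matrix of
# outputs in pop order, top of stack first)
fuzz_pure_specs <- function() {
  u <- function(n, lo = -50, hi = 50) stats::runif(n, lo, hi)
  pair <- function(n, lo = -50, hi = 50) cbind(u(n, lo, hi), u(n, lo, hi))
  eqpair <- function(n) {
    m <- pair(n)
    same <- stats::runif(n) < 0.3
    m[same, 2] <- m[same, 1]
    m
  }
  boolpair <- function(n)
    cbind(sample(c(0, 0, 1, -2.5), n, TRUE), sample(c(0, 1, 1, 3.7), n, TRUE))
  cmp <- function(f) function(x) cbind(as.numeric(f(x[, 1], x[, 2])))
  un <- function(f) function(x) cbind(f(x[, 1]))
  list(
    OPNULL   = list(gen = function(n) cbind(u(n)), m = 1, ref = un(identity)),
    ADD      = list(gen = pair, m = 1, ref = function(x) cbind(x[, 1] + x[, 2])),
    SUB      = list(gen = pair, m = 1, ref = function(x) cbind(x[, 1] - x[, 2])),
    MUL      = list(gen = pair, m = 1, ref = function(x) cbind(x[, 1] * x[, 2])),
    DIV      = list(gen = pair, m = 1, ref = function(x) cbind(x[, 1] / x[, 2])),
    SADD_P   = list(gen = pair, m = 1, ref = function(x) cbind(x[, 1] + x[, 2])),
    SSUB_P   = list(gen = pair, m = 1, ref = function(x) cbind(x[, 1] - x[, 2])),
    NEG      = list(gen = function(n) cbind(u(n)), m = 1, ref = un(function(a) -a)),
    NOT      = list(gen = function(n) cbind(sample(c(0, 1, -3.2, 0), n, TRUE)),
                    m = 1, ref = un(function(a) as.numeric(a == 0))),
    AND      = list(gen = boolpair, m = 1,
                    ref = cmp(function(a, b) a != 0 & b != 0)),
    OR       = list(gen = boolpair, m = 1,
                    ref = cmp(function(a, b) a != 0 | b != 0)),
    SWAP     = list(gen = pair, m = 2, ref = function(x) cbind(x[, 1], x[, 2])),
    DUP      = list(gen = function(n) cbind(u(n)), m = 2,
                    ref = function(x) cbind(x[, 1], x[, 1])),
    DROP     = list(gen = function(n) cbind(u(n)), m = 0,
                    ref = function(x) matrix(numeric(0), nrow(x), 0)),
    EQ       = list(gen = eqpair, m = 1, ref = cmp(`==`)),
    NEQ      = list(gen = eqpair, m = 1, ref = cmp(`!=`)),
    GT       = list(gen = eqpair, m = 1, ref = cmp(`>`)),
    LT       = list(gen = eqpair, m = 1, ref = cmp(`<`)),
    GTEQ     = list(gen = eqpair, m = 1, ref = cmp(`>=`)),
    LTEQ     = list(gen = eqpair, m = 1, ref = cmp(`<=`)),
    TERNARY  = list(gen = function(n) cbind(sample(c(0, 1, -2, 0), n, TRUE),
                                            u(n), u(n)),
                    m = 1,
                    ref = function(x) cbind(ifelse(x[, 1] != 0, x[, 2], x[, 3]))),
    SIN      = list(gen = function(n) cbind(u(n)), m = 1, ref = un(sin), tol = 1e-13),
    COS      = list(gen = function(n) cbind(u(n)), m = 1, ref = un(cos), tol = 1e-13),
    TAN      = list(gen = function(n) cbind(u(n)), m = 1, ref = un(tan), tol = 1e-13),
    ASIN     = list(gen = function(n) cbind(u(n, -1, 1)), m = 1, ref = un(asin), tol = 1e-13),
    ACOS     = list(gen = function(n) cbind(u(n, -1, 1)), m = 1, ref = un(acos), tol = 1e-13),
    ATAN     = list(gen = function(n) cbind(u(n)), m = 1, ref = un(atan), tol = 1e-13),
    EXP      = list(gen = function(n) cbind(u(n, -200, 200)), m = 1, ref = un(exp), tol = 1e-13),
    LOG      = list(gen = function(n) cbind(u(n, 1e-6, 1e3)), m = 1, ref = un(log), tol = 1e-13),
    ERF      = list(gen = function(n) cbind(u(n, -6, 6)), m = 1,
                    ref = un(function(a) 2 * stats::pnorm(a * sqrt(2)) - 1), tol = 1e-13),
    SQRT     = list(gen = function(n) cbind(u(n, 0, 1e4)), m = 1, ref = un(sqrt)),
    ABS      = list(gen = function(n) cbind(u(n)), m = 1, ref = un(abs)),
    FLOOR    = list(gen = function(n) cbind(u(n, -1e4, 1e4)), m = 1, ref = un(floor)),
    POW      = list(gen = function(n) cbind(u(n, 0.1, 20), u(n, -5, 5)), m = 1,
                    ref = function(x) cbind(x[, 1]^x[, 2]), tol = 1e-13),
    FMOD     = list(gen = function(n) cbind(u(n), sample(c(-1, 1), n, TRUE) *
                                              stats::runif(n, 0.5, 10)),
                    m = 1,
                    ref = function(x) cbind(x[, 1] - trunc(x[, 1] / x[, 2]) * x[, 2]))
  )
}

# --- stack addressing ops -------------------------------------------------

# SREAD: push 6 values, read the slot at a random offset, drain the stack
fuzz_sread <- function(n) {
  d <- 6L
  v <- matrix(round(stats::runif(n * d, -99, 99), 4), n, d)
  off <- sample(1:d, n, TRUE)
  e <- fz_pat(); e$out_slots <- integer(0); e$out_offsets <- integer(0)
  for (j in seq_len(d)) pat_value(e, 0, param = TRUE)
  pat_value(e, 0, param = TRUE)          # offset
  pat_op(e, "SREAD")
  for (k in seq_len(d + 1L)) pat_write_out(e, k - 1L)
  rep <- fz_tile_run(e, n, params = cbind(v, off), outs_per_case = d + 1L)
  got <- matrix(rep$env$out, ncol = d + 1L, byrow = TRUE)
  want <- cbind(v[cbind(seq_len(n), d - off + 1L)], v[, d:1])
  sum(got != want)
}

# SWRITE: push 6 values, overwrite the slot at a random offset, drain
fuzz_swrite <- function(n) {
  d <- 6L
  v <- matrix(round(stats::runif(n * d, -99, 99), 4), n, d)
  newv <- round(stats::runif(n, -99, 99), 4)
  off <- sample(1:d, n, TRUE)
  e <- fz_pat(); e$out_slots <- integer(0); e$out_offsets <- integer(0)
  for (j in seq_len(d)) pat_value(e, 0, param = TRUE)
  pat_value(e, 0, param = TRUE)          # new value
  pat_value(e, 0, param = TRUE)          # offset
  pat_op(e, "SWRITE")
  for (k in seq_len(d)) pat_write_out(e, k - 1L)
  rep <- fz_tile_run(e, n, params = cbind(v, newv, off), outs_per_case = d)
  got <- matrix(rep$env$out, ncol = d, byrow = TRUE)
  want <- v
  want[cbind(seq_len(n), d - off + 1L)] <- newv
  want <- want[, d:1, drop = FALSE]
  sum(got != want)
}

# --- heap ops: MALLOC / PTR_STORE / MEMCPY / PTR_DEREF / FREE -------------

fuzz_memory <- function(n) {
  k <- 8L
  v <- matrix(round(stats::runif(n * k, -999, 999), 3), n, k)
  e <- fz_pat(); e$out_slots <- integer(0); e$out_offsets <- integer(0)
  pat_value(e, k); pat_op(e, "MALLOC")                 # [p1]
  for (j in seq_len(k)) {
    pat_value(e, 0, param = TRUE)                      # [p1 v]
    pat_value(e, 2); pat_op(e, "SREAD")                # [p1 v p1]
    pat_value(e, j - 1); pat_op(e, "SADD_P")           # [p1 v p1+j-1]
    pat_op(e, "PTR_STORE")                             # [p1]
  }
  pat_value(e, k); pat_op(e, "MALLOC")                 # [p1 p2]
  pat_value(e, 1); pat_op(e, "SREAD")                  # [p1 p2 p2]
  pat_value(e, 3); pat_op(e, "SREAD")                  # [p1 p2 p2 p1]
  pat_value(e, k); pat_op(e, "MEMCPY")                 # [p1 p2]
  for (j in seq_len(k)) {
    pat_value(e, 1); pat_op(e, "SREAD")                # [p1 p2 p2]
    pat_value(e, j - 1); pat_op(e, "SADD_P")
    pat_op(e, "PTR_DEREF")                             # [p1 p2 v_j]
    pat_write_out(e, j - 1L)
  }
  pat_value(e, 1); pat_op(e, "SREAD"); pat_op(e, "FREE")   # free p2
  pat_value(e, 2); pat_op(e, "SREAD"); pat_op(e, "FREE")   # free p1
  pat_op(e, "DROP"); pat_op(e, "DROP")
  rep <- fz_tile_run(e, n, params = v, outs_per_case = k,
                     heap_words = 2 * k * n + 64)
  got <- matrix(rep$env$out, ncol = k, byrow = TRUE)
  sum(got != v)
}

# --- typed env I/O --------------------------------------------------------
# write a random value at a random index, read it back; the narrowing
# reference is an independent model (4-byte round trip for f32, truncation
# for i32/char)

narrow_f32 <- function(x)
  readBin(writeBin(x, raw(), size = 4), "numeric", size = 4, n = length(x))

fuzz_env_io <- function(n, type) {
  blen <- 32L
  gen <- switch(type,
    f64 = function(n) stats::runif(n, -1e6, 1e6),
    f32 = function(n) stats::runif(n, -1e6, 1e6),
    i32 = function(n) stats::runif(n, -2e9, 2e9),
    char = function(n) stats::runif(n, 0, 255.99))
  ref <- switch(type,
    f64 = identity, f32 = narrow_f32, i32 = trunc, char = trunc)
  v <- gen(n); idx <- sample(0:(blen - 1L), n, TRUE)
  e <- fz_pat(); e$out_slots <- integer(0); e$out_offsets <- integer(0)
  pat_value(e, 0, param = TRUE)          # value
  pat_value(e, 0, param = TRUE)          # index
  pat_value(e, 0)                        # buffer id 0
  pat_op(e, fz_write_op[[type]])
  pat_value(e, 0, param = TRUE)          # index again
  pat_value(e, 0)
  pat_op(e, fz_read_op[[type]])
  pat_write_out(e, 0L, bufid = 1)
  extra <- data.frame(name = "buf", type = type, len = blen,
                      stringsAsFactors = FALSE)
  rep <- fz_tile_run(e, n, params = cbind(v, idx, idx), outs_per_case = 1L,
                     extra_env = extra)
  sum(rep$env$out != ref(v))
}

# --- casts ----------------------------------------------------------------
# DOUBLETOLONGLONG then LONGLONGTODOUBLE = round half away from zero

fuzz_casts <- function(n) {
  v <- stats::runif(n, -1e6, 1e6)
  v[seq(1, n, by = 10)] <- round(v[seq(1, n, by = 10)]) + 0.5  # exercise ties
  e <- fz_pat(); e$out_slots <- integer(0); e$out_offsets <- integer(0)
  pat_value(e, 0, param = TRUE)
  pat_op(e, "DOUBLETOLONGLONG")
  pat_op(e, "LONGLONGTODOUBLE")
  pat_write_out(e, 0L)
  rep <- fz_tile_run(e, n, params = cbind(v), outs_per_case = 1L)
  sum(rep$env$out != sign(v) * floor(abs(v) + 0.5))
}

# --- register ops ---------------------------------------------------------

# LDPC pushes the executing instruction's own index
fuzz_ldpc <- function(n) {
  e <- fz_pat(); e$out_slots <- integer(0); e$out_offsets <- integer(0)
  pat_op(e, "OPNULL")
  pat_op(e, "LDPC")
  pat_write_out(e, 0L)
  L <- length(e$ins)
  rep <- fz_tile_run(e, n, outs_per_case = 1L)
  expected <- (0:(n - 1)) * L + 1
  sum(rep$env$out != expected)
}

# LDSTK_PTR pushes the current stack pointer; vary the depth 0..5
fuzz_ldstk <- function(n) {
  mism <- 0L
  per <- ceiling(n / 6)
  for (d in 0:5) {
    e <- fz_pat(); e$out_slots <- integer(0); e$out_offsets <- integer(0)
    for (j in seq_len(d)) pat_value(e, 0, param = TRUE)
    pat_op(e, "LDSTK_PTR")
    pat_write_out(e, 0L)
    for (j in seq_len(d)) pat_op(e, "DROP")
    params <- if (d > 0)
      matrix(stats::runif(per * d, -9, 9), per, d) else NULL
    rep <- fz_tile_run(e, per, params = params, outs_per_case = 1L)
    mism <- mism + sum(rep$env$out != d)
  }
  mism
}

# LDTID across randomized lane counts
fuzz_ldtid <- function(n_runs) {
  mism <- 0L
  for (i in seq_len(n_runs)) {
    nl <- sample(1:64, 1)
    p <- bc_program(c("OP", "OP", "VALUE", "OP"),
                    c("LDTID", "LDTID", NA, "WRITE_F64"),
                    c(0, 0, 0, 0), env_table = fz_out_table(nl))
    rep <- run_program(p, n_lanes = nl, limits = list(heap_words = 64))
    mism <- mism + sum(rep$env$out != 0:(nl - 1))
  }
  mism
}

# --- barriers -------------------------------------------------------------
# every lane publishes tid + 1, syncs, reads its scope neighbor's slot

fuzz_sync <- function(n_runs) {
  mism <- 0L
  for (i in seq_len(n_runs)) {
    scope <- sample(c("SYNCWARP", "SYNCBLOCK", "SYNCGRID"), 1)
    warp <- sample(c(2L, 4L, 8L, 16L), 1)
    nl <- if (scope == "SYNCWARP") warp * sample(1:4, 1) else sample(2:32, 1)
    group <- if (scope == "SYNCWARP") warp else nl
    et <- data.frame(name = c("shared", "got"), type = "f64",
                     len = c(nl, nl), stringsAsFactors = FALSE)
    e <- fz_pat(); e$out_slots <- integer(0); e$out_offsets <- integer(0)
    pat_op(e, "LDTID"); pat_op(e, "DUP"); pat_op(e, "DUP")
    pat_value(e, 1); pat_op(e, "ADD"); pat_op(e, "SWAP")
    pat_value(e, 0); pat_op(e, "WRITE_F64")            # shared[t] = t+1 ; [t]
    pat_op(e, scope)
    pat_op(e, "DUP")                                   # [t t]
    pat_value(e, group); pat_op(e, "DIV"); pat_op(e, "FLOOR")
    pat_value(e, group); pat_op(e, "MUL")              # [t base]
    pat_value(e, 2); pat_op(e, "SREAD")                # [t base t]
    pat_value(e, 1); pat_op(e, "ADD")
    pat_value(e, group); pat_op(e, "FMOD")             # [t base (t+1)%g]
    pat_op(e, "ADD")                                   # [t nb]
    pat_value(e, 0); pat_op(e, "READ_F64")             # [t shared[nb]]
    pat_op(e, "SWAP"); pat_value(e, 1); pat_op(e, "WRITE_F64")
    p <- bc_program(e$ins, e$ops, e$vals, env_table = et)
    rep <- run_program(p, n_lanes = nl,
                       limits = list(warp_size = warp, max_steps = 1e5,
                                     heap_words = 64))
    if (!all(rep$status == "halted")) { mism <- mism + nl; next }
    t <- 0:(nl - 1)
    base <- (t %/% group) * group
    nb <- base + (t + 1) %% group
    mism <- mism + sum(rep$env$got != nb + 1)
  }
  mism
}

# --- console syscalls -----------------------------------------------------

fuzz_console <- function(n) {
  v <- stats::runif(n, -1e4, 1e4)
  v[seq(1, n, by = 3)] <- round(v[seq(1, n, by = 3)])
  ch <- sample(c(32:126, 10L), n, TRUE)
  e <- fz_pat(); e$out_slots <- integer(0); e$out_offsets <- integer(0)
  pat_value(e, 0, param = TRUE); pat_op(e, "PRINTF")
  pat_value(e, 0, param = TRUE); pat_op(e, "PRINTC")
  L <- length(e$ins)
  ins <- rep(e$ins, n); ops <- rep(e$ops, n); vals <- rep(e$vals, n)
  vals[seq(e$slots[1], by = L, length.out = n)] <- v
  vals[seq(e$slots[2], by = L, length.out = n)] <- ch
  p <- bc_program(ins, ops, vals)
  rep <- run_program(p, limits = list(max_steps = 1e7, heap_words = 64))
  stopifnot(all(rep$status == "halted"))
  nums <- ifelse(v == trunc(v), sprintf("%.0f", v), sprintf("%g", v))
  nums[nums == "-0"] <- "0"            # integral negative zero prints as 0
  want <- paste0(nums,
                 vapply(ch, function(c) rawToChar(as.raw(c)), ""),
                 collapse = "")
  as.integer(!identical(rep$console, want))
}

# --- full suite -----------------------------------------------------------
# returns a named vector of mismatch counts (0 everywhere = pass)

fuzz_all_ops <- function(n_cases = 10000L, seed = 1L) {
  with_seed <- get("with_local_seed", envir = asNamespace("blochvm"))
  with_seed(seed, {
    res <- c()
    specs <- fuzz_pure_specs()
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      x <- sp$gen(n_cases)
      got <- fuzz_run_pure(nm, x, sp$m)
      want <- sp$ref(x)
      if (is.null(sp$tol)) {
        res[nm] <- sum(got != want)
      } else {
        res[nm] <- sum(abs(got - want) > sp$tol * pmax(1, abs(want)))
      }
    }
    res["SREAD"] <- fuzz_sread(n_cases)
    res["SWRITE"] <- fuzz_swrite(n_cases)
    res["MEMORY"] <- fuzz_memory(n_cases)
    for (ty in c("f64", "f32", "i32", "char"))
      res[paste0("ENV_", toupper(ty))] <- fuzz_env_io(n_cases, ty)
    res["CASTS"] <- fuzz_casts(n_cases)
    res["LDPC"] <- fuzz_ldpc(n_cases)
    res["LDSTK_PTR"] <- fuzz_ldstk(n_cases)
    res["LDTID"] <- fuzz_ldtid(50L)
    res["SYNC"] <- fuzz_sync(40L)
    res["CONSOLE"] <- fuzz_console(n_cases)
    res
  })
}
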