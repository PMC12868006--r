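diag_of <- function(expr) {
  tryCatch({ expr; NULL }, vm_diag_error = function(e) e)
}

test_that("parser accepts the core constructs and reports located errors", {
  ast <- parse_source("let a = 2 + 3; print(a);")
  expect_s3_class(ast, "vm_ast")
  expect_length(ast, 2)
  expect_identical(ast[[1]]$k, "let")
  expect_identical(ast[[2]]$k, "print")

  e <- diag_of(parse_source("let a = ;"))
  expect_false(is.null(e))
  expect_equal(e$diagnostics$line, 1)
  expect_match(e$diagnostics$message, "unexpected ';'")

  e2 <- diag_of(parse_source("let x = 1 +\n  * 2;"))
  expect_equal(e2$diagnostics$line, 2)

  # the shipped benchmark sources parse without diagnostics
  expect_silent(parse_source(rule110_source(16, 4)))
  expect_silent(parse_source(mandelbrot_source(8, 8, 10)))
})

test_that("semantic analysis resolves symbols, types and overloads", {
  e <- diag_of(compile_source("print(b);"))
  expect_match(e$message, "unresolved symbol b")

  e <- diag_of(compile_source("let a[3]; let x = 1; x = a;"))
  expect_match(e$message, "type error")

  e <- diag_of(compile_source("env q: f64[2];\nenv q: f64[3];"))
  expect_match(e$message, "duplicate env name")

  # polymorphic dispatch: f(number) and f(array) are distinct definitions
  src <- "
fn f(x) { return x + 1; }
fn f(x: array) { return x[0] * 10; }
let a[2];
a[0] = 7;
print(f(5));
print(f(a));
"
  expect_identical(run_program(compile_source(src))$console, "6\n70\n")

  # recursion is rejected (calls are inlined)
  e <- diag_of(compile_source("fn g(x) { return g(x); } print(g(1));"))
  expect_match(e$message, "recursive")
})

test_that("codegen lowers arithmetic, loops and conditionals correctly", {
  expect_identical(run_program(compile_source("print(2+3);"))$console, "5\n")
  src <- "let s = 0; for (i = 1; i <= 10; i = i + 1) { s = s + i; } print(s);"
  expect_identical(run_program(compile_source(src))$console, "55\n")
  # while with a false condition executes its body zero times
  src2 <- "let n = 0; while (n > 0) { n = n - 1; print(1); } print(n);"
  expect_identical(run_program(compile_source(src2))$console, "0\n")
  # nested control flow and shadowing block scopes
  src3 <- "
let x = 1;
if (x == 1) { let x = 2; print(x); } else { print(99); }
print(x);
"
  expect_identical(run_program(compile_source(src3))$console, "2\n1\n")
  # operator precedence and unary minus
  expect_identical(run_program(compile_source("print(2 + 3 * 4);"))$console, "14\n")
  expect_identical(run_program(compile_source("print(-2 * 3);"))$console, "-6\n")
  expect_identical(run_program(compile_source("print((1 < 2) && (3 > 4));"))$console, "0\n")
})

test_that("fusion rewrites adjacent pairs and preserves behavior", {
  p <- bc_program(c("VALUE", "VALUE", "OP"), c(NA, NA, "ADD"), c(2, 3, 0),
                  meta = list(label_slots = integer(0), jump_targets = integer(0)))
  q <- optimize_program(p)
  expect_identical(q$instructions, c("VALUE", "SI_VALUE_OP"))
  expect_identical(q$operations[2], "ADD")
  expect_identical(q$values[2], 3)
  # both versions leave the same value behind
  i1 <- vm_load(p); for (k in 1:3) s1 <- vm_step(i1, 0)
  i2 <- vm_load(q); for (k in 1:2) s2 <- vm_step(i2, 0)
  expect_identical(s1$stack, s2$stack)

  # a VALUE that is a jump target is never fused into its predecessor
  loop <- compile_source("let i = 0; while (i < 3) { i = i + 1; } print(i);",
                         optimize = FALSE)
  opt <- optimize_program(loop)
  expect_true(fusion_complete(opt))
  for (tgt in opt$meta$jump_targets) {
    if (tgt > 0 && tgt < length(opt$instructions)) {
      prev <- opt$instructions[tgt]      # instruction before the target
      this <- opt$instructions[tgt + 1]
      expect_false(prev == "VALUE" && this == "OP")
    }
  }
  expect_identical(run_program(loop)$console, run_program(opt)$console)
})

test_that("optimized and unoptimized programs behave identically (random programs)", {
  for (seed in 1:40) {
    r <- check_optimizer_parity(seed)
    expect_true(isTRUE(r), label = paste0("seed ", seed, ": ", r))
  }
})

test_that("compilation is deterministic and always yields valid bytecode", {
  src <- random_source(123, n_stmts = 10)
  p1 <- compile_source(src)
  p2 <- compile_source(src)
  expect_identical(p1, p2)
  expect_identical(encode_program(p1), encode_program(p2))
  for (seed in c(5, 17)) {
    p <- compile_source(random_source(seed))
    expect_true(validate_program(p))
  }
})

test_that("arrays support dynamic lengths, function args, and runtime bounds", {
  src <- "
env n: f64[1];
fn total(a: array, len) {
  let s = 0;
  for (i = 0; i < len; i = i + 1) { s = s + a[i]; }
  return s;
}
let k = n[0];
let a[k];
for (i = 0; i < k; i = i + 1) { a[i] = i * i; }
print(total(a, k));
"
  rep <- run_program(compile_source(src), env = list(n = 5))
  expect_identical(rep$console, "30\n")   # 0+1+4+9+16
})

test_that("environment buffers convert at typed read/write boundaries", {
  src <- "
env ints: i32[2];
env chars: char[3];
env out: f64[2];
ints[0] = 3.9;             # narrows by truncation
chars[0] = 65; chars[1] = 66; chars[2] = 67;
out[0] = ints[0] + ints[1];
out[1] = chars[2];
"
  rep <- run_program(compile_source(src), env = list(ints = c(0L, 7L)))
  expect_identical(rep$env$ints, c(3L, 7L))
  expect_identical(rep$env$out, c(10, 67))
  expect_identical(rawToChar(rep$env$chars), "ABC")
})
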