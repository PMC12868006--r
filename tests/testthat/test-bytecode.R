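test_that("encode/decode round-trips programs exactly", {
  p <- simple_add_program()
  txt <- encode_program(p)
  expect_true(grepl('"instructions":\\["VALUE","VALUE","OP"\\]', txt))
  expect_identical(decode_program(txt), p)
  # property: arbitrary valid triples round-trip bit for bit
  set.seed(42)
  for (i in 1:25) {
    q <- random_valid_program(sample(1:40, 1))
    expect_identical(decode_program(encode_program(q)), q)
  }
  # deterministic serialization
  expect_identical(encode_program(p), encode_program(p))
})

test_that("validation rejects broken programs with the failing index", {
  expect_error(bc_program(character(0)), "empty program")
  expect_error(
    bc_program(c("VALUE", "OP"), c(NA, NA), c(2, 0)),
    "index 1.*null operation")
  p <- simple_add_program()
  p$operations <- p$operations[1:2]
  expect_error(validate_program(p), "differ in length")
  expect_error(bc_program("CALL"), "unknown instruction 'CALL'")
  expect_error(bc_program("OP", "FROBNICATE", 0), "unknown operation 'FROBNICATE'")
  expect_error(
    bc_program("OP", "ADD", 0,
               env_table = data.frame(name = c("x", "x"), type = "f64", len = 1L)),
    "duplicate environment name")
})

test_that("validation rejects single-field mutations of valid programs", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_valid_program(10L)
    mutation <- sample(c("len", "op", "instr", "env"), 1)
    broken <- p
    if (mutation == "len") broken$values <- c(broken$values, 1)
    if (mutation == "op") {
      j <- which(broken$instructions %in% c("OP", "SI_VALUE_OP", "SI_OP_VALUE"))
      if (!length(j)) next
      broken$operations[j[1]] <- "NO_SUCH_OP"
    }
    if (mutation == "instr") broken$instructions[1] <- "HCF"
    if (mutation == "env") broken$env_table$type[1] <- "f128"
    expect_error(validate_program(broken))
  }
})

test_that("decode rejects malformed input", {
  expect_error(decode_program("{not json"), "parse error")
  txt <- encode_program(simple_add_program())
  expect_error(decode_program(gsub("VALUE", "CALL", txt)), "unknown instruction")
  bad <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  bad$values <- bad$values[1:2]
  expect_error(decode_program(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "differ in length")
})

test_that("disassembly is one line per index and re-assembles exactly", {
  p <- simple_add_program()
  lines <- strsplit(disassemble(p), "\n")[[1]]
  expect_identical(lines, c("0 VALUE 2", "1 VALUE 3", "2 OP ADD"))
  # fused instruction prints value and op on one line
  q <- bc_program("SI_VALUE_OP", "MUL", 3)
  expect_identical(strsplit(disassemble(q), "\n")[[1]], "0 SI_VALUE_OP 3 MUL")
  expect_identical(assemble(disassemble(p)), p)
  # round trip on a full compiled benchmark, including env and meta
  r110 <- compile_source(rule110_source(16, 4), name = "rule110")
  expect_identical(assemble(disassemble(r110)), r110)
})

test_that("every implemented operation belongs to one category with fixed arities", {
  tab <- op_table()
  expect_true(all(!is.na(tab$arity_in) & tab$arity_in >= 0))
  expect_true(all(!is.na(tab$arity_out) & tab$arity_out >= 0))
  expect_false(any(duplicated(tab$name)))
  expect_setequal(
    unique(tab$category),
    c("null", "stack", "arithmetic", "memory", "comparison", "extra_memory",
      "float_io", "integer_io", "char_io", "math", "syscall", "cast",
      "environment", "sync"))
})
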