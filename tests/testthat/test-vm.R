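test_that("loading initializes lanes with distinct thread ids", {
  et <- data.frame(name = "out", type = "f64", len = 4L, stringsAsFactors = FALSE)
  # each lane writes its tid into out[tid]
  p <- bc_program(
    c("OP", "OP", "VALUE", "OP"),
    c("LDTID", "LDTID", NA, "WRITE_F64"),
    c(0, 0, 0, 0),
    env_table = et)
  rep <- run_program(p, n_lanes = 4)
  expect_identical(rep$env$out, c(0, 1, 2, 3))
  expect_true(all(rep$status == "halted"))
})

test_that("load rejects bad bindings and limits", {
  p <- add_to_env_program()
  expect_error(vm_load(p, env = list(out = c(1, 2))), "binding error")
  expect_error(vm_load(p, env = list(nope = 1)), "binding error")
  expect_error(vm_load(p, n_lanes = 0), "argument error")
  expect_error(vm_load(p, limits = list(stack_capacity = 0)), "argument error")
})

test_that("step applies exactly one instruction's semantics", {
  p <- simple_add_program()
  inst <- vm_load(p)
  s <- vm_step(inst, 0)
  expect_equal(s$stack, 2)
  s <- vm_step(inst, 0)
  expect_equal(s$stack, c(2, 3))
  s <- vm_step(inst, 0)
  expect_equal(s$stack, 5)
  expect_identical(s$status, "halted")

  # JUMPIFZERO: target on top, condition beneath; zero takes the jump
  p2 <- bc_program(
    c("VALUE", "VALUE", "JUMPIFZERO", "VALUE", "VALUE", "VALUE", "VALUE"),
    values = c(0, 5, 0, 99, 99, 7, 8))
  inst2 <- vm_load(p2)
  for (k in 1:3) s <- vm_step(inst2, 0)
  expect_equal(s$pc, 5)
  # nonzero condition falls through
  p3 <- bc_program(c("VALUE", "VALUE", "JUMPIFZERO", "VALUE"),
                   values = c(1, 3, 0, 42))
  inst3 <- vm_load(p3)
  for (k in 1:3) s <- vm_step(inst3, 0)
  expect_equal(s$pc, 3)
  expect_equal(s$stack, numeric(0))

  # SI_VALUE_OP pushes then executes in a single step
  p4 <- bc_program(c("VALUE", "SI_VALUE_OP"), c(NA, "MUL"), c(2, 3))
  inst4 <- vm_load(p4)
  vm_step(inst4, 0)
  s <- vm_step(inst4, 0)
  expect_equal(s$stack, 6)
  expect_identical(s$status, "halted")
})

test_that("structural errors fault the lane; IEEE arithmetic does not", {
  # stack underflow
  p <- bc_program("OP", "ADD", 0)
  s <- vm_step(vm_load(p), 0)
  expect_identical(s$status, "faulted")
  expect_match(s$fault, "underflow")
  # jump out of range
  p2 <- bc_program(c("VALUE", "JUMP"), values = c(99, 0))
  r <- vm_run(vm_load(p2))
  expect_identical(r$status, "faulted")
  expect_match(r$fault, "jump target")
  # executing a null op slot is impossible to build via bc_program; check
  # division by zero propagates inf instead of faulting
  expect_identical(exec_op("DIV", c(1, 0)), Inf)
  expect_identical(exec_op("DIV", c(-1, 0)), -Inf)
})

test_that("run writes environment mutations into the report snapshot", {
  rep <- run_program(add_to_env_program())
  expect_identical(rep$env$out, 5)
  expect_identical(rep$status, "halted")
})

test_that("analytic operation anchors hold", {
  expect_equal(exec_op("SQRT", 4), 2)
  expect_equal(exec_op("LOG", 1), 0)
  expect_equal(exec_op("ACOS", 1), 0)
  # TERNARY pops else (top), then, cond
  expect_equal(exec_op("TERNARY", c(0, 10, 20)), 20)
  expect_equal(exec_op("TERNARY", c(1, 10, 20)), 10)
  expect_equal(exec_op("SWAP", c(1, 2)), c(2, 1))
  expect_equal(exec_op("NOT", 0), 1)
})

test_that("execution is deterministic bit for bit", {
  src <- random_source(99, n_stmts = 10)
  p <- compile_source(src)
  r1 <- run_program(p, n_lanes = 3)
  r2 <- run_program(p, n_lanes = 3)
  expect_identical(r1, r2)
})

test_that("lane-local execution is order independent without env writes", {
  # lanes compute pure per-lane results; manual interleavings must agree
  src <- "
let x = tid() + 1;
let s = 0;
for (i = 0; i < 10; i = i + 1) { s = s + x * i; }
"
  p <- compile_source(src)
  a <- vm_load(p, n_lanes = 2)
  b <- vm_load(p, n_lanes = 2)
  # a: round robin; b: lane 1 to completion, then lane 0
  repeat {
    st0 <- vm_lane(a, 0); st1 <- vm_lane(a, 1)
    if (st0$status != "running" && st1$status != "running") break
    if (st0$status == "running") vm_step(a, 0)
    if (st1$status == "running") vm_step(a, 1)
  }
  while (vm_lane(b, 1)$status == "running") vm_step(b, 1)
  while (vm_lane(b, 0)$status == "running") vm_step(b, 0)
  for (l in 0:1) {
    sa <- vm_lane(a, l); sb <- vm_lane(b, l)
    expect_identical(sa$stack, sb$stack)
    expect_identical(sa$pc, sb$pc)
    expect_identical(sa$status, sb$status)
  }
})

test_that("grid barriers publish prior env writes to all lanes", {
  # lane t writes t+1 to shared[t], barrier, then reads shared[(t+1) mod 4]
  et <- data.frame(name = c("shared", "got"), type = "f64", len = c(4L, 4L),
                   stringsAsFactors = FALSE)
  ins <- c("OP", "OP", "OP", "VALUE", "OP", "OP", "VALUE", "OP",
           "OP",
           "OP", "VALUE", "OP", "VALUE", "OP", "VALUE", "OP", "OP", "VALUE", "OP")
  ops <- c("LDTID", "DUP", "DUP", NA, "ADD", "SWAP", NA, "WRITE_F64",
           "SYNCGRID",
           "DUP", NA, "ADD", NA, "FMOD", NA, "READ_F64", "SWAP", NA, "WRITE_F64")
  vals <- c(0, 0, 0, 1, 0, 0, 0, 0,
            0,
            0, 1, 0, 4, 0, 0, 0, 0, 1, 0)
  p <- bc_program(ins, ops, vals, env_table = et)
  rep <- run_program(p, n_lanes = 4)
  expect_true(all(rep$status == "halted"))
  expect_identical(rep$env$got, c(2, 3, 4, 1))
})

test_that("a lane halting before a barrier deadlocks the waiters", {
  # JUMPIFZERO with cond = tid, target = 6: lane 0 jumps straight past the
  # barrier and halts; lanes 1..3 arrive at SYNCGRID and can never be released
  p <- bc_program(
    c("OP", "VALUE", "JUMPIFZERO", "OP", "VALUE", "JUMP", "OP"),
    c("LDTID", NA, NA, "SYNCGRID", NA, NA, "OPNULL"),
    c(0, 6, 0, 0, 6, 0, 0))
  rep <- run_program(p, n_lanes = 4, limits = list(max_steps = 1000))
  expect_identical(rep$status[1], "halted")
  expect_true(all(rep$status[2:4] == "faulted"))
  expect_true(all(grepl("deadlock", rep$fault[2:4])))
})

test_that("runaway programs stop at the step limit", {
  # pc 0: push 0, jump to 0 forever
  p <- bc_program(c("VALUE", "JUMP"), values = c(0, 0))
  rep <- run_program(p, limits = list(max_steps = 500))
  expect_identical(rep$status, "step-limit")
  expect_true(rep$steps <= 501)
})

test_that("heap operations enforce the allocation table", {
  # MALLOC, PTR_STORE, PTR_DEREF round trip
  src <- "
env out: f64[3];
let a[4];
a[0] = 11; a[3] = 44;
out[0] = a[0]; out[1] = a[1]; out[2] = a[3];
"
  rep <- run_program(compile_source(src))
  expect_identical(rep$env$out, c(11, 0, 44))
  # out-of-range index faults at runtime
  rep2 <- run_program(compile_source("let a[4]; a[9] = 1;"))
  expect_identical(rep2$status, "faulted")
  expect_match(rep2$fault, "PTR_STORE")
  # FREE on a dead handle faults
  asm <- paste("0 SI_VALUE_OP 4 MALLOC",
               "1 OP DUP", "2 OP FREE", "3 OP FREE", sep = "\n")
  rep3 <- run_program(assemble(asm))
  expect_identical(rep3$status, "faulted")
  expect_match(rep3$fault, "non-live")
})

test_that("console output captures characters and formatted numbers", {
  rep <- run_program(compile_source("printc(72); printc(105); print(3.5); print(7);"))
  expect_identical(rep$console, "Hi3.5\n7\n")
})
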