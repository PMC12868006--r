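# Shared fixtures: tiny programs and a small reusable phantom.

simple_add_program <- function() {
  bc_program(c("VALUE", "VALUE", "OP"), c(NA, NA, "ADD"), c(2, 3, 0))
}

# one f64 output buffer `out`, program computes 2 + 3 and stores it
add_to_env_program <- function() {
  et <- data.frame(name = "out", type = "f64", len = 1L, stringsAsFactors = FALSE)
  bc_program(
    c("VALUE", "VALUE", "OP", "VALUE", "VALUE", "OP"),
    c(NA, NA, "ADD", NA, NA, "WRITE_F64"),
    c(2, 3, 0, 0, 0, 0),
    env_table = et)
}

# random valid program triples for round-trip property tests
random_valid_program <- function(n = 20L) {
  tab <- op_table()
  ins <- sample(BC_INSTRUCTIONS <- c("OP", "VALUE", "JUMP", "JUMPIFZERO",
                                     "SI_VALUE_OP", "SI_OP_VALUE"), n, replace = TRUE)
  ops <- ifelse(ins %in% c("OP", "SI_VALUE_OP", "SI_OP_VALUE"),
                sample(tab$name, n, replace = TRUE), NA_character_)
  vals <- round(stats::runif(n, -100, 100), 3)
  vals[!(ins %in% c("VALUE", "SI_VALUE_OP", "SI_OP_VALUE"))] <- 0
  bc_program(ins, ops, vals,
             env_table = data.frame(name = c("a", "b"), type = c("f64", "i32"),
                                    len = c(3L, 2L), stringsAsFactors = FALSE),
             meta = list(source = "random"))
}

small_phantom <- function(nx = 16L, ny = 16L) {
  make_phantom(default_phantom_spec(nx = nx, ny = ny))
}
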