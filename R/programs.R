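# Canonical benchmark programs in the high-level language, with independent
# brute-force oracles.  The VM-executed versions must reproduce the oracles
# exactly (characters for the automaton, integers for the escape counts).

#' Rule 110 cellular automaton oracle
#'
#' Direct application of the Rule 110 neighborhood map
#' (111->0, 110->1, 101->1, 100->0, 011->1, 010->1, 001->1, 000->0) to each
#' cell, generation by generation.
#'
#' @param initial Binary vector (0/1), the generation-0 row.
#' @param generations Number of update steps (>= 0).
#' @param boundary `"fixed"` (cells beyond the edge read 0) or `"wrap"`.
#' @return Integer matrix with `generations + 1` rows (row 1 = initial).
#' @export
rule110_oracle <- function(initial, generations, boundary = c("fixed", "wrap")) {
  boundary <- match.arg(boundary)
  stopifnot(all(initial %in% c(0, 1)), generations >= 0)
  w <- length(initial)
  # new cell = f(l, c, r); Rule 110 truth table indexed by 4l + 2c + r
  tab <- c(0L, 1L, 1L, 1L, 0L, 1L, 1L, 0L)   # patterns 000..111
  rows <- matrix(0L, nrow = generations + 1, ncol = w)
  rows[1, ] <- as.integer(initial)
  cur <- as.integer(initial)
  for (g in seq_len(generations)) {
    l <- if (boundary == "wrap") cur[c(w, seq_len(w - 1))] else c(0L, cur[-w])
    r <- if (boundary == "wrap") cur[c(seq_len(w)[-1], 1)] else c(cur[-1], 0L)
    cur <- tab[4L * l + 2L * cur + r + 1L]
    rows[g + 1, ] <- cur
  }
  rows
}

#' Render automaton rows as console text
#'
#' `'*'` for 1 and `' '` for 0, one generation per line (each line ends with
#' a newline, matching the VM program's character output).
#'
#' @param rows Matrix from [rule110_oracle()] (or any 0/1 matrix).
#' @return A single string.
#' @export
render_automaton <- function(rows) {
  if (is.vector(rows)) rows <- matrix(rows, nrow = 1)
  lines <- apply(rows, 1, function(r) paste(ifelse(r == 1, "*", " "), collapse = ""))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Source text of the Rule 110 benchmark program
#'
#' Builds the high-level source for a run of `generations` updates over
#' `width` cells, starting from a single 1 at the rightmost cell, printing
#' every generation (including the initial row) with `'*'`/`' '`.
#'
#' @param width Domain size in cells.
#' @param generations Number of update steps.
#' @param boundary `"fixed"` or `"wrap"` edge handling.
#' @return Source text (character scalar).
#' @export
rule110_source <- function(width = 310L, generations = 100L,
                           boundary = c("fixed", "wrap")) {
  boundary <- match.arg(boundary)
  edges <- if (boundary == "fixed") "
  if (i > 0) { l = cur[i - 1]; }
  if (i < w - 1) { r = cur[i + 1]; }
" else "
  if (i > 0) { l = cur[i - 1]; } else { l = cur[w - 1]; }
  if (i < w - 1) { r = cur[i + 1]; } else { r = cur[0]; }
"
  sprintf("
# Rule 110 cellular automaton: new = (c OR r) AND NOT (l AND c AND r)
fn next_cell(l, c, r) {
  let v = 0;
  if (c + r > 0) { v = 1; }
  if (l * c * r > 0) { v = 0; }
  return v;
}

fn show_row(a: array, n) {
  let j = 0;
  while (j < n) {
    if (a[j] > 0) { printc(42); } else { printc(32); }
    j = j + 1;
  }
  printc(10);
  return 0;
}

let w = %d;
let g = %d;
let cur[w];
let nxt[w];
let i = 0;
while (i < w) { cur[i] = 0; i = i + 1; }
cur[w - 1] = 1;
show_row(cur, w);
let gen = 0;
while (gen < g) {
  i = 0;
  while (i < w) {
    let l = 0;
    let r = 0;%s
    nxt[i] = next_cell(l, cur[i], r);
    i = i + 1;
  }
  i = 0;
  while (i < w) { cur[i] = nxt[i]; i = i + 1; }
  show_row(cur, w);
  gen = gen + 1;
}
", width, generations, edges)
}

#' Run the Rule 110 benchmark on the VM
#'
#' Compiles [rule110_source()] and executes it single-lane; the console
#' output is the automaton rendering.
#'
#' @inheritParams rule110_source
#' @param optimize Use the fusion pass.
#' @return The console text.
#' @export
run_rule110_vm <- function(width = 310L, generations = 100L,
                           boundary = "fixed", optimize = TRUE) {
  p <- compile_source(rule110_source(width, generations, boundary),
                      name = "rule110", optimize = optimize)
  rep <- run_program(p, limits = list(heap_words = 4 * width + 16,
                                      max_steps = 1e9))
  if (any(rep$status != "halted"))
    stop("rule110 program did not halt cleanly: ", paste(rep$fault, collapse = "; "))
  rep$console
}

#' Mandelbrot escape-time oracle
#'
#' Counts, for each pixel center `c`, the first `n <= cap` with
#' `|z_n| > 2` under `z_(n+1) = z_n^2 + c`, `z_0 = 0` (squared-magnitude
#' test, identical operation order to the VM program so results match
#' bit for bit); `cap` if the orbit never escapes.
#'
#' @param width,height Pixel counts.
#' @param cap Iteration cap (>= 1).
#' @param bounds Complex-plane rectangle `c(xmin, xmax, ymin, ymax)`.
#' @return Integer matrix `height x width` of escape counts.
#' @export
mandelbrot_oracle <- function(width = 256L, height = 192L, cap = 1500L,
                              bounds = c(-2.5, 1, -1, 1)) {
  stopifnot(cap >= 1)
  xmin <- bounds[1]; xmax <- bounds[2]; ymin <- bounds[3]; ymax <- bounds[4]
  px <- rep(seq_len(width) - 1, each = height)
  py <- rep(seq_len(height) - 1, times = width)
  cr <- xmin + (px + 0.5) * (xmax - xmin) / width
  ci <- ymin + (py + 0.5) * (ymax - ymin) / height
  np <- width * height
  counts <- rep.int(as.integer(cap), np)
  zr <- numeric(np); zi <- numeric(np)
  active <- seq_len(np)
  for (k in seq_len(cap)) {
    t <- zr[active] * zr[active] - zi[active] * zi[active] + cr[active]
    zi[active] <- 2 * zr[active] * zi[active] + ci[active]
    zr[active] <- t
    esc <- zr[active] * zr[active] + zi[active] * zi[active] > 4
    counts[active[esc]] <- k
    active <- active[!esc]
    if (!length(active)) break
  }
  matrix(counts, nrow = height, ncol = width)
}

#' Source text of the Mandelbrot benchmark program
#'
#' Lane-parallel escape-time kernel: lane `tid` computes pixels
#' `tid, tid + n_lanes, ...` and writes counts to the `counts` environment
#' buffer (row index varies fastest, matching [mandelbrot_oracle()]).
#'
#' @inheritParams mandelbrot_oracle
#' @param n_lanes Lane count the program is built for.
#' @return Source text.
#' @export
mandelbrot_source <- function(width = 256L, height = 192L, cap = 1500L,
                              bounds = c(-2.5, 1, -1, 1), n_lanes = 32L) {
  sprintf("
env counts: i32[%d];
let w = %d;
let h = %d;
let cap = %d;
let xmin = %.17g;
let xmax = %.17g;
let ymin = %.17g;
let ymax = %.17g;
let nl = %d;
let np = w * h;
let p = tid();
while (p < np) {
  let px = floor(p / h);
  let py = p - px * h;
  let cr = xmin + (px + 0.5) * (xmax - xmin) / w;
  let ci = ymin + (py + 0.5) * (ymax - ymin) / h;
  let zr = 0;
  let zi = 0;
  let n = 0;
  let esc = 0;
  while (n < cap && esc == 0) {
    n = n + 1;
    let t = zr * zr - zi * zi + cr;
    zi = 2 * zr * zi + ci;
    zr = t;
    if (zr * zr + zi * zi > 4) { esc = 1; }
  }
  if (esc == 0) { n = cap; }
  counts[p] = n;
  p = p + nl;
}
", width * height, width, height, cap, bounds[1], bounds[2], bounds[3],
  bounds[4], n_lanes)
}

#' Run the Mandelbrot benchmark on the VM
#'
#' @inheritParams mandelbrot_source
#' @param optimize Use the fusion pass.
#' @return Integer matrix `height x width` of escape counts.
#' @export
run_mandelbrot_vm <- function(width = 256L, height = 192L, cap = 1500L,
                              bounds = c(-2.5, 1, -1, 1), n_lanes = 32L,
                              optimize = TRUE) {
  p <- compile_source(mandelbrot_source(width, height, cap, bounds, n_lanes),
                      name = "mandelbrot", optimize = optimize)
  rep <- run_program(p, n_lanes = n_lanes,
                     limits = list(max_steps = 1e10, heap_words = 16))
  if (any(rep$status != "halted"))
    stop("mandelbrot program did not halt cleanly: ",
         paste(unique(rep$fault), collapse = "; "))
  matrix(rep$env$counts, nrow = height, ncol = width)
}

#' Render an escape-count grid to a grayscale PNG
#'
#' Pixel brightness is the escape count normalized by the cap.
#'
#' @param counts Integer matrix of escape counts.
#' @param path Output PNG path.
#' @param cap Iteration cap used (defaults to `max(counts)`).
#' @return Invisibly, the normalized matrix written.
#' @export
render_escape <- function(counts, path, cap = max(counts)) {
  img <- counts / cap
  png::writePNG(img, target = path)
  invisible(img)
}
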