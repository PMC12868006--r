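# VM execution path for the dynamic parameter updates: the T1-rescaling and
# off-resonance routines are written in the high-level language, compiled
# once, and re-run each frame over shared environment buffers (coordinates,
# baseline maps, parameters, output map).  Lanes stride over voxels.

#' Source of the VM T1-update routine
#'
#' Computes the contrast propagator and the rescaled T1 voxel-wise;
#' lane `tid` handles voxels `tid, tid + n_lanes, ...`.
#'
#' @param n Number of voxels.
#' @return Source text with env buffers `xs, ys, t1b, rho, prm, t1out`
#'   (prm = x0, y0, sigma0, D, lambda, A, t, n_lanes).
#' @export
t1_update_source <- function(n) {
  sprintf("
env xs: f64[%d];
env ys: f64[%d];
env t1b: f64[%d];
env rho: f64[%d];
env prm: f64[8];
env t1out: f64[%d];
let x0 = prm[0];
let y0 = prm[1];
let s0 = prm[2];
let dc = prm[3];
let lam = prm[4];
let amp = prm[5];
let t = prm[6];
let nl = prm[7];
let nvox = %d;
let denom = 2 * (s0 * s0 + 2 * dc * t);
let i = tid();
while (i < nvox) {
  let dx = xs[i] - x0;
  let dy = ys[i] - y0;
  let p = exp(-(dx * dx + dy * dy) / denom) * exp(-(lam * rho[i] * t));
  t1out[i] = t1b[i] - amp * t1b[i] * p;
  i = i + nl;
}
", n, n, n, n, n, n)
}

#' Source of the VM off-resonance update routine
#'
#' Evaluates the rectangular heat kernel (erf products; indicator limit at
#' `t <= 0`) and the PRF shift `domega0 - c_thermo * H` voxel-wise.
#'
#' @param n Number of voxels.
#' @return Source text with env buffers `xs, ys, dom0, prm, domout`
#'   (prm = T0, a, b, kx, ky, c_thermo, t, n_lanes).
#' @export
domega_update_source <- function(n) {
  sprintf("
env xs: f64[%d];
env ys: f64[%d];
env dom0: f64[%d];
env prm: f64[8];
env domout: f64[%d];
let t0 = prm[0];
let ha = 0.5 * prm[1];
let hb = 0.5 * prm[2];
let kx = prm[3];
let ky = prm[4];
let cth = prm[5];
let t = prm[6];
let nl = prm[7];
let nvox = %d;
let i = tid();
if (t <= 0) {
  while (i < nvox) {
    let fx = 0;
    if (abs(xs[i]) < ha) { fx = 2; }
    if (abs(xs[i]) == ha) { fx = 1; }
    let fy = 0;
    if (abs(ys[i]) < hb) { fy = 2; }
    if (abs(ys[i]) == hb) { fy = 1; }
    domout[i] = dom0[i] - cth * (t0 / 4 * (fx * fy));
    i = i + nl;
  }
} else {
  let sx = 2 * sqrt(kx * t);
  let sy = 2 * sqrt(ky * t);
  while (i < nvox) {
    let fx = erf((xs[i] + ha) / sx) - erf((xs[i] - ha) / sx);
    let fy = erf((ys[i] + hb) / sy) - erf((ys[i] - hb) / sy);
    domout[i] = dom0[i] - cth * (t0 / 4 * (fx * fy));
    i = i + nl;
  }
}
", n, n, n, n, n)
}

# Build per-frame update closures backed by compiled VM programs.
vm_update_engine <- function(phantom, co, dynamics, n_lanes) {
  n <- phantom$nx * phantom$ny
  lims <- list(stack_capacity = 256, heap_words = 16, max_steps = 1e8)
  out <- list()
  if (!is.null(dynamics$contrast)) {
    prog_t1 <- compile_source(t1_update_source(n), name = "t1_update")
    p <- dynamics$contrast
    out$t1 <- function(t) {
      env <- list(xs = as.vector(co$x), ys = as.vector(co$y),
                  t1b = as.vector(phantom$t1_map),
                  rho = as.vector(phantom$rho_map),
                  prm = c(p$x0, p$y0, p$sigma0, p$d_coef, p$lam, p$amp, t,
                          n_lanes))
      rep <- run_program(prog_t1, n_lanes = n_lanes, env = env, limits = lims)
      if (any(rep$status != "halted"))
        stop("VM T1 update faulted: ", paste(unique(rep$fault), collapse = "; "))
      matrix(rep$env$t1out, phantom$nx, phantom$ny)
    }
  }
  if (!is.null(dynamics$heat)) {
    prog_dom <- compile_source(domega_update_source(n), name = "domega_update")
    h <- dynamics$heat$h; tp <- dynamics$heat$tp
    out$domega <- function(t) {
      env <- list(xs = as.vector(co$x), ys = as.vector(co$y),
                  dom0 = as.vector(phantom$domega0_map),
                  prm = c(h$t0, h$a, h$b, h$kx, h$ky, tp$c_thermo, t, n_lanes))
      rep <- run_program(prog_dom, n_lanes = n_lanes, env = env, limits = lims)
      if (any(rep$status != "halted"))
        stop("VM off-resonance update faulted: ",
             paste(unique(rep$fault), collapse = "; "))
      matrix(rep$env$domout, phantom$nx, phantom$ny)
    }
  }
  out
}
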