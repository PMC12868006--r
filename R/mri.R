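# Strang-split Bloch SPGR CINE simulator with dynamically recomputed
# parameter maps: a Gaussian contrast-agent propagator rescales the T1 map
# and a rectangular heat kernel shifts the off-resonance map, either natively
# (vectorized R) or through compiled routines executed on the VM over shared
# environment buffers.  Phase convention: transverse magnetization precesses
# as M+ <- M+ * exp(-i * domega * dt).

#' SPGR CINE sequence parameters
#'
#' @param te Echo time (s); default 8 ms.
#' @param tr Repetition time (s); default 102 ms.
#' @param flip Flip angle (rad); default 30 degrees.
#' @param n_frames Number of CINE frames.
#' @param lines_per_frame Excitations per frame (the frame image is the
#'   voxel-wise complex signal at the final line's echo).
#' @param inter_frame_delay Delay between frames (s); default 0.
#' @param n_substeps Strang substeps used for each free-evolution interval.
#' @return A validated parameter list.
#' @export
seq_params <- function(te = 0.008, tr = 0.102, flip = pi / 6, n_frames = 10L,
                       lines_per_frame = 8L, inter_frame_delay = 0,
                       n_substeps = 2L) {
  stopifnot(te > 0, te < tr, flip > 0, flip <= pi, n_frames >= 1,
            lines_per_frame >= 1, inter_frame_delay >= 0, n_substeps >= 1)
  list(te = te, tr = tr, flip = flip, n_frames = as.integer(n_frames),
       lines_per_frame = as.integer(lines_per_frame),
       inter_frame_delay = inter_frame_delay,
       n_substeps = as.integer(n_substeps))
}

#' Contrast-agent propagator parameters
#'
#' @param sigma0 Initial spread (mm).
#' @param d_coef Spread-growth coefficient D entering `sigma0^2 + 2 D t`
#'   (used with units mm^2/s).
#' @param lam Washout decay rate lambda (1/s).
#' @param amp Amplitude A in `[0, 1]` (keeps the rescaled T1 positive).
#' @param x0,y0 Injection center (mm).
#' @return A validated parameter list.
#' @export
contrast_params <- function(sigma0 = 4, d_coef = 0.1, lam = 0.0012, amp = 0.7,
                            x0 = 20, y0 = -20) {
  stopifnot(sigma0 > 0, amp >= 0, amp <= 1)
  list(sigma0 = sigma0, d_coef = d_coef, lam = lam, amp = amp, x0 = x0, y0 = y0)
}

#' Heat-source parameters
#'
#' A rectangular initial temperature distribution diffusing anisotropically.
#'
#' @param t0 Initial temperature amplitude (degrees C).
#' @param a,b Rectangle edge lengths (mm); default 4 cm x 3 cm.
#' @param kx,ky Thermal diffusion coefficients (mm^2/s).
#' @return A validated parameter list.
#' @export
heat_params <- function(t0 = 40.3, a = 40, b = 30, kx = 0.3, ky = 0.2) {
  stopifnot(a > 0, b > 0, kx > 0, ky > 0)
  list(t0 = t0, a = a, b = b, kx = kx, ky = ky)
}

#' Thermometry coefficient parameters
#'
#' The proton-resonance-frequency shift enters as
#' `domega = domega0 - c_thermo * H`, and phase differences convert back to
#' temperature as `dT = dphi / (c_thermo * TE)`; `c_thermo` is the combined
#' coefficient alpha*gamma (rad/s per degree C).  The default corresponds to
#' a PRF coefficient of -0.01 ppm/C at 3 T (2*pi*0.01*42.58*3).
#'
#' @param c_thermo Combined coefficient (rad s^-1 C^-1), nonzero.
#' @return A validated parameter list.
#' @export
thermo_params <- function(c_thermo = 2 * pi * 0.01 * 42.58 * 3) {
  stopifnot(c_thermo != 0)
  list(c_thermo = c_thermo)
}

#' Contrast-agent propagator
#'
#' `P(x, y, t) = exp(-((x-x0)^2 + (y-y0)^2) / (2 (sigma0^2 + 2 D t))) *
#' exp(-lambda rho t)`: a spreading Gaussian bolus with tissue-dependent
#' washout.  Unitless, in `[0, 1]`.
#'
#' @param x,y Coordinates (mm), vectorized.
#' @param t Time (s), `>= 0`.
#' @param p [contrast_params()].
#' @param rho Value(s) of the tissue field at (x, y).
#' @return Propagator value(s).
#' @export
propagator <- function(x, y, t, p, rho = 0) {
  denom <- 2 * (p$sigma0 * p$sigma0 + 2 * p$d_coef * t)
  dx <- x - p$x0
  dy <- y - p$y0
  exp(-(dx * dx + dy * dy) / denom) * exp(-(p$lam * rho * t))
}

#' Dynamic T1 map under contrast-agent arrival
#'
#' `T1(x, y, t) = T1(x, y, 0) - A * T1(x, y, 0) * P(x, y, t)` voxel-wise.
#'
#' @param t1_baseline Baseline T1 map (s).
#' @param p [contrast_params()] (refused if `amp > 1`, which would produce a
#'   non-positive T1).
#' @param rho_map Tissue field map.
#' @param t Time (s).
#' @param coords Voxel-center coordinates from [phantom_coords()].
#' @return T1 map at time `t`.
#' @export
update_t1 <- function(t1_baseline, p, rho_map, t, coords) {
  if (p$amp > 1) stop("amp > 1 would produce non-positive T1")
  pr <- propagator(coords$x, coords$y, t, p, rho_map)
  t1_baseline - p$amp * t1_baseline * pr
}

#' Rectangular heat kernel
#'
#' `H(x, y, t) = T0/4 * [erf((x + a/2) / (2 sqrt(kx t))) -
#' erf((x - a/2) / (2 sqrt(kx t)))] * [same in y]`.  For `t <= 0` the
#' `t -> 0+` limit is used: `T0` times the indicator of the rectangle
#' (value `T0/2` on edge midlines, `T0/4` at corners).
#'
#' @param x,y Coordinates (mm), vectorized.
#' @param t Time (s).
#' @param h [heat_params()].
#' @return Temperature (degrees C).
#' @export
heat_kernel <- function(x, y, t, h) {
  ha <- 0.5 * h$a; hb <- 0.5 * h$b
  if (t <= 0) {
    fx <- ifelse(abs(x) < ha, 2, ifelse(abs(x) == ha, 1, 0))
    fy <- ifelse(abs(y) < hb, 2, ifelse(abs(y) == hb, 1, 0))
  } else {
    sx <- 2 * sqrt(h$kx * t)
    sy <- 2 * sqrt(h$ky * t)
    fx <- pracma::erf((x + ha) / sx) - pracma::erf((x - ha) / sx)
    fy <- pracma::erf((y + hb) / sy) - pracma::erf((y - hb) / sy)
  }
  (h$t0 / 4) * (fx * fy)
}

#' Dynamic off-resonance map under heating
#'
#' `domega(x, y, t) = domega0(x, y) - c_thermo * H(x, y, t)` voxel-wise
#' (rad/s).
#'
#' @param domega0_map Baseline off-resonance map (rad/s).
#' @param h [heat_params()].
#' @param tp [thermo_params()].
#' @param t Time (s).
#' @param coords Coordinates from [phantom_coords()].
#' @return Off-resonance map (rad/s).
#' @export
update_domega <- function(domega0_map, h, tp, t, coords) {
  domega0_map - tp$c_thermo * heat_kernel(coords$x, coords$y, t, h)
}

#' One symmetric Strang step of the Bloch evolution
#'
#' Applies relaxation over `dt/2`, then the rotation stage over `dt` (an RF
#' tip by `rf$flip` about the transverse axis at angle `rf$phase`, if given,
#' composed with z-precession by `domega * dt`), then relaxation over `dt/2`.
#' Relaxation is the exact exponential operator: `mx, my` scale by
#' `exp(-h/T2)` and `mz -> M0 + (mz - M0) exp(-h/T1)` with `h = dt/2`.
#' With relaxation disabled (infinite T1, T2) the step is a pure rotation
#' and conserves the magnetization norm to machine precision.
#'
#' @param state List with `mx`, `my`, `mz` (matrices or vectors) and clock `t`.
#' @param maps List with `t1`, `t2` (s), `pd` (equilibrium M0) and `domega`
#'   (rad/s), conformable with the state.
#' @param dt Step length (s), `> 0`.
#' @param rf `NULL`, or `list(flip =, phase =)` in radians.
#' @return The state after the step (clock advanced by `dt`).
#' @export
strang_step <- function(state, maps, dt, rf = NULL) {
  stopifnot(dt > 0)
  h <- dt / 2
  relax <- function(s) {
    e2 <- exp(-h / maps$t2)
    e1 <- exp(-h / maps$t1)
    s$mx <- s$mx * e2
    s$my <- s$my * e2
    s$mz <- maps$pd + (s$mz - maps$pd) * e1
    s
  }
  state <- relax(state)
  if (!is.null(rf)) {
    cphi <- cos(rf$phase); sphi <- sin(rf$phase)
    ca <- cos(rf$flip); sa <- sin(rf$flip)
    u <- state$mx * cphi + state$my * sphi        # along the tip axis
    v <- -state$mx * sphi + state$my * cphi       # perpendicular, in plane
    v2 <- v * ca + state$mz * sa
    mz2 <- -v * sa + state$mz * ca
    state$mx <- u * cphi - v2 * sphi
    state$my <- u * sphi + v2 * cphi
    state$mz <- mz2
  }
  theta <- maps$domega * dt
  ct <- cos(theta); st_ <- sin(theta)
  mx2 <- state$mx * ct + state$my * st_
  state$my <- -state$mx * st_ + state$my * ct
  state$mx <- mx2
  state <- relax(state)
  state$t <- state$t + dt
  state
}

free_evolve <- function(state, maps, duration, n_substeps) {
  dt <- duration / n_substeps
  for (i in seq_len(n_substeps)) state <- strang_step(state, maps, dt)
  state
}

#' Simulate an SPGR CINE acquisition
#'
#' Per excitation: perfect spoiling (transverse magnetization zeroed), an
#' instantaneous RF tip by the flip angle (phase 0), Strang free evolution to
#' the echo under the current T1/T2/off-resonance maps, recording of the
#' per-voxel complex signal `mx + i my` at TE, and completion of the TR.
#' Before each frame the T1 and/or off-resonance maps are recomputed at the
#' frame's start time from the contrast propagator and/or heat kernel —
#' either natively or by compiled routines running on the VM over shared
#' environment buffers (`engine = "vm"`), mirroring a host simulator invoking
#' embedded runtime-programmable parameter updates.
#'
#' @param phantom A [make_phantom()] object.
#' @param seq [seq_params()].
#' @param dynamics List with optional entries `contrast`
#'   ([contrast_params()]) and `heat` (`list(h = heat_params(),
#'   tp = thermo_params())`).
#' @param engine `"native"` or `"vm"`.
#' @param vm_lanes Lane count for the VM engine.
#' @return A `frame_set`: complex array `nx x ny x n_frames`, frame start
#'   times, and the sequence parameters.
#' @export
simulate_spgr_cine <- function(phantom, seq = seq_params(),
                               dynamics = list(), engine = c("native", "vm"),
                               vm_lanes = 32L) {
  engine <- match.arg(engine)
  co <- phantom_coords(phantom)
  n <- phantom$nx * phantom$ny
  upd <- if (engine == "vm")
    vm_update_engine(phantom, co, dynamics, vm_lanes) else NULL
  maps <- list(t1 = phantom$t1_map, t2 = phantom$t2_map, pd = phantom$pd_map,
               domega = phantom$domega0_map)
  state <- list(mx = matrix(0, phantom$nx, phantom$ny),
                my = matrix(0, phantom$nx, phantom$ny),
                mz = phantom$pd_map, t = 0)
  frames <- array(complex(real = 0), dim = c(phantom$nx, phantom$ny, seq$n_frames))
  times <- numeric(seq$n_frames)
  zero <- matrix(0, phantom$nx, phantom$ny)
  for (f in seq_len(seq$n_frames)) {
    times[f] <- state$t
    if (!is.null(dynamics$contrast)) {
      maps$t1 <- if (engine == "vm") upd$t1(state$t) else
        update_t1(phantom$t1_map, dynamics$contrast, phantom$rho_map,
                  state$t, co)
    }
    if (!is.null(dynamics$heat)) {
      maps$domega <- if (engine == "vm") upd$domega(state$t) else
        update_domega(phantom$domega0_map, dynamics$heat$h, dynamics$heat$tp,
                      state$t, co)
    }
    for (line in seq_len(seq$lines_per_frame)) {
      state$mx <- zero
      state$my <- zero
      # instantaneous tip by flip about x (phase 0): mz rotates into +y
      sa <- sin(seq$flip); ca <- cos(seq$flip)
      state$my <- state$mz * sa
      state$mz <- state$mz * ca
      state <- free_evolve(state, maps, seq$te, seq$n_substeps)
      if (line == seq$lines_per_frame)
        frames[, , f] <- complex(real = state$mx, imaginary = state$my)
      state <- free_evolve(state, maps, seq$tr - seq$te, seq$n_substeps)
    }
    state$t <- state$t + seq$inter_frame_delay
  }
  structure(list(frames = frames, times = times, seq = seq,
                 nx = phantom$nx, ny = phantom$ny),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat("<frame_set> ", x$nx, "x", x$ny, " voxels, ",
      dim(x$frames)[3], " frame(s), t = [",
      format(min(x$times), digits = 4), ", ",
      format(max(x$times), digits = 4), "] s\n", sep = "")
  invisible(x)
}

#' PRF-shift thermometry reconstruction
#'
#' Subtracts each frame's phase from the matching baseline frame (acquired
#' with no heating and zero baseline off-resonance), wraps the difference to
#' `(-pi, pi]`, and converts to temperature change via
#' `dT = dphi / (c_thermo * TE)`.  No spatial unwrapping is performed, so
#' values are only meaningful where the true `|dphi| < pi`.
#'
#' @param frames Heated [simulate_spgr_cine()] frame set.
#' @param baseline Baseline frame set (same geometry and sequence).
#' @param seq [seq_params()] used for both acquisitions.
#' @param tp [thermo_params()].
#' @return Numeric array `nx x ny x n_frames` of temperature change
#'   (degrees C).
#' @export
reconstruct_thermometry <- function(frames, baseline, seq, tp) {
  if (!identical(dim(frames$frames), dim(baseline$frames)))
    stop("geometry mismatch between frames and baseline")
  dphi <- Arg(frames$frames * Conj(baseline$frames))
  dphi / (tp$c_thermo * seq$te)
}
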