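# Synthetic 2-D digital phantoms: per-voxel T1/T2/PD maps, baseline
# off-resonance, and the unitless tissue field rho entering the contrast
# agent's exp(-lambda * rho * t) washout term (rho defaults to the binary
# tissue mask so the washout acts only within tissue).

#' Default brain-like phantom specification
#'
#' Three concentric elliptical tissue classes on a zero-PD background:
#' an outer CSF-like ring (T1 = 4.5 s, T2 = 2.2 s), a middle GM-like ring
#' (T1 = 1.2 s, T2 = 0.1 s) and an inner WM-like core (T1 = 0.8 s,
#' T2 = 0.07 s).  Tissue values are conventional 2-D phantom defaults.
#'
#' @param nx,ny Grid size in voxels.
#' @param dx,dy Voxel spacing in mm.
#' @return A phantom specification list for [make_phantom()].
#' @export
default_phantom_spec <- function(nx = 64L, ny = 64L, dx = 3, dy = 3) {
  fov_x <- nx * dx; fov_y <- ny * dy
  list(
    nx = nx, ny = ny, dx = dx, dy = dy,
    classes = list(
      list(name = "csf", t1 = 4.5, t2 = 2.2, pd = 1.0,
           shape = list(kind = "ellipse", cx = 0, cy = 0,
                        rx = 0.45 * fov_x, ry = 0.45 * fov_y)),
      list(name = "gm", t1 = 1.2, t2 = 0.1, pd = 0.85,
           shape = list(kind = "ellipse", cx = 0, cy = 0,
                        rx = 0.38 * fov_x, ry = 0.38 * fov_y)),
      list(name = "wm", t1 = 0.8, t2 = 0.07, pd = 0.7,
           shape = list(kind = "ellipse", cx = 0, cy = 0,
                        rx = 0.25 * fov_x, ry = 0.25 * fov_y))
    ),
    seed = 1L)
}

#' Voxel-center coordinates of a phantom grid
#'
#' Centered convention: voxel `i` (0-based) has
#' `x = (i - nx/2 + 0.5) * dx`, likewise `y`; the origin is the grid center.
#'
#' @param phantom A `phantom` object (or any list with nx, ny, dx, dy).
#' @return List with matrices `x` and `y` (nx rows, ny columns, mm).
#' @export
phantom_coords <- function(phantom) {
  xs <- (seq_len(phantom$nx) - 1 - phantom$nx / 2 + 0.5) * phantom$dx
  ys <- (seq_len(phantom$ny) - 1 - phantom$ny / 2 + 0.5) * phantom$dy
  list(x = matrix(xs, phantom$nx, phantom$ny),
       y = matrix(ys, phantom$nx, phantom$ny, byrow = TRUE))
}

shape_mask <- function(shape, cx_map, cy_map) {
  if (shape$kind == "ellipse") {
    ((cx_map - shape$cx) / shape$rx)^2 + ((cy_map - shape$cy) / shape$ry)^2 <= 1
  } else if (shape$kind == "rect") {
    abs(cx_map - shape$cx) <= shape$w / 2 & abs(cy_map - shape$cy) <= shape$h / 2
  } else stop("unknown shape kind '", shape$kind, "'")
}

#' Build a synthetic phantom from a specification
#'
#' Rasterizes the spec's geometric primitives (ellipses/rectangles) onto the
#' grid in order: later classes overwrite earlier ones where they overlap;
#' the background has zero PD (and yields exactly zero signal).  Deterministic
#' for a fixed spec.
#'
#' @param spec Specification as in [default_phantom_spec()]: grid, spacing
#'   and a list of classes with `t1`, `t2`, `pd`, optional `domega0` (rad/s)
#'   and `rho`, and a `shape`.
#' @return A `phantom` object: per-voxel maps `t1_map`, `t2_map` (s),
#'   `pd_map`, `domega0_map` (rad/s), `rho_map`, integer `labels`
#'   (0 = background), and grid geometry.
#' @export
make_phantom <- function(spec = default_phantom_spec()) {
  nx <- spec$nx; ny <- spec$ny
  co <- phantom_coords(spec)
  t1 <- matrix(0, nx, ny); t2 <- matrix(0, nx, ny); pd <- matrix(0, nx, ny)
  dom0 <- matrix(0, nx, ny); rho <- matrix(0, nx, ny)
  labels <- matrix(0L, nx, ny)
  for (k in seq_along(spec$classes)) {
    cl <- spec$classes[[k]]
    if (cl$t1 <= 0 || cl$t2 <= 0)
      stop("validation error: class '", cl$name, "' has non-positive T1/T2")
    m <- shape_mask(cl$shape, co$x, co$y)
    t1[m] <- cl$t1; t2[m] <- cl$t2; pd[m] <- cl$pd
    dom0[m] <- if (is.null(cl$domega0)) 0 else cl$domega0
    rho[m] <- if (is.null(cl$rho)) 1 else cl$rho
    labels[m] <- k
  }
  # background voxels never relax; give them harmless positive constants
  bg <- labels == 0L
  t1[bg] <- 1; t2[bg] <- 1
  structure(list(nx = nx, ny = ny, dx = spec$dx, dy = spec$dy,
                 t1_map = t1, t2_map = t2, pd_map = pd,
                 domega0_map = dom0, rho_map = rho, labels = labels,
                 class_names = vapply(spec$classes, function(c) c$name, "")),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", x$nx, "x", x$ny, " voxels, ",
      x$dx, "x", x$dy, " mm spacing\n", sep = "")
  tab <- table(factor(x$labels, levels = 0:length(x$class_names),
                      labels = c("background", x$class_names)))
  for (nm in names(tab)) cat(sprintf("  %-12s %6d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

PHANTOM_FORMAT_VERSION <- 1L

#' Save phantom maps to a JSON file
#'
#' Lossless (full double precision) plain-text round trip of all maps and
#' grid geometry.
#'
#' @param phantom A `phantom`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_phantom <- function(phantom, path) {
  obj <- list(version = PHANTOM_FORMAT_VERSION,
              nx = phantom$nx, ny = phantom$ny,
              dx = phantom$dx, dy = phantom$dy,
              class_names = as.list(phantom$class_names),
              t1_map = as.vector(phantom$t1_map),
              t2_map = as.vector(phantom$t2_map),
              pd_map = as.vector(phantom$pd_map),
              domega0_map = as.vector(phantom$domega0_map),
              rho_map = as.vector(phantom$rho_map),
              labels = as.vector(phantom$labels))
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)),
             path)
  invisible(path)
}

#' Load phantom maps from a JSON file
#'
#' @param path File written by [save_phantom()].
#' @return A `phantom`.
#' @export
load_phantom <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("I/O error: corrupt phantom file: ",
                                           conditionMessage(e)))
  if (is.null(obj$version) || obj$version != PHANTOM_FORMAT_VERSION)
    stop("phantom file version mismatch (found ",
         if (is.null(obj$version)) "none" else obj$version,
         ", expected ", PHANTOM_FORMAT_VERSION, ")")
  nx <- obj$nx; ny <- obj$ny
  m <- function(v) matrix(v, nx, ny)
  rho <- if (is.null(obj$rho_map)) {
    warning("phantom file has no rho_map; defaulting to zeros")
    matrix(0, nx, ny)
  } else m(obj$rho_map)
  structure(list(nx = nx, ny = ny, dx = obj$dx, dy = obj$dy,
                 t1_map = m(obj$t1_map), t2_map = m(obj$t2_map),
                 pd_map = m(obj$pd_map), domega0_map = m(obj$domega0_map),
                 rho_map = rho, labels = m(as.integer(obj$labels)),
                 class_names = as.character(unlist(obj$class_names))),
            class = "phantom")
}
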