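test_that("a single ellipse covering the grid gives uniform maps", {
  spec <- list(nx = 8L, ny = 8L, dx = 2, dy = 2,
               classes = list(list(name = "t", t1 = 1.5, t2 = 0.2, pd = 0.9,
                                   shape = list(kind = "ellipse", cx = 0, cy = 0,
                                                rx = 100, ry = 100))))
  ph <- make_phantom(spec)
  expect_true(all(ph$t1_map == 1.5))
  expect_true(all(ph$t2_map == 0.2))
  expect_true(all(ph$pd_map == 0.9))
  expect_true(all(ph$labels == 1L))
  expect_true(all(ph$rho_map == 1))
})

test_that("an empty spec yields zero PD and hence zero signal", {
  ph <- make_phantom(list(nx = 8L, ny = 8L, dx = 2, dy = 2, classes = list()))
  expect_true(all(ph$pd_map == 0))
  fs <- simulate_spgr_cine(ph, seq_params(n_frames = 2, lines_per_frame = 2))
  expect_true(all(fs$frames == 0))
})

test_that("non-positive relaxation times are rejected", {
  spec <- list(nx = 4L, ny = 4L, dx = 1, dy = 1,
               classes = list(list(name = "bad", t1 = -1, t2 = 0.1, pd = 1,
                                   shape = list(kind = "rect", cx = 0, cy = 0,
                                                w = 2, h = 2))))
  expect_error(make_phantom(spec), "non-positive")
})

test_that("label histogram matches a brute-force rasterization oracle", {
  spec <- default_phantom_spec(nx = 48L, ny = 48L)
  ph <- make_phantom(spec)
  # independent oracle: loop over voxel centers, last covering class wins
  xs <- (seq_len(spec$nx) - 1 - spec$nx / 2 + 0.5) * spec$dx
  ys <- (seq_len(spec$ny) - 1 - spec$ny / 2 + 0.5) * spec$dy
  want <- matrix(0L, spec$nx, spec$ny)
  for (i in seq_len(spec$nx)) for (j in seq_len(spec$ny)) {
    for (k in seq_along(spec$classes)) {
      sh <- spec$classes[[k]]$shape
      if ((xs[i] / sh$rx)^2 + (ys[j] / sh$ry)^2 <= 1) want[i, j] <- k
    }
  }
  expect_identical(ph$labels, want)
  # voxel counts agree with the continuous ellipse areas to perimeter order
  for (k in seq_along(spec$classes)) {
    sh <- spec$classes[[k]]$shape
    area_vox <- pi * sh$rx * sh$ry / (spec$dx * spec$dy)
    count <- sum(ph$labels >= k)       # ellipses are nested
    perim_vox <- 2 * pi * sqrt((sh$rx^2 + sh$ry^2) / 2) / spec$dx
    expect_lt(abs(count - area_vox), perim_vox)
  }
})

test_that("later primitives overwrite earlier ones where they overlap", {
  spec <- list(nx = 16L, ny = 16L, dx = 1, dy = 1, classes = list(
    list(name = "big", t1 = 2, t2 = 0.5, pd = 1,
         shape = list(kind = "rect", cx = 0, cy = 0, w = 12, h = 12)),
    list(name = "small", t1 = 1, t2 = 0.1, pd = 0.5,
         shape = list(kind = "rect", cx = 0, cy = 0, w = 4, h = 4))))
  ph <- make_phantom(spec)
  center <- ph$t1_map[8, 8]
  expect_identical(center, 1)
  expect_identical(ph$t1_map[3, 8], 2)
})

test_that("save/load round-trips phantoms losslessly", {
  ph <- small_phantom(12L, 12L)
  path <- tempfile(fileext = ".json")
  save_phantom(ph, path)
  ph2 <- load_phantom(path)
  expect_equal(ph2, ph)
  expect_identical(ph2$t1_map, ph$t1_map)

  # missing rho_map defaults to zeros with a warning
  obj <- jsonlite::fromJSON(path)
  obj$rho_map <- NULL
  path2 <- tempfile(fileext = ".json")
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)),
             path2)
  expect_warning(ph3 <- load_phantom(path2), "rho_map")
  expect_true(all(ph3$rho_map == 0))

  # version mismatch is an explicit error
  obj2 <- jsonlite::fromJSON(path)
  obj2$version <- 99
  path3 <- tempfile(fileext = ".json")
  writeLines(as.character(jsonlite::toJSON(obj2, auto_unbox = TRUE, digits = NA)),
             path3)
  expect_error(load_phantom(path3), "version mismatch")
  expect_error(load_phantom(tempfile()), "not found")
})
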