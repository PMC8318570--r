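# Phantom generator: geometry, determinism, contrast, misalignment,
# degradation.

test_that("single-ellipsoid phantom matches the analytic volume and label set", {
  st <- data.frame(name = "blob", cx = 0.5, cy = 0.5, cz = 0.5,
                   ax = 0.30, ay = 0.30, az = 0.30, parent = 0L,
                   stringsAsFactors = FALSE)
  spec <- phantom_spec(grid_shape = c(32, 32, 32), n_structures = 1,
                       geometry_seed = 2, wobble = 0, structures = st)
  lab <- generate_label_map(spec)
  expect_setequal(unique(as.vector(lab$data)), c(0L, 1L))
  analytic <- 4 / 3 * pi * prod(c(0.30, 0.30, 0.30) * 32)
  count <- sum(lab$data == 1L)
  expect_lt(abs(count - analytic) / analytic, 0.20)
})

test_that("label maps are deterministic in (spec, seed) and vary with seed", {
  spec <- small_phantom(grid = c(24, 24, 24), n_structures = 3)
  a <- generate_label_map(spec)
  b <- generate_label_map(spec)
  expect_identical(a$data, b$data)
  spec2 <- small_phantom(grid = c(24, 24, 24), n_structures = 3,
                         geometry_seed = 99)
  expect_false(identical(a$data, generate_label_map(spec2)$data))
})

test_that("nested structures stay inside the parent's analytic region", {
  st <- data.frame(name = c("outer", "inner"),
                   cx = c(0.5, 0.52), cy = c(0.5, 0.5), cz = c(0.5, 0.48),
                   ax = c(0.34, 0.12), ay = c(0.34, 0.12), az = c(0.34, 0.12),
                   parent = c(0L, 1L), stringsAsFactors = FALSE)
  spec <- phantom_spec(grid_shape = c(32, 32, 32), n_structures = 2,
                       geometry_seed = 7, wobble = 0, structures = st)
  lab <- generate_label_map(spec)
  # the child is clipped to the parent's pre-carving region, so the union
  # of {parent, child} is that region; no child voxel may touch background
  child <- which(lab$data == 2L, arr.ind = TRUE)
  expect_gt(nrow(child), 0)
  d <- dim(lab$data)
  for (ax in 1:3) for (dir in c(-1L, 1L)) {
    nb <- child
    nb[, ax] <- pmin(pmax(nb[, ax] + dir, 1L), d[ax])
    expect_true(all(lab$data[nb] != 0L))
  }
  # every declared label present and nonempty
  expect_setequal(unique(as.vector(lab$data)), 0:2)
})

test_that("structures outside the grid are rejected", {
  st <- data.frame(name = "escapee", cx = 0.9, cy = 0.5, cz = 0.5,
                   ax = 0.3, ay = 0.2, az = 0.2, parent = 0L,
                   stringsAsFactors = FALSE)
  spec <- phantom_spec(grid_shape = c(32, 32, 32), n_structures = 1,
                       wobble = 0, structures = st)
  expect_error(generate_label_map(spec), "outside the grid")
})

test_that("noiseless rendering is piecewise constant at the table means", {
  lab <- generate_label_map(small_phantom(grid = c(24, 24, 24),
                                          n_structures = 3))
  con <- modality_contrast("t1", 3, noise_sigma = 0, bias_amplitude = 0)
  img <- render_modality(lab, con, seed = 1)
  expect_equal(img$data, array(con$means[lab$data + 1L], dim(lab$data)))
})

test_that("rendered noise has the configured standard deviation", {
  lab <- generate_label_map(small_phantom(grid = c(32, 32, 32),
                                          n_structures = 2))
  con <- modality_contrast("t1", 2, noise_sigma = 5)
  img <- render_modality(lab, con, seed = 21)
  for (s in 0:2) {
    vox <- img$data[lab$data == s]
    if (length(vox) < 1000) next
    expect_lt(abs(sd(vox) - 5) / 5, 0.15)
  }
})

test_that("renderings with different seeds differ only in the noise", {
  lab <- generate_label_map(small_phantom(grid = c(24, 24, 24),
                                          n_structures = 2))
  con <- modality_contrast("t1", 2, noise_sigma = 4)
  a <- render_modality(lab, con, seed = 1)
  b <- render_modality(lab, con, seed = 2)
  expect_false(identical(a$data, b$data))
  resid_a <- a$data - con$means[lab$data + 1L]
  resid_b <- b$data - con$means[lab$data + 1L]
  expect_lt(abs(mean(resid_a) - mean(resid_b)), 0.2)
  expect_lt(abs(sd(resid_a) - sd(resid_b)), 0.2)
})

test_that("rendering rejects labels missing from the contrast table", {
  lab <- generate_label_map(small_phantom(grid = c(24, 24, 24),
                                          n_structures = 3))
  expect_error(render_modality(lab, modality_contrast("t1", 2)),
               "does not cover")
})

test_that("default contrast tables encode the T1-vs-CT gray/white separation", {
  t1 <- modality_contrast("t1", 8)
  ct <- modality_contrast("ct", 8)
  # structure 1 is the gray-matter-like shell, structure 2 the white matter
  expect_gte(abs(t1$means[2] - t1$means[3]), 4 * t1$noise_sigma)
  expect_lte(abs(ct$means[2] - ct$means[3]), 1 * ct$noise_sigma)
})

test_that("a nearest-mean intensity classifier separates GM/WM better on T1 than CT", {
  lab <- generate_label_map(small_phantom(grid = c(32, 32, 32),
                                          n_structures = 2))
  acc <- sapply(c("t1", "ct"), function(m) {
    con <- modality_contrast(m, 2)
    img <- render_modality(lab, con, seed = 31)
    sel <- lab$data %in% c(1L, 2L)
    pred <- ifelse(abs(img$data[sel] - con$means[2]) <
                     abs(img$data[sel] - con$means[3]), 1L, 2L)
    mean(pred == lab$data[sel])
  })
  expect_gt(acc[["t1"]], acc[["ct"]])
  expect_gt(acc[["t1"]], 0.95)
})

test_that("misalign with zero bounds is an exact no-op with identity transform", {
  pair <- phantom_pair(grid = c(24, 24, 24), n_structures = 2)
  out <- misalign(pair$image, 0, 0, seed = 3)
  expect_identical(out$volume$data, pair$image$data)
  expect_equal(out$transform$matrix, diag(4))
})

test_that("rotating a sphere label map preserves its volume within 2%", {
  st <- data.frame(name = "sphere", cx = 0.5, cy = 0.5, cz = 0.5,
                   ax = 0.28, ay = 0.28, az = 0.28, parent = 0L,
                   stringsAsFactors = FALSE)
  spec <- phantom_spec(grid_shape = c(32, 32, 32), n_structures = 1,
                       wobble = 0, structures = st)
  lab <- generate_label_map(spec)
  out <- misalign(lab, max_rotation_deg = 5, max_translation_mm = 0, seed = 4)
  v0 <- sum(lab$data == 1L)
  v1 <- sum(out$volume$data == 1L)
  expect_lt(abs(v1 - v0) / v0, 0.02)
})

test_that("degrade is identity at sigma 0 and PSNR decreases with sigma", {
  pair <- phantom_pair(grid = c(24, 24, 24), n_structures = 2)
  expect_identical(degrade(pair$image, 0, seed = 1)$data, pair$image$data)
  psnr <- sapply(c(5, 15, 40), function(s) {
    noisy <- degrade(pair$image, s, seed = 11)
    mse <- mean((noisy$data - pair$image$data)^2)
    10 * log10(diff(range(pair$image$data))^2 / mse)
  })
  expect_true(all(diff(psnr) < 0))
})

test_that("phantom pairs are self-consistent and misalignment bounds validated", {
  spec <- small_phantom(grid = c(24, 24, 24), n_structures = 2)
  pairs <- phantom_dataset(2, spec, modality_contrast("t1", 2), seed = 5)
  expect_length(pairs, 2)
  for (p in pairs) {
    expect_identical(dim(p$image$data), dim(p$labels$data))
    con <- modality_contrast("t1", 2, noise_sigma = 5)
    resid <- p$image$data - con$means[p$labels$data + 1L]
    expect_lt(abs(sd(resid) - 5), 0.5)  # image really rendered from labels
  }
  expect_error(misalign(pairs[[1]]$image, -1, 0), ">= 0")
})
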