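# Argmax segmentation, MC-dropout sampling, CV quality gate, and the
# end-to-end pipeline.

softmax_from <- function(m, d = NULL) {
  if (is.null(d)) d <- c(dim(m)[1], 1, 1)
  ms_softmax(array(m, c(d, ncol(m))))
}

test_that("hard segmentation takes the argmax with ties toward lower labels", {
  one_hot_m <- modalseg::one_hot(c(0, 2, 1, 1), 3)
  sm <- softmax_from(one_hot_m, c(4, 1, 1))
  expect_equal(as.vector(hard_segmentation(sm)$data), c(0, 2, 1, 1))
  sm2 <- softmax_from(rbind(c(0.2, 0.5, 0.3)), c(1, 1, 1))
  expect_equal(as.vector(hard_segmentation(sm2)$data), 1L)
  tie <- softmax_from(rbind(c(0.5, 0.5)), c(1, 1, 1))
  expect_equal(as.vector(hard_segmentation(tie)$data), 0L)
})

test_that("MC sampling is reproducible and degenerates correctly", {
  net <- unet(c(16, 16, 16), n_classes = 3, depth = 1, n_filters = 4,
              dropout = 0.3, seed = 1)
  withr::with_seed(3, {
    v <- ms_volume(array(runif(16^3, 0, 100), c(16, 16, 16)))
  })
  cfg <- inference_config("t1", n_samples = 3, seed = 5)
  a <- mc_predict(net, v, cfg, normalize = FALSE)
  b <- mc_predict(net, v, cfg, normalize = FALSE)
  expect_identical(a$samples, b$samples)
  expect_length(a$samples, 3)
  # N = 1 equals a single stochastic pass with the derived seed
  cfg1 <- inference_config("t1", n_samples = 1, seed = 5)
  one <- mc_predict(net, v, cfg1, normalize = FALSE)
  direct <- forward_unet(net, v, stochastic = TRUE, seed = one$seeds[1])
  expect_equal(array(one$samples[[1]],
                     c(16, 16, 16, 3)), direct$data, tolerance = 0)
  # r = 0: all samples equal the deterministic pass
  net0 <- unet(c(16, 16, 16), n_classes = 3, depth = 1, n_filters = 4,
               dropout = 0, seed = 1)
  s0 <- mc_predict(net0, v, inference_config("t1", n_samples = 3, seed = 2),
                   normalize = FALSE)
  det <- forward_unet(net0, v)
  for (s in s0$samples)
    expect_equal(array(s, c(16, 16, 16, 3)), det$data, tolerance = 0)
  expect_error(inference_config(n_samples = 0), "n_samples")
})

test_that("softmax-sum aggregation reduces to argmax for degenerate sets", {
  net <- unet(c(16, 16, 16), n_classes = 3, depth = 1, n_filters = 4,
              dropout = 0.3, seed = 2)
  withr::with_seed(4, {
    v <- ms_volume(array(runif(16^3, 0, 100), c(16, 16, 16)))
  })
  one <- mc_predict(net, v, inference_config("t1", n_samples = 1, seed = 7),
                    normalize = FALSE)
  agg1 <- aggregate_mc(one)
  hs <- hard_segmentation(softmax_from(one$samples[[1]], c(16, 16, 16)))
  expect_identical(agg1$data, hs$data)
  # identical samples: aggregation equals any single-sample argmax
  dup <- one
  dup$samples <- rep(one$samples, 4)
  expect_identical(aggregate_mc(dup)$data, agg1$data)
})

test_that("aggregation sums the votes exactly", {
  s <- structure(list(samples = list(rbind(c(0.6, 0.4)), rbind(c(0.3, 0.7))),
                      grid = list(dim = c(1L, 1L, 1L), spacing = c(1, 1, 1),
                                  affine = diag(4)),
                      n_classes = 2L),
                 class = "ms_mcsamples")
  expect_equal(as.vector(aggregate_mc(s)$data), 1L)  # sums (0.9, 1.1)
})

test_that("volume CV follows the sample-SD definition and conventions", {
  mk <- function(n1) {  # sample with n1 voxels of label 1 out of 200
    P <- matrix(0, 200, 2); P[, 1] <- 1
    if (n1 > 0) { P[seq_len(n1), 1] <- 0; P[seq_len(n1), 2] <- 1 }
    P
  }
  s <- structure(list(samples = list(mk(90), mk(110)),
                      grid = list(dim = c(200L, 1L, 1L), spacing = c(1, 1, 1),
                                  affine = diag(4)),
                      n_classes = 2L),
                 class = "ms_mcsamples")
  qc <- volume_cv(s, label_scheme(1), threshold = 0.1)
  expect_equal(qc$per_structure$mean_volume_mm3, 100)
  expect_equal(qc$per_structure$sd_volume_mm3, sqrt(200), tolerance = 1e-12)
  expect_equal(qc$cv, sqrt(200) / 100, tolerance = 1e-12)
  expect_true(qc$flagged)  # 0.1414 > 0.1
  # identical samples: CV 0, not flagged
  s2 <- s; s2$samples <- list(mk(90), mk(90))
  qc2 <- volume_cv(s2, label_scheme(1), threshold = 0.1)
  expect_equal(qc2$cv, 0)
  expect_false(qc2$flagged)
  # CV invariant under uniform voxel-volume rescaling
  qc3 <- volume_cv(s, label_scheme(1), spacing = c(2, 2, 2), threshold = 0.1)
  expect_equal(qc3$cv, qc$cv, tolerance = 1e-12)
  expect_equal(qc3$per_structure$mean_volume_mm3, 800)
})

test_that("structures absent from every sample are excluded from the CV mean", {
  P1 <- matrix(0, 100, 3); P1[, 1] <- 1; P1[1:40, ] <- c(0); P1[1:40, 2] <- 1
  P2 <- matrix(0, 100, 3); P2[, 1] <- 1; P2[1:60, ] <- c(0); P2[1:60, 2] <- 1
  s <- structure(list(samples = list(P1, P2),
                      grid = list(dim = c(100L, 1L, 1L), spacing = c(1, 1, 1),
                                  affine = diag(4)),
                      n_classes = 3L),
                 class = "ms_mcsamples")
  qc <- volume_cv(s, label_scheme(2), threshold = 0.5)
  expect_equal(qc$per_structure$cv[qc$per_structure$id == 2], 0)
  # mean over present structures only: equals structure 1's CV
  expect_equal(qc$cv, qc$per_structure$cv[qc$per_structure$id == 1])
  expect_warning(volume_cv(structure(list(samples = list(P1),
    grid = s$grid, n_classes = 3L), class = "ms_mcsamples"),
    label_scheme(2)), "single")
})

test_that("the full pipeline returns a mask on the native grid with QC", {
  m <- trained_tiny_model()
  pair <- phantom_dataset(1, m$spec, m$contrast, seed = 77)[[1]]
  cfg <- inference_config("t1", n_samples = 5, seed = 3, cv_threshold = 0.05,
                          input_shape = c(24, 24, 24))
  res <- segment_volume(pair$image, m$fit, reference = NULL, config = cfg)
  expect_s3_class(res$labels, "ms_labels")
  expect_identical(dim(res$labels$data), dim(pair$image$data))
  expect_identical(res$labels$affine, pair$image$affine)
  expect_s3_class(res$qc, "qc_report")
  # aligned input with no registration equals the plain MC path
  mc <- mc_predict(m$fit, pair$image, cfg)
  agg <- aggregate_mc(mc, scheme = label_scheme(3))
  expect_identical(res$labels$data, agg$data)
  # back-projected masks only contain labels the network produced
  expect_true(all(unique(as.vector(res$labels$data)) %in% 0:3))
  # segmentation quality on a clean phantom is high
  expect_gt(average_dice(res$labels, pair$labels, label_scheme(3)), 0.85)
})

test_that("a translated input segments almost as well after registration", {
  m <- trained_tiny_model()
  pair <- phantom_dataset(1, m$spec, m$contrast, seed = 78)[[1]]
  cfg <- inference_config("t1", n_samples = 5, seed = 3, cv_threshold = 0.05,
                          input_shape = c(24, 24, 24))
  aligned <- segment_volume(pair$image, m$fit, reference = NULL,
                            config = cfg)
  d_aligned <- average_dice(aligned$labels, pair$labels, label_scheme(3))
  mis <- misalign(pair$image, max_rotation_deg = 0, max_translation_mm = 2,
                  seed = 9)
  moved <- segment_volume(mis$volume, m$fit, reference = pair$image,
                          config = cfg)
  # the misaligned scan's ground truth is the label map carried through
  # the same transform (moved(x) = original(T x))
  truth_moved <- apply_transform(pair$labels, mis$transform,
                                 target_grid = pair$labels)
  d_moved <- average_dice(moved$labels, truth_moved, label_scheme(3))
  expect_gt(d_moved, d_aligned - 0.1)
})

test_that("QC reports serialize to JSON", {
  m <- trained_tiny_model()
  pair <- phantom_dataset(1, m$spec, m$contrast, seed = 79)[[1]]
  cfg <- inference_config("t1", n_samples = 4, seed = 2,
                          input_shape = c(24, 24, 24))
  mc <- mc_predict(m$fit, pair$image, cfg)
  qc <- volume_cv(mc, label_scheme(3), threshold = cfg$cv_threshold)
  f <- withr::local_tempfile(fileext = ".json")
  qc_to_json(qc, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$cv, qc$cv, tolerance = 1e-12)
  expect_equal(back$flagged, qc$flagged)
})
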