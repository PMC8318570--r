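# Evaluation metrics against independent brute-force oracles.

test_that("Dice handles the canonical hand cases", {
  d <- c(6, 6, 6)
  a <- array(0L, d); a[1:4, 1, 1] <- 1L
  b <- array(0L, d); b[3:4, 1, 1] <- 1L
  expect_equal(dice_score(a, b, 1), 2 * 2 / (4 + 2))
  expect_equal(dice_score(a, a, 1), 1.0)
  disj <- array(0L, d); disj[1, 6, 6] <- 1L
  expect_equal(dice_score(a, disj, 1), 0.0)
  expect_equal(dice_score(a, b, 5), 1.0)  # empty in both, by convention
  expect_error(dice_score(a, array(0L, c(4, 4, 4)), 1), "match")
})

test_that("average and weighted Dice follow their definitions", {
  d <- c(8, 8, 8)
  truth <- array(0L, d)
  truth[1:3, 1, 1] <- 1L   # structure 1: 3 voxels
  truth[1, 2, 1] <- 2L     # structure 2: 1 voxel
  pred <- truth
  pred[1, 2, 1] <- 0L; pred[2, 2, 1] <- 2L  # s2 disjoint-ish
  # s1: dice 1; s2: pred {2,2,1} vs truth {1,2,1} -> 0 overlap
  sc <- label_scheme(2)
  expect_equal(average_dice(pred, truth, sc), mean(c(1, 0)))
  # weighted by predicted volumes 3 and 1
  expect_equal(weighted_dice(pred, truth, sc), (3 * 1 + 1 * 0) / 4)
  # all structures equal masks
  expect_equal(average_dice(truth, truth, sc), 1.0)
  expect_equal(weighted_dice(truth, truth, sc), 1.0)
  # all-background prediction: weighted dice undefined
  expect_true(is.na(weighted_dice(array(0L, d), truth, sc)))
})

test_that("weighted Dice equals average Dice for equal volumes", {
  d <- c(8, 8, 8)
  truth <- array(0L, d)
  truth[1:2, 1, 1] <- 1L; truth[1:2, 3, 1] <- 2L
  pred <- array(0L, d)
  pred[1:2, 1, 1] <- 1L; pred[c(2, 3), 3, 1] <- 2L
  sc <- label_scheme(2)
  expect_equal(weighted_dice(pred, truth, sc), average_dice(pred, truth, sc))
})

test_that("surface extraction matches exhaustive enumeration", {
  d <- c(7, 7, 7)
  cube <- array(FALSE, d); cube[3:5, 3:5, 3:5] <- TRUE
  s <- extract_surface(cube)
  expect_equal(nrow(s), 26)  # 27-voxel cube minus its center
  single <- array(FALSE, d); single[4, 4, 4] <- TRUE
  expect_equal(nrow(extract_surface(single)), 1)
  sheet <- array(FALSE, d); sheet[, , 4] <- TRUE
  expect_equal(nrow(extract_surface(sheet)), 49)  # 1-thick: all surface
  expect_equal(nrow(extract_surface(array(FALSE, d))), 0)
  # border voxels count the outside as background
  full <- array(TRUE, c(3, 3, 3))
  expect_equal(nrow(extract_surface(full)), 26)
})

test_that("ASSD hand cases including anisotropic spacing", {
  d <- c(6, 6, 6)
  a <- array(0L, d); a[1, 1, 1] <- 1L
  b <- array(0L, d); b[4, 1, 1] <- 1L
  expect_equal(assd(b, a, 1, spacing = c(1, 1, 1)), 3.0)
  expect_equal(assd(b, a, 1, spacing = c(2, 1, 1)), 6.0)
  expect_equal(assd(a, a, 1, spacing = c(1, 1, 1)), 0.0)
  expect_true(is.na(assd(array(0L, d), a, 1)))
})

test_that("metrics agree with brute-force oracles on random maps", {
  for (seed in 1:20) {
    d <- withr::with_seed(seed, sample(6:12, 3, replace = TRUE))
    nlab <- withr::with_seed(seed + 100, sample(1:4, 1))
    pred <- random_label_array(d, nlab, seed)
    truth <- random_label_array(d, nlab, seed + 1000)
    spacing <- withr::with_seed(seed + 2000, sample(c(0.5, 1, 2), 3, TRUE))
    for (s in seq_len(nlab)) {
      expect_equal(dice_score(pred, truth, s), oracle_dice(pred, truth, s),
                   tolerance = 1e-12)
      a_pkg <- assd(pred, truth, s, spacing)
      a_ora <- oracle_assd(pred, truth, s, spacing)
      if (is.na(a_ora)) expect_true(is.na(a_pkg))
      else expect_equal(a_pkg, a_ora, tolerance = 1e-9)
    }
    sc <- label_scheme(nlab)
    expect_equal(average_dice(pred, truth, sc),
                 mean(sapply(seq_len(nlab), function(s)
                   oracle_dice(pred, truth, s))), tolerance = 1e-12)
  }
})

test_that("Dice and ASSD are symmetric and translation invariant", {
  for (seed in 1:5) {
    pred <- random_label_array(c(9, 9, 9), 2, seed)
    truth <- random_label_array(c(9, 9, 9), 2, seed + 50)
    expect_equal(dice_score(pred, truth, 1), dice_score(truth, pred, 1))
    expect_equal(assd(pred, truth, 1), assd(truth, pred, 1),
                 tolerance = 1e-12)
  }
  base <- array(0L, c(12, 12, 12)); base[3:5, 4:6, 3:4] <- 1L
  other <- array(0L, c(12, 12, 12)); other[4:7, 4:5, 3:5] <- 1L
  shift <- function(m) {
    out <- array(0L, dim(m)); out[4:12, 3:12, 2:12] <- m[1:9, 1:10, 1:11]
    out
  }
  expect_equal(dice_score(shift(base), shift(other), 1),
               dice_score(base, other, 1))
  expect_equal(assd(shift(base), shift(other), 1), assd(base, other, 1),
               tolerance = 1e-12)
})

test_that("eroding a solid prediction lowers Dice and raises ASSD", {
  st <- data.frame(name = "sphere", cx = 0.5, cy = 0.5, cz = 0.5,
                   ax = 0.3, ay = 0.3, az = 0.3, parent = 0L,
                   stringsAsFactors = FALSE)
  lab <- generate_label_map(phantom_spec(grid_shape = c(24, 24, 24),
                                         n_structures = 1, wobble = 0,
                                         structures = st))
  truth <- lab$data
  erode <- function(m) {
    keep <- array(TRUE, dim(m))
    d <- dim(m)
    for (ax in 1:3) for (dir in c(-1, 1)) {
      idx <- lapply(d, seq_len)
      idx[[ax]] <- pmin(pmax(idx[[ax]] + dir, 1), d[ax])
      keep <- keep & (m[idx[[1]], idx[[2]], idx[[3]]] == 1L)
    }
    out <- m; out[!(keep & m == 1L)] <- 0L
    out
  }
  pred1 <- erode(truth)
  pred2 <- erode(pred1)
  d0 <- dice_score(truth, truth, 1)
  d1 <- dice_score(pred1, truth, 1)
  d2 <- dice_score(pred2, truth, 1)
  expect_true(d0 > d1 && d1 > d2)
  a0 <- assd(truth, truth, 1)
  a1 <- assd(pred1, truth, 1)
  a2 <- assd(pred2, truth, 1)
  expect_true(a0 <= a1 && a1 <= a2)
  expect_gt(a2, a0)
})

test_that("evaluation reports satisfy their invariants and serialize", {
  for (seed in c(3, 14)) {
    pred <- ms_labels(random_label_array(c(10, 10, 10), 3, seed),
                      spacing = c(1, 1, 2))
    truth <- ms_labels(random_label_array(c(10, 10, 10), 3, seed + 7),
                       spacing = c(1, 1, 2))
    rep_ <- evaluate_segmentation(pred, truth, label_scheme(3))
    per <- rep_$per_structure
    expect_true(all(per$dice >= 0 & per$dice <= 1))
    expect_true(all(per$assd_mm >= 0, na.rm = TRUE))
    expect_gte(rep_$average_dice, min(per$dice))
    expect_lte(rep_$average_dice, max(per$dice))
    expect_gte(rep_$weighted_dice, min(per$dice))
    expect_lte(rep_$weighted_dice, max(per$dice))
    expect_equal(rep_$total_volume_mm3, sum(per$volume_mm3))
    f <- withr::local_tempfile(fileext = ".json")
    metrics_to_json(rep_, f)
    back <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_equal(back$average_dice, rep_$average_dice, tolerance = 1e-12)
    expect_equal(unlist(back$dice), setNames(per$dice, per$name),
                 tolerance = 1e-12)
  }
  # identical maps: perfect aggregates
  same <- ms_labels(random_label_array(c(8, 8, 8), 2, 5))
  rep0 <- evaluate_segmentation(same, same, label_scheme(2))
  expect_equal(rep0$average_dice, 1.0)
  expect_equal(rep0$weighted_dice, 1.0)
  expect_equal(rep0$mean_assd_mm, 0.0)
})
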