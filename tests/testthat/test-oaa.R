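test_that("random affine draws respect ranges, seeds, and degenerate cases", {
  cfg <- search_config(rotation_range = c(0, 0), scale_range = c(1, 1),
                       translation_range = c(0, 0))
  p <- random_affine(cfg, dims = c(32, 32), seed = 1)
  expect_equal(p$rotation, 0)
  expect_equal(p$scale, 1)
  expect_equal(p$translation, c(0, 0))
  cfg2 <- search_config(rotation_range = c(-10, 10))
  expect_identical(random_affine(cfg2, c(64, 64), seed = 4),
                   random_affine(cfg2, c(64, 64), seed = 4))
  # uniform law: mean of many rotation draws near the range midpoint
  set.seed(10)
  rots <- replicate(10000, random_affine(cfg2, c(64, 64))$rotation)
  expect_lt(abs(mean(rots)), 0.3)
  expect_true(all(rots >= -10 & rots <= 10))
})

test_that("apply_affine is identity at identity and involutive at 180 degrees", {
  m <- matrix(runif(64) > 0.6, 8, 8)
  expect_identical(apply_affine(m, affine_params()), m)
  img <- array(runif(8 * 8 * 2), c(8, 8, 2))
  expect_equal(apply_affine(img, affine_params(), centre = c(4.5, 4.5)), img)
  # 180-degree rotation applied twice restores a centroid-symmetric mask
  sq <- matrix(FALSE, 11, 11); sq[3:7, 4:8] <- TRUE
  once <- apply_affine(sq, affine_params(rotation = 180))
  twice <- apply_affine(once, affine_params(rotation = 180))
  expect_identical(twice, sq)
  expect_equal(sum(once), sum(sq))
})

test_that("scaling changes mask area by the square of the factor", {
  m <- matrix(FALSE, 64, 64); m[29:36, 29:36] <- TRUE  # centered 8x8 square
  big <- apply_affine(m, affine_params(scale = 2))
  expect_lt(abs(sum(big) - 4 * sum(m)) / (4 * sum(m)), 0.05)
  small <- apply_affine(m, affine_params(scale = 0.5))
  expect_lt(abs(sum(small) - 0.25 * sum(m)) / (0.25 * sum(m)), 0.1)
})

test_that("a transform mapping the foreground out of bounds is flagged", {
  m <- matrix(FALSE, 8, 8); m[4, 4] <- TRUE
  expect_warning(out <- apply_affine(m, affine_params(translation = c(100, 0))),
                 "out of bounds")
  expect_true(isTRUE(attr(out, "empty")))
})

test_that("overlap counts query pixels outside the target region exactly", {
  target <- matrix(FALSE, 8, 8); target[2:5, 2:5] <- TRUE
  inside <- matrix(FALSE, 8, 8); inside[3:4, 3:4] <- TRUE
  expect_equal(overlap(inside, target), 0L)
  spill <- matrix(FALSE, 8, 8); spill[6:8, 1:4] <- TRUE  # 12 px, all outside
  expect_equal(overlap(spill, target), 12L)
  expect_error(overlap(matrix(FALSE, 3, 3), target), "same grid")
  set.seed(3)
  for (k in 1:20) {
    q <- matrix(runif(64) > 0.5, 8, 8)
    t <- matrix(runif(64) > 0.5, 8, 8)
    brute <- 0L
    for (i in 1:8) for (j in 1:8) if (q[i, j] && !t[i, j]) brute <- brute + 1L
    expect_identical(overlap(q, t), brute)
  }
})

test_that("oaa returns a perfect slot untouched and honors vacuous tolerance", {
  tax <- toy_taxonomy()
  lab <- matrix(0L, 16, 16); lab[5:9, 5:9] <- 1L; lab[12:14, 2:4] <- 3L
  src <- toy_sample(lab, "src"); tgt <- toy_sample(lab, "tgt")
  ident <- search_config(rotation_range = c(0, 0), scale_range = c(1, 1),
                         translation_range = c(0, 0), tau = 5)
  r <- oaa(src, tgt, 1, tax, ident, seed = 1)
  expect_equal(r$overlap, 0L)
  expect_true(r$converged)
  expect_equal(r$shift, c(0L, 0L))
  expect_identical(r$mask, extract_primary_mask(lab, tax, 1))
  # infinite tolerance: converged at the initial placement, no search
  free <- search_config(tau = Inf)
  r2 <- oaa(src, tgt, 1, tax, free, seed = 2)
  expect_true(r2$converged)
  expect_equal(r2$n_evaluated, 0L)
  expect_error(oaa(toy_sample(matrix(0L, 16, 16), "e"), tgt, 1, tax, ident),
               "absent from source")
})

test_that("greedy search matches the exhaustive shift-grid oracle", {
  tax <- toy_taxonomy()
  set.seed(21)
  for (k in 1:15) {
    n <- sample(16:24, 1)
    ls <- matrix(0L, n, n); lt <- matrix(0L, n, n)
    r0 <- sample(2:(n - 6), 1); c0 <- sample(2:(n - 6), 1)
    ls[r0:(r0 + 4), c0:(c0 + 4)] <- 1L
    r1 <- sample(2:(n - 6), 1); c1 <- sample(2:(n - 6), 1)
    lt[r1:(r1 + 3), c1:(c1 + 3)] <- 1L
    src <- toy_sample(ls, "s"); tgt <- toy_sample(lt, "t")
    cfg <- search_config(tau = 0, rotation_range = c(-15, 15),
                         scale_range = c(0.8, 1.2), translation_range = c(-3, 3),
                         shift_range = c(-4, 4), stepsize = 1, early_stop = FALSE)
    res <- oaa(src, tgt, 1, tax, cfg, seed = 300 + k)
    # independent oracle: transform once with the recorded params, then scan
    q <- apply_affine(extract_primary_mask(ls, tax, 1),
                      res$params, centre = res$centre)
    anti <- !extract_primary_mask(lt, tax, 1)
    oracle <- exhaustive_min_overlap(q, anti, -4:4)
    expect_identical(res$overlap, as.integer(oracle))
    # contract: never worse than the unshifted placement; bound on evaluations
    expect_lte(res$overlap, sum(q & anti))
    expect_lte(res$n_evaluated, 81L)
    expect_identical(res$converged, res$overlap < res$tau)
    # overlap is recomputable from the returned mask
    expect_identical(res$overlap, overlap(res$mask, extract_primary_mask(lt, tax, 1)))
  }
})

test_that("oaa transports labels and channels under one shared transform", {
  ds <- generate_dataset(2, small_phantom_config(), seed = 31)
  src <- ds$samples[[1]]; tgt <- ds$samples[[2]]
  res <- oaa(src, tgt, 2, ds$taxonomy, search_config(), seed = 77)
  # mask is exactly the nonzero support of the transported labels
  expect_identical(res$mask, res$labels > 0L)
  # labels: nearest-neighbor transform of the source's region-p labels + shift
  subs <- subregions_of(ds$taxonomy, 2)
  lab_p <- src$labels; lab_p[!(lab_p %in% subs)] <- 0L
  lab_ref <- prmixr:::shift_grid(
    apply_affine(lab_p, res$params, centre = res$centre, filter = "nearest"),
    res$shift)
  expect_identical(res$labels, lab_ref)
  # channels: bilinear transform of the full source image under the same
  # geometry, restricted to the mask — both channels move as a coupled unit
  img_ref <- prmixr:::shift_grid(
    apply_affine(src$image, res$params, centre = res$centre, filter = "bilinear"),
    res$shift)
  for (ch in 1:2) {
    expect_equal(res$image_patch[, , ch][res$mask], img_ref[, , ch][res$mask])
    expect_true(all(res$image_patch[, , ch][!res$mask] == 0))
  }
  # determinism: identical inputs and seed give a bit-identical result
  res2 <- oaa(src, tgt, 2, ds$taxonomy, search_config(), seed = 77)
  expect_identical(res, res2)
})
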