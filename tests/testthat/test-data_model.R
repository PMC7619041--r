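test_that("sample I/O round-trips bit-exactly through TIFF", {
  tax <- toy_taxonomy()
  set.seed(1)
  lab <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  img <- array(runif(8 * 8 * 2), c(8, 8, 2))
  s <- labeled_sample(img, lab, "rt", tax)
  d <- withr::local_tempdir()
  write_sample(s, file.path(d, "rt_img.tif"), file.path(d, "rt_lab.tif"))
  back <- load_sample(file.path(d, "rt_img.tif"), file.path(d, "rt_lab.tif"), tax)
  expect_identical(back$labels, s$labels)
  expect_lt(max(abs(back$image - s$image)), 1e-6)  # 32-bit float storage
  # label maps are bit-exact, including large values through 16-bit TIFF
  big <- matrix(c(0L, 117L, 9999L, 65535L), 2, 2)
  prmixr:::write_label_map(big, file.path(d, "big.tif"))
  expect_identical(prmixr:::read_label_map(file.path(d, "big.tif")), big)
})

test_that("images are rescaled to [0,1] by dtype maximum on load", {
  d <- withr::local_tempdir()
  # an 8-bit PNG holding the dtype maximum must load as intensity 1.0
  png::writePNG(matrix(c(0, 127, 255) / 255, 1, 3), file.path(d, "i.png"))
  img <- prmixr:::read_image_file(file.path(d, "i.png"))
  expect_equal(max(img), 1.0)
  expect_equal(dim(img)[3], 1L)  # single channel promoted to C = 1
})

test_that("validation rejects unknown labels and mismatched grids", {
  tax <- toy_taxonomy()
  lab <- matrix(c(1L, 999L, 0L, 2L), 2, 2)
  expect_error(labeled_sample(array(0.5, c(2, 2, 1)), lab, "bad", tax), "999")
  expect_error(
    labeled_sample(array(0.5, c(3, 2, 1)), matrix(0L, 2, 2)),
    "share the same grid")
  expect_error(labeled_sample(array(2, c(2, 2, 1)), matrix(0L, 2, 2)), "\\[0, 1\\]")
})

test_that("extract_primary_mask equals the union of subregion masks", {
  tax <- toy_taxonomy()
  lab <- matrix(c(1, 2, 0, 3,
                  2, 1, 3, 0,
                  0, 0, 1, 2,
                  3, 3, 0, 1), 4, 4, byrow = TRUE)
  s <- toy_sample(lab)
  m1 <- extract_primary_mask(s$labels, tax, 1)
  # brute-force union over the primary region's subregions
  oracle <- (s$labels == 1L) | (s$labels == 2L)
  expect_identical(m1, oracle)
  expect_identical(extract_primary_mask(s$labels, tax, 2), s$labels == 3L)
  # absent region and all-background map give all-false masks, not errors
  tax3 <- region_taxonomy(c(`1` = 1, `3` = 2, `7` = 3), c("A", "B", "C"))
  expect_false(any(extract_primary_mask(s$labels, tax3, 3)))
  expect_false(any(extract_primary_mask(matrix(0L, 3, 3), tax, 1)))
  expect_error(extract_primary_mask(s$labels, tax, 9), "unknown primary region")
})

test_that("primary masks plus background partition the grid", {
  set.seed(7)
  for (k in 1:5) {
    ph <- generate_phantom(small_phantom_config(dropout_prob = 0.2),
                           seed = 100 + k)
    total <- matrix(0L, nrow(ph$sample$labels), ncol(ph$sample$labels))
    for (p in seq_len(ph$taxonomy$P)) {
      total <- total + extract_primary_mask(ph$sample$labels, ph$taxonomy, p)
    }
    total <- total + (ph$sample$labels == 0L)
    expect_true(all(total == 1L))  # pairwise disjoint and covering
  }
})

test_that("primary masks are invariant to grouping-preserving relabeling", {
  tax_a <- region_taxonomy(c(`1` = 1, `2` = 1, `3` = 2), c("A", "B"))
  tax_b <- region_taxonomy(c(`10` = 1, `20` = 1, `30` = 2), c("A", "B"))
  lab <- matrix(c(1L, 2L, 3L, 0L), 2, 2)
  relab <- matrix(c(10L, 20L, 30L, 0L), 2, 2)
  for (p in 1:2) {
    expect_identical(extract_primary_mask(lab, tax_a, p),
                     extract_primary_mask(relab, tax_b, p))
  }
})

test_that("pad_to_common pads with background anchored top-left", {
  a <- toy_sample(matrix(1L, 2, 3), "a")
  b <- toy_sample(matrix(3L, 4, 2), "b")
  ps <- pad_to_common(a, b)
  expect_equal(dim(ps[[1]]$labels), c(4, 3))
  expect_identical(ps[[1]]$labels[1:2, 1:3], a$labels)
  expect_true(all(ps[[1]]$labels[3:4, ] == 0L))
  expect_true(all(ps[[2]]$labels[, 3] == 0L))
  expect_true(all(ps[[1]]$image[3:4, , ] == 0))
})

test_that("taxonomy invariants and JSON round trip hold", {
  tax <- default_taxonomy()
  expect_s3_class(tax, "region_taxonomy")
  expect_equal(tax$P, 11L)
  expect_equal(length(tax$subregion_to_primary), 118L)
  expect_setequal(tax$primary_names,
                  c("CB", "TH", "MB", "HB", "Isocortex", "HY", "OLF",
                    "CTXsp", "STR", "PAL", "HPF"))
  d <- withr::local_tempdir()
  write_taxonomy(tax, file.path(d, "t.json"))
  back <- read_taxonomy(file.path(d, "t.json"))
  expect_identical(back$subregion_to_primary, tax$subregion_to_primary)
  expect_identical(back$primary_names, tax$primary_names)
  # invalid taxonomies are rejected
  expect_error(region_taxonomy(c(`0` = 1), "A"), "background")
  expect_error(region_taxonomy(c(`1` = 1, `2` = 3), c("A", "B")), "1\\.\\.P")
})
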