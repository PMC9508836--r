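# Image encoding: quality-scaled intensities, one-hot geometry, channel
# assignment, PNG round-trip.

test_that("intensity is the capped quality product", {
  m <- intensity_model()
  expect_identical(pixel_intensity(40, 60, m), 255L)  # saturation
  expect_identical(pixel_intensity(0, 60, m), 0L)
  expect_identical(pixel_intensity(20, 30, m), 64L)   # round(255 * .5 * .5)
  expect_identical(pixel_intensity(80, 90, m), 255L)  # above caps
  expect_error(pixel_intensity(-1, 60, m), "non-negative")
  # monotone in both arguments over a grid
  grid <- expand.grid(bq = seq(0, 50, 5), mq = seq(0, 70, 7))
  v <- pixel_intensity(grid$bq, grid$mq, m)
  for (mq in unique(grid$mq)) {
    expect_true(all(diff(v[grid$mq == mq]) >= 0))
  }
  for (bq in unique(grid$bq)) {
    expect_true(all(diff(v[grid$bq == bq]) >= 0))
  }
})

test_that("single-read geometry: 4-pixel one-hot blocks anchored at 20", {
  r <- manual_read("r1", 80L, strrep("A", 41), qual = 40L, mapq = 60L)
  w <- manual_window(child_reads = list(r), pos0 = 100L)
  ch <- encode_member(w$reads$child, w$variant_position)
  expect_identical(dim(ch), c(160L, 164L))
  # an all-A read spanning the window lights column 4k+1 for k = 0..40
  expect_identical(which(ch[1, ] != 0), as.integer(4 * (0:40) + 1))
  expect_true(all(ch[1, 4 * (0:40) + 1] == 255L))
  expect_identical(sum(ch[-1, ]), 0L)
})

test_that("trio channels map to child/father/mother and the variant block", {
  fx <- small_fixture()
  i <- which(fx$simset$manifest$inheritance == "denovo" &
               fx$simset$manifest$variant_type == "substitution")[1]
  sim <- fx$simset$sims[[i]]
  img <- encode_trio(sim$window)
  expect_identical(dim(unclass(img)), c(160L, 164L, 3L))
  expect_true(all(img >= 0L & img <= 255L))
  # variant block is columns 81..84 (0-based block index 20)
  alt_col <- 4L * 20L + match(substr(sim$site$alt, 1, 1),
                              c("A", "C", "T", "G"))
  expect_gt(sum(img[, alt_col, 1] > 0), 0)          # child carries alt
  expect_identical(sum(img[, alt_col, 2] > 0), 0L)  # clean father
  expect_identical(sum(img[, alt_col, 3] > 0), 0L)  # clean mother

  # swapping parents swaps channels exactly
  w2 <- sim$window
  w2$reads <- list(child = w2$reads$child, father = w2$reads$mother,
                   mother = w2$reads$father)
  names(w2$reads) <- c("child", "father", "mother")
  img2 <- encode_trio(w2)
  expect_identical(img2[, , 2], img[, , 3])
  expect_identical(img2[, , 3], img[, , 2])
  expect_identical(img2[, , 1], img[, , 1])
})

test_that("one-hot invariant and determinism hold on random windows", {
  set.seed(77)
  ref <- synth_reference(2000L, seed = 77)
  for (trial in 1:6) {
    p <- sim_params(
      depth_mean = sample(5:40, 1),
      inheritance = sample(c("denovo", "inherited_father", "artifact"), 1),
      variant = list(type = sample(c("substitution", "insertion",
                                     "deletion"), 1), len = sample(1:2, 1))
    )
    s <- simulate_site(p, position = 600 + 100 * trial, reference = ref)
    img <- encode_trio(s$window)
    expect_identical(dim(unclass(img)), c(160L, 164L, 3L))
    # at most one lit pixel per (row, block, channel)
    for (k in 1:3) {
      blocks <- array(unclass(img)[, , k], dim = c(160, 4, 41))
      lit_per_block <- apply(blocks != 0, c(1, 3), sum)
      expect_true(all(lit_per_block <= 1))
    }
    expect_identical(encode_trio(s$window), img)
  }
})

test_that("row cap keeps the first 160 reads; empty windows encode to zero", {
  ref <- synth_reference(2000L, seed = 5)
  s <- simulate_site(sim_params(depth_mean = 500), reference = ref,
                     seed = 12)
  img <- encode_trio(s$window)
  occupied <- sum(rowSums(img[, , 1] != 0) > 0)
  expect_identical(occupied, 160L)
  s0 <- simulate_site(sim_params(depth_mean = 0), reference = ref,
                      seed = 13)
  expect_identical(sum(encode_trio(s0$window) != 0L), 0L)
})

test_that("read permutation permutes rows without changing content", {
  fx <- small_fixture()
  sim <- fx$simset$sims[[2]]
  img <- encode_trio(sim$window)
  w2 <- shuffle_reads(sim$window, seed = 4)
  img2 <- encode_trio(w2)
  for (k in 1:3) {
    a <- img[, , k]; b <- img2[, , k]
    expect_identical(a[order(apply(a, 1, paste, collapse = ",")), ],
                     b[order(apply(b, 1, paste, collapse = ",")), ])
  }
})

test_that("PNG export round-trips losslessly", {
  fx <- small_fixture()
  img <- encode_trio(fx$simset$sims[[1]]$window)
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, path)
  back <- read_image_png(path)
  expect_identical(back, array(unclass(img), dim = dim(img)))
  # all-zero image -> black PNG
  z <- array(0L, c(160L, 164L, 3L))
  write_image_png(structure(z, class = "dnm_image"), path)
  expect_identical(sum(read_image_png(path)), 0L)
})
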