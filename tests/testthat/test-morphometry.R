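test_that("load_image honors the normalization contract for 8- and 16-bit files", {
  d <- withr::local_tempdir()
  p8 <- file.path(d, "white.png")
  png::writePNG(matrix(1, 4, 4), p8)
  img8 <- load_image(p8)
  expect_equal(unclass(img8), matrix(1, 4, 4), ignore_attr = TRUE)
  expect_identical(attr(img8, "source_bit_depth"), 8L)

  p16 <- file.path(d, "mid.tif")
  tiff::writeTIFF(matrix(32768 / 65535, 3, 5), p16, bits.per.sample = 16)
  img16 <- load_image(p16)
  expect_equal(unclass(img16)[1, 1], 32768 / 65535, tolerance = 1e-12)
  expect_identical(attr(img16, "source_bit_depth"), 16L)
  expect_identical(dim(img16), c(3L, 5L))
})

test_that("load_image errors on multi-channel input without a channel index", {
  d <- withr::local_tempdir()
  prgb <- file.path(d, "rgb.png")
  png::writePNG(array(runif(4 * 4 * 3), c(4, 4, 3)), prgb)
  expect_error(load_image(prgb), "channel required")
  expect_silent(load_image(prgb, channel = 2L))
  expect_error(load_image(file.path(d, "nope.png")), "nope\\.png")
})

test_that("top-hat removes constants and sub-element peaks exactly", {
  expect_equal(tophat(matrix(0.37, 12, 12), radius = 3),
               matrix(0, 12, 12))
  img <- matrix(0.2, 15, 15)
  img[8, 8] <- 0.9
  th <- tophat(img, radius = 2)
  expect_equal(th[8, 8], 0.7, tolerance = 1e-12)
  expect_equal(max(th[-(8 + 7 * 15)]), 0, tolerance = 1e-12)
  expect_error(tophat(img, radius = 0), "radius")
})

test_that("top-hat suppresses a ramp while keeping a narrow line, matching the brute-force opening", {
  rl <- ramp_line_image()
  th <- tophat(rl$img, radius = 5)
  oracle <- tophat_bruteforce(rl$img, radius = 5L)
  expect_equal(th, oracle, tolerance = 1e-10)
  excl <- unique(as.integer(outer(rl$line_rows, -2:2, "+")))
  off_line <- th[setdiff(seq_len(nrow(th)), excl), ]
  expect_lt(max(off_line), 0.02)
  expect_gte(min(th[rl$line_rows, ]), 0.45)
})

test_that("Otsu binarization separates a two-mode ROI and is idempotent on binary input", {
  img <- matrix(c(rep(0.2, 60), rep(0.8, 40)), 10, 10)
  roi <- matrix(TRUE, 10, 10)
  net <- binarize_otsu(img, roi)
  t_star <- attr(net, "threshold")
  expect_gt(t_star, 0.2)
  expect_lt(t_star, 0.8)
  expect_identical(as_mat(net), unclass(img) == 0.8)

  bin <- matrix(as.numeric(runif(100) > 0.5), 10, 10)
  net2 <- binarize_otsu(bin, roi)
  expect_identical(as_mat(net2), bin == 1)
})

test_that("constant ROI yields empty foreground with a warning", {
  img <- matrix(0.5, 8, 8)
  roi <- matrix(TRUE, 8, 8)
  expect_warning(net <- binarize_otsu(img, roi), "degenerate")
  expect_false(any(net))
})

test_that("Otsu threshold is computed within the ROI only", {
  img <- matrix(0.9, 16, 16)       # bright rim outside ROI
  roi <- matrix(FALSE, 16, 16)
  roi[5:12, 5:12] <- TRUE
  img[roi] <- rep(c(0.1, 0.4), each = 32)
  net <- binarize_otsu(img, roi)
  expect_true(attr(net, "threshold") < 0.4)  # rim cannot push it above
  expect_identical(as_mat(net), roi & unclass(img) == 0.4)
})

test_that("apply_mask is an AND with exact count semantics", {
  withr::with_seed(5, {
    net <- matrix(runif(100) < 0.3, 10, 10)
  })
  all_true <- matrix(TRUE, 10, 10)
  expect_identical(apply_mask(net, all_true), net)
  expect_false(any(apply_mask(net, !all_true)))
  mask <- matrix(FALSE, 10, 10)
  mask[1:5, ] <- TRUE
  expect_identical(sum(apply_mask(net, mask)), sum(net & mask))
  expect_error(apply_mask(net, matrix(TRUE, 9, 10)), "shape")
})

test_that("skeletonize leaves 1-px lines unchanged and thins a 3-wide bar to its midline", {
  line <- matrix(FALSE, 5, 24)
  line[3, 3:22] <- TRUE
  expect_identical(skeletonize(line), line)

  expect_identical(skeletonize(matrix(FALSE, 6, 6)), matrix(FALSE, 6, 6))

  bar <- matrix(FALSE, 9, 15)
  bar[4:6, 4:12] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(bar[sk]))
  hits <- which(sk, arr.ind = TRUE)
  expect_gte(nrow(hits), 7)   # within +/-2 px of the 9-px bar length
  expect_lte(nrow(hits), 11)
  interior <- hits[hits[, 2] > 4 & hits[, 2] < 12, , drop = FALSE]
  expect_true(all(interior[, 1] == 5))  # midline row except possibly ends
})

test_that("skeletonization preserves the number of 8-connected components", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      x <- matrix(runif(900) < 0.35, 30, 30)
    })
    x <- EBImage::imageData(EBImage::dilate(EBImage::Image(x * 1),
                                            EBImage::makeBrush(3, "box"))) > 0
    sk <- skeletonize(x)
    expect_true(all(x[sk]))
    expect_identical(attr(label_components(sk), "n_components"),
                     attr(label_components(x), "n_components"))
  }
})

test_that("branch points: lines have none, junction pixels are detected", {
  line <- matrix(FALSE, 5, 9)
  line[3, 2:8] <- TRUE
  expect_identical(nrow(branch_points(line)), 0L)

  plus <- matrix(FALSE, 9, 9)
  plus[5, 2:8] <- TRUE
  plus[2:8, 5] <- TRUE
  bp <- branch_points(plus)
  expect_identical(bp, branch_points_bruteforce(plus))
  expect_true(any(bp$row == 5 & bp$col == 5))       # crossing center, 4 neighbors
  expect_identical(nrow(branch_points(plus, merge = TRUE)), 1L)

  tee <- matrix(FALSE, 9, 9)
  tee[5, 2:8] <- TRUE
  tee[6:9, 5] <- TRUE
  bpt <- branch_points(tee)
  expect_identical(bpt, branch_points_bruteforce(tee))
  expect_true(any(bpt$row == 5 & bpt$col == 5))     # the junction pixel
  expect_identical(nrow(branch_points(tee, merge = TRUE)), 1L)
})

test_that("quantify_image composes the stages and respects the containment chain", {
  sp <- small_spec(rng_seed = 31L)
  sim <- simulate_network(sp)
  img <- render_network(sim$segments, sp,
                        render_spec(psf_sigma = 0, background_amplitude = 0,
                                    noise_gaussian_sigma = 0,
                                    noise_poisson_scale = 0))
  q <- quantify_image(img, sim$roi, tophat_radius = 8L)
  expect_true(all(sim$roi[q$binary]))
  expect_true(all(q$binary[q$skeleton]))
  if (nrow(q$branch_points)) {
    expect_true(all(q$skeleton[cbind(q$branch_points$row, q$branch_points$col)]))
  }
  # noise-free recovery: skeleton pixel count close to true length
  true_len <- sim$truth$true_skeleton_length_px[["total"]]
  expect_gt(sum(q$skeleton), 0.6 * true_len)
  expect_lt(sum(q$skeleton), 1.1 * true_len)
})

test_that("a smooth background field barely perturbs the binarized network", {
  sp <- small_spec(rng_seed = 32L)
  sim <- simulate_network(sp)
  clean <- render_network(sim$segments, sp,
                          render_spec(psf_sigma = 0.8, background_amplitude = 0,
                                      noise_gaussian_sigma = 0,
                                      noise_poisson_scale = 0))
  shaded <- render_network(sim$segments, sp,
                           render_spec(psf_sigma = 0.8,
                                       background_amplitude = 0.3,
                                       noise_gaussian_sigma = 0,
                                       noise_poisson_scale = 0))
  q0 <- quantify_image(clean, sim$roi, tophat_radius = 8L)
  q1 <- quantify_image(shaded, sim$roi, tophat_radius = 8L)
  differing <- sum(q0$binary != q1$binary)
  expect_lt(differing / sum(sim$roi), 0.02)
})

test_that("an all-zero image produces empty outputs and a warning", {
  img <- matrix(0, 32, 32)
  roi <- matrix(TRUE, 32, 32)
  expect_warning(expect_warning(q <- quantify_image(img, roi, tophat_radius = 3L)))
  expect_false(any(q$binary))
  expect_false(any(q$skeleton))
  expect_identical(nrow(q$branch_points), 0L)
})

test_that("binarization is invariant to intensity rescaling of a two-mode image", {
  sp <- small_spec(rng_seed = 33L)
  sim <- simulate_network(sp)
  img <- render_network(sim$segments, sp,
                        render_spec(psf_sigma = 0, background_amplitude = 0,
                                    noise_gaussian_sigma = 0,
                                    noise_poisson_scale = 0))
  base_net <- binarize_otsu(unclass(img), sim$roi)
  for (s in c(0.5, 0.7, 0.9)) {
    net_s <- binarize_otsu(unclass(img) * s, sim$roi)
    expect_identical(as_mat(net_s), as_mat(base_net))
  }
})

test_that("skeleton and branch points are translation-equivariant", {
  sp <- small_spec(rng_seed = 34L)
  sim <- simulate_network(sp)
  img <- render_network(sim$segments, sp,
                        render_spec(psf_sigma = 0.8, background_amplitude = 0,
                                    noise_gaussian_sigma = 0,
                                    noise_poisson_scale = 0))
  # embed with a margin wider than the structuring element so the disk
  # never touches the canvas border (interior-safe instance)
  margin <- 16L
  dy <- 7L; dx <- 5L
  nr <- nrow(img) + 2L * margin + dy
  nc <- ncol(img) + 2L * margin + dx
  embed <- function(m, oy, ox, fill = 0) {
    out <- matrix(fill, nr, nc)
    out[oy + seq_len(nrow(m)), ox + seq_len(ncol(m))] <- m
    out
  }
  img1 <- embed(unclass(img), margin, margin)
  roi1 <- embed(sim$roi, margin, margin, FALSE) > 0
  img2 <- embed(unclass(img), margin + dy, margin + dx)
  roi2 <- embed(sim$roi, margin + dy, margin + dx, FALSE) > 0
  q1 <- quantify_image(img1, roi1, tophat_radius = 8L)
  q2 <- quantify_image(img2, roi2, tophat_radius = 8L)
  sk1_shifted <- embed(q1$skeleton[margin + seq_len(nrow(img)),
                                   margin + seq_len(ncol(img))],
                       margin + dy, margin + dx, FALSE) > 0
  expect_identical(unclass(q2$skeleton), sk1_shifted)
  expect_identical(q2$branch_points$row, q1$branch_points$row + dy)
  expect_identical(q2$branch_points$col, q1$branch_points$col + dx)
})
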