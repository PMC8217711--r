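# Independent brute-force oracles used against the vectorized
# implementations, plus small shared fixtures.

# Exhaustive between-class-variance maximization: plain loop over all
# candidate thresholds (upper edges of bins 1..n_bins-1), smallest argmax.
otsu_bruteforce <- function(values, n_bins = 256L) {
  bin <- pmin(floor(values * n_bins) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  if (sum(h > 0) < 2L) return(NA_real_)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  total <- sum(h)
  best_k <- NA_integer_
  best <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(h[1:k]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:k] * centers[1:k]) / n0
    mu1 <- sum(h[(k + 1):n_bins] * centers[(k + 1):n_bins]) / n1
    s <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    if (s > best) {  # strict improvement keeps the smallest argmax
      best <- s
      best_k <- k
    }
  }
  best_k / n_bins
}

# Per-pixel loop counting TRUE 8-neighbors; the oracle for branch_points.
branch_points_bruteforce <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  out <- NULL
  for (c in seq_len(nc)) {    # column-major, the order which() reports
    for (r in seq_len(nr)) {
      if (!sk[r, c]) next
      cnt <- 0L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && sk[rr, cc]) {
          cnt <- cnt + 1L
        }
      }
      if (cnt >= 3L) out <- rbind(out, c(r, c))
    }
  }
  if (is.null(out)) {
    data.frame(row = integer(0), col = integer(0))
  } else {
    data.frame(row = as.integer(out[, 1]), col = as.integer(out[, 2]))
  }
}

# Brute-force flat-disk grayscale opening (erosion then dilation), looped
# over structuring-element offsets; the oracle for tophat().
tophat_bruteforce <- function(img, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  d <- EBImage::makeBrush(2L * radius + 1L, "disc")
  offs <- offs[d[cbind(offs$dr + radius + 1L, offs$dc + radius + 1L)] > 0, ]
  nr <- nrow(img); nc <- ncol(img)
  minmax_filter <- function(x, f, init) {
    out <- matrix(init, nr, nc)
    for (i in seq_len(nrow(offs))) {
      dr <- offs$dr[i]; dc <- offs$dc[i]
      shifted <- matrix(init, nr, nc)
      r_src <- max(1, 1 + dr):min(nr, nr + dr)
      c_src <- max(1, 1 + dc):min(nc, nc + dc)
      shifted[r_src - dr, c_src - dc] <- x[r_src, c_src]
      out <- f(out, shifted)
    }
    out
  }
  er <- minmax_filter(img, pmin, Inf)
  op <- minmax_filter(er, pmax, -Inf)
  img - op
}

# The ramp-plus-line instance: linear background ramp 0 -> 0.4 across
# columns plus a 2-px-wide bright line at 0.9.
ramp_line_image <- function(nr = 60L, nc = 160L, line_rows = c(30L, 31L)) {
  img <- matrix(rep(seq(0, 0.4, length.out = nc), each = nr), nr, nc)
  img[line_rows, ] <- 0.9
  list(img = img, line_rows = line_rows)
}

# Small fast network spec for simulation-heavy tests; any field can be
# overridden through ...
small_spec <- function(...) {
  args <- list(domain_shape = c(128L, 128L), step_length = 6,
               crossing_trees = 4L, branch_rate = 0.05,
               step_survival = 0.99, angle_sigma = 0.2, fiber_width = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(network_spec, args)
}

# strip non-dim attributes for exact matrix comparison
as_mat <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# Random thinned masks for oracle suites.
random_skeleton <- function(seed, nr = 32L, nc = 32L, p = 0.35) {
  withr::with_seed(seed, {
    x <- matrix(stats::runif(nr * nc) < p, nr, nc)
    x <- EBImage::imageData(EBImage::dilate(EBImage::Image(x * 1),
                                            EBImage::makeBrush(3, "box"))) > 0
  })
  skeletonize(x)
}
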