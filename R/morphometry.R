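#' Morphological top-hat filtering
#'
#' Subtracts the grayscale opening of the image by a flat disk from the
#' image itself. Structures narrower than the disk (bright fibers) survive;
#' smooth background broader than the disk is suppressed toward zero. This
#' is the first stage of the whole-mount quantification pipeline, applied
#' to the GFP channel before thresholding.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param radius Disk radius in pixels (>= 1). The disk must be larger than
#'   the fibers to preserve them; the default used for cohort fixtures is
#'   15 px, roughly three times the fiber-width estimate.
#' @return Numeric matrix, same shape, nonnegative.
#' @export
tophat <- function(img, radius = 15L) {
  if (radius < 1) stop("tophat radius must be >= 1")
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(unclass(img)), kern))
  pmax(matrix(out, nrow(img), ncol(img)), 0)
}

#' Otsu threshold of intensities
#'
#' Histogram the values over `n_bins` equal-width bins on \[0, 1\] and pick
#' the threshold maximizing the between-class variance
#' \eqn{\sigma^2_B(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2}. Candidate
#' thresholds are the upper edges of bins 1..n_bins-1; ties are broken to
#' the smallest maximizing threshold.
#'
#' @param values Numeric vector of intensities in \[0, 1\].
#' @param n_bins Number of histogram bins (default 256, the classical
#'   formulation regardless of source bit depth).
#' @return The threshold on the \[0, 1\] intensity scale, or `NA` when the
#'   histogram is degenerate (all mass in a single bin).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  n_bins <- as.integer(n_bins)
  bin <- pmin(floor(values * n_bins) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  if (sum(h > 0) < 2L) return(NA_real_)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(h)
  s0 <- cumsum(h * centers)
  tot <- w0[n_bins]
  stot <- s0[n_bins]
  k <- seq_len(n_bins - 1L)
  w1 <- tot - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  mu0 <- s0[k][valid] / w0[k][valid]
  mu1 <- (stot - s0[k][valid]) / w1[valid]
  sigma_b[valid] <- (w0[k][valid] / tot) * (w1[valid] / tot) * (mu0 - mu1)^2
  k_star <- which.max(sigma_b)  # first maximum = smallest threshold
  k_star / n_bins
}

#' Automatic binarization within a region of interest
#'
#' Computes the Otsu threshold from the intensity histogram restricted to
#' the ROI (so background outside the tissue cannot bias it), then marks as
#' foreground every ROI pixel with intensity strictly greater than the
#' threshold. Pixels outside the ROI are always background.
#'
#' A constant (or single-bin) ROI histogram is degenerate: the result is an
#' empty foreground with a warning, since a blank image is a valid if
#' useless observation.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param roi Logical matrix, same shape, with at least one `TRUE` pixel.
#' @param n_bins Histogram bins passed to [otsu_threshold()].
#' @return Logical foreground matrix with attribute `threshold`.
#' @export
binarize_otsu <- function(img, roi, n_bins = 256L) {
  stopifnot(all(dim(img) == dim(roi)))
  if (!any(roi)) stop("ROI is empty")
  t_star <- otsu_threshold(unclass(img)[roi], n_bins = n_bins)
  if (is.na(t_star)) {
    warning("degenerate ROI histogram (constant intensity): empty foreground")
    net <- matrix(FALSE, nrow(img), ncol(img))
  } else {
    net <- roi & (unclass(img) > t_star)
  }
  attr(net, "threshold") <- t_star
  net
}

#' Apply a region-of-interest mask to a binary network
#'
#' Pixelwise AND; the foreground count never increases.
#'
#' @param net Logical foreground matrix.
#' @param roi Logical ROI matrix, same shape.
#' @return Logical matrix.
#' @export
apply_mask <- function(net, roi) {
  if (!all(dim(net) == dim(roi))) stop("mask shape mismatch")
  unclass(net) & unclass(roi)
}

# 8-neighborhood planes of the interior of a zero-padded matrix, in the
# P2..P9 clockwise order (N, NE, E, SE, S, SW, W, NW).
.neighbor_planes <- function(pad) {
  nr <- nrow(pad); nc <- ncol(pad)
  i <- 2:(nr - 1L); j <- 2:(nc - 1L)
  list(
    p2 = pad[i - 1L, j], p3 = pad[i - 1L, j + 1L],
    p4 = pad[i, j + 1L], p5 = pad[i + 1L, j + 1L],
    p6 = pad[i + 1L, j], p7 = pad[i + 1L, j - 1L],
    p8 = pad[i, j - 1L], p9 = pad[i - 1L, j - 1L]
  )
}

.pad_false <- function(m) {
  out <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  out
}

#' Skeletonize a binary network by homotopic thinning
#'
#' Two-subiteration Guo-Hall thinning, iterated to convergence: the result
#' is a one-pixel-wide, 8-connected trace that preserves the number of
#' connected components of the input. No spur pruning is applied.
#'
#' @param net Logical foreground matrix.
#' @return Logical skeleton matrix (subset of `net`).
#' @export
skeletonize <- function(net) {
  m <- unclass(net) > 0
  attributes(m) <- list(dim = dim(m))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      pad <- .pad_false(m)
      nb <- .neighbor_planes(pad)
      C <-(!nb$p2 & (nb$p3 | nb$p4)) + (!nb$p4 & (nb$p5 | nb$p6)) +
           (!nb$p6 & (nb$p7 | nb$p8)) + (!nb$p8 & (nb$p9 | nb$p2))
      n1 <- (nb$p9 | nb$p2) + (nb$p3 | nb$p4) + (nb$p5 | nb$p6) + (nb$p7 | nb$p8)
      n2 <- (nb$p2 | nb$p3) + (nb$p4 | nb$p5) + (nb$p6 | nb$p7) + (nb$p8 | nb$p9)
      nmin <- pmin(n1, n2)
      m_cond <- if (sub == 1L) {
        (nb$p6 | nb$p7 | !nb$p9) & nb$p8
      } else {
        (nb$p2 | nb$p3 | !nb$p5) & nb$p4
      }
      del <- m & (C == 1) & (nmin >= 2) & (nmin <= 3) & !m_cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Count skeleton neighbors of every pixel
#'
#' @param sk Logical skeleton matrix.
#' @return Integer matrix: for each pixel, the number of `TRUE` pixels
#'   among its 8 neighbors.
#' @export
neighbor_counts <- function(sk) {
  pad <- .pad_false(unclass(sk) > 0)
  nb <- .neighbor_planes(pad)
  Reduce(`+`, lapply(nb, as.integer))
}

#' Detect branch points of a skeleton
#'
#' A branch point is a skeleton pixel with three or more skeleton-true
#' neighbors in its 8-neighborhood. Adjacent qualifying pixels each count
#' as separate branch points unless `merge = TRUE`, which collapses
#' 8-connected clusters of qualifying pixels to one representative each.
#'
#' @param sk Logical skeleton matrix (one pixel wide).
#' @param merge Collapse adjacent branch pixels into single junctions.
#' @return A data frame with integer columns `row`, `col` (1-based).
#' @export
branch_points <- function(sk, merge = FALSE) {
  counts <- neighbor_counts(sk)
  bp <- (unclass(sk) > 0) & (counts >= 3L)
  if (merge && any(bp)) {
    lab <- label_components(bp)
    idx <- which(bp, arr.ind = TRUE)
    labs <- lab[idx]
    keep <- !duplicated(labs)
    idx <- idx[keep, , drop = FALSE]
  } else {
    idx <- which(bp, arr.ind = TRUE)
  }
  data.frame(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]))
}

#' Run the full morphometry pipeline on one image
#'
#' Deterministic composition of the whole-mount quantification stages, in
#' order: top-hat enhancement, Otsu binarization within the ROI, ROI
#' masking, homotopic skeletonization, branch-point detection. All
#' intermediate products are returned for audit.
#'
#' @param img Numeric matrix in \[0, 1\] (the GFP channel).
#' @param roi Logical ROI matrix, same shape.
#' @param tophat_radius Disk radius for [tophat()].
#' @param n_bins Histogram bins for [binarize_otsu()].
#' @param merge_branch_points Passed to [branch_points()].
#' @return A list with elements `tophat`, `binary`, `skeleton`,
#'   `branch_points` (data frame), and `threshold`.
#' @export
quantify_image <- function(img, roi, tophat_radius = 15L, n_bins = 256L,
                           merge_branch_points = FALSE) {
  stopifnot(all(dim(img) == dim(roi)))
  th <- tophat(img, radius = tophat_radius)
  net <- binarize_otsu(th, roi, n_bins = n_bins)
  t_star <- attr(net, "threshold")
  net <- apply_mask(net, roi)
  sk <- skeletonize(net)
  bp <- branch_points(sk, merge = merge_branch_points)
  if (!any(net)) {
    warning("empty network after binarization")
  }
  list(tophat = th, binary = net, skeleton = sk, branch_points = bp,
       threshold = t_star)
}

#' Label 8-connected components of a binary matrix
#'
#' Flood-fill labelling under 8-connectivity (the connectivity convention
#' of the skeleton). Used by tests and the simulator's ground-truth checks.
#'
#' @param m Logical matrix.
#' @return Integer matrix of component labels (0 = background), with
#'   attribute `n_components`.
#' @export
label_components <- function(m) {
  m <- unclass(m) > 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  idx <- which(m)
  n <- 0L
  off <- c(-1L - nr, -nr, 1L - nr, -1L, 1L, nr - 1L, nr, nr + 1L)
  for (start in idx) {
    if (lab[start] != 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      cands <- p + off
      # drop wrap-arounds at matrix edges
      keep <- rep(TRUE, 8L)
      if (r == 1L) keep[c(1L, 4L, 6L)] <- FALSE
      if (r == nr) keep[c(3L, 5L, 8L)] <- FALSE
      cands <- cands[keep]
      cands <- cands[cands >= 1L & cands <= nr * nc]
      cands <- cands[m[cands] & lab[cands] == 0L]
      if (length(cands)) {
        lab[cands] <- n
        queue <- c(queue, cands)
      }
    }
  }
  attr(lab, "n_components") <- n
  lab
}
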