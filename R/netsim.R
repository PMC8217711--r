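#' Default ventricular-septum-like ROI polygon
#'
#' A convex-ish polygon, wide at the basal (top) edge and tapering toward
#' the apex, mimicking the opened left-ventricular septum exposed in a
#' whole-mount preparation. Vertices are (row, col) pixel coordinates.
#'
#' @param domain_shape Integer vector `c(height, width)`.
#' @return Two-column matrix of polygon vertices (row, col).
#' @export
default_roi_polygon <- function(domain_shape = c(256L, 256L)) {
  h <- domain_shape[1]; w <- domain_shape[2]
  rbind(
    c(0.04 * h, 0.16 * w), c(0.04 * h, 0.84 * w),
    c(0.45 * h, 0.92 * w), c(0.88 * h, 0.64 * w),
    c(0.96 * h, 0.50 * w), c(0.88 * h, 0.36 * w),
    c(0.45 * h, 0.08 * w)
  )
}

.shoelace_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- nrow(poly)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Rasterize a polygon into a logical mask
#'
#' Pixel centers (integer row/col coordinates) inside or on the polygon
#' are `TRUE`.
#'
#' @param poly Two-column matrix of (row, col) vertices.
#' @param shape `c(height, width)` in pixels.
#' @return Logical matrix.
#' @export
polygon_mask <- function(poly, shape) {
  if (.shoelace_area(poly) == 0) stop("degenerate ROI polygon (zero area)")
  key <- paste(c(shape, signif(as.numeric(poly), 10)), collapse = ",")
  cached <- .polygon_cache[[key]]
  if (!is.null(cached)) return(cached)
  rr <- rep(seq_len(shape[1]), times = shape[2])
  cc <- rep(seq_len(shape[2]), each = shape[1])
  inside <- pracma::inpolygon(cc, rr, poly[, 2], poly[, 1], boundary = TRUE)
  out <- matrix(inside, shape[1], shape[2])
  if (length(.polygon_cache) < 32L) .polygon_cache[[key]] <- out
  out
}

# rasterized-ROI memo; the same polygon recurs for every heart of a cohort
.polygon_cache <- new.env(parent = emptyenv())

#' Specification of a synthetic Purkinje-like branching network
#'
#' Parameters of the seeded stochastic branching walk that generates
#' ground-truth fiber networks. Trees grow from the basal (top) edge of
#' the ROI toward the apex; at every step a tip advances by roughly
#' `step_length` pixels with its heading jittered by `angle_sigma`,
#' bifurcates with probability `branch_rate` times the local band
#' multiplier, and survives the step with probability `step_survival`
#' times the band multiplier. Several independent interleaved trees
#' (`crossing_trees`) model the intercrossing of fibers seen in
#' whole-mount images.
#'
#' @param domain_shape `c(height, width)` in pixels.
#' @param roi_polygon (row, col) vertex matrix; default a septum-like
#'   polygon from [default_roi_polygon()].
#' @param trunk_origin `c(row, col)` seed point on the basal edge, or
#'   `NULL` to place it at the middle of the top ROI rows.
#' @param step_length Mean segment length, px.
#' @param angle_sigma Heading jitter per step, radians.
#' @param branch_rate Bifurcation probability per step, in \[0, 1\].
#' @param crossing_trees Number of independent interleaved trees.
#' @param region_multipliers List with numeric length-3 elements `branch`
#'   and `survival`: per-band (base, mid, apex) multiplicative factors on
#'   `branch_rate` and on `step_survival`. All must be positive.
#' @param step_survival Base per-step survival probability.
#' @param fiber_width Rasterized fiber width, px (>= 1).
#' @param max_segments Cap on generated segments (guards runaway growth).
#' @param rng_seed Integer seed; identical spec + seed gives identical
#'   output.
#' @return A validated list of class `network_spec`.
#' @export
network_spec <- function(domain_shape = c(384L, 384L),
                         roi_polygon = default_roi_polygon(domain_shape),
                         trunk_origin = NULL,
                         step_length = 9, angle_sigma = 0.16,
                         branch_rate = 0.04, crossing_trees = 12L,
                         region_multipliers = list(branch = c(1, 1, 1),
                                                   survival = c(1, 1, 1)),
                         step_survival = 0.995, fiber_width = 2,
                         max_segments = 4000L, rng_seed = 1L) {
  if (is.numeric(region_multipliers)) {
    region_multipliers <- list(branch = region_multipliers,
                               survival = c(1, 1, 1))
  }
  stopifnot(
    length(domain_shape) == 2L, all(domain_shape >= 8),
    is.matrix(roi_polygon), ncol(roi_polygon) == 2L, nrow(roi_polygon) >= 3L,
    step_length > 0, angle_sigma >= 0,
    branch_rate >= 0, branch_rate <= 1,
    crossing_trees >= 1L,
    length(region_multipliers$branch) == 3L,
    length(region_multipliers$survival) == 3L,
    all(region_multipliers$branch > 0), all(region_multipliers$survival > 0),
    step_survival > 0, step_survival <= 1,
    fiber_width >= 1, max_segments >= 1L
  )
  structure(list(
    domain_shape = as.integer(domain_shape), roi_polygon = roi_polygon,
    trunk_origin = trunk_origin, step_length = step_length,
    angle_sigma = angle_sigma, branch_rate = branch_rate,
    crossing_trees = as.integer(crossing_trees),
    region_multipliers = region_multipliers, step_survival = step_survival,
    fiber_width = fiber_width, max_segments = as.integer(max_segments),
    rng_seed = as.integer(rng_seed)
  ), class = "network_spec")
}

#' Rendering parameters for synthetic fluorescence images
#'
#' The camera model: rasterized fibers of constant emission are convolved
#' with a Gaussian point-spread function, summed with a smooth
#' low-frequency background field (uneven illumination / tissue
#' autofluorescence), corrupted with Poisson photon noise then Gaussian
#' read noise, clipped and quantized to the sensor bit depth. The
#' background field is a fixed smooth function scaled to
#' `background_amplitude`, so the noise-free expectation of an image
#' depends only on the segments, not on the seed.
#'
#' @param psf_sigma Gaussian blur scale, px (>= 0; 0 disables).
#' @param background_amplitude Peak background intensity relative to full
#'   scale.
#' @param noise_gaussian_sigma Additive read-noise standard deviation.
#' @param noise_poisson_scale Photon count at full scale (0 disables shot
#'   noise).
#' @param signal_amplitude Fiber emission intensity before blur.
#' @param bit_depth 8 or 16.
#' @param rng_seed Integer seed for the noise draws.
#' @return A validated list of class `render_spec`.
#' @export
render_spec <- function(psf_sigma = 0.8, background_amplitude = 0.15,
                        noise_gaussian_sigma = 0.01,
                        noise_poisson_scale = 200,
                        signal_amplitude = 0.55,
                        bit_depth = 16L, rng_seed = 1L) {
  stopifnot(psf_sigma >= 0, background_amplitude >= 0,
            noise_gaussian_sigma >= 0, noise_poisson_scale >= 0,
            signal_amplitude > 0, bit_depth %in% c(8L, 16L))
  structure(list(
    psf_sigma = psf_sigma, background_amplitude = background_amplitude,
    noise_gaussian_sigma = noise_gaussian_sigma,
    noise_poisson_scale = noise_poisson_scale,
    signal_amplitude = signal_amplitude,
    bit_depth = as.integer(bit_depth), rng_seed = as.integer(rng_seed)
  ), class = "render_spec")
}

# Deterministic smooth low-frequency illumination field, peak-normalized.
.background_field <- function(shape) {
  y <- (seq_len(shape[1]) - 1) / (shape[1] - 1)
  x <- (seq_len(shape[2]) - 1) / (shape[2] - 1)
  Y <- matrix(y, shape[1], shape[2])
  X <- matrix(x, shape[1], shape[2], byrow = TRUE)
  f <- 0.6 * exp(-((X - 0.35)^2 + (Y - 0.30)^2) / (2 * 0.35^2)) +
       0.4 * (1 - 0.7 * Y) + 0.2 * X
  f / max(f)
}

#' Grow a synthetic branching network
#'
#' Runs the seeded branching walk of a [network_spec()] and returns the
#' generated segments together with exact ground-truth tallies: skeleton
#' length, branch-event count, rasterized foreground area and ROI area,
#' each per base/mid/apex band and in total. Bands follow the same
#' equal-extent row partition as [partition_regions()].
#'
#' @param spec A [network_spec()].
#' @return A list with elements `segments` (data frame `r0,c0,r1,c1`),
#'   `truth` (list of per-band tallies, each a named vector
#'   `base, mid, apex, total`), `roi` (logical mask), `labels` (band
#'   labels), and `branch_events` (data frame of bifurcation coordinates).
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  H <- spec$domain_shape[1]; W <- spec$domain_shape[2]
  roi <- polygon_mask(spec$roi_polygon, spec$domain_shape)
  if (!any(roi)) stop("degenerate ROI polygon (empty mask)")
  labels <- partition_regions(roi, axis = "row", n_regions = 3L)
  rows_in <- which(rowSums(roi) > 0)
  lo <- min(rows_in); hi <- max(rows_in)

  inside <- function(r, c) {
    ri <- round(r); ci <- round(c)
    ri >= 1 && ri <= H && ci >= 1 && ci <= W && roi[ri, ci]
  }
  if (!is.null(spec$trunk_origin) &&
      !inside(spec$trunk_origin[1], spec$trunk_origin[2])) {
    stop("trunk origin lies outside the ROI")
  }

  bmul <- spec$region_multipliers$branch
  smul <- spec$region_multipliers$survival

  segs <- vector("list", 512L)
  n_seg <- 0L
  ev_r <- numeric(0); ev_c <- numeric(0)

  withr::with_seed(spec$rng_seed, {
    # tree origins: spread across the basal edge of the ROI
    top_cols <- which(colSums(roi[lo:min(lo + 2L, H), , drop = FALSE]) > 0)
    for (tree in seq_len(spec$crossing_trees)) {
      if (tree == 1L && !is.null(spec$trunk_origin)) {
        org <- c(spec$trunk_origin[1], spec$trunk_origin[2])
      } else {
        q <- (tree - 0.5) / spec$crossing_trees
        c0 <- stats::quantile(top_cols, q, names = FALSE) +
          stats::rnorm(1, 0, 2)
        c0 <- min(max(c0, min(top_cols)), max(top_cols))
        org <- c(lo, c0)
      }
      if (!inside(org[1], org[2])) next
      # tips: list of c(r, c, theta); theta measured from the +row
      # (apexward) axis
      tips <- list(c(org[1], org[2], stats::rnorm(1, 0, 0.3)))
      while (length(tips) > 0L && n_seg < spec$max_segments) {
        tip <- tips[[length(tips)]]
        tips[[length(tips)]] <- NULL
        r <- tip[1]; c <- tip[2]; theta <- tip[3]
        theta <- theta + stats::rnorm(1, 0, spec$angle_sigma)
        step <- spec$step_length * stats::runif(1, 0.7, 1.3)
        r2 <- r + step * cos(theta)
        c2 <- c + step * sin(theta)
        died <- FALSE
        if (!inside(r2, c2)) {
          # bisect toward the ROI boundary; keep the inside part
          t_lo <- 0; t_hi <- 1
          for (k in 1:10) {
            t_mid <- (t_lo + t_hi) / 2
            if (inside(r + t_mid * (r2 - r), c + t_mid * (c2 - c))) {
              t_lo <- t_mid
            } else {
              t_hi <- t_mid
            }
          }
          r2 <- r + t_lo * (r2 - r)
          c2 <- c + t_lo * (c2 - c)
          died <- TRUE
          if (t_lo * step < 0.5) next  # too short to record
        }
        n_seg <- n_seg + 1L
        if (n_seg > length(segs)) segs <- c(segs, vector("list", length(segs)))
        segs[[n_seg]] <- c(r, c, r2, c2)
        if (died) next
        b <- band_of(r2, lo, hi)
        if (stats::runif(1) >= min(spec$step_survival * smul[b], 1)) next
        if (stats::runif(1) < min(spec$branch_rate * bmul[b], 1)) {
          ev_r <- c(ev_r, r2); ev_c <- c(ev_c, c2)
          spread <- abs(stats::rnorm(1, 0.5, 0.15))
          tips[[length(tips) + 1L]] <- c(r2, c2, theta - spread)
          tips[[length(tips) + 1L]] <- c(r2, c2, theta + spread)
        } else {
          tips[[length(tips) + 1L]] <- c(r2, c2, theta)
        }
      }
    }
  })

  segs <- segs[seq_len(n_seg)]
  segments <- if (n_seg > 0) {
    m <- do.call(rbind, segs)
    data.frame(r0 = m[, 1], c0 = m[, 2], r1 = m[, 3], c1 = m[, 4])
  } else {
    data.frame(r0 = numeric(0), c0 = numeric(0),
               r1 = numeric(0), c1 = numeric(0))
  }

  truth <- .ground_truth(segments, ev_r, roi, labels, lo, hi,
                         spec$fiber_width, spec$domain_shape)
  list(segments = segments, truth = truth, roi = roi, labels = labels,
       branch_events = data.frame(row = ev_r, col = ev_c))
}

# Exact tallies over the generated segments: banded skeleton length
# (segments clipped at band-boundary rows), branch events by band,
# rasterized foreground area within the ROI, ROI area.
.ground_truth <- function(segments, event_rows, roi, labels, lo, hi,
                          fiber_width, shape) {
  n_regions <- 3L
  h <- (hi - lo + 1) / n_regions
  # band b covers rows ((lo - 1) + (b-1)*h, (lo - 1) + b*h]
  band_len <- numeric(n_regions)
  if (nrow(segments) > 0) {
    len <- sqrt((segments$r1 - segments$r0)^2 + (segments$c1 - segments$c0)^2)
    rmin <- pmin(segments$r0, segments$r1)
    rmax <- pmax(segments$r0, segments$r1)
    for (b in seq_len(n_regions)) {
      b_lo <- (lo - 1) + (b - 1) * h
      b_hi <- (lo - 1) + b * h
      span <- rmax - rmin
      frac <- ifelse(span < 1e-9,
                     as.numeric(band_of(segments$r0, lo, hi) == b),
                     pmax(0, pmin(rmax, b_hi) - pmax(rmin, b_lo)) / span)
      band_len[b] <- sum(len * frac)
    }
  }
  ev_band <- if (length(event_rows)) {
    tabulate(band_of(event_rows, lo, hi), nbins = n_regions)
  } else {
    integer(n_regions)
  }
  ras <- rasterize_segments(segments, shape, fiber_width) & roi
  lab <- unclass(labels)
  fg_band <- tabulate(lab[ras], nbins = n_regions)
  area_band <- tabulate(lab[lab > 0], nbins = n_regions)
  tot <- function(x) c(x, sum(x))
  nm <- c("base", "mid", "apex", "total")
  truth <- list(
    true_skeleton_length_px = stats::setNames(tot(band_len), nm),
    true_branch_count = stats::setNames(tot(ev_band), nm),
    true_foreground_area_px = stats::setNames(tot(fg_band), nm),
    roi_area_px = stats::setNames(tot(area_band), nm)
  )
  truth
}

#' Rasterize line segments at a fixed fiber width
#'
#' Marks every pixel whose center lies within `width / 2` of any segment.
#'
#' @param segments Data frame with columns `r0, c0, r1, c1`.
#' @param shape `c(height, width)` of the output.
#' @param width Fiber width in pixels.
#' @return Logical matrix.
#' @export
rasterize_segments <- function(segments, shape, width = 3) {
  out <- matrix(FALSE, shape[1], shape[2])
  if (nrow(segments) == 0) return(out)
  half <- width / 2
  pad <- ceiling(half) + 1L
  for (i in seq_len(nrow(segments))) {
    r0 <- segments$r0[i]; c0 <- segments$c0[i]
    r1 <- segments$r1[i]; c1 <- segments$c1[i]
    rr <- max(1L, floor(min(r0, r1)) - pad):min(shape[1], ceiling(max(r0, r1)) + pad)
    cc <- max(1L, floor(min(c0, c1)) - pad):min(shape[2], ceiling(max(c0, c1)) + pad)
    if (!length(rr) || !length(cc)) next
    R <- matrix(rr, length(rr), length(cc))
    C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    dr <- r1 - r0; dc <- c1 - c0
    l2 <- dr * dr + dc * dc
    if (l2 < 1e-12) {
      d2 <- (R - r0)^2 + (C - c0)^2
    } else {
      t <- pmin(pmax(((R - r0) * dr + (C - c0) * dc) / l2, 0), 1)
      d2 <- (R - (r0 + t * dr))^2 + (C - (c0 + t * dc))^2
    }
    hit <- d2 <= half^2
    out[rr, cc] <- out[rr, cc] | hit
  }
  out
}

#' Render segments as a synthetic fluorescence image
#'
#' Applies the camera model of [render_spec()] to a rasterized network.
#' The returned image is normalized to \[0, 1\] and carries the noise-free
#' expectation in its `"expected"` attribute.
#'
#' @param segments Data frame with columns `r0, c0, r1, c1`.
#' @param spec The [network_spec()] the segments came from (supplies
#'   domain shape and fiber width).
#' @param rspec A [render_spec()].
#' @return Numeric matrix in \[0, 1\] with attribute `expected`.
#' @export
render_network <- function(segments, spec, rspec) {
  stopifnot(inherits(spec, "network_spec"), inherits(rspec, "render_spec"))
  shape <- spec$domain_shape
  sig <- rspec$signal_amplitude *
    rasterize_segments(segments, shape, spec$fiber_width)
  if (rspec$psf_sigma > 0) {
    sig <- EBImage::imageData(EBImage::gblur(EBImage::Image(sig),
                                             sigma = rspec$psf_sigma))
    sig <- matrix(sig, shape[1], shape[2])
  }
  expected <- sig
  if (rspec$background_amplitude > 0) {
    expected <- expected + rspec$background_amplitude * .background_field(shape)
  }
  expected <- pmin(pmax(expected, 0), 1)
  img <- expected
  withr::with_seed(rspec$rng_seed, {
    if (rspec$noise_poisson_scale > 0) {
      img <- stats::rpois(length(img), img * rspec$noise_poisson_scale) /
        rspec$noise_poisson_scale
      dim(img) <- shape
    }
    if (rspec$noise_gaussian_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, rspec$noise_gaussian_sigma)
    }
  })
  q <- 2^rspec$bit_depth - 1
  img <- round(pmin(pmax(img, 0), 1) * q) / q
  dim(img) <- shape
  attr(img, "expected") <- expected
  img
}

#' Derive a per-heart seed from the cohort master seed
#'
#' Linear-congruential style derivation; keeps the result a positive
#' 32-bit integer so the whole cohort is reproducible from one seed.
#'
#' @param master Integer master seed.
#' @param i Heart index (1-based).
#' @return Integer seed.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483399 + 48271 * i) %% 2147483399) + 1L
}

#' Apply a knockout effect to a network specification
#'
#' Multiplies the per-band branch and survival multipliers of a WT spec by
#' the effect factors, producing the KO generating law.
#'
#' @param spec A [network_spec()].
#' @param ko_effect Numeric length-3 vector (per-band branch-rate
#'   multipliers) or list with `branch` and/or `survival` length-3
#'   elements.
#' @return A new `network_spec`.
#' @export
apply_ko_effect <- function(spec, ko_effect) {
  if (is.numeric(ko_effect)) ko_effect <- list(branch = ko_effect)
  rm <- spec$region_multipliers
  if (!is.null(ko_effect$branch)) rm$branch <- rm$branch * ko_effect$branch
  if (!is.null(ko_effect$survival)) rm$survival <- rm$survival * ko_effect$survival
  spec$region_multipliers <- rm
  spec
}

#' Ground-truth density report for one simulated heart
#'
#' The exact analogue of [density_report()] computed from the simulator's
#' ground truth instead of processed pixels: skeleton density is true
#' skeleton length per unit ROI area, foreground density the true
#' rasterized area fraction, branch-point density the bifurcation-event
#' count per unit area.
#'
#' @param truth The `truth` element of a [simulate_network()] result.
#' @param heart_id,group Identifiers copied into the report.
#' @return Data frame shaped like [density_report()] output.
#' @export
truth_report <- function(truth, heart_id = NA_character_,
                         group = NA_character_) {
  area <- truth$roi_area_px
  data.frame(
    heart_id = heart_id, group = group,
    region = names(area),
    masked_area_px = as.numeric(area),
    foreground_px = as.numeric(truth$true_foreground_area_px),
    skeleton_px = as.numeric(truth$true_skeleton_length_px),
    branchpoint_count = as.numeric(truth$true_branch_count),
    foreground_density = as.numeric(truth$true_foreground_area_px / area),
    skeleton_density = as.numeric(truth$true_skeleton_length_px / area),
    branchpoint_density = as.numeric(truth$true_branch_count / area),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Simulate a WT/KO cohort's ground truth without rendering
#'
#' Fast path for statistical calibration: generates the networks for a
#' two-group cohort and stacks their [truth_report()]s, skipping image
#' rendering and morphometry entirely.
#'
#' @param n_per_group Hearts per group (>= 1).
#' @param wt_spec [network_spec()] for the WT generating law.
#' @param ko_effect Passed to [apply_ko_effect()]; `c(1, 1, 1)` gives a
#'   null cohort.
#' @param seed Master seed; per-heart seeds come from [derive_seed()].
#' @return Data frame of stacked ground-truth reports.
#' @export
simulate_truth_cohort <- function(n_per_group, wt_spec,
                                  ko_effect = c(1, 1, 1), seed = 1L) {
  stopifnot(n_per_group >= 1)
  ko_spec <- apply_ko_effect(wt_spec, ko_effect)
  out <- vector("list", 2L * n_per_group)
  for (i in seq_len(2L * n_per_group)) {
    grp <- if (i <= n_per_group) "WT" else "KO"
    j <- if (grp == "WT") i else i - n_per_group
    sp <- if (grp == "WT") wt_spec else ko_spec
    sp$rng_seed <- derive_seed(seed, i)
    sim <- simulate_network(sp)
    out[[i]] <- truth_report(sim$truth,
                             heart_id = sprintf("%s%02d", grp, j),
                             group = grp)
  }
  do.call(rbind, out)
}

#' Generate a full WT/KO image cohort on disk
#'
#' Writes, for each heart: a 16-bit grayscale TIFF of the rendered GFP
#' channel, an 8-bit PNG ROI mask, and a JSON ground-truth file; plus one
#' sample sheet CSV (`heart_id, group, image_path, mask_path, seed`)
#' for the whole cohort. Per-heart seeds derive deterministically from the
#' master seed, so a fixed seed reproduces the cohort byte for byte.
#'
#' @param n_per_group Hearts per group (the quantified whole-mount
#'   comparison this emulates used 4).
#' @param wt_spec [network_spec()] for the WT generating law.
#' @param ko_effect Passed to [apply_ko_effect()].
#' @param rspec [render_spec()] shared by all hearts (per-heart noise
#'   seeds are derived).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param overwrite Overwrite an existing sample sheet in `out_dir`.
#' @return Invisibly, a list with `sheet` (data frame), `truths` (list of
#'   per-heart ground truths) and `sheet_path`.
#' @export
make_cohort <- function(n_per_group = 4L, wt_spec = network_spec(),
                        ko_effect = c(1, 1, 1), rspec = render_spec(),
                        seed = 1L, out_dir, overwrite = FALSE) {
  stopifnot(n_per_group >= 1)
  sheet_path <- file.path(out_dir, "samples.csv")
  if (file.exists(sheet_path) && !overwrite) {
    stop("output directory already contains a cohort (samples.csv); ",
         "use overwrite = TRUE")
  }
  for (d in file.path(out_dir, c("images", "masks", "truth"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  ko_spec <- apply_ko_effect(wt_spec, ko_effect)
  n <- 2L * n_per_group
  rows <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- if (i <= n_per_group) "WT" else "KO"
    j <- if (grp == "WT") i else i - n_per_group
    heart_id <- sprintf("%s%02d", grp, j)
    hseed <- derive_seed(seed, i)
    sp <- if (grp == "WT") wt_spec else ko_spec
    sp$rng_seed <- hseed
    rs <- rspec
    rs$rng_seed <- derive_seed(seed, i + n)
    sim <- simulate_network(sp)
    img <- render_network(sim$segments, sp, rs)
    image_path <- file.path("images", paste0(heart_id, ".tif"))
    mask_path <- file.path("masks", paste0(heart_id, "_mask.png"))
    write_gray_image(img, file.path(out_dir, image_path),
                     bits = rs$bit_depth)
    write_mask(sim$roi, file.path(out_dir, mask_path))
    jsonlite::write_json(
      lapply(sim$truth, as.list),
      file.path(out_dir, "truth", paste0(heart_id, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    truths[[i]] <- sim$truth
    rows[[i]] <- data.frame(heart_id = heart_id, group = grp,
                            image_path = image_path, mask_path = mask_path,
                            seed = hseed, stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, rows)
  utils::write.csv(sheet, sheet_path, row.names = FALSE)
  names(truths) <- sheet$heart_id
  invisible(list(sheet = sheet, truths = truths, sheet_path = sheet_path))
}
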