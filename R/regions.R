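#' Partition a region of interest into base/mid/apex bands
#'
#' The ROI's bounding box along the base-to-apex axis is split into
#' `n_regions` bands of equal extent; every ROI pixel is labelled by the
#' band containing it. A pixel falling exactly on a band boundary belongs
#' to the band with the smaller index (base side), a deterministic
#' tie-break. By convention the base is at the low end of the axis (top of
#' the image for `axis = "row"`).
#'
#' @param roi Logical ROI matrix.
#' @param axis `"row"` (default; base at the top) or `"col"`.
#' @param n_regions Number of bands (default 3: base, mid, apex).
#' @return Integer matrix of labels: 0 outside the ROI, `1..n_regions`
#'   inside; attribute `region_names` gives the band names
#'   (`base`, `mid`, `apex` when `n_regions == 3`).
#' @export
partition_regions <- function(roi, axis = c("row", "col"), n_regions = 3L) {
  axis <- match.arg(axis)
  roi <- unclass(roi) > 0
  if (!any(roi)) stop("ROI is empty")
  idx <- which(roi, arr.ind = TRUE)
  pos <- if (axis == "row") idx[, 1] else idx[, 2]
  lo <- min(pos); hi <- max(pos)
  extent <- hi - lo + 1L
  if (extent < n_regions) {
    stop("ROI spans only ", extent, " pixels along the ", axis,
         " axis; cannot form ", n_regions, " bands")
  }
  h <- extent / n_regions
  # ceiling() keeps a pixel landing exactly on a boundary in the lower band
  band <- pmin(as.integer(ceiling((pos - lo + 1L) / h)), as.integer(n_regions))
  lab <- matrix(0L, nrow(roi), ncol(roi))
  lab[idx] <- band
  attr(lab, "region_names") <- region_names(n_regions)
  attr(lab, "axis") <- axis
  lab
}

region_names <- function(n_regions) {
  if (n_regions == 3L) c("base", "mid", "apex") else paste0("band", seq_len(n_regions))
}

#' Band index of a continuous axis coordinate
#'
#' Maps a (possibly fractional) coordinate along the base-to-apex axis to
#' its band, using the same equal-extent rule as [partition_regions()].
#' Used by the simulator to band ground-truth segments and branch events.
#'
#' @param pos Numeric vector of coordinates (same axis and units as the
#'   ROI's pixel indices).
#' @param lo,hi Bounding-box limits of the ROI along the axis.
#' @param n_regions Number of bands.
#' @return Integer vector of band indices in `1..n_regions`.
#' @export
band_of <- function(pos, lo, hi, n_regions = 3L) {
  h <- (hi - lo + 1) / n_regions
  b <- ceiling((pos - lo + 1) / h)
  pmin(pmax(as.integer(b), 1L), as.integer(n_regions))
}

#' Per-region density report for one heart
#'
#' Counts foreground, skeleton and branch-point pixels per band and
#' divides each by the band's masked area ("density per unit of masked
#' region"). A `total` row aggregates the whole ROI; by construction the
#' total density is the area-weighted mean of the band densities. A band
#' with zero masked area gets `NA` densities.
#'
#' @param net Logical foreground matrix (inside ROI).
#' @param sk Logical skeleton matrix.
#' @param bp Branch-point data frame from [branch_points()].
#' @param labels Integer label matrix from [partition_regions()].
#' @param heart_id,group Identifiers copied into the report.
#' @return A data frame with one row per region (`base`, `mid`, `apex`,
#'   `total`) and columns `masked_area_px`, `foreground_px`, `skeleton_px`,
#'   `branchpoint_count`, `foreground_density`, `skeleton_density`,
#'   `branchpoint_density`.
#' @export
density_report <- function(net, sk, bp, labels, heart_id = NA_character_,
                           group = NA_character_) {
  stopifnot(all(dim(net) == dim(labels)), all(dim(sk) == dim(labels)))
  rnames <- attr(labels, "region_names")
  n_regions <- length(rnames)
  lab <- unclass(labels)
  area <- tabulate(lab[lab > 0L], nbins = n_regions)
  fg <- tabulate(lab[unclass(net) > 0], nbins = n_regions)
  skc <- tabulate(lab[unclass(sk) > 0], nbins = n_regions)
  bpc <- if (nrow(bp)) {
    tabulate(lab[cbind(bp$row, bp$col)], nbins = n_regions)
  } else {
    integer(n_regions)
  }
  area <- c(area, sum(area))
  fg <- c(fg, sum(fg))
  skc <- c(skc, sum(skc))
  bpc <- c(bpc, sum(bpc))
  dens <- function(x) ifelse(area > 0, x / area, NA_real_)
  data.frame(
    heart_id = heart_id, group = group,
    region = c(rnames, "total"),
    masked_area_px = area, foreground_px = fg, skeleton_px = skc,
    branchpoint_count = bpc,
    foreground_density = dens(fg),
    skeleton_density = dens(skc),
    branchpoint_density = dens(bpc),
    stringsAsFactors = FALSE
  )
}
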