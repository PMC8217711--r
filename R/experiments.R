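#' Simulate, render and quantify a cohort in memory
#'
#' The end-to-end recovery experiment: generates a WT/KO cohort, renders
#' each heart with the camera model, runs the morphometry pipeline on the
#' rendered images, and returns both the pipeline density reports and the
#' matching ground-truth reports for the same hearts. No files are
#' written; per-heart seeds derive from the master seed exactly as in
#' [make_cohort()].
#'
#' @param n_per_group Hearts per group.
#' @param wt_spec [network_spec()] for the WT generating law.
#' @param ko_effect Passed to [apply_ko_effect()].
#' @param rspec [render_spec()].
#' @param seed Master seed.
#' @param config [pipeline_config()] supplying top-hat radius and bins.
#' @return A list with `reports` (pipeline [density_report()] rows) and
#'   `truth_reports` ([truth_report()] rows for the same hearts).
#' @export
simulate_pipeline_cohort <- function(n_per_group, wt_spec = network_spec(),
                                     ko_effect = c(1, 1, 1),
                                     rspec = render_spec(), seed = 1L,
                                     config = pipeline_config()) {
  ko_spec <- apply_ko_effect(wt_spec, ko_effect)
  n <- 2L * n_per_group
  reports <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- if (i <= n_per_group) "WT" else "KO"
    j <- if (grp == "WT") i else i - n_per_group
    heart_id <- sprintf("%s%02d", grp, j)
    sp <- if (grp == "WT") wt_spec else ko_spec
    sp$rng_seed <- derive_seed(seed, i)
    rs <- rspec
    rs$rng_seed <- derive_seed(seed, i + n)
    sim <- simulate_network(sp)
    img <- render_network(sim$segments, sp, rs)
    q <- quantify_image(unclass(img), sim$roi,
                        tophat_radius = config$tophat_radius,
                        n_bins = config$n_bins)
    reports[[i]] <- density_report(q$binary, q$skeleton, q$branch_points,
                                   sim$labels, heart_id = heart_id,
                                   group = grp)
    truths[[i]] <- truth_report(sim$truth, heart_id = heart_id, group = grp)
  }
  list(reports = do.call(rbind, reports),
       truth_reports = do.call(rbind, truths))
}

#' Percent change of a metric between groups
#'
#' Convenience accessor: the `percent_change` field of [compare_groups()].
#'
#' @inheritParams compare_groups
#' @return A single number.
#' @export
percent_change <- function(reports, metric = "skeleton_density",
                           region = "total", groups = c("WT", "KO")) {
  compare_groups(reports, metric = metric, region = region,
                 groups = groups)$percent_change
}
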