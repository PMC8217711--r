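#' Pipeline configuration
#'
#' All tunable parameters of the quantification pipeline, with
#' serialization-stable defaults. A config round-trips unchanged through
#' its YAML file form ([write_config()] / [read_config()]).
#'
#' @param tophat_radius Disk radius for [tophat()], px.
#' @param n_bins Otsu histogram bins.
#' @param connectivity Neighborhood connectivity (8; recorded for the
#'   audit log, the skeleton operations are 8-connected).
#' @param region_axis Base-to-apex axis for [partition_regions()].
#' @param n_regions Number of bands.
#' @param test `"student"` or `"welch"`.
#' @param seed Master RNG seed (used only by simulation verbs; the
#'   quantification itself is deterministic).
#' @param overwrite Overwrite existing outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tophat_radius = 15L, n_bins = 256L,
                            connectivity = 8L, region_axis = "row",
                            n_regions = 3L, test = "student",
                            seed = 1L, overwrite = FALSE) {
  stopifnot(tophat_radius >= 1, n_bins >= 2, connectivity == 8L,
            region_axis %in% c("row", "col"), n_regions >= 1,
            test %in% c("student", "welch"))
  structure(list(
    tophat_radius = as.integer(tophat_radius), n_bins = as.integer(n_bins),
    connectivity = as.integer(connectivity), region_axis = region_axis,
    n_regions = as.integer(n_regions), test = test,
    seed = as.integer(seed), overwrite = isTRUE(overwrite)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Read a cohort sample sheet
#'
#' @param path CSV with columns `heart_id`, `group`, `image_path`,
#'   `mask_path` (paths relative to the sheet's directory or absolute).
#' @return Data frame with paths resolved against the sheet location.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("heart_id", "group", "image_path", "mask_path")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  sheet$image_path <- resolve(sheet$image_path)
  sheet$mask_path <- resolve(sheet$mask_path)
  sheet
}

#' Quantify one heart and write audit artifacts
#'
#' Runs [quantify_image()] on one image/mask pair and, when `out_dir` is
#' given, writes audit PNGs (binary network, skeleton, branch-point
#' overlay) and a JSON stage summary. Branch-point coordinates in the JSON
#' are 0-based (row, col).
#'
#' @param image_path,mask_path Input files.
#' @param heart_id,group Identifiers for the report.
#' @param config A [pipeline_config()].
#' @param out_dir Directory for audit artifacts, or `NULL` to skip.
#' @return A list with `report` (the [density_report()] rows) and `stages`
#'   (the [quantify_image()] products plus labels).
#' @export
quantify_heart <- function(image_path, mask_path, heart_id = NA_character_,
                           group = NA_character_,
                           config = pipeline_config(), out_dir = NULL) {
  img <- load_image(image_path)
  roi <- load_mask(mask_path)
  if (!all(dim(img) == dim(roi))) {
    stop("image and mask shapes differ for heart ", heart_id)
  }
  q <- quantify_image(img, roi, tophat_radius = config$tophat_radius,
                      n_bins = config$n_bins)
  labels <- partition_regions(roi, axis = config$region_axis,
                              n_regions = config$n_regions)
  rep <- density_report(q$binary, q$skeleton, q$branch_points, labels,
                        heart_id = heart_id, group = group)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mask(q$binary, file.path(out_dir, paste0(heart_id, "_binary.png")))
    write_mask(q$skeleton,
               file.path(out_dir, paste0(heart_id, "_skeleton.png")))
    overlay <- array(0, c(dim(img), 3))
    overlay[, , 2] <- q$skeleton * 1
    if (nrow(q$branch_points)) {
      idx <- cbind(q$branch_points$row, q$branch_points$col)
      overlay[cbind(idx, 1L)] <- 1
      overlay[cbind(idx, 2L)] <- 0
    }
    png::writePNG(overlay,
                  file.path(out_dir, paste0(heart_id, "_overlay.png")))
    jsonlite::write_json(
      list(heart_id = heart_id, group = group,
           threshold = q$threshold,
           foreground_px = sum(q$binary), skeleton_px = sum(q$skeleton),
           branchpoint_count = nrow(q$branch_points),
           branch_points_rc0 = unname(as.matrix(q$branch_points)) - 1L),
      file.path(out_dir, paste0(heart_id, "_summary.json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  list(report = rep, stages = c(q, list(labels = labels)))
}

#' Run the full quantification and comparison pipeline
#'
#' For every heart in the sample sheet: load image and mask, run the
#' morphometry stages, partition into bands, compute the density report.
#' Then compare WT vs KO for every density metric in every region. The
#' run is deterministic given the config and inputs: repeated runs write
#' byte-identical CSVs.
#'
#' @param sheet A sample-sheet data frame (see [read_sample_sheet()]) or a
#'   path to one.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; receives `densities.csv` (long form:
#'   one row per heart x region x metric), `comparisons.csv`, per-heart
#'   audit artifacts under `audit/`, and `run_log.txt`.
#' @return Invisibly, a list with `reports` (stacked density reports) and
#'   `comparisons`.
#' @export
run_pipeline <- function(sheet, config = pipeline_config(), out_dir) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  groups <- unique(sheet$group)
  if (length(groups) != 2L) {
    stop("two groups required (sample sheet has: ",
         paste(groups, collapse = ", "), ")")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("hpsmorph ", as.character(utils::packageVersion("hpsmorph"))),
    paste0("config: ", jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
  )
  reports <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    hid <- sheet$heart_id[i]
    res <- withCallingHandlers(
      tryCatch(
        quantify_heart(sheet$image_path[i], sheet$mask_path[i],
                       heart_id = hid, group = sheet$group[i],
                       config = config,
                       out_dir = file.path(out_dir, "audit")),
        error = function(e) {
          stop("heart ", hid, ", stage quantify: ", conditionMessage(e),
               call. = FALSE)
        }
      ),
      warning = function(w) {
        log_lines <<- c(log_lines,
                        paste0("warning [", hid, "]: ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    reports[[i]] <- res$report
    log_lines <- c(log_lines, paste0("quantified ", hid))
  }
  reports <- do.call(rbind, reports)
  ref <- if ("WT" %in% groups) {
    c("WT", setdiff(groups, "WT"))
  } else {
    sort(groups)
  }
  regions <- c(region_names(config$n_regions), "total")
  comparisons <- compare_all(reports, regions = regions,
                             test = config$test, groups = ref)

  long <- .densities_long(reports)
  utils::write.csv(long, file.path(out_dir, "densities.csv"),
                   row.names = FALSE)
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(reports = reports, comparisons = comparisons))
}

.densities_long <- function(reports) {
  metrics <- c("masked_area_px", "foreground_px", "skeleton_px",
               "branchpoint_count", "foreground_density",
               "skeleton_density", "branchpoint_density")
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(heart_id = reports$heart_id, group = reports$group,
               region = reports$region, metric = m,
               value = reports[[m]], stringsAsFactors = FALSE)
  }))
}
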