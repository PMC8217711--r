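#' Compare a density metric between two genotype groups
#'
#' Two-tailed two-sample t-test of one density metric in one region,
#' WT versus KO, with the percent change of the KO mean relative to the WT
#' mean. The default is the pooled-variance Student's test
#' (df = n_WT + n_KO - 2); Welch's unequal-variance test is available via
#' `test = "welch"`. Group means and standard errors of the mean are
#' reported alongside the test.
#'
#' Two degenerate contracts: identical constant groups give t = 0, p = 1;
#' a zero WT mean makes `percent_change` undefined (`NA`).
#'
#' @param reports Data frame of stacked [density_report()] rows (one heart
#'   may contribute several regions).
#' @param metric Column name to compare, e.g. `"foreground_density"`,
#'   `"skeleton_density"`, `"branchpoint_density"`.
#' @param region Region to compare (`"base"`, `"mid"`, `"apex"`, `"total"`).
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#' @param groups Length-2 character vector naming the reference (WT) and
#'   comparison (KO) levels of the `group` column.
#' @return One-row data frame: `metric`, `region`, `mean_WT`, `sem_WT`,
#'   `mean_KO`, `sem_KO`, `n_WT`, `n_KO`, `t`, `df`, `p`, `percent_change`.
#' @export
compare_groups <- function(reports, metric = "foreground_density",
                           region = "total", test = c("student", "welch"),
                           groups = c("WT", "KO")) {
  test <- match.arg(test)
  if (!metric %in% names(reports)) stop("unknown metric: ", metric)
  sub <- reports[reports$region == region, , drop = FALSE]
  wt <- sub[[metric]][sub$group == groups[1]]
  ko <- sub[[metric]][sub$group == groups[2]]
  wt <- wt[!is.na(wt)]; ko <- ko[!is.na(ko)]
  if (length(wt) < 2L || length(ko) < 2L) {
    stop("insufficient replicates: need >= 2 hearts per group (have ",
         length(wt), " ", groups[1], ", ", length(ko), " ", groups[2], ")")
  }
  m_wt <- mean(wt); m_ko <- mean(ko)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  if (stats::sd(wt) == 0 && stats::sd(ko) == 0) {
    # constant data: t.test() refuses; define t = 0, p = 1 when means agree
    if (m_wt == m_ko) {
      tt <- list(statistic = 0, parameter = length(wt) + length(ko) - 2L,
                 p.value = 1)
    } else {
      tt <- list(statistic = sign(m_ko - m_wt) * Inf,
                 parameter = length(wt) + length(ko) - 2L, p.value = 0)
    }
  } else {
    ht <- stats::t.test(ko, wt, var.equal = (test == "student"))
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  data.frame(
    metric = metric, region = region,
    mean_WT = m_wt, sem_WT = sem(wt),
    mean_KO = m_ko, sem_KO = sem(ko),
    n_WT = length(wt), n_KO = length(ko),
    t = as.numeric(tt$statistic), df = as.numeric(tt$parameter),
    p = as.numeric(tt$p.value),
    percent_change = if (m_wt != 0) 100 * (m_ko - m_wt) / m_wt else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Compare all density metrics across all regions
#'
#' Runs [compare_groups()] over the cartesian product of metrics and
#' regions and stacks the rows. No multiple-testing correction is applied
#' by default (per-comparison alpha, as in the whole-mount analysis this
#' reproduces); `bonferroni = TRUE` adds a `p_adj` column adjusted across
#' all rows.
#'
#' @inheritParams compare_groups
#' @param metrics Character vector of metric columns.
#' @param regions Character vector of regions.
#' @param bonferroni Add a Bonferroni-adjusted `p_adj` column.
#' @return Data frame with one row per metric x region.
#' @export
compare_all <- function(reports,
                        metrics = c("foreground_density", "skeleton_density",
                                    "branchpoint_density"),
                        regions = c("base", "mid", "apex", "total"),
                        test = c("student", "welch"),
                        groups = c("WT", "KO"), bonferroni = FALSE) {
  test <- match.arg(test)
  out <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(regions, function(r) {
      compare_groups(reports, metric = m, region = r, test = test,
                     groups = groups)
    }))
  }))
  if (bonferroni) out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  rownames(out) <- NULL
  out
}
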