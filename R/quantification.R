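#' Gene detection efficiency or relative gene abundance from FOV counts
#'
#' Per field of view (FOV), the efficiency is
#' `100 * positive_cells / total_cells`; the result reports the unweighted
#' mean of the per-FOV percentages and their sample standard deviation
#' (n - 1 denominator). In `"efficiency"` mode, `total_cells` are all
#' counted (DAPI-stained) cells; in `"rga"` mode they are the 16S
#' rRNA-probe-positive cells, so the mean is the relative gene abundance.
#' A pooled estimate (total positives over total cells) is also reported
#' for reference but is not the headline statistic.
#'
#' @param fovs data.frame with columns `fov_id`, `total_cells`,
#'   `positive_cells` (see [read_fov_counts()]).
#' @param mode `"efficiency"` (default) or `"rga"`.
#' @return An object of class `efficiency_result`: `mode`, `percentages`
#'   (per FOV, named), `mean_percent`, `sd_percent` (NA for a single FOV),
#'   `pooled_percent`, `n_fovs`, `n_cells_total`.
#' @export
#' @examples
#' fovs <- data.frame(fov_id = 1:3, total_cells = c(50, 40, 60),
#'                    positive_cells = c(25, 10, 30))
#' detection_efficiency(fovs)
detection_efficiency <- function(fovs, mode = c("efficiency", "rga")) {
  mode <- match.arg(mode)
  stopifnot(all(c("fov_id", "total_cells", "positive_cells") %in% names(fovs)))
  if (nrow(fovs) < 1) stop("at least one FOV required", call. = FALSE)
  bad <- fovs$positive_cells > fovs$total_cells | fovs$positive_cells < 0 |
    fovs$total_cells < 1
  if (any(bad))
    stop("invalid counts in FOV(s): ", paste(fovs$fov_id[bad], collapse = ", "),
         call. = FALSE)
  pct <- 100 * fovs$positive_cells / fovs$total_cells
  names(pct) <- as.character(fovs$fov_id)
  structure(list(
    mode = mode, percentages = pct,
    mean_percent = mean(pct),
    sd_percent = if (length(pct) > 1) sd(pct) else NA_real_,
    pooled_percent = 100 * sum(fovs$positive_cells) / sum(fovs$total_cells),
    n_fovs = nrow(fovs), n_cells_total = sum(fovs$total_cells)),
    class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  lab <- if (x$mode == "rga") "relative gene abundance" else "detection efficiency"
  cat(sprintf("%s: %.1f%% +/- %s%% (%d FOVs, %d cells; pooled %.1f%%)\n",
              lab, x$mean_percent,
              if (is.na(x$sd_percent)) "NA" else sprintf("%.1f", x$sd_percent),
              x$n_fovs, x$n_cells_total, x$pooled_percent))
  invisible(x)
}

#' Compare two groups of per-FOV percentages
#'
#' Two-stage comparison as used for detection-efficiency contrasts: a
#' two-sample F-test for equality of variances first, then a two-tailed
#' pooled-variance t-test (the t-test assuming equal variances). When the
#' F-test rejects equality at `alpha_variance`, `equal_variance_assumed` is
#' FALSE and the Welch t-test results are the ones to report; both are
#' always returned.
#'
#' @param group_a,group_b Numeric vectors of per-FOV percentages (each of
#'   length >= 2), e.g. the `percentages` field of two
#'   [detection_efficiency()] results.
#' @param alpha_variance Significance level of the variance F-test
#'   (default 0.05).
#' @return An object of class `comparison_result`: `f_statistic`,
#'   `f_p_value`, `t_statistic`, `t_p_value`, `df` (pooled test),
#'   `equal_variance_assumed`, `welch_t_statistic`, `welch_t_p_value`,
#'   `welch_df`, `mean_difference` and `significance` (stars:
#'   `***` p <= 0.001, `**` p <= 0.01, `*` p <= 0.05, `ns` otherwise, for
#'   the test selected by the variance check).
#' @export
#' @examples
#' compare_groups(c(40, 45, 42), c(20, 22, 24))
compare_groups <- function(group_a, group_b, alpha_variance = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  f <- var.test(group_a, group_b)
  tt <- t.test(group_a, group_b, var.equal = TRUE)
  tw <- t.test(group_a, group_b, var.equal = FALSE)
  equal <- f$p.value >= alpha_variance
  p_sel <- if (equal) tt$p.value else tw$p.value
  structure(list(
    f_statistic = unname(f$statistic), f_p_value = f$p.value,
    t_statistic = unname(tt$statistic), t_p_value = tt$p.value,
    df = unname(tt$parameter),
    equal_variance_assumed = equal,
    welch_t_statistic = unname(tw$statistic), welch_t_p_value = tw$p.value,
    welch_df = unname(tw$parameter),
    mean_difference = mean(group_a) - mean(group_b),
    significance = significance_stars(p_sel)),
    class = "comparison_result")
}

#' Significance tier stars for a p-value
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `ns`
#' otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) NA_character_
    else if (x <= 0.001) "***"
    else if (x <= 0.01) "**"
    else if (x <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("F = %.4f (p = %.4g); equal variances %s\n",
              x$f_statistic, x$f_p_value,
              if (x$equal_variance_assumed) "assumed" else "rejected"))
  cat(sprintf("pooled t = %.4f, df = %g, p = %.4g; Welch t = %.4f, df = %.2f, p = %.4g [%s]\n",
              x$t_statistic, x$df, x$t_p_value,
              x$welch_t_statistic, x$welch_df, x$welch_t_p_value, x$significance))
  invisible(x)
}

#' Summarize a count table by experiment, with optional pairwise comparison
#'
#' @param counts data.frame as read by [read_fov_counts()], with an
#'   `experiment_id` column.
#' @param mode `"efficiency"` or `"rga"`.
#' @param compare_to Optional experiment id (e.g. the negative control) to
#'   compare every other experiment against.
#' @return List with `summary` (data.frame: one row per experiment) and,
#'   when `compare_to` is given, `comparisons` (data.frame of pairwise
#'   statistics).
#' @export
quantify_experiments <- function(counts, mode = c("efficiency", "rga"),
                                 compare_to = NULL) {
  mode <- match.arg(mode)
  stopifnot("experiment_id" %in% names(counts))
  ids <- unique(counts$experiment_id)
  effs <- lapply(ids, function(id)
    detection_efficiency(counts[counts$experiment_id == id, , drop = FALSE], mode))
  names(effs) <- ids
  summary <- data.frame(
    experiment_id = ids,
    mode = mode,
    mean_percent = vapply(effs, `[[`, numeric(1), "mean_percent"),
    sd_percent = vapply(effs, `[[`, numeric(1), "sd_percent"),
    n_fovs = vapply(effs, function(e) as.integer(e$n_fovs), integer(1)),
    n_cells_total = vapply(effs, function(e) as.integer(e$n_cells_total), integer(1)),
    pooled_percent = vapply(effs, `[[`, numeric(1), "pooled_percent"),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  out <- list(summary = summary, results = effs)
  if (!is.null(compare_to)) {
    if (!compare_to %in% ids) stop("compare_to experiment '", compare_to,
                                   "' not in table", call. = FALSE)
    ref <- effs[[compare_to]]$percentages
    comp <- lapply(setdiff(ids, compare_to), function(id) {
      cr <- compare_groups(effs[[id]]$percentages, ref)
      data.frame(experiment_id = id, reference = compare_to,
                 f_statistic = cr$f_statistic, f_p_value = cr$f_p_value,
                 t_statistic = cr$t_statistic, t_p_value = cr$t_p_value,
                 equal_variance_assumed = cr$equal_variance_assumed,
                 significance = cr$significance, stringsAsFactors = FALSE)
    })
    out$comparisons <- do.call(rbind, comp)
  }
  out
}
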