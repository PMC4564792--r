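# Segmentation error metrics, computed in voxel counts between an automatic
# and a manual (reference) labelling:
#   E_fp  = (|A| - |A  n M|) / |M| * 100     false positive error
#   E_fn  = (|M| - |A n M|) / |M| * 100      false negative error
#   E_vol = (|A| / |M| - 1) * 100            signed volume error
#   E_sim = (1 - 2|A n M| / (|A| + |M|)) * 100   similarity (1 - Dice) error
# The identity E_vol = E_fp - E_fn holds exactly, and E_sim is the Dice
# complement on a percent scale. E_vol is computed signed per tooth; tables
# report its absolute value.

#' Segmentation error metrics
#'
#' Computes the four per-tooth errors between automatic and manual
#' segmentations. Inputs may be a pair of [label_volume()]s / integer
#' arrays (teeth matched by label) or a pair of logical masks (treated as
#' one tooth).
#'
#' @param auto Automatic segmentation (label volume, integer array or
#'   logical mask).
#' @param manual Manual / ground-truth segmentation on the same grid; every
#'   evaluated label must be nonempty in `manual`.
#' @param labels Integer labels to evaluate; defaults to all nonzero labels
#'   present in `manual`.
#' @return A `metrics_report`: a data frame with one row per tooth
#'   (`tooth`, `n_auto`, `n_manual`, `n_intersect`, `e_fp`, `e_fn`, `e_vol`,
#'   `e_vol_abs`, `e_sim`), all error columns in percent.
#' @examples
#' a <- array(0L, c(4, 4, 2)); m <- a
#' a[1:2, 1:2, ] <- 1L; m[1:2, 1:3, ] <- 1L
#' compute_metrics(a, m)
#' @export
compute_metrics <- function(auto, manual, labels = NULL) {
  a <- seg_data(auto)
  m <- seg_data(manual)
  if (!identical(dim(a), dim(m)))
    stop("auto and manual grids have different shapes", call. = FALSE)
  if (is.logical(a) || is.logical(m)) {
    a <- array(as.integer(a), dim = dim(a))
    m <- array(as.integer(m), dim = dim(m))
  }
  if (is.null(labels)) labels <- setdiff(sort(unique(as.vector(m))), 0L)
  if (length(labels) == 0L)
    stop("manual segmentation is empty: metrics are undefined", call. = FALSE)
  rows <- lapply(labels, function(k) {
    va <- a == k
    vm <- m == k
    n_m <- sum(vm)
    if (n_m == 0L)
      stop(sprintf("manual mask for label %d is empty: denominator undefined", k),
           call. = FALSE)
    n_a <- sum(va)
    n_i <- sum(va & vm)
    e_fp <- (n_a - n_i) / n_m * 100
    e_fn <- (n_m - n_i) / n_m * 100
    e_vol <- (n_a / n_m - 1) * 100
    e_sim <- (1 - 2 * n_i / (n_a + n_m)) * 100
    data.frame(tooth = k, n_auto = n_a, n_manual = n_m, n_intersect = n_i,
               e_fp = e_fp, e_fn = e_fn, e_vol = e_vol,
               e_vol_abs = abs(e_vol), e_sim = e_sim)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_report", "data.frame")
  out
}

seg_data <- function(x) {
  if (inherits(x, c("label_volume", "volume_image"))) x$data else x
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<metrics_report> %d teeth\n", nrow(df)))
  print(format(df, digits = 4), row.names = FALSE)
  need <- c("e_fp", "e_fn", "e_vol_abs", "e_sim")
  if (!all(need %in% names(df)) || nrow(df) == 0L) return(invisible(x))
  cat(sprintf("mean +/- sd:  E_fp %.2f +/- %.2f  E_fn %.2f +/- %.2f  |E_vol| %.2f +/- %.2f  E_sim %.2f +/- %.2f (%%)\n",
              mean(df$e_fp), sd0(df$e_fp), mean(df$e_fn), sd0(df$e_fn),
              mean(df$e_vol_abs), sd0(df$e_vol_abs),
              mean(df$e_sim), sd0(df$e_sim)))
  invisible(x)
}

sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0

#' Dataset-level metrics table
#'
#' Aggregates per-tooth reports into one row per dataset (mean and standard
#' deviation across teeth of each error, with `E_vol` reported as an
#' absolute value) plus a grand row pooling all teeth.
#'
#' @param reports A `metrics_report` or list of them (one per dataset).
#' @param file Optional CSV output path.
#' @return A data frame with columns `dataset`, `n_teeth` and
#'   `<metric>_mean` / `<metric>_sd` for `e_fp`, `e_fn`, `e_vol_abs`,
#'   `e_sim`; written to `file` as CSV when requested.
#' @export
report_table <- function(reports, file = NULL) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  if (!length(reports)) stop("need at least one report", call. = FALSE)
  metrics <- c("e_fp", "e_fn", "e_vol_abs", "e_sim")
  row_of <- function(df, name) {
    out <- data.frame(dataset = name, n_teeth = nrow(df))
    for (mcol in metrics) {
      out[[paste0(mcol, "_mean")]] <- mean(df[[mcol]])
      out[[paste0(mcol, "_sd")]] <- sd0(df[[mcol]])
    }
    out
  }
  names(reports) <- names(reports) %||% as.character(seq_along(reports))
  rows <- Map(function(r, nm) row_of(as.data.frame(r), nm),
              reports, names(reports))
  pooled <- do.call(rbind, lapply(reports, as.data.frame))
  tab <- rbind(do.call(rbind, unname(rows)), row_of(pooled, "all"))
  rownames(tab) <- NULL
  if (!is.null(file)) write.csv(tab, file, row.names = FALSE)
  tab
}

#' One-line textual summary of a metrics table
#'
#' @param tab A table from [report_table()].
#' @return Character vector, one formatted `mean +/- sd` line per dataset.
#' @export
format_metrics_table <- function(tab) {
  vapply(seq_len(nrow(tab)), function(i) {
    sprintf("dataset %-6s E_fp %5.2f+/-%.2f  E_fn %5.2f+/-%.2f  |E_vol| %5.2f+/-%.2f  E_sim %5.2f+/-%.2f",
            tab$dataset[i], tab$e_fp_mean[i], tab$e_fp_sd[i],
            tab$e_fn_mean[i], tab$e_fn_sd[i],
            tab$e_vol_abs_mean[i], tab$e_vol_abs_sd[i],
            tab$e_sim_mean[i], tab$e_sim_sd[i])
  }, character(1))
}
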