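# Evaluation layer: accuracy metrics, optimal-percentile search by
# measurement-method category and plot position, and the derived comparison
# statistics of the sensor study.

#' Campaign-to-method mapping
#'
#' Manual height method by data-collection campaign: campaigns 1-2 fall in
#' vegetative stages measured soil-to-top-of-stem (method A), campaigns 3-5
#' in reproductive stages measured soil-to-top-of-spike excluding awns
#' (method B).
#'
#' @param campaign campaign index (1-5), vectorized.
#' @return `"A"` or `"B"` per campaign.
#' @export
campaign_method <- function(campaign) {
  if (any(!campaign %in% 1:5)) stop("campaign must be in 1..5", call. = FALSE)
  ifelse(campaign <= 2, "A", "B")
}

check_pair <- function(est, ref) {
  if (length(est) != length(ref)) {
    stop("length mismatch between estimates and references", call. = FALSE)
  }
  if (length(est) < 1L) stop("need at least one pair", call. = FALSE)
}

#' Root-mean-square error
#' @param est,ref equal-length numeric vectors, meters.
#' @return `sqrt(mean((est - ref)^2))`.
#' @export
rmse <- function(est, ref) {
  check_pair(est, ref)
  sqrt(mean((est - ref)^2))
}

#' Mean bias (estimate minus reference)
#'
#' Negative bias means underestimation.
#'
#' @param est,ref equal-length numeric vectors, meters.
#' @return `mean(est - ref)`.
#' @export
bias <- function(est, ref) {
  check_pair(est, ref)
  mean(est - ref)
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' The convention used throughout: R-squared is the squared Pearson
#' correlation between estimates and references, so it measures linear
#' association and is reported alongside a separate bias. The
#' regression-style `1 - SSres/SStot` about the identity line is available
#' via `convention = "identity"`.
#'
#' @param est,ref equal-length numeric vectors (n >= 2, non-constant).
#' @param convention `"pearson"` (default) or `"identity"`.
#' @return unitless value (in \[0, 1\] for `"pearson"`).
#' @export
r_squared <- function(est, ref, convention = c("pearson", "identity")) {
  convention <- match.arg(convention)
  check_pair(est, ref)
  if (length(est) < 2L) stop("need at least 2 pairs for r_squared", call. = FALSE)
  if (stats::sd(est) == 0 || stats::sd(ref) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  if (convention == "pearson") {
    stats::cor(est, ref)^2
  } else {
    1 - sum((est - ref)^2) / sum((ref - mean(ref))^2)
  }
}

# Join ladders (plot_id [, campaign, position], percentile, height) with the
# reference table and return the estimate matrix (rows = plot-campaign
# pairs, cols = percentile grid) plus the aligned reference vector.
ladder_matrix <- function(ladders, ref) {
  has_campaign <- "campaign" %in% names(ladders) && "campaign" %in% names(ref)
  key <- function(df) {
    if (has_campaign) paste(df$plot_id, df$campaign, sep = "#") else as.character(df$plot_id)
  }
  grid <- sort(unique(ladders$percentile))
  lk <- key(ladders)
  rk <- key(ref)
  units <- intersect(unique(lk), rk)
  if (!length(units)) stop("empty selection: no plots shared by ladders and references", call. = FALSE)
  ord <- order(lk, ladders$percentile)
  lad <- ladders[ord, ]
  lk <- lk[ord]
  per_unit <- split(lad$height, lk)
  lens <- lengths(per_unit)
  if (any(lens != length(grid))) {
    stop("all ladders must share the percentile grid", call. = FALSE)
  }
  est <- do.call(rbind, per_unit[units])
  colnames(est) <- grid
  list(est = est, ref = ref$height_m[match(units, rk)], grid = grid,
       units = units)
}

#' Optimal percentile within a method category
#'
#' Scans every percentile of the shared ladder grid, computes the RMSE of
#' the ladder heights against the reference heights over the selected plots
#' (filtered by method category and, optionally, plot position), and returns
#' the grid argmin; ties break toward the lowest percentile. The percentile
#' maximizing R-squared is reported alongside, since the two optima need not
#' agree.
#'
#' @param ladders data.frame of per-plot ladders: columns `plot_id`,
#'   `percentile`, `height`, optionally `campaign` and `position`.
#' @param ref reference table: columns `plot_id`, `height_m`, optionally
#'   `campaign` and `method`.
#' @param category `"A"`, `"B"` or `"all"`.
#' @param position `"side"`, `"middle"` or `"pooled"`.
#' @return list: `percentile`, `rmse`, `bias`, `r_squared` (at the optimal
#'   percentile), `n`, `category`, `position`, `r2_percentile` (grid argmax
#'   of R-squared), `rmse_by_percentile` (named vector over the grid).
#' @export
optimal_percentile <- function(ladders, ref, category = "all",
                               position = "pooled") {
  category <- match.arg(category, c("A", "B", "all"))
  position <- match.arg(position, c("side", "middle", "pooled"))
  if (category != "all") {
    if (!"method" %in% names(ref) && "campaign" %in% names(ref)) {
      ref$method <- campaign_method(ref$campaign)
    }
    if (!"method" %in% names(ref)) {
      stop("reference table needs 'method' or 'campaign' to filter by category",
           call. = FALSE)
    }
    ref <- ref[ref$method == category, , drop = FALSE]
  }
  if (position != "pooled") {
    if (!"position" %in% names(ladders)) {
      stop("ladders need a 'position' column to filter by plot position",
           call. = FALSE)
    }
    ladders <- ladders[ladders$position == position, , drop = FALSE]
  }
  if (!nrow(ref) || !nrow(ladders)) {
    stop("empty selection for category=", category, ", position=", position,
         call. = FALSE)
  }
  lm_ <- ladder_matrix(ladders, ref)
  errs <- lm_$est - lm_$ref
  rmse_by_p <- sqrt(colMeans(errs^2))
  i <- which.min(rmse_by_p)  # which.min takes the first (lowest) on ties
  r2_by_p <- if (nrow(lm_$est) >= 2 && stats::sd(lm_$ref) > 0) {
    apply(lm_$est, 2, function(col) {
      if (stats::sd(col) == 0) NA_real_ else stats::cor(col, lm_$ref)^2
    })
  } else rep(NA_real_, length(lm_$grid))
  list(percentile = lm_$grid[i],
       rmse = unname(rmse_by_p[i]),
       bias = mean(lm_$est[, i] - lm_$ref),
       r_squared = unname(r2_by_p[i]),
       n = nrow(lm_$est),
       category = category, position = position,
       r2_percentile = if (all(is.na(r2_by_p))) NA_real_ else lm_$grid[which.max(r2_by_p)],
       rmse_by_percentile = rmse_by_p)
}

#' Percent reduction of a processed RMSE relative to a raw RMSE
#'
#' `(rmse_raw - rmse_processed) / rmse_raw * 100`, reported to 2 decimals
#' (round half up) — the statistic quantifying how much the point-cloud
#' pre-processing lowers the minimum RMSE.
#'
#' @param rmse_raw raw-cloud minimum RMSE, meters (> 0).
#' @param rmse_processed processed-cloud minimum RMSE, meters.
#' @return percent reduction, 2 decimals.
#' @export
percent_reduction <- function(rmse_raw, rmse_processed) {
  if (any(rmse_raw <= 0)) stop("rmse_raw must be > 0", call. = FALSE)
  round_half_up((rmse_raw - rmse_processed) / rmse_raw * 100, 2)
}

#' Percent by which one RMSE exceeds another
#'
#' `(a / b - 1) * 100`, reported to 2 decimals (round half up).
#'
#' @param a,b RMSEs, meters (`b > 0`).
#' @return percent excess of `a` over `b`, 2 decimals.
#' @export
percent_exceed <- function(a, b) {
  if (any(b <= 0)) stop("the reference RMSE must be > 0", call. = FALSE)
  round_half_up((a / b - 1) * 100, 2)
}

#' Average RMSE increase when plot positions are pooled
#'
#' For each method category, the combined (position-pooled) minimum RMSE
#' minus the unweighted mean of the side and middle minimum RMSEs; returns
#' the mean over categories to 4 decimals (round half up). Quantifies what
#' is lost by not differentiating side from middle plots.
#'
#' @param categories list of lists/vectors, each with `combined_rmse`,
#'   `side_rmse`, `middle_rmse` (meters, all > 0).
#' @return mean RMSE increase in meters, 4 decimals.
#' @export
average_rmse_increase <- function(categories) {
  if (!length(categories)) stop("empty category list", call. = FALSE)
  inc <- vapply(categories, function(cc) {
    cc <- as.list(cc)
    vals <- c(cc$combined_rmse, cc$side_rmse, cc$middle_rmse)
    if (any(vals <= 0)) stop("all RMSE values must be > 0", call. = FALSE)
    cc$combined_rmse - mean(c(cc$side_rmse, cc$middle_rmse))
  }, numeric(1))
  round_half_up(mean(inc), 4)
}

#' Assemble the sensor-comparison report
#'
#' Pools every campaign and scores the three sensing modalities against the
#' reference heights: per-sensor pooled RMSE/bias/R-squared (LiDAR and UAS
#' at their per-category optimal percentiles), per-category optimal
#' percentiles, the raw-versus-processed LiDAR table, and the side/middle
#' stratification.
#'
#' @param lidar_ladders processed-cloud ladders (plot_id, campaign,
#'   position, percentile, height); `NULL` to skip.
#' @param lidar_raw_ladders raw-cloud ladders in the same layout; `NULL` to
#'   skip the raw-vs-processed table.
#' @param uas_ladders UAS pixel ladders (plot_id, campaign, percentile,
#'   height); `NULL` to skip.
#' @param ultrasonic estimates data.frame (plot_id, campaign, height_m);
#'   `NULL` to skip.
#' @param ref reference table (plot_id, campaign, method, height_m).
#' @return a `comparison_report` list: `sensors` (data.frame sensor, rmse,
#'   bias, r_squared, n), `lidar_categories`, `uas_categories` (per-category
#'   optima), `raw_vs_processed` (per-campaign minimum RMSEs and the percent
#'   reduction), `position_table` (side/middle breakdown),
#'   `avg_rmse_increase`, `missing_plots`.
#' @export
build_comparison_report <- function(lidar_ladders = NULL,
                                    lidar_raw_ladders = NULL,
                                    uas_ladders = NULL,
                                    ultrasonic = NULL, ref) {
  if (!"method" %in% names(ref)) ref$method <- campaign_method(ref$campaign)
  sensors <- list()
  report <- list()

  safe_r2 <- function(est, ref_h) {
    tryCatch(r_squared(est, ref_h), error = function(e) NA_real_)
  }

  pooled_from_categories <- function(ladders) {
    # per-category optimal percentile, then pooled metrics over all plots
    cats <- intersect(c("A", "B"), unique(ref$method))
    opts <- lapply(cats, function(m) optimal_percentile(ladders, ref, m))
    names(opts) <- cats
    est <- ref$height_m * NA_real_
    for (m in cats) {
      sel <- ref$method == m
      sub <- ladders[ladders$percentile == opts[[m]]$percentile, ]
      k <- paste(ref$plot_id[sel], ref$campaign[sel], sep = "#")
      sk <- paste(sub$plot_id, sub$campaign, sep = "#")
      est[sel] <- sub$height[match(k, sk)]
    }
    list(est = est, optima = opts)
  }

  missing <- character(0)
  if (!is.null(lidar_ladders)) {
    pl <- pooled_from_categories(lidar_ladders)
    ok <- !is.na(pl$est)
    missing <- c(missing, paste0("lidar:", sum(!ok)))
    sensors$lidar <- data.frame(
      sensor = "lidar", rmse = rmse(pl$est[ok], ref$height_m[ok]),
      bias = bias(pl$est[ok], ref$height_m[ok]),
      r_squared = safe_r2(pl$est[ok], ref$height_m[ok]), n = sum(ok))
    report$lidar_categories <- pl$optima
  }
  if (!is.null(uas_ladders)) {
    pu <- pooled_from_categories(uas_ladders)
    ok <- !is.na(pu$est)
    missing <- c(missing, paste0("uas:", sum(!ok)))
    sensors$uas <- data.frame(
      sensor = "uas", rmse = rmse(pu$est[ok], ref$height_m[ok]),
      bias = bias(pu$est[ok], ref$height_m[ok]),
      r_squared = safe_r2(pu$est[ok], ref$height_m[ok]), n = sum(ok))
    report$uas_categories <- pu$optima
  }
  if (!is.null(ultrasonic)) {
    k <- paste(ref$plot_id, ref$campaign, sep = "#")
    uk <- paste(ultrasonic$plot_id, ultrasonic$campaign, sep = "#")
    est <- ultrasonic$height_m[match(k, uk)]
    ok <- !is.na(est)
    missing <- c(missing, paste0("ultrasonic:", sum(!ok)))
    sensors$ultrasonic <- data.frame(
      sensor = "ultrasonic", rmse = rmse(est[ok], ref$height_m[ok]),
      bias = bias(est[ok], ref$height_m[ok]),
      r_squared = safe_r2(est[ok], ref$height_m[ok]), n = sum(ok))
  }

  if (!is.null(lidar_ladders) && !is.null(lidar_raw_ladders)) {
    campaigns <- sort(unique(ref$campaign))
    rv <- lapply(campaigns, function(cmp) {
      rsub <- ref[ref$campaign == cmp, ]
      o_raw <- optimal_percentile(lidar_raw_ladders[lidar_raw_ladders$campaign == cmp, ], rsub)
      o_prc <- optimal_percentile(lidar_ladders[lidar_ladders$campaign == cmp, ], rsub)
      data.frame(campaign = cmp,
                 raw_min_rmse = o_raw$rmse, raw_percentile = o_raw$percentile,
                 processed_min_rmse = o_prc$rmse,
                 processed_percentile = o_prc$percentile,
                 percent_reduction = percent_reduction(o_raw$rmse, o_prc$rmse))
    })
    report$raw_vs_processed <- do.call(rbind, rv)
  }

  if (!is.null(lidar_ladders) && "position" %in% names(lidar_ladders)) {
    cats <- c(intersect(c("A", "B"), unique(ref$method)), "all")
    pos_tab <- do.call(rbind, lapply(cats, function(m) {
      do.call(rbind, lapply(c("pooled", "side", "middle"), function(p) {
        o <- optimal_percentile(lidar_ladders, ref, m, p)
        data.frame(category = m, position = p, n = o$n, min_rmse = o$rmse,
                   optimal_percentile = o$percentile)
      }))
    }))
    report$position_table <- pos_tab
    by_cat <- lapply(intersect(c("A", "B"), unique(ref$method)), function(m) {
      list(combined_rmse = pos_tab$min_rmse[pos_tab$category == m & pos_tab$position == "pooled"],
           side_rmse = pos_tab$min_rmse[pos_tab$category == m & pos_tab$position == "side"],
           middle_rmse = pos_tab$min_rmse[pos_tab$category == m & pos_tab$position == "middle"])
    })
    if (length(by_cat)) report$avg_rmse_increase <- average_rmse_increase(by_cat)
  }

  report$sensors <- do.call(rbind, unname(sensors))
  report$missing_plots <- missing
  class(report) <- "comparison_report"
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  if (!is.null(x$sensors)) {
    print(transform(x$sensors, rmse = round(rmse, 4), bias = round(bias, 4),
                    r_squared = round(r_squared, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Write a comparison report to CSV tables and a JSON summary
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$sensors)) {
    utils::write.csv(report$sensors, file.path(dir, "sensor_comparison.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$raw_vs_processed)) {
    utils::write.csv(report$raw_vs_processed,
                     file.path(dir, "raw_vs_processed.csv"), row.names = FALSE)
  }
  if (!is.null(report$position_table)) {
    utils::write.csv(report$position_table,
                     file.path(dir, "category_position.csv"), row.names = FALSE)
  }
  summary <- list(
    sensors = report$sensors,
    lidar_optimal_percentiles = lapply(report$lidar_categories, function(o)
      list(percentile = o$percentile, rmse = o$rmse, bias = o$bias,
           r2_percentile = o$r2_percentile)),
    uas_optimal_percentiles = lapply(report$uas_categories, function(o)
      list(percentile = o$percentile, rmse = o$rmse, bias = o$bias)),
    avg_rmse_increase = report$avg_rmse_increase,
    missing_plots = report$missing_plots)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
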