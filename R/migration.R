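# Per-track motility metrics and condition-level comparisons.

#' Motility metrics for one cell track
#'
#' Total distance is the sum of consecutive Euclidean steps (gaps from
#' dropped frames are bridged by straight segments); net distance the
#' Euclidean start-to-end displacement; directionality index DI =
#' net / total (0 when the cell never moves); speed = total distance /
#' elapsed time in micrometres per hour.
#'
#' @param track data.frame with columns `t` (minutes), `x`, `y`
#'   (micrometres), at least 2 rows, strictly increasing `t`.
#' @return one-row data.frame: `speed`, `directionality_index`,
#'   `net_distance`, `total_distance`, `duration` (hours), `n_points`.
#' @export
track_metrics <- function(track) {
  if (nrow(track) < 2L) stop("track needs at least 2 points")
  if (anyDuplicated(track$t)) stop("duplicate timestamps in track")
  ord <- order(track$t)
  t <- track$t[ord]; x <- track$x[ord]; y <- track$y[ord]
  if (any(!is.finite(c(x, y)))) stop("non-finite positions")
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  total <- sum(steps)
  net <- sqrt((x[length(x)] - x[1L])^2 + (y[length(y)] - y[1L])^2)
  duration <- (t[length(t)] - t[1L]) / 60
  data.frame(speed = if (duration > 0) total / duration else NA_real_,
             directionality_index = if (total > 0) net / total else 0,
             net_distance = net, total_distance = total,
             duration = duration, n_points = nrow(track))
}

#' Metrics for every track in a track table
#'
#' @param tracks track table (see [read_tracks()]); per-track metrics
#'   are computed with [track_metrics()].
#' @return data.frame with one row per track: `track_id`, metrics
#'   columns, plus `condition` / `cell_line` when present.
#' @export
track_metrics_table <- function(tracks) {
  sp <- split(tracks, tracks$track_id)
  out <- do.call(rbind, lapply(names(sp), function(id) {
    m <- track_metrics(sp[[id]])
    m$track_id <- id
    if (!is.null(sp[[id]]$condition)) m$condition <- sp[[id]]$condition[1L]
    if (!is.null(sp[[id]]$cell_line)) m$cell_line <- sp[[id]]$cell_line[1L]
    m
  }))
  rownames(out) <- NULL
  out
}

#' Compare a motility metric across conditions
#'
#' Two conditions: two-sided Mann-Whitney U test. More than two:
#' Kruskal-Wallis plus Dunn pairwise tests with BH adjustment.
#' Conditions with fewer than `min_tracks` tracks are excluded with a
#' message. Data from independent experiments are pooled (rows are
#' tracks).
#'
#' @param metrics per-track metrics (see [track_metrics_table()]).
#' @param value_col metric column to compare (default "speed").
#' @param condition_col grouping column (default "condition").
#' @param min_tracks minimum tracks per condition (default 3).
#' @return list: `test` ("mann-whitney" or "kruskal-wallis"), `p_value`
#'   (global), `pairwise` (Dunn table or NULL), `n` per condition.
#' @export
compare_conditions <- function(metrics, value_col = "speed",
                               condition_col = "condition", min_tracks = 3) {
  x <- metrics[[value_col]]
  g <- metrics[[condition_col]]
  if (is.null(x) || is.null(g)) stop("missing value or condition column")
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  tb <- table(g)
  drop <- names(tb)[tb < min_tracks]
  if (length(drop)) {
    message("excluded condition(s) with < ", min_tracks, " tracks: ",
            paste(drop, collapse = ", "))
    keep <- !g %in% drop
    x <- x[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) stop("need >=2 usable conditions")
  if (nlevels(g) == 2L) {
    w <- suppressWarnings(stats::wilcox.test(x[g == levels(g)[1L]],
                                             x[g == levels(g)[2L]]))
    list(test = "mann-whitney", p_value = w$p.value, pairwise = NULL,
         n = as.list(table(g)))
  } else {
    kw <- stats::kruskal.test(x, g)
    list(test = "kruskal-wallis", p_value = kw$p.value,
         pairwise = dunn_test(x, g), n = as.list(table(g)))
  }
}

#' Filter a track table by duration and length
#'
#' Keeps tracks with at least `min_points` points and duration at least
#' `min_duration` minutes (both inclusive).
#'
#' @param tracks track table.
#' @param min_duration minimum elapsed minutes (default 0).
#' @param min_points minimum number of points (default 2).
#' @return filtered track table; counts reported via message.
#' @export
filter_tracks <- function(tracks, min_duration = 0, min_points = 2) {
  sp <- split(tracks, tracks$track_id)
  keep <- vapply(sp, function(tr)
    nrow(tr) >= min_points && (max(tr$t) - min(tr$t)) >= min_duration,
    logical(1))
  message(sum(keep), "/", length(keep), " tracks retained")
  out <- do.call(rbind, sp[keep])
  if (is.null(out))
    out <- tracks[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
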