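#' Construct a 1-Hz depth series
#'
#' The basic archival record: an uninterrupted depth trace sampled at exactly
#' 1 Hz, depth positive down in metres. Negative sensor readings (surface
#' splash, zero-offset error) are clamped to 0. Records with internal gaps
#' should be split into separate series before construction (see
#' [read_depth_csv()]).
#'
#' @param depth Numeric vector of depths (m, positive down), one per second.
#' @param start_time POSIXct (UTC) time of the first sample.
#' @param tag_id Tag identifier.
#' @param utc_offset Hours to add to UTC to obtain local time.
#' @return An object of class `depth_series`.
#' @export
depth_series <- function(depth, start_time = as.POSIXct("2008-06-01", tz = "UTC"),
                         tag_id = "tag1", utc_offset = -7) {
  depth <- as.numeric(depth)
  if (any(!is.finite(depth))) stop("depth values must be finite")
  depth[depth < 0] <- 0
  structure(
    list(tag_id = tag_id, start_time = as.POSIXct(start_time, tz = "UTC"),
         depth = depth, utc_offset = utc_offset),
    class = "depth_series")
}

#' @export
print.depth_series <- function(x, ...) {
  cat(sprintf("<depth_series> tag %s: %d samples (%.2f hr) from %s, max depth %.1f m\n",
              x$tag_id, length(x$depth), length(x$depth) / 3600,
              format(x$start_time, "%Y-%m-%d %H:%M:%S UTC"), max(x$depth)))
  invisible(x)
}

#' @export
length.depth_series <- function(x) length(x$depth)

# Time (POSIXct UTC) of a 1-based sample index.
series_time <- function(series, idx) series$start_time + (idx - 1)

#' Read 1-Hz depth records from CSV
#'
#' Expects columns `tag_id`, `timestamp` (ISO-8601 UTC) and `depth_m` (the
#' format written by [write_deployment_csv()]). Samples must be strictly
#' 1 s apart within a tag; gaps split the record into separate series.
#'
#' @param path CSV file path.
#' @param utc_offset Hours added to UTC for local time (passed through).
#' @return A list of [depth_series()] objects.
#' @export
read_depth_csv <- function(path, utc_offset = -7) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "timestamp", "depth_m")
  if (!all(need %in% names(df))) {
    stop("depth CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (tag in unique(df$tag_id)) {
    sub <- df[df$tag_id == tag, ]
    t <- as.POSIXct(sub$timestamp, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
    o <- order(t)
    t <- t[o]; d <- sub$depth_m[o]
    dt <- as.numeric(diff(t), units = "secs")
    if (any(dt <= 0)) stop("duplicate or unordered timestamps for tag ", tag)
    brk <- c(0, which(dt != 1), length(d))
    for (j in seq_len(length(brk) - 1)) {
      sel <- (brk[j] + 1):brk[j + 1]
      out[[length(out) + 1]] <- depth_series(d[sel], t[sel[1]], tag, utc_offset)
    }
  }
  out
}

#' Write a synthetic deployment's depth record and fixes to CSV
#'
#' @param deployment A deployment from [generate_deployment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_deployment_csv <- function(deployment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- deployment$series
  depth_path <- file.path(dir, "depth.csv")
  n <- length(s$depth)
  ts <- format(s$start_time + seq_len(n) - 1, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(
    data.frame(tag_id = s$tag_id, timestamp = ts, depth_m = round(s$depth, 2)),
    depth_path, row.names = FALSE)
  fix_path <- file.path(dir, "fixes.csv")
  fx <- deployment$fixes
  fx$time <- format(fx$time, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(fx, fix_path, row.names = FALSE)
  invisible(c(depth = depth_path, fixes = fix_path))
}

#' Read a GPS fix table from CSV
#'
#' Columns: `tag_id`, `time` (ISO-8601 UTC), `lon`, `lat`.
#' @param path CSV file path.
#' @return A data frame sorted by time within tag.
#' @export
read_fix_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time <- as.POSIXct(df$time, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180)) stop("fix coordinates out of range")
  df[order(df$tag_id, df$time), , drop = FALSE]
}
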