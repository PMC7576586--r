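## CSV interchange for footfall event tables and run reporting.  CSV is
## the interchange format: no domain standard exists for footfall
## timelines.

#' Write footfall timelines to an events CSV
#'
#' One row per stance interval, columns \code{horse_id}, \code{gait},
#' \code{limb}, \code{on_time_s}, \code{off_time_s}; times in seconds with
#' six decimal places.
#'
#' @param timelines a \code{\linkS4class{FootfallTimeline}} or list of
#'   them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEventsCsv <- function(timelines, path) {
  if (is(timelines, "FootfallTimeline")) timelines <- list(timelines)
  rows <- do.call(rbind, lapply(timelines, function(tl) {
    iv <- tl@intervals
    data.frame(horse_id = tl@horseId, gait = tl@gait, limb = iv$limb,
               on_time_s = sprintf("%.6f", iv$on_time),
               off_time_s = sprintf("%.6f", iv$off_time))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read footfall timelines from an events CSV
#'
#' Inverse of \code{\link{writeEventsCsv}}.  Rows are grouped by
#' \code{(horse_id, gait)} into one timeline per group and every timeline
#' is validated on load (positive interval lengths, per-limb
#' disjointness); a malformed row or an interval violation is an error
#' naming the offending line or limb.
#'
#' @param path CSV file with header \code{horse_id, gait, limb,
#'   on_time_s, off_time_s}.
#' @return List of \code{\linkS4class{FootfallTimeline}} (possibly
#'   empty).
#' @export
readEventsCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("horse_id", "gait", "limb", "on_time_s", "off_time_s")
  if (!identical(names(d)[seq_along(need)], need))
    stop("events CSV must have columns: ", paste(need, collapse = ", "))
  if (!nrow(d)) return(list())
  on <- suppressWarnings(as.numeric(d$on_time_s))
  off <- suppressWarnings(as.numeric(d$off_time_s))
  badNum <- which(is.na(on) | is.na(off))
  if (length(badNum))
    stop(sprintf("malformed numeric value at data line %d", badNum[1L]))
  badIv <- which(on >= off)
  if (length(badIv))
    stop(sprintf("on_time >= off_time at data line %d (limb %s)",
                 badIv[1L], d$limb[badIv[1L]]))
  badLimb <- which(!d$limb %in% limbIds())
  if (length(badLimb))
    stop(sprintf("unknown limb '%s' at data line %d",
                 d$limb[badLimb[1L]], badLimb[1L]))
  key <- paste(d$horse_id, d$gait, sep = "\r")
  lapply(split(seq_len(nrow(d)), key), function(idx) {
    FootfallTimeline(d$horse_id[idx[1L]], d$gait[idx[1L]],
                     data.frame(limb = d$limb[idx], on_time = on[idx],
                                off_time = off[idx]))
  })
}

#' Per-gait descriptive summary of a feature table
#'
#' Mean and sd of the main stride variables per gait: the descriptive
#' table one reports for a cohort (stride duration and frequency, mean
#' stance duration, mean duty factor, stride count).
#'
#' @param features stride feature table.
#' @return data.frame, one row per gait present.
#' @examples
#' coh <- simulateCohort(cohortConfig(c(warmblood = 2L), stridesPerTrial = 10L),
#'                       seed = 1)
#' gaitSummary(featureTable(coh$timelines))
#' @export
gaitSummary <- function(features) {
  vars <- c("stride_duration", "stride_frequency", "stance_duration_mean",
            "duty_factor_mean")
  gaits <- intersect(gaitLabels(), unique(features$gait))
  out <- do.call(rbind, lapply(gaits, function(g) {
    sub <- features[features$gait == g, vars, drop = FALSE]
    row <- data.frame(gait = g, n_strides = nrow(sub))
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(sub[[v]])
      row[[paste0(v, "_sd")]] <- stats::sd(sub[[v]])
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Write the standard result files of a pipeline run
#'
#' Emits the per-gait descriptive table, the Hildebrand scatter export
#' (one x/y row per stride), the accuracy grid summary, and one confusion
#' CSV per grid cell, plus a short human-readable summary.
#'
#' @param features stride feature table.
#' @param grid result of \code{\link{runExperimentGrid}} (optional).
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
reportRun <- function(features, grid = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    files <<- c(files, p)
  }
  w(gaitSummary(features), "gait_summary.csv")
  w(hildebrandTable(features), "hildebrand.csv")
  lines <- c("equigait run report",
             sprintf("strides: %d; gaits: %s", nrow(features),
                     paste(sort(unique(features$gait)), collapse = ", ")))
  if (!is.null(grid)) {
    w(grid$summary, "accuracy_grid.csv")
    w(grid$folds, "accuracy_folds.csv")
    for (nm in names(grid$results)) {
      cm <- grid$results[[nm]]@confusion
      p <- file.path(dir, paste0("confusion_", gsub("/", "_", nm), ".csv"))
      utils::write.csv(as.data.frame(cm), p)
      files <- c(files, p)
    }
    best <- grid$summary[which.max(grid$summary$mean_accuracy), ]
    lines <- c(lines, sprintf("best cell: %s/%s at %.3f +/- %.3f",
                              best$kind, best$subset, best$mean_accuracy,
                              best$sd_accuracy))
  }
  p <- file.path(dir, "summary.txt")
  writeLines(lines, p)
  invisible(c(files, p))
}
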