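# MaxN relative abundance: the maximum number of individuals of a species
# visible in any single frame of an activity sequence, aggregated over
# configurable time intervals.  Re-entering animals in later sequences are
# counted anew (no individual re-identification).

#' Per-frame species counts within a sequence
#'
#' Counts the (confidence-filtered, NMS-applied) detections per frame and
#' species within a sequence's frame span, zero-filled over all frames of
#' the span.  Counting is per camera stream; the left camera is canonical.
#'
#' @param detections detections data.frame (columns frame, class; a
#'   `camera` column is filtered to `camera` when present)
#' @param startFrame,endFrame inclusive frame span of the sequence
#' @param camera counted camera stream
#' @return data.frame: frame, species, count (zero-filled)
#' @export
perFrameCounts <- function(detections, startFrame, endFrame,
                           camera = "left") {
  if ("camera" %in% names(detections))
    detections <- detections[detections$camera == camera, , drop = FALSE]
  det <- detections[detections$frame >= startFrame &
                      detections$frame <= endFrame, , drop = FALSE]
  species <- sort(unique(det$class))
  frames <- startFrame:endFrame
  if (!length(species))
    return(data.frame(frame = integer(), species = character(),
                      count = integer()))
  grid <- expand.grid(frame = frames, species = species,
                      stringsAsFactors = FALSE)
  tab <- table(factor(det$frame, levels = frames),
               factor(det$class, levels = species))
  grid$count <- as.integer(tab)
  grid
}

#' MaxN per species within one sequence
#'
#' The maximum single-frame count per species over the sequence, with the
#' earliest frame attaining it (ties break to the first frame).
#'
#' @param counts data.frame from [perFrameCounts()]
#' @return data.frame: species, maxn, frame
#' @export
maxN <- function(counts) {
  if (!nrow(counts))
    return(data.frame(species = character(), maxn = integer(),
                      frame = integer()))
  counts <- counts[order(counts$frame), , drop = FALSE]
  do.call(rbind, lapply(split(counts, counts$species), function(p) {
    i <- which.max(p$count)  # earliest argmax: which.max takes the first
    data.frame(species = p$species[1], maxn = as.integer(p$count[i]),
               frame = p$frame[i], row.names = NULL)
  }))
}

#' Sequence-level MaxN records for a detection stream
#'
#' Applies [perFrameCounts()] and [maxN()] to each activity sequence.
#'
#' @param detections detections data.frame
#' @param sequences data.frame from [extractSequences()] (stream_id,
#'   start_frame, end_frame)
#' @param camera counted camera stream
#' @return data.frame: sequence, stream_id, start_frame, end_frame,
#'   species, maxn, frame (the frame attaining the maximum)
#' @export
sequenceMaxN <- function(detections, sequences, camera = "left") {
  out <- lapply(seq_len(nrow(sequences)), function(i) {
    s <- sequences[i, ]
    m <- maxN(perFrameCounts(detections, s$start_frame, s$end_frame,
                             camera = camera))
    if (!nrow(m)) return(NULL)
    cbind(sequence = i, stream_id = s$stream_id,
          start_frame = s$start_frame, end_frame = s$end_frame, m)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(sequence = integer(), stream_id = character(),
                      start_frame = integer(), end_frame = integer(),
                      species = character(), maxn = integer(),
                      frame = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate MaxN records over time intervals
#'
#' Sums sequence-level MaxN values per species over intervals: `"hour"`,
#' `"day"` (wall-clock, computed from the frame index, frame rate and
#' stream epoch) or a fixed number of frames.  A sequence belongs to the
#' interval containing its start frame; each sequence contributes anew
#' (re-entering animals are counted as new individuals).  Summed totals
#' over all intervals equal the sum over sequences.
#'
#' @param records data.frame from [sequenceMaxN()]
#' @param interval `"hour"`, `"day"` or an integer number of frames
#' @param fps frame rate, frames per second (time-based intervals)
#' @param epoch POSIXct start time of frame 1 (time-based intervals)
#' @return data.frame: interval_start, interval_end, species, maxn_sum,
#'   n_sequences
#' @export
aggregateAbundance <- function(records, interval = "hour", fps = 20,
                               epoch = NULL) {
  if (!nrow(records))
    return(data.frame(interval_start = character(),
                      interval_end = character(), species = character(),
                      maxn_sum = integer(), n_sequences = integer()))
  if (is.character(interval)) {
    if (is.null(epoch))
      stop("time-based aggregation requires a stream epoch timestamp")
    secs <- switch(interval, hour = 3600, day = 86400,
                   stop("interval must be 'hour', 'day' or a frame count"))
    t0 <- epoch + (records$start_frame - 1) / fps
    bin <- floor(as.numeric(difftime(t0, epoch, units = "secs")) / secs)
    istart <- format(epoch + bin * secs, "%Y-%m-%d %H:%M:%S")
    iend <- format(epoch + (bin + 1) * secs, "%Y-%m-%d %H:%M:%S")
  } else {
    bin <- (records$start_frame - 1) %/% as.integer(interval)
    istart <- as.character(bin * as.integer(interval) + 1)
    iend <- as.character((bin + 1) * as.integer(interval))
  }
  key <- paste(bin, records$species, sep = "\r")
  agg <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    data.frame(interval_start = istart[idx[1]], interval_end = iend[idx[1]],
               species = records$species[idx[1]],
               maxn_sum = sum(records$maxn[idx]),
               n_sequences = length(idx))
  })
  res <- do.call(rbind, agg)
  res <- res[order(res$interval_start, res$species), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write abundance records as CSV
#'
#' @param abundance data.frame from [aggregateAbundance()]
#' @param path output file
#' @return invisibly, `path`
#' @export
writeAbundance <- function(abundance, path) {
  utils::write.csv(abundance, path, row.names = FALSE)
  invisible(path)
}
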