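# Annotation-manifest handling: VIAME-style track CSV ingestion, per-class
# dataset summaries and the per-image train/validation split with hard-day
# holdout.

#' Read VIAME-style track annotations
#'
#' Reads the VIAME detection/track CSV format: columns track id, image
#' identifier, frame index, box corners (TL_x, TL_y, BR_x, BR_y), detection
#' confidence, target length, then the class label and class confidence.
#' Comment lines starting with `#` are tolerated; malformed rows are
#' rejected with line-numbered errors and duplicate (track, frame) rows
#' signal a corrupt manifest.
#'
#' @param path file path
#' @return annotations data.frame: track, image_id, frame, x1, y1, x2, y2,
#'   confidence, class (one row per box; tracks are the groups of rows
#'   sharing a track id, frames strictly increasing within each)
#' @export
readViame <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- c("track", "image_id", "frame", "x1", "y1", "x2", "y2",
            "confidence", "length", "class", "class_confidence")
  if (!length(lines))
    return(data.frame(track = integer(), image_id = character(),
                      frame = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(), confidence = numeric(),
                      class = character()))
  parts <- strsplit(lines, ",")
  bad <- which(vapply(parts, length, integer(1)) < 10)
  if (length(bad))
    stop("malformed VIAME rows (fewer than 10 fields) at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  m <- do.call(rbind, lapply(parts, function(p) p[1:11]))
  d <- data.frame(track = as.integer(m[, 1]),
                  image_id = trimws(m[, 2]),
                  frame = as.integer(m[, 3]),
                  x1 = as.numeric(m[, 4]), y1 = as.numeric(m[, 5]),
                  x2 = as.numeric(m[, 6]), y2 = as.numeric(m[, 7]),
                  confidence = as.numeric(m[, 8]),
                  class = trimws(m[, 10]))
  nonnum <- which(is.na(d$track) | is.na(d$frame) | is.na(d$x1) |
                    is.na(d$y2))
  if (length(nonnum))
    stop("malformed VIAME rows (non-numeric fields) at line(s): ",
         paste(utils::head(nonnum, 5), collapse = ", "))
  if (anyDuplicated(d[, c("track", "frame")]))
    stop("corrupt manifest: duplicate (track, frame) rows")
  if (any(d$x1 >= d$x2 | d$y1 >= d$y2))
    stop("corrupt manifest: degenerate boxes (x1 >= x2 or y1 >= y2)")
  d <- d[order(d$track, d$frame), ]
  rownames(d) <- NULL
  d
}

#' @rdname readViame
#' @param annotations annotations data.frame to write
#' @export
writeViame <- function(annotations, path) {
  header <- paste("# 1: Detection or Track-id, 2: Video or Image Identifier,",
                  "3: Unique Frame Identifier, 4-7: Img-bbox(TL_x,TL_y,BR_x,BR_y),",
                  "8: Detection confidence, 9: Target Length,",
                  "10-11: Species, Confidence")
  rows <- sprintf("%d,%s,%d,%.17g,%.17g,%.17g,%.17g,%.17g,-1,%s,%.17g",
                  annotations$track, annotations$image_id,
                  annotations$frame, annotations$x1, annotations$y1,
                  annotations$x2, annotations$y2, annotations$confidence,
                  annotations$class,
                  if ("class_confidence" %in% names(annotations))
                    annotations$class_confidence else annotations$confidence)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Summarize an annotation manifest
#'
#' Per-class counts of annotated images (images containing at least one box
#' of the class), bounding boxes and tracks, plus a totals row.  The image
#' total is the number of distinct annotated images, which can be smaller
#' than the per-class sum since one image may host several classes; the box
#' and track totals are exact column sums.
#'
#' @param annotations annotations data.frame (see [readViame()])
#' @return data.frame: class, images, boxes, tracks, with a final `Total`
#'   row
#' @export
summarizeAnnotations <- function(annotations) {
  if (!nrow(annotations)) stop("empty annotation manifest")
  per <- do.call(rbind, lapply(split(annotations, annotations$class),
                               function(p) data.frame(
    class = p$class[1],
    images = length(unique(p$image_id)),
    boxes = nrow(p),
    tracks = length(unique(p$track)))))
  per <- per[order(-per$boxes), ]
  tot <- data.frame(class = "Total",
                    images = length(unique(annotations$image_id)),
                    boxes = nrow(annotations),
                    tracks = length(unique(annotations$track)))
  res <- rbind(per, tot)
  rownames(res) <- NULL
  res
}

#' Per-image train/validation split with hard-day holdout
#'
#' Randomly samples images into a training set at the given ratio; the
#' split is per image, so all boxes of an image land in exactly one set.
#' Images recorded on `holdoutDays` are forced into the validation set
#' first (hard samples whose days contribute nothing to training), and
#' random sampling of the remainder then fills the training set to the
#' target ratio of all images.  Deterministic given `seed`.
#'
#' @param images data.frame with column image_id and, when holdout days are
#'   requested, day
#' @param ratio training fraction in (0, 1)
#' @param seed integer seed
#' @param holdoutDays character vector of day labels held out of training
#' @return list with character vectors `train` and `val` (disjoint,
#'   covering all image ids)
#' @export
splitImages <- function(images, ratio = 0.85, seed = 1L,
                        holdoutDays = NULL) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  images <- unique(images[, intersect(c("image_id", "day"), names(images)),
                          drop = FALSE])
  ids <- unique(images$image_id)
  if (!is.null(holdoutDays) && length(holdoutDays)) {
    if (!"day" %in% names(images))
      stop("holdout days requested but images carry no day metadata")
    hold <- unique(images$image_id[images$day %in% holdoutDays])
  } else hold <- character()
  pool <- setdiff(ids, hold)
  nTrain <- min(round(ratio * length(ids)), length(pool))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  train <- sort(sample(pool, nTrain))
  list(train = train, val = sort(setdiff(ids, train)))
}

#' Read the packaged dataset-manifest tables
#'
#' Per-class image/box/track counts of the reference annotation manifest
#' (`table = "manifest"`) and the per-class train/validation counts of its
#' split (`table = "split"`), shipped as plain-text data.
#'
#' @param table which table to read
#' @return data.frame of per-class counts
#' @export
datasetManifest <- function(table = c("manifest", "split")) {
  table <- match.arg(table)
  f <- system.file("extdata", paste0(table, "_counts.csv"),
                   package = "stereofish", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Expand per-class manifest counts into synthetic annotations
#'
#' Reconstructs an annotation table with exactly the given per-class image,
#' box and track counts (synthetic image and track ids; box geometry is
#' arbitrary unit boxes).  Useful to exercise [summarizeAnnotations()]
#' against published per-class count tables.
#'
#' @param counts data.frame: class, images, boxes, tracks
#' @return annotations data.frame
#' @export
expandManifestCounts <- function(counts) {
  out <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$boxes[i]
    nim <- counts$images[i]
    ntr <- counts$tracks[i]
    stopifnot(n >= nim, n >= ntr)
    data.frame(track = 1000L * i + rep(seq_len(ntr), length.out = n),
               image_id = sprintf("cls%02d_img%06d", i,
                                  rep(seq_len(nim), length.out = n)),
               frame = seq_len(n),
               x1 = 0, y1 = 0, x2 = 1, y2 = 1, confidence = 1,
               class = counts$class[i])
  })
  do.call(rbind, out)
}
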