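# Activity detection: reduce continuous video to sequences containing
# motion.  Each pixel's intensity history is modeled by an online mixture
# of Gaussians (adaptive background estimation in the Zivkovic style);
# frames are median prefiltered to suppress particle noise.  The stage is
# tuned for recall: its purpose is to discard empty video, not to produce
# accurate foreground masks.

#' Activity-detection parameters
#'
#' @param medianKernel odd median-filter kernel width, pixels (1 disables)
#' @param history background model history length, frames; also sets the
#'   default learning rate `1/history`
#' @param nComponents maximum Gaussian components per pixel
#' @param varThreshold squared-Mahalanobis threshold separating foreground
#'   from the background components
#' @param learningRate model update rate in (0, 1]
#' @param fractionThreshold foreground pixel fraction above which a frame is
#'   active
#' @param minLength minimum active-run length kept, frames
#' @param mergeGap active runs separated by fewer than this many inactive
#'   frames are joined
#' @param backgroundRatio cumulative weight defining which components count
#'   as background
#' @return an `ActivityParams` list
#' @export
activityParams <- function(medianKernel = 5, history = 100, nComponents = 5,
                           varThreshold = 16, learningRate = 1 / history,
                           fractionThreshold = 0.001, minLength = 5,
                           mergeGap = 10, backgroundRatio = 0.9) {
  stopifnot(medianKernel >= 1, medianKernel %% 2 == 1,
            history >= 1, nComponents >= 1, varThreshold > 0,
            learningRate > 0, learningRate <= 1,
            fractionThreshold > 0, fractionThreshold < 1,
            minLength >= 1, mergeGap >= 0,
            backgroundRatio > 0, backgroundRatio <= 1)
  structure(list(medianKernel = as.integer(medianKernel),
                 history = as.integer(history),
                 nComponents = as.integer(nComponents),
                 varThreshold = varThreshold, learningRate = learningRate,
                 fractionThreshold = fractionThreshold,
                 minLength = as.integer(minLength),
                 mergeGap = as.integer(mergeGap),
                 backgroundRatio = backgroundRatio),
            class = "ActivityParams")
}

median_prefilter <- function(m, kernel) {
  if (kernel <= 1) return(m)
  as.matrix(EBImage::medianFilter(pmin(pmax(m, 0), 1), (kernel - 1L) %/% 2L))
}

#' Per-frame foreground fraction
#'
#' Runs the adaptive Gaussian-mixture background model over a grayscale
#' frame sequence and returns, per frame, the fraction of pixels classified
#' as foreground.  Each pixel keeps up to `nComponents` weighted Gaussians
#' over (median-filtered) intensity; components covering the top
#' `backgroundRatio` of the weight mass are background, and a pixel is
#' foreground when its intensity lies beyond `sqrt(varThreshold)` standard
#' deviations of every background component.  Weights, means and variances
#' are updated online with the learning rate; unexplained intensities
#' replace the weakest component.
#'
#' @param frames list of intensity matrices in `[0, 1]` (or a 3D array,
#'   frames along the third dimension)
#' @param params an [activityParams()] list
#' @return numeric vector of per-frame foreground fractions in `[0, 1]`
#' @export
foregroundFraction <- function(frames, params = activityParams()) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!length(frames)) stop("empty frame stream")
  K <- params$nComponents
  alpha <- params$learningRate
  npix <- length(frames[[1]])
  initVar <- 0.01   # variance given to newly spawned components
  minVar <- 1e-6    # variance floor, keeps the model responsive to noise-free input
  f0 <- as.numeric(median_prefilter(frames[[1]], params$medianKernel))
  w <- matrix(0, npix, K);  w[, 1] <- 1
  mu <- matrix(0, npix, K); mu[, 1] <- f0
  v <- matrix(initVar, npix, K)
  fractions <- numeric(length(frames))
  for (t in seq_along(frames)) {
    x <- as.numeric(median_prefilter(frames[[t]], params$medianKernel))
    d2 <- (x - mu)^2
    # background test: inside the gate of any background-weighted component.
    # Components are taken in decreasing-weight order until backgroundRatio
    # of the weight mass is covered (repeated max.col instead of a per-row
    # sort; K is small).
    ww <- w
    isbg <- matrix(FALSE, npix, K)
    cum <- numeric(npix)
    for (r in seq_len(K)) {
      top <- max.col(ww, ties.method = "first")
      idx <- cbind(seq_len(npix), top)
      isbg[idx] <- cum < params$backgroundRatio & w[idx] > 0
      cum <- cum + w[idx]
      ww[idx] <- -Inf
    }
    inside_bg <- d2 <= params$varThreshold * v
    fg <- rowSums(inside_bg & isbg) == 0
    fractions[t] <- mean(fg)
    # ownership: closest component within its gate (3-sigma style via the
    # same varThreshold gate) wins the update
    inside <- d2 <= params$varThreshold * v
    maha <- d2 / v
    maha[!inside] <- Inf
    owner <- max.col(-maha, ties.method = "first")
    has_owner <- is.finite(maha[cbind(seq_len(npix), owner)])
    o <- matrix(0, npix, K)
    o[cbind(which(has_owner), owner[has_owner])] <- 1
    w <- w + alpha * (o - w)
    oid <- cbind(which(has_owner), owner[has_owner])
    rho <- alpha / pmax(w[oid], alpha)
    mu[oid] <- mu[oid] + rho * (x[has_owner] - mu[oid])
    v[oid] <- pmax(v[oid] + rho * ((x[has_owner] - mu[oid])^2 - v[oid]),
                   minVar)
    # unexplained pixels spawn a component in the weakest slot
    if (any(!has_owner)) {
      weak <- max.col(-w[!has_owner, , drop = FALSE], ties.method = "first")
      nid <- cbind(which(!has_owner), weak)
      w[nid] <- alpha
      mu[nid] <- x[!has_owner]
      v[nid] <- initVar
    }
    w <- w / rowSums(w)
  }
  fractions
}

#' Extract activity sequences from a fraction series
#'
#' Frames with foreground fraction at or above the threshold are active;
#' active runs separated by fewer than `mergeGap` inactive frames are
#' joined, and runs shorter than `minLength` are discarded.  The result is
#' a sorted, non-overlapping set of frame intervals.
#'
#' @param fractions per-frame foreground fractions
#' @param params an [activityParams()] list
#' @param streamId identifier recorded with each sequence
#' @return data.frame: stream_id, start_frame, end_frame (inclusive),
#'   mean_fraction
#' @export
extractSequences <- function(fractions, params = activityParams(),
                             streamId = "stream") {
  if (!length(fractions)) stop("empty fraction series")
  active <- fractions >= params$fractionThreshold
  empty <- data.frame(stream_id = character(), start_frame = integer(),
                      end_frame = integer(), mean_fraction = numeric())
  if (!any(active)) return(empty)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # join runs whose separating gap is shorter than mergeGap
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
    if (gap < params$mergeGap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= params$minLength, ,
                   drop = FALSE]
  if (!nrow(merged)) return(empty)
  data.frame(stream_id = streamId, start_frame = merged$start,
             end_frame = merged$end,
             mean_fraction = vapply(seq_len(nrow(merged)), function(i)
               mean(fractions[merged$start[i]:merged$end[i]]), numeric(1)),
             row.names = NULL)
}

#' Write activity sequences as CSV
#'
#' @param sequences data.frame from [extractSequences()]
#' @param path output file
#' @return invisibly, `path`
#' @export
writeSequences <- function(sequences, path) {
  utils::write.csv(sequences, path, row.names = FALSE)
  invisible(path)
}
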