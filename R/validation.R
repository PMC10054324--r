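# Checkerboard-based validation of the measurement chain: triangulate
# detected inner corners, measure every horizontal and vertical 3D
# inter-corner distance, compare to the known board geometry
# (gap k corners apart = k * square size) and summarize the error against
# the recording distance.

#' Checkerboard measurement errors
#'
#' Implements the four-step board validation: (1) take the detected inner
#' corners of each synchronized image pair, (2) triangulate each corner
#' from its left/right pixel positions, (3) compute the 3D distance between
#' every ordered corner pair sharing a grid row (horizontal) or column
#' (vertical) at all index gaps `k >= 1`, (4) compare against the expected
#' `k * squareMm`.  Per image, horizontal and vertical mean absolute errors
#' are reported separately together with the mean corner depth; pairs are
#' averaged uniformly (not weighted by gap).
#'
#' @param corners data.frame with columns image_id, camera, grid_i, grid_j,
#'   px, py and optionally observed (e.g. from [projectCheckerboard()],
#'   plus an image_id column, or read from a corner CSV)
#' @param rect a [RectifiedRig-class]
#' @param spec a [BoardSpec-class]
#' @return data.frame, one row per usable image pair: image_id,
#'   horizontal_mm, vertical_mm, distance_mm, n_corners, n_horizontal_pairs,
#'   n_vertical_pairs; aggregate means are in attributes `horizontal_mm`
#'   and `vertical_mm`
#' @export
boardErrors <- function(corners, rect, spec = boardSpec()) {
  if (!"image_id" %in% names(corners)) corners$image_id <- 1L
  if (!"observed" %in% names(corners)) corners$observed <- TRUE
  out <- list()
  for (img in unique(corners$image_id)) {
    cc <- corners[corners$image_id == img & corners$observed, , drop = FALSE]
    L <- cc[cc$camera == "left", , drop = FALSE]
    R <- cc[cc$camera == "right", , drop = FALSE]
    key <- function(d) paste(d$grid_i, d$grid_j)
    common <- intersect(key(L), key(R))
    if (length(common) < 2) {
      message("image ", img, ": fewer than 2 corners visible in both views, skipped")
      next
    }
    L <- L[match(common, key(L)), ]
    R <- R[match(common, key(R)), ]
    X <- suppressWarnings(
      triangulate(rect, cbind(L$px, L$py), cbind(R$px, R$py)))
    gi <- L$grid_i; gj <- L$grid_j
    herr <- c(); verr <- c()
    n <- length(common)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      d <- sqrt(sum((X[a, ] - X[b, ])^2))
      if (gj[a] == gj[b]) {
        herr <- c(herr, abs(d - abs(gi[a] - gi[b]) * spec@squareMm))
      } else if (gi[a] == gi[b]) {
        verr <- c(verr, abs(d - abs(gj[a] - gj[b]) * spec@squareMm))
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      image_id = img,
      horizontal_mm = if (length(herr)) mean(herr) else NA_real_,
      vertical_mm = if (length(verr)) mean(verr) else NA_real_,
      distance_mm = mean(X[, 3]),
      n_corners = n, n_horizontal_pairs = length(herr),
      n_vertical_pairs = length(verr))
  }
  if (!length(out))
    return(data.frame(image_id = integer(), horizontal_mm = numeric(),
                      vertical_mm = numeric(), distance_mm = numeric(),
                      n_corners = integer(), n_horizontal_pairs = integer(),
                      n_vertical_pairs = integer()))
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  attr(rep, "horizontal_mm") <- mean(rep$horizontal_mm, na.rm = TRUE)
  attr(rep, "vertical_mm") <- mean(rep$vertical_mm, na.rm = TRUE)
  rep
}

#' Measurement error versus recording distance
#'
#' Bins per-image board-error reports by their mean recording distance and
#' summarizes the horizontal and vertical errors per bin.  Empty bins are
#' omitted.
#'
#' @param report output of [boardErrors()]
#' @param binWidthMm distance bin width, millimetres
#' @param originMm lower edge of the first bin, millimetres; e.g. width 500
#'   with origin 250 yields bins centered on 0.5, 1.0, 1.5, ... m
#' @return data.frame, bins ascending: bin_start_mm, bin_end_mm, n,
#'   horizontal_mean_mm, horizontal_sd_mm, vertical_mean_mm, vertical_sd_mm
#' @export
errorVsDistance <- function(report, binWidthMm = 500, originMm = 0) {
  if (!nrow(report)) stop("no board-error reports supplied")
  bin <- floor((report$distance_mm - originMm) / binWidthMm)
  parts <- split(report, bin)
  out <- do.call(rbind, lapply(names(parts), function(b) {
    p <- parts[[b]]
    data.frame(bin_start_mm = as.numeric(b) * binWidthMm + originMm,
               bin_end_mm = (as.numeric(b) + 1) * binWidthMm + originMm,
               n = nrow(p),
               horizontal_mean_mm = mean(p$horizontal_mm, na.rm = TRUE),
               horizontal_sd_mm = stats::sd(p$horizontal_mm),
               vertical_mean_mm = mean(p$vertical_mm, na.rm = TRUE),
               vertical_sd_mm = stats::sd(p$vertical_mm))
  }))
  out[order(out$bin_start_mm), , drop = FALSE]
}

#' Plot measurement error against distance
#'
#' @param binned output of [errorVsDistance()]
#' @param ... passed to [graphics::matplot()]
#' @return invisibly, `binned`
#' @export
plotErrorVsDistance <- function(binned, ...) {
  mid <- (binned$bin_start_mm + binned$bin_end_mm) / 2
  graphics::matplot(mid / 1000,
                    cbind(binned$horizontal_mean_mm, binned$vertical_mean_mm),
                    type = "b", pch = c(1, 2), lty = 1,
                    xlab = "recording distance [m]",
                    ylab = "mean measurement error [mm]", ...)
  graphics::legend("topleft", c("horizontal", "vertical"), pch = c(1, 2),
                   col = 1:2, bty = "n")
  invisible(binned)
}

#' Read a corner CSV
#'
#' Columns: image_id, camera, grid_i, grid_j, px, py (optional: observed).
#'
#' @param path file path
#' @return corners data.frame for [boardErrors()]
#' @export
readCorners <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
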