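# IoU, NMS and the detection-evaluation suite.

make_boxes <- function(x1, y1, w = 30, h = 20, class = "A", conf = 1,
                       frame = 1, camera = "left") {
  data.frame(frame = frame, camera = camera, x1 = x1, y1 = y1,
             x2 = x1 + w, y2 = y1 + h, class = class, confidence = conf)
}

test_that("IoU: identity, disjointness, symmetry and a hand case", {
  expect_equal(boxIoU(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(boxIoU(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0)
  expect_equal(boxIoU(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)  # 2 / 6
  set.seed(3)
  for (i in 1:20) {
    a <- c(runif(2), 0, 0); a[3:4] <- a[1:2] + runif(2, 0.1, 1)
    b <- c(runif(2), 0, 0); b[3:4] <- b[1:2] + runif(2, 0.1, 1)
    expect_equal(boxIoU(a, b), boxIoU(b, a))
  }
})

test_that("NMS keeps the top detection and respects threshold semantics", {
  d <- make_boxes(c(0, 0), c(0, 0), conf = c(0.9, 0.8))
  expect_equal(nmsFilter(d)$confidence, 0.9)
  # IoU exactly 0.5 at threshold 0.6: both kept (suppression needs > 0.6)
  d2 <- data.frame(frame = 1, camera = "left",
                   x1 = c(0, 0), y1 = c(0, 0), x2 = c(10, 10),
                   y2 = c(10, 5), class = "A", confidence = c(0.9, 0.8))
  expect_equal(boxIoU(as.numeric(d2[1, 3:6]), as.numeric(d2[2, 3:6])), 0.5)
  expect_equal(nrow(nmsFilter(d2, 0.6)), 2)
  expect_equal(nrow(nmsFilter(d2, 0.4)), 1)
})

test_that("NMS equals the set-based suppression oracle on random boxes", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 10
    d <- data.frame(frame = 1, camera = "left",
                    x1 = runif(n, 0, 60), y1 = runif(n, 0, 60),
                    class = "A", confidence = runif(n))
    d$x2 <- d$x1 + runif(n, 10, 40); d$y2 <- d$y1 + runif(n, 10, 40)
    expect_equal(nmsFilter(d, 0.4), nms_oracle(d, 0.4))
  }
})

test_that("perfect detections give mAP 1 and a diagonal confusion matrix", {
  set.seed(5)
  truth <- make_boxes(runif(10, 0, 500), runif(10, 0, 400),
                      class = rep(c("A", "B"), 5), frame = rep(1:5, 2))
  det <- truth; det$confidence <- 0.9
  ev <- evaluateDetections(truth, det, classes = c("A", "B"))
  expect_equal(meanAP(ev), 1)
  expect_equal(unname(apByClass(ev)), c(1, 1))
  cm <- confusionMatrix(ev)
  expect_equal(sum(diag(cm)), 10)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
})

test_that("F1 equals precision and recall at their equality point", {
  # 100 ground-truth boxes; 93 matched detections + 7 false positives
  # give precision = recall = 0.93, so F1 must be 0.93 (harmonic mean at
  # equality)
  truth <- make_boxes(rep(100, 100), rep(100, 100), frame = 1:100)
  det <- rbind(make_boxes(rep(100, 93), rep(100, 93), frame = 1:93,
                          conf = 0.8),
               make_boxes(rep(400, 7), rep(50, 7), frame = 1:7, conf = 0.8))
  ev <- evaluateDetections(truth, det, classes = "A")
  cur <- prCurves(ev)
  row <- cur[cur$confidence == 0.5, ]
  expect_equal(row$precision, 0.93)
  expect_equal(row$recall, 0.93)
  expect_equal(row$f1, 0.93)
})

test_that("toy set with a miss and a class swap matches the hand tally", {
  # frame 1: A detected as A; frame 2: A missed; frame 3: A detected as B
  truth <- make_boxes(c(10, 10, 10), c(10, 10, 10), class = "A",
                      frame = 1:3)
  det <- rbind(make_boxes(10, 10, class = "A", conf = 0.9, frame = 1),
               make_boxes(10, 10, class = "B", conf = 0.8, frame = 3))
  ev <- evaluateDetections(truth, det, classes = c("A", "B"))
  cm <- confusionMatrix(ev)
  expect_equal(cm["A", "A"], 1)           # correct detection
  expect_equal(cm["A", "B"], 1)           # class swap
  expect_equal(cm["A", "background"], 1)  # miss
  expect_equal(sum(cm["background", ]), 0)
  expect_equal(sum(cm["A", ]), 3)         # conserves ground truth
  # AP for A: one TP at rank 1 of 3 GT -> all-point AP = 1/3
  expect_equal(unname(apByClass(ev)["A"]), ap_oracle(c(TRUE), 3))
  # AP for B: one FP, no GT -> undefined (NA), excluded from the mean
  expect_true(is.na(apByClass(ev)["B"]))
})

test_that("AP equals the all-threshold oracle on ranked toy cases", {
  cases <- list(c(TRUE, FALSE, TRUE, TRUE, FALSE),
                c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
                c(TRUE, TRUE, TRUE),
                c(FALSE, FALSE))
  for (tp in cases) {
    nGT <- sum(tp) + 1
    # build a truth/detections pair realizing exactly these ranked flags
    truth <- make_boxes(rep(10, nGT), rep(10, nGT), frame = seq_len(nGT))
    conf <- seq(0.9, 0.5, length.out = length(tp))
    det <- do.call(rbind, lapply(seq_along(tp), function(i) {
      if (tp[i]) make_boxes(10, 10, frame = sum(tp[1:i]), conf = conf[i])
      else make_boxes(300, 300, frame = 1, conf = conf[i])
    }))
    ev <- evaluateDetections(truth, det, classes = "A")
    expect_equal(unname(apByClass(ev)["A"]), ap_oracle(tp, nGT))
  }
})

test_that("mAP is invariant to class order and monotone under deletion", {
  set.seed(6)
  truth <- make_boxes(runif(20, 0, 500), runif(20, 0, 400),
                      class = sample(c("A", "B"), 20, replace = TRUE),
                      frame = rep(1:10, 2))
  det <- truth; det$confidence <- runif(20, 0.4, 1)
  ev1 <- evaluateDetections(truth, det, classes = c("A", "B"))
  ev2 <- evaluateDetections(truth, det, classes = c("B", "A"))
  expect_equal(meanAP(ev1), meanAP(ev2))
  # deleting detections from a perfect set never raises AP
  perfect <- truth; perfect$confidence <- 0.9
  ap_full <- meanAP(evaluateDetections(truth, perfect,
                                       classes = c("A", "B")))
  for (drop in list(1:2, 1:6, 1:10)) {
    ap_sub <- meanAP(evaluateDetections(truth, perfect[-drop, ],
                                        classes = c("A", "B")))
    expect_lte(ap_sub, ap_full + 1e-12)
  }
})

test_that("confusion raw counts conserve ground-truth totals", {
  set.seed(7)
  n <- 200
  truth <- make_boxes(runif(n, 0, 1000), runif(n, 0, 800),
                      class = sample(c("A", "B", "C"), n, replace = TRUE),
                      frame = seq_len(n))
  det <- truth
  det$confidence <- runif(n, 0.3, 1)
  # perturb: drop 10%, swap 10% of labels, add 15 false positives
  det <- det[-sample(n, n / 10), ]
  sw <- sample(nrow(det), nrow(det) / 10)
  det$class[sw] <- sample(c("A", "B", "C"), length(sw), replace = TRUE)
  det <- rbind(det, make_boxes(runif(15, 2000, 3000), runif(15, 0, 800),
                               class = "A", conf = 0.9,
                               frame = sample(n, 15)))
  ev <- evaluateDetections(truth, det, matrixConfidence = 0,
                           classes = c("A", "B", "C"))
  cm <- confusionMatrix(ev)
  for (cl in c("A", "B", "C"))
    expect_equal(sum(cm[cl, ]), sum(truth$class == cl))
  expect_equal(sum(cm["background", ]),
               nrow(det) - sum(cm[c("A", "B", "C"), c("A", "B", "C")]))
})

test_that("unknown detection labels signal a vocabulary mismatch", {
  truth <- make_boxes(10, 10)
  det <- make_boxes(10, 10, class = "Z", conf = 0.9)
  expect_error(evaluateDetections(truth, det, classes = c("A", "B")),
               "vocabulary")
})

test_that("detections CSV round trip and YOLO conversion", {
  det <- make_boxes(c(5, 50), c(5, 50), conf = c(0.7, 0.9))
  p <- tempfile(fileext = ".csv")
  writeDetections(det, p)
  back <- readDetections(p)
  expect_equal(back$x1, det$x1)
  expect_equal(back$class, det$class)
  # YOLO normalized center format -> corner pixels
  yp <- tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.25 0.25 0.8", yp)
  y <- readYoloDetections(yp, c(1280, 1024), classes = c("A", "B"))
  expect_equal(as.numeric(y[1, c("x1", "y1", "x2", "y2")]),
               c(480, 384, 800, 640))
  expect_equal(y$class, "A")
  expect_equal(y$confidence, 0.8)
})
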