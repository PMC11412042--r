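#' Confusion tensor for a K-class pixel classification
#'
#' Tallies a K x K matrix of pixel counts, rows indexed by the true class and
#' columns by the predicted class. All segmentation accuracy metrics (IoU,
#' MIoU, F1, precision, recall) derive from this tensor one-vs-rest.
#'
#' @param pred_mask integer matrix/array of predicted labels in `0..k-1`.
#' @param truth_mask integer matrix/array of true labels, same shape.
#' @param k number of classes (default 3: soil = 0, wheat = 1, weed = 2).
#' @param class_names optional character vector of length `k`.
#' @return object of class `confusion_tensor`: a `k x k` integer matrix with
#'   `dimnames` truth x predicted.
#' @export
confusion_counts <- function(pred_mask, truth_mask, k = 3,
                             class_names = NULL) {
  pred <- as.integer(pred_mask)
  truth <- as.integer(truth_mask)
  if (length(pred) != length(truth) ||
      !identical(dim(pred_mask), dim(truth_mask))) {
    stop("pred_mask and truth_mask must have identical shape")
  }
  if (length(pred) == 0L) stop("masks are empty")
  if (anyNA(pred) || anyNA(truth)) stop("masks contain missing labels")
  if (min(pred, truth) < 0L || max(pred, truth) >= k) {
    stop(sprintf("labels must lie in 0..%d", k - 1L))
  }
  counts <- matrix(tabulate(truth * k + pred + 1L, nbins = k * k),
                   nrow = k, byrow = TRUE)
  if (is.null(class_names)) {
    class_names <- if (k == 3) c("soil", "wheat", "weed")
                   else paste0("class", seq_len(k) - 1L)
  }
  dimnames(counts) <- list(truth = class_names, predicted = class_names)
  class(counts) <- c("confusion_tensor", class(counts))
  counts
}

# one-vs-rest TP/FP/FN/TN for class index i (1-based) of a confusion tensor
ovr_counts <- function(tensor, i) {
  tp <- tensor[i, i]
  fp <- sum(tensor[, i]) - tp
  fn <- sum(tensor[i, ]) - tp
  tn <- sum(tensor) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn, n = sum(tensor))
}

#' Per-class IoU and mean IoU
#'
#' IoU = TP / (FN + FP + TP) per class one-vs-rest; MIoU is the unweighted
#' mean over evaluated classes. A class absent from both truth and prediction
#' carries no information and is excluded, with the mean's denominator
#' adjusted accordingly.
#'
#' @param tensor a `confusion_tensor`.
#' @return list with `iou` (named vector, `NA` for excluded classes) and
#'   `miou` (scalar).
#' @export
iou_and_miou <- function(tensor) {
  k <- nrow(tensor)
  iou <- rep(NA_real_, k)
  names(iou) <- rownames(tensor)
  for (i in seq_len(k)) {
    o <- ovr_counts(tensor, i)
    denom <- o$tp + o$fp + o$fn
    if (denom > 0) iou[i] <- o$tp / denom
  }
  if (all(is.na(iou))) stop("no class present in truth or prediction")
  list(iou = iou, miou = mean(iou, na.rm = TRUE))
}

#' Precision, recall and F1 for one class
#'
#' One-vs-rest: precision = TP/(TP+FP), recall = TP/(TP+FN) and
#' F1 = 2*TP / (N + TP - TN), where N is the total pixel count. Because
#' N = TP + TN + FP + FN this F1 form equals the usual 2TP/(2TP+FP+FN)
#' identically. When TP + FP = 0 the precision is undefined and reported as
#' `NA` (not zero).
#'
#' @param tensor a `confusion_tensor`.
#' @param class class label in `0..k-1`.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(tensor, class) {
  k <- nrow(tensor)
  i <- as.integer(class) + 1L
  if (i < 1L || i > k) stop(sprintf("class must lie in 0..%d", k - 1L))
  o <- ovr_counts(tensor, i)
  if (o$tp + o$fp + o$fn == 0) {
    stop("class absent from both truth and prediction")
  }
  precision <- if (o$tp + o$fp > 0) o$tp / (o$tp + o$fp) else NA_real_
  recall <- if (o$tp + o$fn > 0) o$tp / (o$tp + o$fn) else NA_real_
  f1 <- 2 * o$tp / (o$n + o$tp - o$tn)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Regression accuracy: RMSE, R-squared and relative error in prediction
#'
#' RMSE = sqrt(mean((pred - obs)^2)); R^2 = 1 - SSE/SST with
#' SSE = sum((pred - obs)^2) and SST = sum((obs - mean(obs))^2);
#' REP = 100 * RMSE / mean(obs) (percent). When the observations are
#' constant (SST = 0) R^2 is undefined and returned as `NA`.
#'
#' @param pred predicted values.
#' @param obs observed (true) values, same length, at least 2.
#' @return object of class `regression_score`: list with `rmse`, `r2`,
#'   `rep`, `n`.
#' @export
regression_scores <- function(pred, obs) {
  pred <- as.numeric(pred)
  obs <- as.numeric(obs)
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  if (length(obs) < 2) stop("need at least 2 observations")
  if (anyNA(pred) || anyNA(obs)) stop("missing values in pred or obs")
  m <- length(obs)
  sse <- sum((pred - obs)^2)
  sst <- sum((obs - mean(obs))^2)
  rmse <- sqrt(sse / m)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  rep_pct <- if (mean(obs) != 0) 100 * rmse / mean(obs) else NA_real_
  structure(list(rmse = rmse, r2 = r2, rep = rep_pct, n = m),
            class = "regression_score")
}

#' @export
print.regression_score <- function(x, ...) {
  cat(sprintf("RMSE %.4g | R2 %.4f | REP %.2f%% | n = %d\n",
              x$rmse, x$r2, x$rep, x$n))
  invisible(x)
}

#' Stratified segmentation accuracy report
#'
#' Pools pixel-level confusion counts over all (prediction, truth) pairs
#' within each stratum (e.g. sowing method x growth stage) and reports
#' per-class precision/recall/F1 plus MIoU per stratum. Pooling over pixels,
#' rather than averaging per-tile metrics, weights every pixel equally; the
#' two differ whenever tiles have unequal class composition.
#'
#' @param pairs list of `list(pred = , truth = , stratum = )`, masks with
#'   labels `0..k-1` and `stratum` a character key.
#' @param strata optional character vector of expected stratum keys; a pair
#'   carrying a key outside this set is an error.
#' @param k number of classes.
#' @return data.frame with one row per stratum x class plus the stratum MIoU.
#' @export
stratified_report <- function(pairs, strata = NULL, k = 3) {
  if (length(pairs) == 0) stop("no evaluation pairs supplied")
  keys <- vapply(pairs, function(p) as.character(p$stratum), character(1))
  if (!is.null(strata) && !all(keys %in% strata)) {
    bad <- setdiff(unique(keys), strata)
    stop(sprintf("unknown stratum key(s): %s", paste(bad, collapse = ", ")))
  }
  out <- list()
  for (key in unique(keys)) {
    tensor <- NULL
    for (p in pairs[keys == key]) {
      cc <- confusion_counts(p$pred, p$truth, k = k)
      tensor <- if (is.null(tensor)) cc else unclass(tensor) + unclass(cc)
    }
    class(tensor) <- c("confusion_tensor", class(tensor))
    mi <- iou_and_miou(tensor)
    for (cl in seq_len(k) - 1L) {
      prf <- tryCatch(precision_recall_f1(tensor, cl),
                      error = function(e) c(precision = NA_real_,
                                            recall = NA_real_, f1 = NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        stratum = key, class = rownames(tensor)[cl + 1L],
        precision = prf[["precision"]], recall = prf[["recall"]],
        f1 = prf[["f1"]], iou = mi$iou[[cl + 1L]], miou = mi$miou,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
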