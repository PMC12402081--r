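# Segmentation evaluation: precision, recall, Dice and Hausdorff distance
# between binary masks, plus per-dataset aggregation and report writers.

.as_mask <- function(m, what = "mask") {
  if (is.logical(m)) {
    if (is.null(dim(m)) || length(dim(m)) != 2L) stop(what, " must be 2-D")
    return(m)
  }
  if (!is.numeric(m) || is.null(dim(m)) || length(dim(m)) != 2L) {
    stop(what, " must be a 2-D logical or 0/1 numeric matrix")
  }
  if (!all(m %in% c(0, 1))) stop(what, " must be strictly binary")
  m > 0.5
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred,ref binary masks (2-D logical or 0/1 matrices) of equal shape.
#' @return named numeric vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(pred, ref) {
  p <- .as_mask(pred, "pred"); r <- .as_mask(ref, "ref")
  if (!identical(dim(p), dim(r))) {
    stop("mask shapes differ: ", paste(dim(p), collapse = "x"), " vs ",
         paste(dim(r), collapse = "x"))
  }
  tp <- sum(p & r)
  c(tp = tp, fp = sum(p) - tp, fn = sum(r) - tp,
    tn = sum(!p & !r))
}

#' Precision, recall and Dice from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `dice = 2TP/(2TP+FP+FN)`.  A fully empty pair (prediction and reference
#' both empty) scores 1 on all three; any other 0/0 ratio scores 0.
#'
#' @param counts named vector from [confusion_counts()].
#' @return named numeric vector `c(precision, recall, dice)`.
#' @export
precision_recall_dice <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (any(c(tp, fp, fn) < 0)) stop("counts must be nonnegative")
  if (tp + fp + fn == 0) {
    return(c(precision = 1, recall = 1, dice = 1))
  }
  c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn),
    dice = 2 * tp / (2 * tp + fp + fn))
}

# boundary pixels: foreground with a 4-neighbour background (image border
# counts as background); coordinates as a (k, 2) matrix of (row, col)
.boundary_coords <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(m & !inner, arr.ind = TRUE)
}

.directed_dists <- function(a, b) {
  # minimal Euclidean distance from each row of a to the set b, chunked to
  # bound the pairwise matrix size
  out <- numeric(nrow(a))
  chunk <- max(1L, floor(4e6 / nrow(b)))
  for (ix in split(seq_len(nrow(a)), ceiling(seq_len(nrow(a)) / chunk))) {
    d2 <- outer(a[ix, 1], b[, 1], "-")^2 + outer(a[ix, 2], b[, 2], "-")^2
    out[ix] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Hausdorff distance between mask boundaries
#'
#' Symmetric aggregation of directed boundary-to-boundary Euclidean
#' distances: each direction's distances are reduced at the given
#' percentile and the maximum of the two is returned.  `percentile = 100`
#' gives the classical Hausdorff distance; the default 95 (HD95) is robust
#' to single-pixel outliers.  Units are pixels.
#'
#' @param pred,ref nonempty binary masks of equal shape.
#' @param percentile percentile in `(0, 100]` of the directed distances.
#' @return nonnegative scalar, pixels.
#' @export
hausdorff_distance <- function(pred, ref, percentile = 95) {
  p <- .as_mask(pred, "pred"); r <- .as_mask(ref, "ref")
  if (!identical(dim(p), dim(r))) stop("mask shapes differ")
  if (!sum(p)) stop("pred mask is empty; Hausdorff distance undefined")
  if (!sum(r)) stop("ref mask is empty; Hausdorff distance undefined")
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  a <- .boundary_coords(p); b <- .boundary_coords(r)
  da <- .directed_dists(a, b)
  db <- .directed_dists(b, a)
  if (percentile == 100) {
    max(max(da), max(db))
  } else {
    max(quantile(da, percentile / 100, names = FALSE, type = 7),
        quantile(db, percentile / 100, names = FALSE, type = 7))
  }
}

#' Evaluate a set of prediction/reference mask pairs
#'
#' Per-image metrics averaged with equal weight (not a pooled confusion
#' matrix).  Images where the Hausdorff distance is undefined because a
#' mask is empty are excluded from the HD mean but counted in the report.
#'
#' @param preds,refs lists of binary masks, pairwise equal shapes.
#' @param percentile Hausdorff percentile (see [hausdorff_distance()]).
#' @return object of class `metrics_report`: list with the mean
#'   `precision`, `recall`, `dice`, `hausdorff`, the counts `n_images` and
#'   `n_hd`, and a `per_image` data frame.
#' @export
evaluate_dataset <- function(preds, refs, percentile = 95) {
  if (length(preds) == 0L) stop("need at least one prediction/reference pair")
  if (length(preds) != length(refs)) stop("preds and refs differ in length")
  rows <- lapply(seq_along(preds), function(i) {
    cc <- confusion_counts(preds[[i]], refs[[i]])
    prd <- precision_recall_dice(cc)
    hd <- if (cc[["tp"]] + cc[["fp"]] > 0 && cc[["tp"]] + cc[["fn"]] > 0) {
      hausdorff_distance(preds[[i]], refs[[i]], percentile)
    } else {
      NA_real_
    }
    data.frame(image = i, precision = prd[["precision"]],
               recall = prd[["recall"]], dice = prd[["dice"]],
               hausdorff = hd)
  })
  per_image <- do.call(rbind, rows)
  structure(list(
    precision = mean(per_image$precision),
    recall = mean(per_image$recall),
    dice = mean(per_image$dice),
    hausdorff = if (all(is.na(per_image$hausdorff))) NA_real_
                else mean(per_image$hausdorff, na.rm = TRUE),
    n_images = nrow(per_image),
    n_hd = sum(!is.na(per_image$hausdorff)),
    percentile = percentile,
    per_image = per_image
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics over %d images: precision %.4f  recall %.4f  dice %.4f  HD%g %.3f px (%d images)\n",
    x$n_images, x$precision, x$recall, x$dice, x$percentile,
    x$hausdorff, x$n_hd))
  invisible(x)
}

#' Write a metrics report as CSV and JSON
#'
#' The CSV holds one row per image plus a `summary` row; the JSON mirrors
#' the full report.
#'
#' @param report a [evaluate_dataset()] result.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return the report, invisibly.
#' @export
write_metrics_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    tab <- report$per_image
    tab$image <- as.character(tab$image)
    tab <- rbind(tab, data.frame(image = "summary",
                                 precision = report$precision,
                                 recall = report$recall,
                                 dice = report$dice,
                                 hausdorff = report$hausdorff))
    write.csv(tab, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null")
  }
  invisible(report)
}
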