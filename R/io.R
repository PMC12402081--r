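# Dataset readers/writers and the EchoNet-style tracing rasterizer.
#
# Coordinate convention (the public tracing tables do not state one): pixel
# centers sit at integer coordinates with x = column and y = row, and masks
# use inside-or-on-boundary inclusion.

#' Read a dataset manifest
#'
#' @param path manifest CSV with columns `image`, `mask`, `split` (and
#'   optionally `source`, `params`); file paths are relative to the
#'   manifest's directory.
#' @return data frame with an attribute `root` (the manifest directory).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "mask", "split")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  bad <- !man$split %in% c("train", "val", "test")
  if (any(bad)) stop("invalid split in manifest row(s) ",
                     paste(which(bad), collapse = ", "))
  attr(man, "root") <- dirname(normalizePath(path))
  man
}

.read_gray_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- apply(px[, , 1:min(3, dim(px)[3]),
                                            drop = FALSE], c(1, 2), mean)
  px
}

#' Load an image/mask directory through its manifest
#'
#' Images are returned as grayscale floats in `[0, 1]`; masks are binarized
#' at an 8-bit threshold of 127 (i.e. 0.5).  All images must share one
#' size; a mismatch is resized to the majority size with a warning, or
#' rejected in strict mode.
#'
#' @param dir dataset directory containing `manifest.csv` (or pass a
#'   manifest path via `manifest`).
#' @param manifest manifest file name inside `dir`.
#' @param split optional split filter (`"train"`, `"val"`, `"test"`).
#' @param strict_size error on image-size mismatches instead of resizing.
#' @return list with `x` (`(H, W, 1, N)` images), `y` (binary masks, same
#'   shape), `split` and `files`.
#' @export
load_image_mask_dir <- function(dir, manifest = "manifest.csv", split = NULL,
                                strict_size = TRUE) {
  man <- read_manifest(file.path(dir, manifest))
  root <- attr(man, "root")
  if (!is.null(split)) man <- man[man$split %in% split, , drop = FALSE]
  if (nrow(man) == 0L) stop("manifest has no rows",
                            if (!is.null(split)) paste0(" for split ", split))
  imgs <- vector("list", nrow(man))
  msks <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    ip <- file.path(root, man$image[i]); mp <- file.path(root, man$mask[i])
    if (!file.exists(ip)) stop("manifest row ", i, ": missing image ", ip)
    if (!file.exists(mp)) stop("manifest row ", i, ": missing mask ", mp)
    imgs[[i]] <- .read_gray_png(ip)
    msks[[i]] <- (.read_gray_png(mp) > 127 / 255) * 1
  }
  sizes <- vapply(imgs, function(m) paste(dim(m), collapse = "x"), "")
  main <- names(sort(table(sizes), decreasing = TRUE))[1]
  if (any(sizes != main)) {
    if (strict_size) {
      stop("image size mismatch at manifest row(s) ",
           paste(which(sizes != main), collapse = ", "),
           " (strict mode); expected ", main)
    }
    warning("resizing ", sum(sizes != main), " images to ", main)
    hw <- as.integer(strsplit(main, "x")[[1]])
    for (i in which(sizes != main)) {
      imgs[[i]] <- matrix(.resize_f(array(imgs[[i]],
                                          c(dim(imgs[[i]]), 1L, 1L)),
                                    hw[1], hw[2])$y, hw[1], hw[2])
      msks[[i]] <- (matrix(.resize_f(array(msks[[i]],
                                           c(dim(msks[[i]]), 1L, 1L)),
                                     hw[1], hw[2])$y, hw[1], hw[2]) > 0.5) * 1
    }
  }
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  x <- array(unlist(imgs), c(H, W, 1L, length(imgs)))
  y <- array(unlist(msks), c(H, W, 1L, length(msks)))
  list(x = x, y = y, split = man$split, files = man$image)
}

# --- tracing rasterization --------------------------------------------------

# normalize chord order and endpoint sides: chords are sorted by the
# projection of their midpoints on the principal axis of all midpoints, and
# each chord's endpoints are assigned to a consistent side of that axis.
.tracing_polygon <- function(rec) {
  p1 <- cbind(rec$X1, rec$Y1)
  p2 <- cbind(rec$X2, rec$Y2)
  mid <- (p1 + p2) / 2
  mc <- scale(mid, scale = FALSE)
  ax <- eigen(crossprod(mc) + diag(1e-12, 2))$vectors[, 1]
  ord <- order(mid %*% ax, apply(mid, 1, paste, collapse = ","))
  p1 <- p1[ord, , drop = FALSE]; p2 <- p2[ord, , drop = FALSE]
  mid <- mid[ord, , drop = FALSE]
  left <- matrix(0, nrow(p1), 2); right <- left
  for (i in seq_len(nrow(p1))) {
    v1 <- p1[i, ] - mid[i, ]
    crossz <- ax[1] * v1[2] - ax[2] * v1[1]
    if (crossz > 0 || (crossz == 0 && p1[i, 1] <= p2[i, 1])) {
      left[i, ] <- p1[i, ]; right[i, ] <- p2[i, ]
    } else {
      left[i, ] <- p2[i, ]; right[i, ] <- p1[i, ]
    }
  }
  rbind(left, right[rev(seq_len(nrow(right))), , drop = FALSE])
}

# even-odd interior test for all pixel centers, boundary-inclusive
.fill_polygon <- function(poly, H, W, tol = 1e-9) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  n <- nrow(poly)
  inside <- matrix(FALSE, H, W)
  onedge <- matrix(FALSE, H, W)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    if (abs(a[2] - b[2]) > tol) {
      hits <- (a[2] <= ys) != (b[2] <= ys)
      xcross <- a[1] + (ys - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      inside <- xor(inside, hits & (xs < xcross))
    }
    # on-segment test
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 > tol) {
      t <- ((xs - a[1]) * ab[1] + (ys - a[2]) * ab[2]) / len2
      px <- a[1] + pmin(pmax(t, 0), 1) * ab[1]
      py <- a[2] + pmin(pmax(t, 0), 1) * ab[2]
      onedge <- onedge | ((xs - px)^2 + (ys - py)^2 <= tol)
    }
  }
  inside | onedge
}

#' Rasterize an EchoNet-style chord tracing to a binary mask
#'
#' The tracing lists paired chord endpoints across the ventricle.  A
#' polygon is built by ordering one endpoint of each chord along one side
#' and the other endpoints in reverse along the other side, then filled
#' with an even-odd pixel-center test (boundary pixels included).  Chord
#' input order does not matter: chords are re-sorted along the principal
#' axis of their midpoints.
#'
#' @param rec data frame with columns `X1, Y1, X2, Y2` (pixel coordinates,
#'   `x` = column, `y` = row); at least 2 chords.
#' @param frame_shape integer `(rows, cols)` of the video frame.
#' @return logical mask matrix `(rows, cols)`.
#' @export
rasterize_tracing <- function(rec, frame_shape) {
  need <- c("X1", "Y1", "X2", "Y2")
  if (!all(need %in% names(rec))) {
    stop("tracing record needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(rec) < 2L) stop("a tracing needs at least 2 chords, got ", nrow(rec))
  H <- as.integer(frame_shape[1]); W <- as.integer(frame_shape[2])
  co <- unlist(rec[need])
  if (any(co < 0) || any(unlist(rec[c("X1", "X2")]) > W + 1) ||
      any(unlist(rec[c("Y1", "Y2")]) > H + 1)) {
    stop("tracing coordinates outside frame bounds ", H, "x", W)
  }
  poly <- .tracing_polygon(rec)
  .fill_polygon(poly, H, W)
}
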