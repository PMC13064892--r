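## Connected-component labelling with 8-connectivity. EBImage::bwlabel is
## 4-connected; labels that touch only diagonally are merged here with a
## union-find pass over adjacent label pairs.
label_components_8 <- function(mask) {
  L <- EBImage::bwlabel(mask)
  L <- matrix(as.integer(EBImage::imageData(L)), nrow(mask), ncol(mask))
  nmax <- max(L)
  if (nmax <= 1L) return(L)
  a1 <- L[-nrow(L), -ncol(L)]; b1 <- L[-1, -1]        # down-right
  a2 <- L[-nrow(L), -1];       b2 <- L[-1, -ncol(L)]  # down-left
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]),
                        cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0) return(L)
  parent <- seq_len(nmax)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  relab <- integer(nmax)
  relab[sort(unique(root))] <- seq_along(unique(root))
  L[L > 0L] <- relab[root[L[L > 0L]]]
  L
}

#' Segment nuclei from a projected DNA channel
#'
#' Gaussian smoothing, a global threshold (Otsu by default, on the
#' image rescaled to \[0, 1\]), hole filling, removal of objects below a
#' minimum area, optional removal of border-touching objects, and
#' 8-connected component labelling. An all-background result is valid and
#' yields zero nuclei.
#'
#' @param dna_image Numeric matrix (row, col), the projected DNA channel.
#' @param smooth_sigma Gaussian smoothing sd in pixels.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold Absolute intensity threshold when
#'   `threshold_method = "fixed"`.
#' @param min_area Minimum object area in pixels.
#' @param clear_border Drop objects touching the image border (default
#'   `TRUE`).
#' @return An object of class `nucleus_label_map`: list with `labels`
#'   (integer matrix, 0 background, 1..n), `n_nuclei`, and `areas`.
#' @export
segment_nuclei <- function(dna_image, smooth_sigma = 2,
                           threshold_method = c("otsu", "fixed"),
                           threshold = NULL, min_area = 200,
                           clear_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.matrix(dna_image))
  empty <- function() structure(
    list(labels = matrix(0L, nrow(dna_image), ncol(dna_image)),
         n_nuclei = 0L, areas = integer(0)),
    class = "nucleus_label_map")

  rng <- range(dna_image)
  if (!all(is.finite(rng)) || rng[2] <= rng[1]) return(empty())
  img01 <- (dna_image - rng[1]) / (rng[2] - rng[1])
  sm <- if (smooth_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(img01),
                                      sigma = smooth_sigma))
  else img01

  if (threshold_method == "otsu") {
    thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  } else {
    if (is.null(threshold))
      stop("threshold_method = 'fixed' requires 'threshold'")
    thr <- (threshold - rng[1]) / (rng[2] - rng[1])
  }
  mask <- sm > thr
  if (!any(mask)) return(empty())
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1)))
  L <- label_components_8(mask > 0)

  if (clear_border) {
    border <- unique(c(L[1, ], L[nrow(L), ], L[, 1], L[, ncol(L)]))
    border <- border[border > 0L]
    if (length(border)) L[L %in% border] <- 0L
  }
  tab <- tabulate(L[L > 0L])
  keep <- which(tab >= min_area)
  if (length(keep) == 0) return(empty())
  relab <- integer(length(tab))
  relab[keep] <- seq_along(keep)
  L[L > 0L] <- relab[L[L > 0L]]
  structure(list(labels = L, n_nuclei = length(keep),
                 areas = tab[keep]),
            class = "nucleus_label_map")
}
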