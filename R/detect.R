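## Scale-normalized Laplacian-of-Gaussian kernel (negated, so blobs give
## positive response). Zero-sum by construction up to truncation; the
## residual mean is removed so the response is invariant to constant
## background.
log_kernel <- function(sigma) {
  half <- ceiling(3.5 * sigma)
  x <- -half:half
  r2 <- outer(x^2, x^2, "+")
  k <- -(r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k <- k * sigma^2          # scale normalization
  k - mean(k)
}

#' Detect centromere foci on a projected reference channel
#'
#' Computes a scale-normalized Laplacian-of-Gaussian response at
#' `log_sigma`, finds local maxima with response at least `min_peak`,
#' enforces a minimum pairwise separation by greedy non-maximum
#' suppression in decreasing response order, refines each peak to
#' subpixel precision by separable parabolic interpolation, and keeps
#' only maxima inside a segmented nucleus.
#'
#' Detection runs on the reference (ACA) channel only; the target channel
#' is later measured at these reference-defined positions, so foci remain
#' detectable even when the target protein is absent.
#'
#' @param ref_image Numeric matrix (row, col), projected reference channel.
#' @param nuclei A `nucleus_label_map` from [segment_nuclei()].
#' @param log_sigma LoG scale in pixels (match the expected spot sd).
#' @param min_peak Minimum LoG response (roughly comparable to spot
#'   amplitude). `NULL` uses a robust data-driven default,
#'   `median(response) + 8 * mad(response)`.
#' @param min_separation Minimum distance between foci, pixels.
#' @return A data frame (class `focus_table`) with columns `row`, `col`
#'   (0-based, subpixel), `nucleus_id`, `response`, `ref_intensity`.
#'   Empty when nothing is detected.
#' @export
detect_foci <- function(ref_image, nuclei, log_sigma = 1.0,
                        min_peak = NULL, min_separation = 3) {
  stopifnot(is.matrix(ref_image), inherits(nuclei, "nucleus_label_map"))
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      nucleus_id = integer(0), response = numeric(0),
                      ref_intensity = numeric(0))
  class(empty) <- c("focus_table", "data.frame")
  if (nuclei$n_nuclei == 0L) return(empty)

  resp <- EBImage::imageData(
    EBImage::filter2(EBImage::Image(ref_image), log_kernel(log_sigma)))
  resp <- matrix(resp, nrow(ref_image), ncol(ref_image))
  if (is.null(min_peak))
    min_peak <- stats::median(resp) + 8 * stats::mad(resp)

  ## candidate peaks: 3x3 local maxima above the response threshold
  mx <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(resp), EBImage::makeBrush(3, "box")))
  cand <- which(resp >= mx - 1e-12 & resp >= min_peak, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)

  ## subpixel refinement by 1-D parabola per axis, clamped to +/- 0.5 px;
  ## refined positions are used for the separation test so that nearby
  ## spots are compared at their true (not rasterized) distance
  refine <- function(i, j) {
    dr <- dc <- 0
    if (i > 1 && i < nrow(resp)) {
      den <- resp[i - 1, j] - 2 * resp[i, j] + resp[i + 1, j]
      if (den < 0) dr <- 0.5 * (resp[i - 1, j] - resp[i + 1, j]) / den
    }
    if (j > 1 && j < ncol(resp)) {
      den <- resp[i, j - 1] - 2 * resp[i, j] + resp[i, j + 1]
      if (den < 0) dc <- 0.5 * (resp[i, j - 1] - resp[i, j + 1]) / den
    }
    c(max(-0.5, min(0.5, dr)), max(-0.5, min(0.5, dc)))
  }
  sub <- t(vapply(seq_len(nrow(cand)),
                  function(k) refine(cand[k, 1], cand[k, 2]), numeric(2)))
  pr <- (cand[, 1] - 1) + sub[, 1]
  pc <- (cand[, 2] - 1) + sub[, 2]

  ## greedy non-maximum suppression, strongest first (position breaks
  ## ties deterministically)
  o <- order(resp[cand], -cand[, 1], -cand[, 2], decreasing = TRUE)
  keep_idx <- integer(0)
  kr <- kc <- numeric(0)
  for (i in o) {
    if (length(kr) == 0 ||
        min((kr - pr[i])^2 + (kc - pc[i])^2) >= min_separation^2) {
      keep_idx <- c(keep_idx, i)
      kr <- c(kr, pr[i]); kc <- c(kc, pc[i])
    }
  }
  keep_idx <- sort(keep_idx)
  cand <- cand[keep_idx, , drop = FALSE]

  nid <- nuclei$labels[cand]
  inside <- nid > 0L
  out <- data.frame(
    row = pr[keep_idx],
    col = pc[keep_idx],
    nucleus_id = as.integer(nid),
    response = resp[cand],
    ref_intensity = ref_image[cand])[inside, , drop = FALSE]
  out <- out[order(out$nucleus_id, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("focus_table", "data.frame")
  out
}
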