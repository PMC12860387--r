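#' Apply an in-silico histology artifact to an RGB image
#'
#' Algorithmic mimics of common H&E slide imperfections, for robustness
#' studies:
#' \itemize{
#'   \item `crack`: a dark random polyline band crossing the tissue; band
#'     width grows with `severity`.
#'   \item `fold`: a band of the image duplicated with a shift and
#'     alpha-blended onto itself (translucent double tissue layer).
#'   \item `stain`: hue/saturation shifts inside random elliptical blobs
#'     (staining irregularities).
#'   \item `crack_fold_stain`: all three, applied crack -> fold -> stain.
#' }
#' Output dimensions equal input dimensions and the result is a pure function
#' of `(image, kind, severity, seed)`.
#'
#' @param image numeric array H x W x 3 with values in `[0,1]`.
#' @param kind one of `"crack"`, `"fold"`, `"stain"`, `"crack_fold_stain"`.
#' @param severity artifact strength in `(0, 1]`.
#' @param seed integer seed.
#' @return perturbed image array of identical dimensions.
#' @export
apply_artifact <- function(image, kind = c("crack", "fold", "stain", "crack_fold_stain"),
                           severity = 0.3, seed = 1) {
  if (is.character(kind) && length(kind) == 1 &&
      !kind %in% c("crack", "fold", "stain", "crack_fold_stain"))
    stop_arg("unknown artifact kind: ", kind)
  kind <- match.arg(kind)
  if (!is.numeric(severity) || severity <= 0 || severity > 1)
    stop_arg("severity must be in (0, 1]")
  if (length(dim(image)) != 3 || dim(image)[3] < 3 || any(dim(image)[1:2] < 1))
    stop_arg("image must be a non-empty H x W x 3 array")
  with_seed(seed, {
    out <- image
    if (kind %in% c("crack", "crack_fold_stain"))
      out <- artifact_crack(out, severity)
    if (kind %in% c("fold", "crack_fold_stain"))
      out <- artifact_fold(out, severity)
    if (kind %in% c("stain", "crack_fold_stain"))
      out <- artifact_stain(out, severity)
    out
  })
}

# dark polyline band from the left to the right edge; width ~ severity
artifact_crack <- function(image, severity) {
  h <- dim(image)[1]; w <- dim(image)[2]
  half <- max(1L, round(severity * 10))
  n_knots <- 6
  kx <- round(seq(1, w, length.out = n_knots))
  ky <- round(stats::runif(n_knots, 0.2 * h, 0.8 * h))
  # piecewise-linear interpolation of the centre line, one y per column
  yline <- stats::approx(kx, ky, xout = seq_len(w))$y
  for (x in seq_len(w)) {
    y0 <- max(1L, round(yline[x]) - half)
    y1 <- min(h, round(yline[x]) + half)
    if (y0 <= y1) image[y0:y1, x, ] <- image[y0:y1, x, ] * 0.15
  }
  image
}

# duplicate a horizontal band shifted downward, alpha-blend (translucent fold)
artifact_fold <- function(image, severity) {
  h <- dim(image)[1]; w <- dim(image)[2]
  band_h <- max(2L, round(severity * 0.25 * h))
  top <- sample.int(max(1L, h - 2L * band_h), 1L)
  shift <- max(1L, round(band_h / 2))
  src <- top:(top + band_h - 1L)
  dst <- pmin(src + shift, h)
  alpha <- 0.55
  image[dst, , ] <- alpha * image[src, , ] * 0.8 + (1 - alpha) * image[dst, , ]
  image
}

# hue/saturation shift inside random elliptical blobs
artifact_stain <- function(image, severity) {
  h <- dim(image)[1]; w <- dim(image)[2]
  n_blobs <- 3L
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- matrix(FALSE, h, w)
  for (b in seq_len(n_blobs)) {
    cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
    rx <- severity * 0.25 * w * stats::runif(1, 0.5, 1)
    ry <- severity * 0.25 * h * stats::runif(1, 0.5, 1)
    mask <- mask | (((cc - cx) / rx)^2 + ((rr - cy) / ry)^2 <= 1)
  }
  if (!any(mask)) return(image)
  idx <- which(mask)
  px <- rbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  hsv_px <- grDevices::rgb2hsv(px, maxColorValue = 1)
  hsv_px[1, ] <- (hsv_px[1, ] + 0.12 * severity / 0.3) %% 1       # hue rotation
  hsv_px[2, ] <- pmin(1, hsv_px[2, ] * (1 + 0.8 * severity))       # saturation boost
  rgb_px <- grDevices::col2rgb(grDevices::hsv(hsv_px[1, ], hsv_px[2, ], hsv_px[3, ])) / 255
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[idx] <- rgb_px[ch, ]
    image[, , ch] <- plane
  }
  image
}
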