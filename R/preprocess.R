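#' Preprocessing configuration
#'
#' Parameters of the T2-style preprocessing chain: bias-field correction
#' surrogate, resampling to a target voxel spacing, brain masking, within-mask
#' z-score normalisation and center crop/zero-pad framing to the network
#' input size.
#'
#' @param target_spacing_mm voxel spacing after resampling (mm), default
#'   1 x 1 x 3.
#' @param input_size network input frame in voxels; the full-size default is
#'   c(96, 192, 192) (desk-scale work uses smaller frames).
#' @param bias_smooth_mm Gaussian smoothing scale (mm) of the bias-field
#'   estimator.
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(target_spacing_mm = c(1, 1, 3),
                              input_size = c(96, 192, 192),
                              bias_smooth_mm = 30) {
  stopifnot(all(target_spacing_mm > 0), all(input_size > 0))
  structure(list(target_spacing_mm = as.numeric(target_spacing_mm),
                 input_size = as.integer(input_size),
                 bias_smooth_mm = bias_smooth_mm),
            class = "preprocess_config")
}

# Separable truncated-Gaussian smoothing of a 3D array, sigma in voxels
# per axis. Dense per-axis smoothing matrices (rows renormalised, which
# extrapolates sensibly at the borders).
gauss_smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    K <- exp(-0.5 * (outer(seq_len(n), seq_len(n), "-") / s)^2)
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dim(m) <- c(n, prod(d[-ax]))
    m <- K %*% m
    dim(m) <- d[perm]
    arr <- aperm(m, order(perm))
  }
  arr
}

#' Bias-field correction surrogate
#'
#' Estimates the low-frequency multiplicative intensity non-uniformity by
#' heavy Gaussian smoothing of the log-intensity within the brain mask
#' (mask-weighted, so the field extrapolates smoothly outside), divides it
#' out, and rescales so the mean intensity inside the mask is preserved.
#'
#' Because one smoothing pass attenuates the very field it estimates, the
#' estimate-and-divide step is iterated (as full bias-field correctors do);
#' each iteration removes the same fraction of the remaining
#' non-uniformity.
#'
#' @param vol an \code{image_volume} with positive intensities inside the
#'   mask.
#' @param brain binary brain mask (\code{image_volume}/\code{tumor_mask}).
#' @param bias_smooth_mm smoothing scale of the field estimate (mm).
#' @param n_iter estimate-and-divide iterations (default 6).
#' @return A bias-corrected \code{image_volume}.
#' @export
correct_bias <- function(vol, brain, bias_smooth_mm = 30, n_iter = 6) {
  stopifnot(inherits(vol, "image_volume"), same_geometry(vol, brain))
  m <- brain$voxels > 0
  if (any(vol$voxels[m] <= 0))
    stop("nonpositive intensities inside the mask: log-domain bias ",
         "estimation undefined")
  sigma <- bias_smooth_mm / vol$spacing
  den <- gauss_smooth3d(array(as.numeric(m), dim(vol$voxels)), sigma)
  den <- pmax(den, 1e-12)
  out <- vol$voxels
  for (it in seq_len(n_iter)) {
    logI <- array(0, dim(out))
    logI[m] <- log(out[m])
    sm <- gauss_smooth3d(logI, sigma) / den
    field <- exp(sm - mean(sm[m]))
    out <- out / field
  }
  out <- out * (mean(vol$voxels[m]) / mean(out[m]))
  image_volume(out, vol$spacing, vol$origin)
}

#' Resample a volume to a target spacing
#'
#' Trilinear interpolation onto a grid with the target voxel spacing whose
#' physical extent matches the input within one voxel. Returns the input
#' unchanged when the spacing already matches.
#'
#' @param vol an \code{image_volume}.
#' @param target_spacing_mm length-3 positive spacing.
#' @return A resampled \code{image_volume}.
#' @export
resample <- function(vol, target_spacing_mm) {
  stopifnot(inherits(vol, "image_volume"))
  target <- as.numeric(target_spacing_mm)
  if (any(target <= 0)) stop("target spacing must be positive")
  d <- dim(vol$voxels)
  if (any(d < 1) || prod(d) == 0) stop("degenerate (zero-extent) volume")
  if (isTRUE(all.equal(vol$spacing, target, tolerance = 1e-10)))
    return(vol)
  extent <- d * vol$spacing
  nd <- pmax(1L, as.integer(round(extent / target)))
  # continuous source index (voxel-center aligned) for each output center
  src <- lapply(1:3, function(ax) {
    ((seq_len(nd[ax]) - 0.5) * target[ax]) / vol$spacing[ax] + 0.5
  })
  out <- trilinear_sample(vol$voxels, src[[1]], src[[2]], src[[3]])
  image_volume(out, target, vol$origin)
}

# Sample arr at the grid outer(fx, fy, fz) of continuous 1-based indices.
trilinear_sample <- function(arr, fx, fy, fz) {
  d <- dim(arr)
  cl <- function(f, n) pmin(pmax(f, 1), n)
  fx <- cl(fx, d[1]); fy <- cl(fy, d[2]); fz <- cl(fz, d[3])
  i0 <- pmin(floor(fx), d[1] - 1); wx <- fx - i0
  j0 <- pmin(floor(fy), d[2] - 1); wy <- fy - j0
  k0 <- pmin(floor(fz), d[3] - 1); wz <- fz - k0
  if (d[1] == 1) { i0 <- rep(1, length(fx)); wx <- rep(0, length(fx)) }
  if (d[2] == 1) { j0 <- rep(1, length(fy)); wy <- rep(0, length(fy)) }
  if (d[3] == 1) { k0 <- rep(1, length(fz)); wz <- rep(0, length(fz)) }
  nd <- c(length(fx), length(fy), length(fz))
  I0 <- array(i0, nd); WX <- array(wx, nd)
  J0 <- array(rep(j0, each = nd[1]), nd)
  WY <- array(rep(wy, each = nd[1]), nd)
  K0 <- array(rep(k0, each = nd[1] * nd[2]), nd)
  WZ <- array(rep(wz, each = nd[1] * nd[2]), nd)
  at <- function(di, dj, dk)
    arr[cbind(c(I0 + di), c(J0 + dj), c(K0 + dk))]
  out <- (1 - WX) * (1 - WY) * (1 - WZ) * at(0, 0, 0) +
    WX * (1 - WY) * (1 - WZ) * at(1, 0, 0) +
    (1 - WX) * WY * (1 - WZ) * at(0, 1, 0) +
    WX * WY * (1 - WZ) * at(1, 1, 0) +
    (1 - WX) * (1 - WY) * WZ * at(0, 0, 1) +
    WX * (1 - WY) * WZ * at(1, 0, 1) +
    (1 - WX) * WY * WZ * at(0, 1, 1) +
    WX * WY * WZ * at(1, 1, 1)
  array(out, nd)
}

#' Brain-mask extraction surrogate
#'
#' Otsu thresholding followed by largest 6-connected component and interior
#' hole filling. Intended for phantoms; an externally computed mask (e.g.
#' from a dedicated skull-stripping tool) is passed through unchanged.
#'
#' @param vol an \code{image_volume}.
#' @param external optional precomputed mask, returned as-is.
#' @return A binary brain mask (\code{tumor_mask}-classed volume).
#' @export
extract_brain <- function(vol, external = NULL) {
  if (!is.null(external)) return(external)
  v <- vol$voxels
  thr <- otsu_threshold(v)
  fg <- v > thr
  if (!any(fg)) stop("empty foreground: no brain voxels above threshold")
  d <- dim(v)
  comp <- largest_component3d(as.integer(fg), as.integer(d))
  filled <- fill_holes3d(comp, as.integer(d))
  tumor_mask(array(as.numeric(filled), d), vol$spacing, vol$origin)
}

# Otsu's threshold on a 256-bin histogram (maximise between-class variance).
otsu_threshold <- function(v) {
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = 257)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (br[-1] + br[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[256]
  sigma_b <- (muT * w0 - mu)^2 / pmax(w0 * (1 - w0), 1e-12)
  mids[which.max(sigma_b[-256])]
}

#' Normalise intensities and frame to the network input size
#'
#' Z-scores intensities with the within-mask mean and standard deviation,
#' zeroes the background, and center-crops or zero-pads to
#' \code{input_size}, centered on the brain-mask centroid.
#'
#' @param vol an \code{image_volume}.
#' @param brain binary brain mask.
#' @param input_size integer triple.
#' @return A framed \code{image_volume}; the framing used is attached as
#'   attribute \code{"frame"} so it can be re-applied to masks with
#'   \code{\link{frame_like}}.
#' @export
normalize_and_frame <- function(vol, brain, input_size) {
  stopifnot(same_geometry(vol, brain))
  m <- brain$voxels > 0
  if (!any(m)) stop("empty brain mask")
  mu <- mean(vol$voxels[m])
  sd_ <- stats::sd(vol$voxels[m])
  if (!is.finite(sd_) || sd_ == 0)
    stop("zero within-mask variance: cannot z-score")
  v <- (vol$voxels - mu) / sd_
  v[!m] <- 0
  idx <- which(m, arr.ind = TRUE)
  centroid <- round(colMeans(idx))
  frame <- list(center = centroid, size = as.integer(input_size))
  out <- apply_frame(v, frame)
  res <- image_volume(out, vol$spacing, vol$origin)
  attr(res, "frame") <- frame
  res
}

# Crop/zero-pad `arr` to frame$size about frame$center.
apply_frame <- function(arr, frame) {
  d <- dim(arr)
  size <- frame$size
  out <- array(0, size)
  lo_src <- frame$center - floor((size - 1) / 2)
  hi_src <- lo_src + size - 1
  s0 <- pmax(lo_src, 1); s1 <- pmin(hi_src, d)
  t0 <- s0 - lo_src + 1; t1 <- t0 + (s1 - s0)
  if (all(s1 >= s0))
    out[t0[1]:t1[1], t0[2]:t1[2], t0[3]:t1[3]] <-
      arr[s0[1]:s1[1], s0[2]:s1[2], s0[3]:s1[3]]
  out
}

#' @rdname normalize_and_frame
#' @param target volume (or mask) to frame identically to a framed volume.
#' @param framed a volume returned by \code{normalize_and_frame}.
#' @export
frame_like <- function(target, framed) {
  frame <- attr(framed, "frame")
  if (is.null(frame)) stop("'framed' carries no frame attribute")
  out <- apply_frame(target$voxels, frame)
  if (inherits(target, "tumor_mask"))
    tumor_mask(out, target$spacing, target$origin)
  else image_volume(out, target$spacing, target$origin)
}

#' Full preprocessing chain for one subject
#'
#' bias correction -> resampling -> brain masking -> normalisation/framing.
#' For phantom input the tumor mask, if supplied, is resampled
#' (nearest-equivalent via trilinear + 0.5 threshold) and framed identically.
#'
#' @param vol an \code{image_volume}.
#' @param config a \code{\link{preprocess_config}}.
#' @param mask optional tumor mask to carry through the same geometry.
#' @param brain optional externally supplied brain mask.
#' @return list(volume, mask, brain): framed network-ready arrays.
#' @export
preprocess_volume <- function(vol, config, mask = NULL, brain = NULL) {
  vol <- resample(vol, config$target_spacing_mm)
  if (!is.null(mask)) {
    mk <- resample(image_volume(mask$voxels, mask$spacing, mask$origin),
                   config$target_spacing_mm)
    mask <- tumor_mask(array(as.numeric(mk$voxels >= 0.5), dim(mk$voxels)),
                       mk$spacing, mk$origin)
  }
  brain <- extract_brain(vol, external = brain)
  # shift intensities if needed so the log-domain bias estimate is defined
  off <- min(vol$voxels[brain$voxels > 0])
  if (off <= 0)
    vol$voxels <- vol$voxels + (1 - off)
  vol <- correct_bias(vol, brain, config$bias_smooth_mm)
  framed <- normalize_and_frame(vol, brain, config$input_size)
  out_mask <- if (!is.null(mask)) frame_like(mask, framed) else NULL
  out_brain <- frame_like(brain, framed)
  list(volume = framed, mask = out_mask, brain = out_brain)
}
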