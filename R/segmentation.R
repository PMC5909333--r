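#' Rasterise the myocardial annulus from endo/epicardial contours
#'
#' A pixel is myocardial iff its centre lies inside the epicardial polygon
#' and outside the endocardial one (even-odd rule, pixel-centre convention).
#'
#' @param contours A [contour_set()] with `endo` and `epi` for every slice.
#' @param dim Spatial dimensions `c(rows, cols, slices)`.
#' @param spacing_mm Pixel spacing `c(row, col)` in mm.
#' @return Logical `rows x cols x slices` array.
#' @export
myocardium_mask <- function(contours, dim, spacing_mm) {
  stopifnot(inherits(contours, "contour_set"))
  if (length(contours$slices) != dim[3])
    stop("input error: contour set has ", length(contours$slices),
         " slice(s) but the series has ", dim[3], call. = FALSE)
  out <- array(FALSE, dim)
  for (s in seq_len(dim[3])) {
    sl <- contours$slices[[s]]
    if (is.null(sl$endo) || is.null(sl$epi))
      stop("input error: slice ", s, " is missing an endo or epi contour",
           call. = FALSE)
    out[, , s] <- rasterize_polygon(sl$epi, dim[1:2], spacing_mm) &
      !rasterize_polygon(sl$endo, dim[1:2], spacing_mm)
  }
  out
}

#' Remote-myocardium reference statistics
#'
#' Sample mean and SD of signal intensity over the remote region of
#' interest. The ROI must contain at least 100 pixels — a hard requirement
#' of the thresholding protocol, not a warning.
#'
#' @param image Numeric matrix or array of signal intensities.
#' @param remote_mask Logical mask of the same shape.
#' @param min_pixels Minimum ROI size (default 100).
#' @return List with `mean`, `sd`, `n`.
#' @export
remote_stats <- function(image, remote_mask, min_pixels = 100L) {
  if (!identical(dim(image), dim(remote_mask)))
    stop("geometry error: image and remote mask shapes disagree", call. = FALSE)
  vals <- image[remote_mask]
  if (length(vals) < min_pixels)
    stop("validation error: remote ROI has ", length(vals),
         " pixels; at least ", min_pixels, " are required", call. = FALSE)
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}

#' n-SD enhancement threshold
#'
#' Threshold for infarct delineation: remote mean plus `k` remote standard
#' deviations, with the protocol default `k = 5`.
#'
#' @param mean Remote mean signal (a.u.).
#' @param sd Remote signal SD (a.u., >= 0).
#' @param k SD multiplier (> 0).
#' @return Threshold in a.u.
#' @export
enhancement_threshold <- function(mean, sd, k = 5) {
  if (sd < 0) stop("input error: sd must be non-negative", call. = FALSE)
  if (k <= 0) stop("input error: k must be positive", call. = FALSE)
  mean + k * sd
}

#' Classify enhanced (infarct) pixels
#'
#' A myocardial pixel is enhanced iff its signal is strictly over the
#' threshold; pixels exactly at the threshold are not enhanced.
#'
#' @param image Numeric matrix/array of signal intensities.
#' @param myo_mask Logical myocardium mask of the same shape.
#' @param threshold Scalar threshold (a.u.).
#' @return Logical mask of enhanced pixels.
#' @export
classify_enhanced <- function(image, myo_mask, threshold) {
  if (!identical(dim(image), dim(myo_mask)))
    stop("geometry error: image and myocardium mask shapes disagree",
         call. = FALSE)
  myo_mask & image > threshold
}

# 8-neighbour shifts
eight_shifts <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                      dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

shift_matrix <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Detect the no-flow core of an infarct (one slice)
#'
#' The no-flow (NF) core is a hypo-enhanced island fully enclosed in-plane
#' by enhanced infarct. Sub-threshold myocardial pixels are labelled into
#' 4-connected components; components that touch each other diagonally are
#' treated as one island (the standard foreground/background connectivity
#' duality — an isolated supra-threshold noise pixel may split an enclosed
#' core into diagonally adjacent halves without opening it). An island is
#' NF iff none of its pixels has an 8-neighbour outside the myocardium (or
#' outside the image): every surrounding in-myocardium pixel is then
#' enhanced, i.e. the island is sealed by infarct rim. Islands reaching the
#' endo/epicardial border are remote myocardium, not an enclosed core. An
#' empty result is valid — not every infarct has a no-flow core.
#'
#' @param image Numeric matrix (one slice).
#' @param myo_mask Logical myocardium mask (same shape).
#' @param enhanced_mask Logical enhanced mask, subset of `myo_mask`.
#' @param threshold Threshold used for `enhanced_mask` (pixels at or below
#'   it count as sub-threshold).
#' @return Logical NF mask.
#' @export
detect_nf <- function(image, myo_mask, enhanced_mask, threshold) {
  stopifnot(is.matrix(image))
  if (any(enhanced_mask & !myo_mask))
    stop("input error: enhanced mask extends outside the myocardium",
         call. = FALSE)
  sub <- myo_mask & image <= threshold
  if (!any(sub)) return(sub)
  lab <- as.matrix(EBImage::bwlabel(sub * 1))
  n_lab <- max(lab)
  # union-find: merge 4-components that touch diagonally into one island
  parent <- seq_len(n_lab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  diag_shifts <- eight_shifts[abs(eight_shifts[, 1]) +
                                abs(eight_shifts[, 2]) == 2L, , drop = FALSE]
  for (i in seq_len(nrow(diag_shifts))) {
    nb <- shift_matrix(lab, diag_shifts[i, 1], diag_shifts[i, 2], 0L)
    pair <- sub & nb > 0L & nb != lab
    if (any(pair)) {
      pairs <- unique(cbind(lab[pair], nb[pair]))
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  root <- vapply(seq_len(n_lab), find, integer(1))
  # an island is disqualified if any member pixel touches non-myocardium
  # (8-neighbourhood) or the image border
  bad_root <- logical(n_lab)
  border <- matrix(FALSE, nrow(sub), ncol(sub))
  border[c(1, nrow(sub)), ] <- TRUE; border[, c(1, ncol(sub))] <- TRUE
  touch <- sub & border
  for (i in seq_len(nrow(eight_shifts))) {
    nb_myo <- shift_matrix(myo_mask, eight_shifts[i, 1],
                           eight_shifts[i, 2], FALSE)
    touch <- touch | (sub & !nb_myo)
  }
  if (any(touch)) bad_root[unique(root[lab[touch]])] <- TRUE
  good <- which(!bad_root[root])
  out <- matrix(FALSE, nrow(image), ncol(image))
  if (length(good)) out[lab %in% good] <- TRUE
  out
}

#' Rasterise a manually drawn no-flow contour
#'
#' Alternate path honouring a drawn NF contour instead of automatic
#' detection: the NF mask is every myocardial pixel whose centre lies inside
#' the traced polygon. Overlap with enhanced pixels is resolved in favour of
#' the NF (the enhanced mask should be clipped accordingly), mirroring the
#' convention that the traced core is included in the infarct as NF.
#'
#' @param contours A [contour_set()] whose slices carry `nf` polygons
#'   (slices without one yield empty masks).
#' @param dim Spatial dimensions `c(rows, cols, slices)`.
#' @param spacing_mm Pixel spacing `c(row, col)` in mm.
#' @param myo_mask Logical myocardium array; the result is clipped to it.
#' @return Logical `rows x cols x slices` NF array.
#' @export
nf_from_manual_contour <- function(contours, dim, spacing_mm, myo_mask) {
  stopifnot(inherits(contours, "contour_set"))
  out <- array(FALSE, dim)
  for (s in seq_len(dim[3])) {
    poly <- contours$slices[[s]]$nf
    if (!is.null(poly))
      out[, , s] <- rasterize_polygon(poly, dim[1:2], spacing_mm) &
        myo_mask[, , s]
  }
  out
}

#' Assemble and validate region masks
#'
#' Enforces the mask algebra on construction: enhanced and NF are disjoint
#' subsets of the myocardium, the total infarct is their union, and the
#' remote ROI (>= 100 pixels per slice) does not intersect the infarct.
#' Manual NF masks take precedence over overlapping enhanced pixels (the
#' overlap is clipped out of `enhanced` with a warning).
#'
#' @param myocardium,remote,enhanced,nf Logical `rows x cols x slices`
#'   arrays.
#' @param remote_mean,remote_sd,threshold Per-slice numeric vectors (a.u.).
#' @param clip_enhanced Clip `enhanced` where it overlaps `nf` (manual-
#'   contour path) instead of failing.
#' @return An object of class `region_masks` with elements `myocardium`,
#'   `remote`, `enhanced`, `nf`, `total_mi`, `remote_mean`, `remote_sd`,
#'   `threshold`.
#' @export
assemble_masks <- function(myocardium, remote, enhanced, nf,
                           remote_mean, remote_sd, threshold,
                           clip_enhanced = FALSE) {
  dims <- dim(myocardium)
  for (m in list(remote, enhanced, nf))
    if (!identical(dim(m), dims))
      stop("assembly error: mask shapes disagree", call. = FALSE)
  if (any(enhanced & !myocardium))
    stop("assembly error: invariant violated: enhanced subset of myocardium",
         call. = FALSE)
  if (any(nf & !myocardium))
    stop("assembly error: invariant violated: nf subset of myocardium",
         call. = FALSE)
  if (any(enhanced & nf)) {
    if (clip_enhanced) {
      warning("manual NF contour overlaps ", sum(enhanced & nf),
              " enhanced pixel(s); overlap assigned to NF", call. = FALSE)
      enhanced <- enhanced & !nf
    } else {
      stop("assembly error: invariant violated: enhanced and nf disjoint",
           call. = FALSE)
    }
  }
  total_mi <- enhanced | nf
  if (any(remote & total_mi))
    stop("assembly error: invariant violated: remote disjoint from total_mi",
         call. = FALSE)
  per_slice_n <- apply(remote, 3, sum)
  if (any(per_slice_n < 100L))
    stop("assembly error: invariant violated: remote ROI >= 100 pixels per slice",
         call. = FALSE)
  n_sl <- dims[3]
  stopifnot(length(remote_mean) == n_sl, length(remote_sd) == n_sl,
            length(threshold) == n_sl)
  structure(list(myocardium = myocardium, remote = remote,
                 enhanced = enhanced, nf = nf, total_mi = total_mi,
                 remote_mean = remote_mean, remote_sd = remote_sd,
                 threshold = threshold),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat("<region_masks>", dim(x$myocardium)[3], "slice(s)\n")
  cat(sprintf("  myocardium %d px | enhanced %d px | nf %d px | total MI %d px\n",
              sum(x$myocardium), sum(x$enhanced), sum(x$nf), sum(x$total_mi)))
  invisible(x)
}

#' Segment an IR gadolinium-enhanced series
#'
#' Full threshold-based delineation of one series: myocardium from the
#' endo/epicardial contours, per-slice remote statistics and
#' `mean + k * SD` threshold, strict-over-threshold enhanced classification,
#' and either automatic enclosed-core NF detection or the manually traced
#' NF contour. The threshold is computed per slice because inversion nulling
#' and coil shading vary across slices.
#'
#' @param series An [image_series()] of kind `"ir-lge"`.
#' @param contours A [contour_set()] with `endo`, `epi`, `remote` (and `nf`
#'   when `manual_nf = TRUE`) per slice.
#' @param k Threshold SD multiplier (default 5).
#' @param manual_nf Use the traced NF contour instead of automatic
#'   detection.
#' @return A [assemble_masks()] `region_masks` object.
#' @export
segment_series <- function(series, contours, k = 5, manual_nf = FALSE) {
  stopifnot(inherits(series, "image_series"))
  if (series$kind != "ir-lge")
    stop("input error: segmentation expects an ir-lge series", call. = FALSE)
  dims <- dim(series$voxels)
  myo <- myocardium_mask(contours, dims, series$pixel_spacing_mm)
  n_sl <- dims[3]
  remote <- array(FALSE, dims)
  enhanced <- array(FALSE, dims)
  nf <- array(FALSE, dims)
  rm_mean <- rm_sd <- thr <- numeric(n_sl)
  for (s in seq_len(n_sl)) {
    rp <- contours$slices[[s]]$remote
    if (is.null(rp))
      stop("input error: slice ", s, " is missing a remote contour",
           call. = FALSE)
    img <- series$voxels[, , s]
    rmask <- rasterize_polygon(rp, dims[1:2], series$pixel_spacing_mm) &
      myo[, , s]
    st <- remote_stats(img, rmask)
    thr[s] <- enhancement_threshold(st$mean, st$sd, k)
    rm_mean[s] <- st$mean; rm_sd[s] <- st$sd
    remote[, , s] <- rmask
    enhanced[, , s] <- classify_enhanced(img, myo[, , s], thr[s])
    if (!manual_nf)
      nf[, , s] <- detect_nf(img, myo[, , s], enhanced[, , s], thr[s])
  }
  if (manual_nf)
    nf <- nf_from_manual_contour(contours, dims, series$pixel_spacing_mm, myo)
  # remote ROI pixels above threshold (noise spikes) would violate the
  # remote/total-MI disjointness invariant; they are not infarct
  enhanced[remote] <- FALSE
  assemble_masks(myo, remote, enhanced, nf, rm_mean, rm_sd, thr,
                 clip_enhanced = manual_nf)
}
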