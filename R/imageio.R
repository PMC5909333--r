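#' Construct an image series
#'
#' Container for one short-axis stack: either a multi-echo T2-weighted
#' series (4-D voxels, `row x col x slice x echo`) or a single
#' inversion-recovery gadolinium-enhanced series (3-D voxels,
#' `row x col x slice`). Geometry metadata travels with the voxels and is
#' validated on construction.
#'
#' @param voxels Numeric array, 3-D (`ir-lge`) or 4-D (`t2-multi-echo`).
#' @param pixel_spacing_mm In-plane spacing `c(row, col)` in mm (> 0).
#'   The default study geometry (300 mm field of view, 256 matrix) gives
#'   300/256 = 1.171875 mm.
#' @param slice_thickness_mm Slice thickness in mm (> 0).
#' @param kind `"t2-multi-echo"` or `"ir-lge"`.
#' @param echo_times_ms Strictly increasing echo times (ms); required for
#'   `kind = "t2-multi-echo"`, length equal to the 4th voxel dimension.
#' @param ti_ms Inversion time (ms); required for `kind = "ir-lge"`.
#' @param post_contrast_min Minutes after contrast injection; required for
#'   `kind = "ir-lge"`.
#' @return An object of class `image_series`.
#' @export
image_series <- function(voxels, pixel_spacing_mm, slice_thickness_mm,
                         kind = c("t2-multi-echo", "ir-lge"),
                         echo_times_ms = NULL, ti_ms = NULL,
                         post_contrast_min = NULL) {
  kind <- match.arg(kind)
  if (any(pixel_spacing_mm <= 0) || slice_thickness_mm <= 0)
    stop("geometry error: pixel spacing and slice thickness must be positive",
         call. = FALSE)
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  nd <- length(dim(voxels))
  if (kind == "t2-multi-echo") {
    if (nd != 4L)
      stop("format error: t2-multi-echo series must be 4-D (row, col, slice, echo)",
           call. = FALSE)
    if (is.null(echo_times_ms))
      stop("format error: t2-multi-echo series requires echo_times_ms",
           call. = FALSE)
    if (length(echo_times_ms) != dim(voxels)[4])
      stop("format error: echo_times_ms length must match 4th voxel dimension",
           call. = FALSE)
    if (any(diff(echo_times_ms) <= 0))
      stop("format error: echo times must be strictly increasing", call. = FALSE)
  } else {
    if (nd != 3L)
      stop("format error: ir-lge series must be 3-D (row, col, slice)",
           call. = FALSE)
    if (is.null(ti_ms) || is.null(post_contrast_min))
      stop("format error: ir-lge series requires ti_ms and post_contrast_min",
           call. = FALSE)
    if (ti_ms <= 0) stop("format error: ti_ms must be positive", call. = FALSE)
  }
  structure(list(voxels = voxels,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 kind = kind,
                 echo_times_ms = echo_times_ms,
                 ti_ms = ti_ms,
                 post_contrast_min = post_contrast_min),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<image_series> kind:", x$kind, "\n")
  cat("  voxels:", paste(d, collapse = " x "),
      sprintf("| spacing %.6g x %.6g mm | slice %.6g mm\n",
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm))
  if (x$kind == "t2-multi-echo")
    cat("  echoes (ms):", paste(x$echo_times_ms, collapse = ", "), "\n")
  else
    cat(sprintf("  TI %.4g ms at %g min post contrast\n",
                x$ti_ms, x$post_contrast_min))
  invisible(x)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write an image series to NIfTI + sidecar JSON
#'
#' Voxels go to a NIfTI file; acquisition metadata NIfTI cannot carry (series
#' kind, echo times or TI / post-contrast minute) goes to a sidecar `.json`
#' next to it. The round trip through [read_series()] is lossless.
#'
#' @param series An [image_series()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  img <- RNifti::asNifti(series$voxels)
  nd <- length(dim(series$voxels))
  pd <- c(series$pixel_spacing_mm[1], series$pixel_spacing_mm[2],
          series$slice_thickness_mm)
  if (nd == 4L) pd <- c(pd, 1)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  meta <- list(kind = series$kind,
               pixel_spacing_mm = series$pixel_spacing_mm,
               slice_thickness_mm = series$slice_thickness_mm,
               echo_times_ms = series$echo_times_ms,
               ti_ms = series$ti_ms,
               post_contrast_min = series$post_contrast_min)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image series written by [write_series()]
#'
#' @param path NIfTI path; the sidecar JSON must sit next to it.
#' @return An [image_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("format error: missing sidecar metadata ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  pd <- RNifti::pixdim(img)
  if (!is.null(meta$pixel_spacing_mm) &&
      any(abs(pd[1:2] - meta$pixel_spacing_mm) > 1e-4))
    stop("geometry error: NIfTI pixdim disagrees with sidecar pixel spacing",
         call. = FALSE)
  image_series(vox,
               pixel_spacing_mm = meta$pixel_spacing_mm,
               slice_thickness_mm = meta$slice_thickness_mm,
               kind = meta$kind,
               echo_times_ms = meta$echo_times_ms,
               ti_ms = meta$ti_ms,
               post_contrast_min = meta$post_contrast_min)
}

#' Construct a contour set
#'
#' Per-slice named polygons in millimetre world coordinates (pixel-centre
#' convention, origin at the image corner): `endo` and `epi` delineate the
#' left-ventricular myocardium, `remote` the reference region of normal
#' myocardium, and the optional `nf` a manually traced no-flow core.
#'
#' @param slices List (one element per slice) of named lists of `n x 2`
#'   vertex matrices. Names among `endo`, `epi`, `remote`, `nf`.
#' @param validate Check polygon simplicity and endo-inside-epi nesting.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(slices, validate = TRUE) {
  stopifnot(is.list(slices), length(slices) >= 1L)
  if (validate) {
    for (s in seq_along(slices)) {
      for (nm in names(slices[[s]])) {
        poly <- slices[[s]][[nm]]
        if (is.null(poly)) next
        if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3)
          stop(sprintf("validation error: slice %d contour '%s' is not an n x 2 matrix",
                       s, nm), call. = FALSE)
        if (!polygon_is_simple(poly))
          stop(sprintf("validation error: slice %d contour '%s' is self-intersecting",
                       s, nm), call. = FALSE)
      }
      if (!is.null(slices[[s]]$endo) && !is.null(slices[[s]]$epi) &&
          !polygon_inside(slices[[s]]$endo, slices[[s]]$epi))
        stop(sprintf("validation error: slice %d endocardial contour not inside epicardial contour",
                     s), call. = FALSE)
    }
  }
  structure(list(slices = slices), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat("<contour_set>", length(x$slices), "slice(s)\n")
  for (s in seq_along(x$slices))
    cat("  slice", s, ":", paste(names(x$slices[[s]]), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read contour sets as JSON
#'
#' Schema: `{"slices": [{"endo": [[x, y], ...], "epi": ..., ...}, ...]}` with
#' vertices in mm. Round trip is lossless.
#'
#' @param cs A [contour_set()].
#' @param path JSON file path.
#' @return `path` invisibly (write) or a `contour_set` (read).
#' @export
write_contours <- function(cs, path) {
  stopifnot(inherits(cs, "contour_set"))
  payload <- list(slices = lapply(cs$slices, function(sl)
    lapply(sl, function(p) unname(apply(p, 1, function(v) v, simplify = FALSE)))))
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  slices <- lapply(payload$slices, function(sl)
    lapply(sl, function(p)
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))))
  contour_set(slices)
}
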