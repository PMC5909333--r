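#' Volume of a voxel mask
#'
#' Pixel counting times voxel size: `sum(mask) * row_spacing * col_spacing *
#' slice_thickness / 1000` millilitres.
#'
#' @param mask Logical matrix or array.
#' @param pixel_spacing_mm Spacing `c(row, col)` in mm (> 0).
#' @param slice_thickness_mm Slice thickness in mm (> 0).
#' @return Volume in ml.
#' @export
mask_volume <- function(mask, pixel_spacing_mm, slice_thickness_mm) {
  if (any(pixel_spacing_mm <= 0) || slice_thickness_mm <= 0)
    stop("input error: spacing and thickness must be positive", call. = FALSE)
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  sum(mask) * pixel_spacing_mm[1] * pixel_spacing_mm[2] *
    slice_thickness_mm / 1000
}

#' Left-ventricular myocardial mass
#'
#' Myocardial volume times the specific gravity of myocardium,
#' 1.05 g/ml.
#'
#' @param myo_volume_ml Myocardial volume in ml (>= 0).
#' @return Mass in grams.
#' @export
lv_mass <- function(myo_volume_ml) {
  if (any(myo_volume_ml < 0))
    stop("input error: volume must be non-negative", call. = FALSE)
  myo_volume_ml * 1.05
}

#' Infarct and no-flow fractions
#'
#' The infarct fraction (MIF) and no-flow fraction (NFF) normalised to the
#' left ventricle, and NF as a percentage of the infarct. The `%LVM`
#' quantities are computed on a volume basis — the denominator is the
#' myocardial volume `lvm_g / 1.05` — so numerator and denominator share
#' units; the literal ml-per-gram ratio differs from these by the constant
#' factor 1.05 and is returned alongside.
#'
#' @param mi_ml Total infarct volume (ml).
#' @param nf_ml No-flow volume (ml, `nf_ml <= mi_ml`).
#' @param lvm_g Left-ventricular mass (g, > 0).
#' @return List with `mif_pct_lvm`, `nff_pct_lvm`, `nff_pct_mi` (NA when
#'   `mi_ml` is 0), and the ml/g variants `mif_pct_lvm_mlg`,
#'   `nff_pct_lvm_mlg`.
#' @export
fractions <- function(mi_ml, nf_ml, lvm_g) {
  if (lvm_g <= 0) stop("input error: lvm_g must be positive", call. = FALSE)
  if (mi_ml == 0 && nf_ml > 0)
    stop("invariant error: nf volume positive while mi volume is zero",
         call. = FALSE)
  if (nf_ml > mi_ml + 1e-9)
    stop("invariant error: nf volume exceeds mi volume", call. = FALSE)
  myo_ml <- lvm_g / 1.05
  list(mif_pct_lvm = 100 * mi_ml / myo_ml,
       nff_pct_lvm = 100 * nf_ml / myo_ml,
       nff_pct_mi = if (mi_ml > 0) 100 * nf_ml / mi_ml else NA_real_,
       mif_pct_lvm_mlg = 100 * mi_ml / lvm_g,
       nff_pct_lvm_mlg = 100 * nf_ml / lvm_g)
}

#' Quantify segmented region masks
#'
#' Converts a [segment_series()] result into the study metrics: myocardial
#' volume and mass, total infarct and no-flow volumes, and the normalised
#' fractions, with a per-slice breakdown.
#'
#' @param masks A `region_masks` object.
#' @param pixel_spacing_mm Spacing `c(row, col)` in mm.
#' @param slice_thickness_mm Slice thickness in mm.
#' @return An object of class `quant_result`: a list of the global metrics
#'   plus `per_slice`, a data frame with per-slice volumes (ml).
#' @export
quantify_masks <- function(masks, pixel_spacing_mm, slice_thickness_mm) {
  stopifnot(inherits(masks, "region_masks"))
  n_sl <- dim(masks$myocardium)[3]
  vol <- function(m) mask_volume(m, pixel_spacing_mm, slice_thickness_mm)
  per_slice <- data.frame(
    slice = seq_len(n_sl),
    myocardium_ml = vapply(seq_len(n_sl), function(s)
      vol(masks$myocardium[, , s]), numeric(1)),
    enhanced_ml = vapply(seq_len(n_sl), function(s)
      vol(masks$enhanced[, , s]), numeric(1)),
    nf_ml = vapply(seq_len(n_sl), function(s)
      vol(masks$nf[, , s]), numeric(1)),
    total_mi_ml = vapply(seq_len(n_sl), function(s)
      vol(masks$total_mi[, , s]), numeric(1)),
    remote_mean_au = masks$remote_mean,
    remote_sd_au = masks$remote_sd,
    threshold_au = masks$threshold)
  myo_ml <- sum(per_slice$myocardium_ml)
  mi_ml <- sum(per_slice$total_mi_ml)
  nf_ml <- sum(per_slice$nf_ml)
  lvm_g <- lv_mass(myo_ml)
  fr <- fractions(mi_ml, nf_ml, lvm_g)
  structure(c(list(lv_myocardial_volume_ml = myo_ml,
                   lvm_g = lvm_g,
                   mi_volume_ml = mi_ml,
                   nf_volume_ml = nf_ml),
              fr,
              list(per_slice = per_slice)),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result>\n")
  cat(sprintf("  LV myocardium %.2f ml (LVM %.2f g)\n",
              x$lv_myocardial_volume_ml, x$lvm_g))
  cat(sprintf("  MI %.2f ml (MIF %.1f %%LVM) | NF %.2f ml (NFF %.1f %%LVM, %.1f %%MI)\n",
              x$mi_volume_ml, x$mif_pct_lvm, x$nf_volume_ml,
              x$nff_pct_lvm, x$nff_pct_mi))
  invisible(x)
}

#' Flat data frame of a quantification result
#'
#' @param x A `quant_result`.
#' @return One-row data frame of the global metrics (column names carry
#'   units).
#' @export
quant_as_row <- function(x) {
  stopifnot(inherits(x, "quant_result"))
  data.frame(lv_myocardial_volume_ml = x$lv_myocardial_volume_ml,
             lvm_g = x$lvm_g,
             mi_volume_ml = x$mi_volume_ml,
             nf_volume_ml = x$nf_volume_ml,
             mif_pct_lvm = x$mif_pct_lvm,
             nff_pct_lvm = x$nff_pct_lvm,
             nff_pct_mi = x$nff_pct_mi,
             mif_pct_lvm_mlg = x$mif_pct_lvm_mlg,
             nff_pct_lvm_mlg = x$nff_pct_lvm_mlg)
}
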