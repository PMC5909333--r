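T2_FLOOR_MS <- 1
T2_CAP_MS <- 2000

# Vectorised two-parameter mono-exponential least-squares fit.
#
# Y: n_pixels x n_echoes matrix of magnitudes; te: echo times (ms).
# Minimises sum (SI - SI0 exp(-TE/T2))^2 in the nonlinear (signal) domain by
# damped Gauss-Newton (Levenberg-Marquardt) with per-pixel damping,
# initialised from the log-linear regression of ln(SI) on TE over positive
# samples. Steps are only accepted when they do not increase the SSE, so the
# final fit is never worse than its initialiser. T2 is clamped to
# [T2_FLOOR_MS, T2_CAP_MS]; pixels ending on a bound, or with fewer than 3
# positive samples, are flagged.
fit_monoexp_engine <- function(Y, te, max_iter = 100L, tol = 1e-14) {
  n <- nrow(Y); m <- length(te)
  stopifnot(ncol(Y) == m)
  flag <- rep("ok", n)

  pos <- Y > 0
  n_pos <- rowSums(pos)
  ok <- n_pos >= 3L
  flag[!ok] <- "insufficient-signal"

  # log-linear initialiser over positive samples
  L <- ifelse(pos, log(pmax(Y, 1e-300)), 0)
  TE <- matrix(te, n, m, byrow = TRUE)
  Sw <- n_pos
  Sx <- rowSums(TE * pos); Sy <- rowSums(L)
  Sxx <- rowSums(TE^2 * pos); Sxy <- rowSums(TE * L)
  denom <- Sw * Sxx - Sx^2
  slope <- ifelse(denom > 0, (Sw * Sxy - Sx * Sy) / denom, 0)
  icept <- ifelse(Sw > 0, (Sy - slope * Sx) / Sw, 0)
  b <- ifelse(slope < 0, -1 / slope, T2_CAP_MS)
  b <- pmin(pmax(b, T2_FLOOR_MS), T2_CAP_MS)
  a <- pmax(exp(pmin(icept, 700)), 1e-12)
  a[!ok] <- NA_real_; b[!ok] <- NA_real_

  act <- which(ok)
  sse <- rep(NA_real_, n)
  if (length(act)) {
    lam <- rep(1e-3, n)
    row_sse <- function(a, b, rows) {
      E <- exp(-tcrossprod(1 / b, te))
      rowSums((Y[rows, , drop = FALSE] - a * E)^2)
    }
    sse[act] <- row_sse(a[act], b[act], act)
    for (iter in seq_len(max_iter)) {
      if (!length(act)) break
      aa <- a[act]; bb <- b[act]; ll <- lam[act]
      E <- exp(-tcrossprod(1 / bb, te))
      r <- Y[act, , drop = FALSE] - aa * E
      J2 <- aa * E * matrix(te, length(act), m, byrow = TRUE) / bb^2
      A11 <- rowSums(E^2); A22 <- rowSums(J2^2); A12 <- rowSums(E * J2)
      g1 <- rowSums(E * r); g2 <- rowSums(J2 * r)
      M11 <- A11 * (1 + ll); M22 <- A22 * (1 + ll)
      det <- pmax(M11 * M22 - A12^2, 1e-300)
      a_t <- pmax(aa + (M22 * g1 - A12 * g2) / det, 1e-12)
      b_t <- pmin(pmax(bb + (M11 * g2 - A12 * g1) / det, T2_FLOOR_MS),
                  T2_CAP_MS)
      new_sse <- row_sse(a_t, b_t, act)
      acc <- new_sse <= sse[act]
      small_gain <- acc & (sse[act] - new_sse) <= tol * (sse[act] + 1e-30)
      a[act[acc]] <- a_t[acc]; b[act[acc]] <- b_t[acc]
      sse[act[acc]] <- new_sse[acc]
      lam[act[acc]] <- pmax(lam[act[acc]] / 3, 1e-12)
      lam[act[!acc]] <- lam[act[!acc]] * 7
      drop <- small_gain | lam[act] > 1e10
      act <- act[!drop]
    }
  }
  flag[ok & b >= T2_CAP_MS] <- "t2-cap"
  flag[ok & b <= T2_FLOOR_MS] <- "t2-floor"
  list(si0 = a, t2_ms = b, residual = sqrt(pmax(sse, 0)), flag = flag)
}

#' Fit a mono-exponential T2 decay to one signal vector
#'
#' Two-parameter least-squares fit of \eqn{SI = SI_0 e^{-TE/T2}} in the
#' signal (not log) domain, initialised from the log-linear regression of
#' `ln(SI)` on TE over positive samples. T2 estimates are floored at 1 ms
#' and capped at 2000 ms; a fit ending on a bound, or with fewer than three
#' positive samples, is flagged rather than silently returned.
#'
#' @param si Signal magnitudes at each echo (>= 3 values).
#' @param te_ms Strictly increasing echo times (ms), same length as `si`.
#' @return List with `si0`, `t2_ms`, `residual` (residual norm) and `flag`
#'   (`"ok"`, `"insufficient-signal"`, `"t2-floor"`, `"t2-cap"`).
#' @examples
#' te <- c(12, 20, 30, 45, 60, 75, 90, 105)
#' fit_monoexp(1000 * exp(-te / 57), te)
#' @export
fit_monoexp <- function(si, te_ms) {
  if (length(si) < 3L || length(te_ms) < 3L)
    stop("input error: at least 3 echoes are required", call. = FALSE)
  if (length(si) != length(te_ms))
    stop("input error: si and te_ms lengths differ", call. = FALSE)
  if (any(diff(te_ms) <= 0))
    stop("input error: echo times must be strictly increasing", call. = FALSE)
  f <- fit_monoexp_engine(matrix(si, nrow = 1), te_ms)
  list(si0 = unname(f$si0[1]), t2_ms = unname(f$t2_ms[1]),
       residual = unname(f$residual[1]), flag = f$flag[1])
}

#' Pixel-wise T2 map of a multi-echo series
#'
#' Applies the mono-exponential fit to every pixel inside `mask` (all
#' pixels at once through a matrix-vectorised Levenberg-Marquardt pass).
#'
#' @param series An [image_series()] of kind `"t2-multi-echo"`.
#' @param mask Logical array matching the series' spatial dimensions.
#' @return An object of class `t2_map`: arrays `si0`, `t2_ms`, `residual`
#'   (NA outside the mask), a character `flag` array, the `mask`, and the
#'   fraction of masked pixels whose fit failed (`failure_rate`).
#' @export
compute_t2_map <- function(series, mask) {
  stopifnot(inherits(series, "image_series"))
  if (series$kind != "t2-multi-echo")
    stop("input error: series is not a multi-echo T2 acquisition", call. = FALSE)
  sp_dim <- dim(series$voxels)[1:3]
  if (!identical(dim(mask), sp_dim))
    stop("geometry error: mask and series shapes disagree", call. = FALSE)
  idx <- which(mask)
  te <- series$echo_times_ms
  n_vox <- prod(sp_dim)
  Y <- matrix(series$voxels, n_vox, length(te))[idx, , drop = FALSE]
  f <- fit_monoexp_engine(Y, te)
  blank <- array(NA_real_, sp_dim)
  si0 <- blank; t2 <- blank; res <- blank
  flag <- array(NA_character_, sp_dim)
  si0[idx] <- f$si0; t2[idx] <- f$t2_ms; res[idx] <- f$residual
  flag[idx] <- f$flag
  structure(list(si0 = si0, t2_ms = t2, residual = res, flag = flag,
                 mask = mask,
                 failure_rate = mean(f$flag != "ok")),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  cat("<t2_map>", sum(x$mask), "fitted pixels |",
      sprintf("%.2f%% flagged\n", 100 * x$failure_rate))
  invisible(x)
}

#' Regional T2 statistics
#'
#' Mean and sample standard deviation (n - 1 denominator, matching the
#' mean +/- SD reporting convention) of fitted T2 over the unflagged pixels
#' of a region.
#'
#' @param map A [compute_t2_map()] result.
#' @param region Logical array, subset of the map's mask.
#' @return List with `mean_ms`, `sd_ms` (NA when n = 1), and `n`.
#' @export
region_t2 <- function(map, region) {
  stopifnot(inherits(map, "t2_map"))
  if (!identical(dim(region), dim(map$mask)))
    stop("geometry error: region and map shapes disagree", call. = FALSE)
  if (any(region & !map$mask))
    stop("input error: region extends outside the fitted mask", call. = FALSE)
  ok <- region & map$flag == "ok" & !is.na(map$flag)
  vals <- map$t2_ms[ok]
  if (length(vals) < 1L)
    stop("input error: region contains no successfully fitted pixels",
         call. = FALSE)
  list(mean_ms = mean(vals),
       sd_ms = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
       n = length(vals))
}
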