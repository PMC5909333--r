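#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA of a complete subjects x timepoints matrix:
#' `F = MS_time / MS_(time x subject)` with `df1 = t - 1` and
#' `df2 = (t - 1)(s - 1)`. Fitted through `stats::aov` with an
#' `Error(subject/time)` stratum. No sphericity correction is applied by
#' default; `gg = TRUE` applies the Greenhouse-Geisser epsilon to the
#' degrees of freedom of the p-value.
#'
#' @param data Numeric matrix, rows = subjects, columns = timepoints;
#'   complete (no NA).
#' @param gg Apply Greenhouse-Geisser correction to the p-value.
#' @return List with `F`, `df1`, `df2`, `p` (and `epsilon` when `gg`).
#' @export
rm_anova_oneway <- function(data, gg = FALSE) {
  data <- as.matrix(data)
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("input error: need at least 2 subjects and 2 timepoints",
         call. = FALSE)
  if (anyNA(data))
    stop("input error: missing cells are not allowed (no imputation)",
         call. = FALSE)
  s <- nrow(data); t <- ncol(data)
  # degenerate case: no between-timepoint variability at all (0/0 in aov)
  if (sum((colMeans(data) - mean(data))^2) == 0)
    return(list(F = 0, df1 = t - 1L, df2 = (t - 1L) * (s - 1L), p = 1))
  d <- data.frame(y = as.vector(data),
                  subject = factor(rep(seq_len(s), times = t)),
                  time = factor(rep(seq_len(t), each = s)))
  fit <- stats::aov(y ~ time + Error(subject / time), data = d)
  tab <- summary(fit)[["Error: subject:time"]][[1]]
  Fv <- tab["time", "F value"]
  df1 <- tab["time", "Df"]; df2 <- tab["Residuals", "Df"]
  if (!is.finite(Fv)) {  # zero residual and zero effect variance
    Fv <- 0; p <- 1
  } else {
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  out <- list(F = unname(Fv), df1 = unname(df1), df2 = unname(df2),
              p = unname(p))
  if (gg) {
    eps <- gg_epsilon(data)
    out$epsilon <- eps
    out$p <- stats::pf(out$F, eps * df1, eps * df2, lower.tail = FALSE)
  }
  out
}

# Greenhouse-Geisser epsilon from the double-centred covariance matrix.
gg_epsilon <- function(data) {
  S <- stats::cov(data)
  t <- ncol(S)
  C <- diag(t) - 1 / t
  Sc <- C %*% S %*% C
  sum(diag(Sc))^2 / ((t - 1) * sum(Sc^2))
}

#' Earliest timepoint significantly different from the reference
#'
#' Post-hoc serial comparison: each non-reference timepoint is compared to
#' the reference with a paired t test, p-values are corrected (Holm by
#' default), and the result is the earliest timepoint that is significant
#' with *all later timepoints also significant* — the "at this time and
#' thereafter" reading of a serial reduction. Gated by a significant
#' repeated-measures ANOVA unless `require_anova = FALSE`.
#'
#' @param data Complete numeric matrix, rows = subjects (>= 2), columns =
#'   timepoints.
#' @param timepoints Numeric timepoints labelling the columns (minutes).
#' @param reference The reference timepoint (must be in `timepoints`).
#' @param alpha Significance level.
#' @param correction Multiplicity correction passed to [stats::p.adjust()];
#'   default `"holm"`.
#' @param require_anova Only test post hoc when the RM-ANOVA is significant.
#' @return List with `timepoint` (`NA` when no qualifying timepoint),
#'   `p_adjusted` (named by timepoint), and `anova`.
#' @export
first_significant_timepoint <- function(data, timepoints,
                                        reference = timepoints[1],
                                        alpha = 0.05,
                                        correction = "holm",
                                        require_anova = TRUE) {
  data <- as.matrix(data)
  if (length(timepoints) != ncol(data))
    stop("input error: timepoints must label the matrix columns",
         call. = FALSE)
  ref_j <- match(reference, timepoints)
  if (is.na(ref_j))
    stop("input error: reference timepoint not present in data", call. = FALSE)
  if (nrow(data) < 2L)
    stop("input error: paired comparison undefined for a single subject",
         call. = FALSE)
  an <- rm_anova_oneway(data)
  others <- setdiff(seq_along(timepoints), ref_j)
  p_raw <- vapply(others, function(j)
    paired_t(data[, j], data[, ref_j])$p, numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = correction)
  names(p_adj) <- timepoints[others]
  tp_out <- NA_real_
  if (!require_anova || an$p < alpha) {
    later <- others[timepoints[others] > timepoints[ref_j]]
    sig <- p_adj[as.character(timepoints[later])] < alpha
    if (any(sig)) {
      # earliest timepoint from which everything later is also significant
      runs <- rev(cumprod(rev(sig)))  # 1 where sig and all later sig
      if (runs[1] == 1 || any(runs == 1))
        tp_out <- timepoints[later][match(1, runs)]
    }
  }
  list(timepoint = tp_out, p_adjusted = p_adj, anova = an)
}

#' Two-sample and paired t tests, KS normality check
#'
#' Thin wrappers with the study's conventions: the independent-samples test
#' uses the pooled-variance form by default (`welch = TRUE` for the Welch
#' variant); two samples that are identical up to zero variance return
#' `t = 0, p = 1` rather than an error.
#'
#' @param a,b Numeric samples (`paired_t` requires equal lengths, n >= 2).
#' @param welch Use the Welch (unequal-variance) form.
#' @return List with `t`, `df`, `p`.
#' @export
independent_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
  h <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(h$statistic), df = unname(h$parameter),
       p = unname(h$p.value))
}

#' @rdname independent_t
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0 && mean(d) == 0)
    return(list(t = 0, df = length(a) - 1L, p = 1))
  h <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(h$statistic), df = unname(h$parameter),
       p = unname(h$p.value))
}

#' @rdname independent_t
#' @param x Numeric sample.
#' @param method `"ks"` for the Kolmogorov-Smirnov statistic against a
#'   normal with the sample's mean and SD, `"lilliefors"` for the
#'   Lilliefors-corrected variant (requires the nortest package).
#' @return For `ks_normality`: list with `D`, `p`.
#' @export
ks_normality <- function(x, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  stopifnot(length(x) >= 4L)
  if (method == "lilliefors") {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("the lilliefors method requires the nortest package", call. = FALSE)
    h <- nortest::lillie.test(x)
  } else {
    h <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(D = unname(h$statistic), p = unname(h$p.value))
}

#' No-flow volume time course from serial segmentations
#'
#' Collects per-timepoint NF and total-infarct volumes into a kinetics
#' series. A timepoint without a segmentation is recorded as missing with a
#' warning (the RM-ANOVA will then refuse the incomplete series).
#'
#' @param masks_by_timepoint Named list (names = post-contrast minutes) of
#'   `region_masks` (or `NULL` for a missing timepoint).
#' @param pixel_spacing_mm,slice_thickness_mm Voxel geometry (mm).
#' @param subject,group Identifier columns carried through.
#' @return An object of class `kinetics_series`: data frame with columns
#'   `subject`, `group`, `timepoint_min`, `nf_volume_ml`, `mi_volume_ml`.
#' @export
nf_timecourse <- function(masks_by_timepoint, pixel_spacing_mm,
                          slice_thickness_mm, subject = "phantom",
                          group = NA_character_) {
  tp <- as.numeric(names(masks_by_timepoint))
  if (anyNA(tp))
    stop("input error: masks_by_timepoint must be named by post-contrast minute",
         call. = FALSE)
  rows <- lapply(seq_along(tp), function(j) {
    m <- masks_by_timepoint[[j]]
    if (is.null(m)) {
      warning("timepoint ", tp[j], " min is missing; recorded as NA",
              call. = FALSE)
      return(data.frame(subject = subject, group = group,
                        timepoint_min = tp[j],
                        nf_volume_ml = NA_real_, mi_volume_ml = NA_real_))
    }
    q <- quantify_masks(m, pixel_spacing_mm, slice_thickness_mm)
    data.frame(subject = subject, group = group, timepoint_min = tp[j],
               nf_volume_ml = q$nf_volume_ml, mi_volume_ml = q$mi_volume_ml)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$timepoint_min), ]
  rownames(out) <- NULL
  class(out) <- c("kinetics_series", "data.frame")
  out
}

#' Simulate a cohort of no-flow volume series
#'
#' Generates a subjects x timepoints matrix of measured NF volumes around a
#' mean time course: per-subject random offsets (between-animal spread) plus
#' independent per-measurement noise. The default mean curve is a step
#' decrease — flat at `baseline_ml` before `step_time_min`, lowered by
#' `step_drop_ml` from then on — emulating a serial reduction detectable
#' against the early reference; `step_drop_ml = 0` gives a null cohort.
#'
#' @param n_subjects Number of subjects (default 7, the study group size).
#' @param timepoints_min Acquisition schedule (min).
#' @param baseline_ml Mean NF volume before the step (default 7.7 ml).
#' @param step_time_min Timepoint at which the mean drops (default 20 min).
#' @param step_drop_ml Size of the drop (ml); default 2.4 (one
#'   between-animal SD).
#' @param subject_sd_ml Between-subject SD of the random offset (default
#'   2.4 ml).
#' @param noise_sd_ml Per-measurement SD (default 0.5 ml).
#' @param seed RNG seed.
#' @return Matrix `n_subjects x length(timepoints_min)` with timepoints as
#'   column names.
#' @export
simulate_nf_cohort <- function(n_subjects = 7L,
                               timepoints_min = c(2, 10, 15, 20, 25, 30, 35, 40, 45),
                               baseline_ml = 7.7,
                               step_time_min = 20,
                               step_drop_ml = 2.4,
                               subject_sd_ml = 2.4,
                               noise_sd_ml = 0.5,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- baseline_ml - step_drop_ml * (timepoints_min >= step_time_min)
  subj <- stats::rnorm(n_subjects, 0, subject_sd_ml)
  m <- outer(subj, mu, "+") +
    matrix(stats::rnorm(n_subjects * length(timepoints_min), 0, noise_sd_ml),
           n_subjects, length(timepoints_min))
  m <- pmax(m, 0)
  colnames(m) <- timepoints_min
  m
}
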