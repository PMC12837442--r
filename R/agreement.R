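#' Pair estimated steps with a reference sequence
#'
#' Both sequences are first aligned on their first contact (the offset
#' `ref_first - est_first` is added to the estimated times, mirroring
#' synchronization of two measurement systems on the first heel contact of
#' a trial), then matched greedily nearest-neighbour within a tolerance.
#' Unmatched steps on either side are excluded from all statistics and
#' reported in attributes.
#'
#' @param est_times,est_lengths estimated step times (s, time of initial
#'   contact) and lengths (m).
#' @param ref_times,ref_lengths reference step times and lengths.
#' @param est_sides optional side labels carried into the result.
#' @param tol matching tolerance after alignment, s.
#' @param align align on first contacts (default `TRUE`).
#' @return data.frame of class `paired_steps` with columns `est`, `ref`,
#'   `side`, `t_est`, `t_ref`; attributes `n_unmatched_est`,
#'   `n_unmatched_ref`.
#' @export
pair_steps <- function(est_times, est_lengths, ref_times, ref_lengths,
                       est_sides = NULL, tol = 0.25, align = TRUE) {
  if (length(est_times) == 0L || length(ref_times) == 0L)
    stop("empty step sequence")
  if (length(est_times) != length(est_lengths) ||
      length(ref_times) != length(ref_lengths))
    stop("times and lengths must have equal length")
  offset <- if (align) ref_times[1] - est_times[1] else 0
  et <- est_times + offset
  # greedy matching by increasing time distance (globally, so a spurious
  # interpolated step cannot steal its neighbour's reference)
  cand <- expand.grid(i = seq_along(et), j = seq_along(ref_times))
  cand$d <- abs(et[cand$i] - ref_times[cand$j])
  cand <- cand[cand$d <= tol, , drop = FALSE]
  cand <- cand[order(cand$d), , drop = FALSE]
  used_e <- rep(FALSE, length(et)); used_r <- rep(FALSE, length(ref_times))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_e[i] || used_r[j]) next
    used_e[i] <- TRUE; used_r[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      est = est_lengths[i], ref = ref_lengths[j],
      side = if (is.null(est_sides)) NA_character_ else est_sides[i],
      t_est = et[i], t_ref = ref_times[j], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(est = numeric(0), ref = numeric(0), side = character(0),
               t_est = numeric(0), t_ref = numeric(0))
  if (nrow(out)) out <- out[order(out$t_est), , drop = FALSE]
  rownames(out) <- NULL
  used <- used_r
  attr(out, "n_unmatched_est") <- length(et) - nrow(out)
  attr(out, "n_unmatched_ref") <- sum(!used)
  class(out) <- c("paired_steps", "data.frame")
  out
}

#' Absolute error of a step-length estimate
#'
#' `AE = calculated - estimated` (reference minus model); the median of
#' `|AE|` is the MdAE headline metric.
#' @param calculated reference value, m.
#' @param estimated model value, m.
#' @return signed error, m.
#' @export
absolute_error <- function(calculated, estimated) calculated - estimated

#' Relative (percent) error
#'
#' `100 * (estimated - calculated) / calculated`.
#' @param calculated reference value, m (nonzero).
#' @param estimated model value, m.
#' @return percent error.
#' @export
percent_error <- function(calculated, estimated) {
  if (any(calculated == 0)) stop("zero reference value in percent error")
  100 * (estimated - calculated) / calculated
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = est - ref`; bias is their mean, limits of agreement
#' `bias +/- 1.96 sd(d)` (sample sd), and the 95% CI of the bias uses the
#' normal approximation `bias +/- 1.96 sd/sqrt(n)`.
#'
#' @param pairs a [pair_steps()] result (or any data.frame with `est`,
#'   `ref`).
#' @return list: `bias`, `bias_ci_lo`, `bias_ci_hi`, `loa_lo`, `loa_hi`,
#'   `sd_diff`, `n`.
#' @export
bland_altman <- function(pairs) {
  d <- pairs$est - pairs$ref
  n <- length(d)
  if (n < 3L) stop("insufficient pairs for Bland-Altman analysis (need >= 3)")
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias,
       bias_ci_lo = bias - 1.96 * s / sqrt(n),
       bias_ci_hi = bias + 1.96 * s / sqrt(n),
       loa_lo = bias - 1.96 * s, loa_hi = bias + 1.96 * s,
       sd_diff = s, n = n)
}

#' Correlation and regression versus the reference
#'
#' Pearson r (with `r2 = r^2`) and ordinary least-squares slope/intercept
#' of the estimate on the reference.
#'
#' @param pairs a [pair_steps()] result.
#' @return list: `r`, `r2`, `slope`, `intercept`, `p_value`, `n`.
#' @export
correlation_regression <- function(pairs) {
  if (nrow(pairs) < 3L) stop("insufficient pairs (need >= 3)")
  if (stats::sd(pairs$ref) == 0) stop("zero variance in reference lengths")
  ct <- stats::cor.test(pairs$est, pairs$ref)
  fit <- stats::lm(est ~ ref, data = pairs)
  r <- unname(ct$estimate)
  list(r = r, r2 = r^2, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = ct$p.value, n = nrow(pairs))
}

#' Normality and paired-difference tests
#'
#' Shapiro-Wilk on the error distribution (supports the choice of
#' non-parametric summaries) and a Wilcoxon signed-rank test of estimate
#' versus reference. All-zero differences make the Wilcoxon degenerate;
#' this is flagged rather than an error.
#'
#' @param pairs a [pair_steps()] result.
#' @return list: `shapiro_stat`, `shapiro_p`, `wilcoxon_stat`,
#'   `wilcoxon_p`, `degenerate`.
#' @export
nonparametric_tests <- function(pairs) {
  d <- pairs$est - pairs$ref
  if (length(d) < 8L) stop("insufficient pairs for distribution tests (need >= 8)")
  if (all(d == d[1])) {
    return(list(shapiro_stat = NA_real_, shapiro_p = NA_real_,
                wilcoxon_stat = NA_real_, wilcoxon_p = NA_real_,
                degenerate = TRUE))
  }
  sw <- stats::shapiro.test(d)
  wt <- suppressWarnings(stats::wilcox.test(pairs$est, pairs$ref,
                                            paired = TRUE, exact = FALSE))
  list(shapiro_stat = unname(sw$statistic), shapiro_p = sw$p.value,
       wilcoxon_stat = unname(wt$statistic), wilcoxon_p = wt$p.value,
       degenerate = FALSE)
}

#' Full agreement report for one pooled set of paired steps
#'
#' @param pairs a [pair_steps()] result.
#' @param tests include Shapiro/Wilcoxon contracts (needs n >= 8).
#' @return list of class `agreement_report`: `mdae`, `iqr_lo`, `iqr_hi`,
#'   `pct_error_median`, Bland-Altman fields, correlation fields, `n`.
#' @export
agreement_report <- function(pairs, tests = nrow(pairs) >= 8L) {
  ae <- abs(absolute_error(pairs$ref, pairs$est))
  q <- unname(stats::quantile(ae, c(0.25, 0.75), type = 7))
  ba <- bland_altman(pairs)
  cr <- correlation_regression(pairs)
  rep <- c(list(mdae = stats::median(ae), iqr_lo = q[1], iqr_hi = q[2],
                pct_error_median = stats::median(percent_error(pairs$ref, pairs$est))),
           ba, cr[c("r", "r2", "slope", "intercept", "p_value")],
           list(n = nrow(pairs)))
  if (tests) rep <- c(rep, nonparametric_tests(pairs))
  class(rep) <- "agreement_report"
  rep
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d steps\n", x$n))
  cat(sprintf("  MdAE %.4f m (IQR [%.4f-%.4f]), median %% error %+.2f%%\n",
              x$mdae, x$iqr_lo, x$iqr_hi, x$pct_error_median))
  cat(sprintf("  Bland-Altman bias %+.4f m (95%% CI [%.4f, %.4f]), LoA [%.4f, %.4f]\n",
              x$bias, x$bias_ci_lo, x$bias_ci_hi, x$loa_lo, x$loa_hi))
  cat(sprintf("  R = %.4f, R2 = %.4f, slope %.4f, intercept %.4f\n",
              x$r, x$r2, x$slope, x$intercept))
  invisible(x)
}

#' Per-subject and grand-median summary tables
#'
#' Per subject and side: MdAE, IQR of |AE| and median percent error; the
#' grand median is the median across subject medians (and the IQR row the
#' IQR of the subject medians).
#'
#' @param pairs_list named list of [pair_steps()] results, one per subject.
#' @return list with `per_subject` (data.frame: subject, side, n, mdae,
#'   iqr_lo, iqr_hi, pct_error) and `grand` (data.frame per side).
#' @export
group_report <- function(pairs_list) {
  stopifnot(length(pairs_list) >= 1L)
  if (is.null(names(pairs_list)))
    names(pairs_list) <- sprintf("S%02d", seq_along(pairs_list))
  per <- list()
  for (s in names(pairs_list)) {
    p <- pairs_list[[s]]
    sides <- if (all(is.na(p$side))) "all" else sort(unique(p$side))
    for (sd in sides) {
      sub <- if (sd == "all") p else p[p$side == sd, , drop = FALSE]
      if (nrow(sub) == 0L) next
      ae <- abs(absolute_error(sub$ref, sub$est))
      q <- unname(stats::quantile(ae, c(0.25, 0.75)))
      per[[length(per) + 1L]] <- data.frame(
        subject = s, side = sd, n = nrow(sub), mdae = stats::median(ae),
        iqr_lo = q[1], iqr_hi = q[2],
        pct_error = stats::median(percent_error(sub$ref, sub$est)),
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  grand <- do.call(rbind, lapply(split(per, per$side), function(g) {
    q <- unname(stats::quantile(g$mdae, c(0.25, 0.75)))
    data.frame(side = g$side[1], n_subjects = nrow(g),
               mdae = stats::median(g$mdae), iqr_lo = q[1], iqr_hi = q[2],
               pct_error = stats::median(g$pct_error),
               stringsAsFactors = FALSE)
  }))
  rownames(grand) <- NULL
  list(per_subject = per, grand = grand)
}
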