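#' Score windows by core-pair phase locking
#'
#' Computes the PLV of each core node pair within every window and combines
#' them (default: arithmetic mean) into one phase-locking score per window.
#' The default core pairs are Fz-Cz and Fz-Pz, the core-node pairings of the
#' frontal-central and frontal-occipital areas.
#'
#' @param ws An `eeg_windows` object. Analytic windows (from
#'   `segment(analytic_signal(rec), ...)`) are used as-is; real-valued
#'   windows get a per-window analytic signal (edge effects are then borne
#'   by each short window).
#' @param core_pairs List of length-2 channel-label vectors
#'   (default [core_pairs()]).
#' @param combine How to combine the per-pair PLVs: `"mean"`, `"min"` or
#'   `"max"`.
#' @return Numeric vector of per-window scores in \[0, 1\].
#' @export
score_windows <- function(ws, core_pairs = eegfbn::core_pairs(),
                          combine = c("mean", "min", "max")) {
  stopifnot(inherits(ws, "eeg_windows"))
  combine <- match.arg(combine)
  if (length(core_pairs) == 0) stop("core pair list must not be empty")
  if (!is.list(core_pairs)) core_pairs <- list(core_pairs)
  labels <- ws$layout$labels
  idx <- lapply(core_pairs, function(p) {
    i <- match(p, labels)
    if (anyNA(i)) stop("core pair channel(s) not in layout: ",
                       paste(p[is.na(i)], collapse = ", "))
    i
  })
  is_analytic <- isTRUE(attr(ws, "analytic"))
  comb_fn <- switch(combine, mean = mean, min = min, max = max)
  vapply(ws$windows, function(w) {
    ph <- if (is_analytic) Arg(w) else
      analytic_signal(w, fs = ws$fs)$phase
    comb_fn(vapply(idx, function(ij) {
      Mod(mean(exp(1i * (ph[ij[1], ] - ph[ij[2], ]))))
    }, numeric(1)))
  }, numeric(1))
}

#' Select high-synchrony windows
#'
#' Keeps windows whose score passes the selection rule: the quantile rule
#' keeps the top fraction `q` (score at or above the (1-q) empirical
#' quantile); the absolute rule keeps scores at or above `tau`. The
#' highest-scoring window is always kept.
#'
#' @param scores Per-window scores from [score_windows()].
#' @param rule `"quantile"` (default) or `"absolute"`.
#' @param q Top fraction to keep under the quantile rule (default 0.3).
#' @param tau Absolute threshold under the absolute rule.
#' @param core_pairs Pair list recorded for provenance.
#' @return A `screening_result`: `scores`, `selected` (logical mask),
#'   `core_pairs`, `rule`, `threshold_used`.
#' @export
select_windows <- function(scores, rule = c("quantile", "absolute"),
                           q = 0.3, tau = NULL,
                           core_pairs = eegfbn::core_pairs()) {
  rule <- match.arg(rule)
  if (!length(scores) || all(!is.finite(scores))) {
    stop("no finite window scores to screen")
  }
  if (rule == "quantile") {
    stopifnot(q > 0, q < 1)
    thr <- stats::quantile(scores, probs = 1 - q, names = FALSE, type = 7)
  } else {
    stopifnot(!is.null(tau), tau >= 0, tau <= 1)
    thr <- tau
  }
  selected <- scores >= thr
  if (!any(selected)) selected[which.max(scores)] <- TRUE
  structure(list(scores = scores, selected = selected,
                 core_pairs = core_pairs, rule = rule,
                 threshold_used = unname(thr)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening_result> %d / %d windows kept (%s rule, threshold %.4f)\n",
    sum(x$selected), length(x$selected), x$rule, x$threshold_used))
  invisible(x)
}

#' Recombine selected windows into a new window set
#'
#' Keeps only the windows flagged by the screening result, preserving their
#' original start offsets. Downstream metrics operate per window; no phase
#' continuity across the recombined sequence is implied.
#'
#' @param ws The `eeg_windows` that was scored.
#' @param sr A `screening_result` whose mask length matches `ws`.
#' @return An `eeg_windows` containing only the selected windows.
#' @export
recombine <- function(ws, sr) {
  stopifnot(inherits(ws, "eeg_windows"), inherits(sr, "screening_result"))
  if (length(sr$selected) != length(ws$windows)) {
    stop("screening mask length (", length(sr$selected),
         ") does not match window count (", length(ws$windows), ")")
  }
  if (!any(sr$selected)) stop("screening selected no windows")
  out <- ws
  out$windows <- ws$windows[sr$selected]
  out$source_indices <- ws$source_indices[sr$selected]
  out
}

#' Screening recovery against planted ground truth
#'
#' Labels a window truth-positive when at least half of it overlaps a
#' planted coupling event that involves any core pair, then reports the
#' screening's sensitivity (selected positives / positives) and specificity
#' (unselected negatives / negatives).
#'
#' @param sr A `screening_result`.
#' @param gt An `eeg_ground_truth` from the generator.
#' @param ws The `eeg_windows` that was screened (for window timing).
#' @param overlap_frac Overlap fraction required for a positive label
#'   (default 0.5).
#' @return List with `sensitivity`, `specificity`, `n_positive`,
#'   `n_selected`, and the logical `truth` vector. `sensitivity` is `NA`
#'   when no window is truth-positive.
#' @export
screening_recovery_report <- function(sr, gt, ws, overlap_frac = 0.5) {
  stopifnot(inherits(sr, "screening_result"),
            inherits(gt, "eeg_ground_truth"),
            inherits(ws, "eeg_windows"))
  wsamp <- round(ws$window_s * ws$fs)
  starts <- (ws$source_indices - 1) / ws$fs
  ends <- starts + wsamp / ws$fs
  canon <- function(p) paste(sort(p), collapse = "~")
  core <- vapply(sr$core_pairs, canon, character(1))
  core_events <- Filter(function(ev) {
    any(vapply(ev$channel_pairs, canon, character(1)) %in% core)
  }, gt$events)
  truth <- rep(FALSE, length(starts))
  for (ev in core_events) {
    e0 <- ev$start_s; e1 <- ev$start_s + ev$duration_s
    ov <- pmax(0, pmin(ends, e1) - pmax(starts, e0))
    truth <- truth | (ov / (wsamp / ws$fs) >= overlap_frac)
  }
  sel <- sr$selected
  sens <- if (any(truth)) sum(sel & truth) / sum(truth) else NA_real_
  spec <- if (any(!truth)) sum(!sel & !truth) / sum(!truth) else NA_real_
  list(sensitivity = sens, specificity = spec,
       n_positive = sum(truth), n_selected = sum(sel), truth = truth)
}
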