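#' Match calcium and LFP events by onset time
#'
#' Pairs events across modalities one-to-one. Candidate pairs are all
#' (calcium, LFP) combinations whose onset offset
#' `|calcium onset - LFP onset|` is at most `tolerance_s`; pairs are
#' accepted greedily by ascending absolute onset offset, ties broken by
#' earlier calcium onset, and each event enters at most one match.
#'
#' @param calcium,lfp `DetectedEvents` data frames (sorted,
#'   non-overlapping).
#' @param tolerance_s Maximum |onset offset| in seconds (default 2, one
#'   calcium frame is 0.5 s while seizure events last tens of seconds).
#' @return A list with `matches` (data frame: `calcium_idx`, `lfp_idx`,
#'   `onset_offset_s`, `calcium_duration_s`, `lfp_duration_s`),
#'   `unmatched_calcium` and `unmatched_lfp` (row indices).
#' @export
match_events <- function(calcium, lfp, tolerance_s = 2.0) {
  nc <- nrow(calcium); nl <- nrow(lfp)
  empty <- data.frame(calcium_idx = integer(), lfp_idx = integer(),
                      onset_offset_s = numeric(),
                      calcium_duration_s = numeric(),
                      lfp_duration_s = numeric())
  if (nc == 0 || nl == 0)
    return(list(matches = empty, unmatched_calcium = seq_len(nc),
                unmatched_lfp = seq_len(nl)))
  cand <- expand.grid(ci = seq_len(nc), li = seq_len(nl))
  cand$off <- calcium$onset_s[cand$ci] - lfp$onset_s[cand$li]
  cand <- cand[abs(cand$off) <= tolerance_s, , drop = FALSE]
  cand <- cand[order(abs(cand$off), calcium$onset_s[cand$ci]), , drop = FALSE]
  used_c <- logical(nc); used_l <- logical(nl)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ci <- cand$ci[k]; li <- cand$li[k]
    if (!used_c[ci] && !used_l[li]) {
      keep[k] <- TRUE; used_c[ci] <- TRUE; used_l[li] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$ci), , drop = FALSE]
  matches <- data.frame(calcium_idx = cand$ci, lfp_idx = cand$li,
                        onset_offset_s = cand$off,
                        calcium_duration_s = calcium$duration_s[cand$ci],
                        lfp_duration_s = lfp$duration_s[cand$li])
  list(matches = matches,
       unmatched_calcium = which(!used_c),
       unmatched_lfp = which(!used_l))
}

#' Calcium-LFP event-duration correlation
#'
#' Ordinary least squares of calcium event duration on LFP event duration
#' over matched pairs, summarising how tightly the two modalities report
#' the same underlying seizures. `r_squared = 1 - SS_res / SS_tot`.
#'
#' @param matches Result of [match_events()], or its `matches` data frame.
#' @return A list of class `CorrelationResult`: `n_pairs`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
duration_correlation <- function(matches) {
  m <- if (is.list(matches) && !is.null(matches$matches)) matches$matches
       else matches
  n <- nrow(m)
  if (n < 2) stop("need at least 2 matched pairs for a fit", call. = FALSE)
  x <- m$lfp_duration_s; y <- m$calcium_duration_s
  if (stats::var(x) == 0)
    stop("LFP durations have zero variance; correlation undefined",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(n_pairs = n,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Duration correlation: n = %d, R^2 = %.3f (slope %.3f, intercept %.3f s)\n",
              x$n_pairs, x$r_squared, x$slope, x$intercept))
  invisible(x)
}

#' Detection performance against planted ground truth
#'
#' Scores a detector against the simulator's planted event windows:
#' a detected event is a true positive if its window overlaps a truth
#' window (one-to-one, greedy by overlap). Sensitivity = TP / n_truth,
#' precision = TP / n_detected.
#'
#' @param events `DetectedEvents` from a detector.
#' @param truth_windows Data frame with `onset_s`, `offset_s`.
#' @return List with `tp`, `fp`, `fn`, `sensitivity`, `precision`.
#' @export
detection_performance <- function(events, truth_windows) {
  nd <- nrow(events); nt <- nrow(truth_windows)
  if (nd == 0 || nt == 0)
    return(list(tp = 0L, fp = nd, fn = nt,
                sensitivity = if (nt == 0) NA_real_ else 0,
                precision = if (nd == 0) NA_real_ else 0))
  ov <- outer(seq_len(nd), seq_len(nt), function(i, j) {
    pmax(0, pmin(events$offset_s[i], truth_windows$offset_s[j]) -
            pmax(events$onset_s[i], truth_windows$onset_s[j]))
  })
  used_t <- logical(nt)
  tp <- 0L
  for (i in seq_len(nd)) {
    j <- which.max(ifelse(used_t, -Inf, ov[i, ]))
    if (length(j) && ov[i, j] > 0 && !used_t[j]) {
      used_t[j] <- TRUE; tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nd - tp, fn = nt - tp,
       sensitivity = tp / nt, precision = tp / nd)
}
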