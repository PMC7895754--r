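#' Define an M1/M2 marker panel
#'
#' @param m1,m2 Data frames with columns `species` (readout species id) and
#'   `readout` (one of `"level"`, `"mRNA"`, `"production_rate"`).
#' @return An object of class `mp_marker_panel`.
#' @export
marker_panel <- function(m1, m2) {
  chk <- function(df, what) {
    stopifnot(is.data.frame(df), all(c("species", "readout") %in% names(df)))
    if (!all(df$readout %in% c("level", "mRNA", "production_rate")))
      stop(what, ": unknown readout mode")
    df
  }
  m1 <- chk(m1, "m1"); m2 <- chk(m2, "m2")
  if (length(intersect(m1$species, m2$species)))
    stop("M1 and M2 marker lists must be disjoint")
  structure(list(m1 = m1, m2 = m2), class = "mp_marker_panel")
}

# fold-change denominator floor: avoids blow-ups when a baseline readout is
# (numerically) zero; floored at a small fraction of the trajectory maximum
baseline_floor <- function(baseline, traj_max) {
  pmax(baseline, 1e-6 * pmax(traj_max, 1e-300), 1e-12)
}

#' Fold change of a readout relative to its baseline
#'
#' @param result An `mp_sim`.
#' @param species Readout species id.
#' @param readout Readout mode (see [marker_panel()]).
#' @param t Time(s) in hours; must be in the result grid. Default: whole grid.
#' @param baseline Baseline value; defaults to the readout value at t = 0.
#' @return Fold change(s) `value(t) / baseline`.
#' @export
fold_change <- function(result, species, readout = "level", t = NULL,
                        baseline = NULL) {
  v <- get_readout(result, species, readout)
  if (is.null(baseline)) baseline <- v[1]
  baseline <- baseline_floor(baseline, max(v))
  if (is.null(t)) return(v / baseline)
  i <- match(t, result$time)
  if (anyNA(i)) stop("time(s) not in the simulation grid")
  v[i] / baseline
}

# matrix (time x markers) of fold changes for one panel side
panel_fold_changes <- function(result, side) {
  out <- matrix(NA_real_, length(result$time), nrow(side),
                dimnames = list(NULL, side$species))
  for (i in seq_len(nrow(side)))
    out[, i] <- fold_change(result, side$species[i], side$readout[i])
  out
}

#' M1, M2 and M1/M2 scores
#'
#' The M1 (M2) score is the geometric mean of the fold changes of the M1
#' (M2) panel markers relative to the untreated t = 0 baseline; the M1/M2
#' score is their ratio, so at t = 0 all three equal 1 (log-transformed: 0).
#' The geometric mean makes the scores invariant to marker ordering and to
#' unit rescaling of any single marker, and swapping the panels inverts the
#' M1/M2 score exactly.
#'
#' @param result An `mp_sim`.
#' @param panel An [marker_panel()]; defaults to the panel annotated on the
#'   simulated network, else [reference_marker_panel()].
#' @param t Optional time(s) at which to evaluate; default: whole grid.
#' @return An object of class `mp_scores`: list with `time`, `m1_score`,
#'   `m2_score`, `m1m2_score` (all positive, normalized to 1 at t = 0).
#' @export
m_scores <- function(result, panel = NULL, t = NULL) {
  if (is.null(panel)) panel <- result$panel %||% reference_marker_panel()
  f1 <- panel_fold_changes(result, panel$m1)
  f2 <- panel_fold_changes(result, panel$m2)
  gm <- function(m) exp(rowMeans(log(pmax(m, 1e-12))))
  m1 <- gm(f1); m2 <- gm(f2)
  sc <- structure(list(time = result$time, m1_score = m1, m2_score = m2,
                       m1m2_score = m1 / m2), class = "mp_scores")
  if (is.null(t)) return(sc)
  i <- match(t, result$time)
  if (anyNA(i)) stop("time(s) not in the simulation grid")
  structure(list(time = sc$time[i], m1_score = m1[i], m2_score = m2[i],
                 m1m2_score = sc$m1m2_score[i]), class = "mp_scores")
}

#' @export
print.mp_scores <- function(x, ...) {
  cat("<mp_scores> ", length(x$time), " time points; final log10 M1/M2 = ",
      signif(log10(x$m1m2_score[length(x$time)]), 3), "\n", sep = "")
  invisible(x)
}

#' Time integral of the log10 M1/M2 score
#'
#' Trapezoidal integral of `log10(m1m2_score)` over a window, the summary
#' statistic used as sensitivity-analysis output (24-h score integral).
#'
#' @param scores An `mp_scores`.
#' @param window Two-element numeric, hours (default `c(0, 24)`).
#' @return Scalar integral (log10-score x hours).
#' @export
score_integral <- function(scores, window = c(0, 24)) {
  keep <- scores$time >= window[1] & scores$time <= window[2]
  if (sum(keep) < 2) stop("score trajectory does not cover the window")
  t <- scores$time[keep]
  y <- log10(scores$m1m2_score[keep])
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Classify a score trajectory
#'
#' Rules on the log10 M1/M2 trajectory: `flat` if `max |log10 score| <
#' delta`; `self-repolarizing` if the sign changes with both extremes
#' exceeding `delta` in magnitude; `self-limiting` if after the absolute
#' peak the trajectory decays by more than 50% toward 0; otherwise
#' `self-promoting`.
#'
#' @param scores An `mp_scores` covering at least 48 h.
#' @param delta Significance threshold in log10 units (default 0.05).
#' @return One of `"flat"`, `"self-repolarizing"`, `"self-limiting"`,
#'   `"self-promoting"`.
#' @export
classify_trajectory <- function(scores, delta = 0.05) {
  if (max(scores$time) < 48)
    stop("trajectory must cover at least 48 h")
  y <- log10(scores$m1m2_score)
  if (max(abs(y)) < delta) return("flat")
  if (max(y) > delta && min(y) < -delta) return("self-repolarizing")
  ipk <- which.max(abs(y))
  peak <- y[ipk]
  final <- y[length(y)]
  if (ipk < length(y) && abs(final) < 0.5 * abs(peak)) return("self-limiting")
  "self-promoting"
}

#' Classify a cell phenotype from its 24-h score
#'
#' @param log10_score Log10 M1/M2 score at the evaluation time.
#' @param tau Threshold in log10 units (default 0.1).
#' @return `"M1-like"` if `> tau`, `"M2-like"` if `< -tau`, else `"M0*"`.
#' @export
classify_cell <- function(log10_score, tau = 0.1) {
  ifelse(log10_score > tau, "M1-like",
         ifelse(log10_score < -tau, "M2-like", "M0*"))
}

#' Canonical stimulation conditions of the reference network
#'
#' The seven single stimuli (10 ng/mL cytokines at t = 0; hypoxia = 2% O2)
#' and, optionally, all 21 pairwise combinations.
#'
#' @param dose Cytokine dose in ng/mL (default 10).
#' @param duration Hours (default 48).
#' @param pairwise Include pairwise combinations (default TRUE).
#' @param include_control Prepend the untreated control condition.
#' @return Named list of [stimulation_protocol()] objects.
#' @export
reference_conditions <- function(dose = 10, duration = 48, pairwise = TRUE,
                                 include_control = FALSE) {
  singles <- list(
    IFNG = list(species = "L_IFNG"), TNFA = list(species = "L_TNFA"),
    IL1B = list(species = "L_IL1B"), IL4 = list(species = "L_IL4"),
    IL10 = list(species = "L_IL10"), VEGF = list(species = "L_VEGFA"),
    Hyp = list(oxygen = 2))
  make <- function(parts, name) {
    ev <- NULL; o2 <- 21
    for (p in parts) {
      if (!is.null(p$species))
        ev <- rbind(ev, dose_event(0, p$species, dose, "ng/mL"))
      if (!is.null(p$oxygen)) o2 <- p$oxygen
    }
    stimulation_protocol(events = ev, oxygen_percent = o2,
                         duration = duration, name = name)
  }
  out <- list()
  if (include_control)
    out$Ctr <- stimulation_protocol(duration = duration, name = "Ctr")
  for (nm in names(singles)) out[[nm]] <- make(singles[nm], nm)
  if (pairwise) {
    nms <- names(singles)
    for (i in seq_along(nms)[-length(nms)])
      for (j in seq((i + 1), length(nms))) {
        nm <- paste0(nms[i], "+", nms[j])
        out[[nm]] <- make(singles[c(i, j)], nm)
      }
  }
  out
}

#' Dynamic polarization map
#'
#' Simulates every condition and tabulates log2 fold changes (relative to
#' the untreated t = 0 baseline) of every panel marker at the requested
#' times.
#'
#' @param net The (reference) `mp_network`.
#' @param conditions Named list of protocols; default
#'   [reference_conditions()] with control row included.
#' @param times Evaluation times in hours (default `c(4, 24, 48)`).
#' @param panel Marker panel; defaults to the network annotation.
#' @param settings [solver_settings()].
#' @param state Optional shared pre-equilibrated baseline state (computed
#'   once if missing).
#' @return Long data frame: condition, marker, readout, time, log2fc, plus
#'   attribute `"scores"` (named list of `mp_scores` per condition).
#' @export
polarization_map <- function(net, conditions = NULL,
                             times = c(4, 24, 48), panel = NULL,
                             settings = solver_settings(), state = NULL) {
  if (is.null(conditions))
    conditions <- reference_conditions(duration = max(times, 48),
                                       include_control = TRUE)
  if (is.null(panel))
    panel <- net$annotations$marker_panel %||% reference_marker_panel()
  if (is.null(state)) state <- equilibrate(net, settings)
  allm <- rbind(cbind(panel$m1, class = "M1"), cbind(panel$m2, class = "M2"))
  rows <- list(); scores <- list()
  for (nm in names(conditions)) {
    sim <- simulate_protocol(net, conditions[[nm]], settings, state = state)
    scores[[nm]] <- m_scores(sim, panel)
    for (i in seq_len(nrow(allm))) {
      fc <- fold_change(sim, allm$species[i], allm$readout[i], t = times)
      rows[[length(rows) + 1]] <- data.frame(
        condition = nm, marker = allm$species[i], readout = allm$readout[i],
        class = allm$class[i], time = times, log2fc = log2(fc),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "scores") <- scores
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
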