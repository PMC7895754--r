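#' Latin hypercube sample in log10 space
#'
#' Each parameter's log10 range is split into `n` equal-probability strata;
#' every column receives exactly one uniform draw per stratum, in a random
#' permutation. Deterministic for a given seed.
#'
#' @param ranges Named list (or 2-row matrix) of `(lo, hi)` bounds, all
#'   positive with `lo < hi`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return `n` x `p` matrix of parameter values (natural scale), columns
#'   named after the parameters.
#' @export
lhs_sample <- function(ranges, n, seed) {
  if (is.matrix(ranges))
    ranges <- stats::setNames(lapply(seq_len(ncol(ranges)),
                                     function(j) ranges[, j]),
                              colnames(ranges))
  p <- length(ranges)
  stopifnot(p >= 1, n >= 1)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (r[1] <= 0 || r[2] <= r[1])
      stop("range for '", nm, "' must satisfy 0 < lo < hi")
  }
  out <- matrix(NA_real_, n, p, dimnames = list(NULL, names(ranges)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (j in seq_len(p)) {
    lo <- log10(ranges[[j]][1]); hi <- log10(ranges[[j]][2])
    strata <- (sample.int(n) - 1 + stats::runif(n)) / n
    out[, j] <- 10 ^ (lo + strata * (hi - lo))
  }
  out
}

rank_transform <- function(x) apply(as.matrix(x), 2, rank)

#' Partial rank correlation coefficients
#'
#' Rank-transforms the design matrix and output, then computes, for each
#' parameter, the correlation between the residuals of `rank(x_j)` and
#' `rank(y)` after linear regression on all other rank columns (evaluated
#' via the precision matrix of the joint rank-correlation matrix).
#' P-values use the t transform with `n - 2 - (p - 1)` degrees of freedom;
#' Benjamini-Hochberg adjusted values are reported alongside.
#'
#' @param X `n` x `p` design matrix (no constant columns).
#' @param y Numeric output vector of length `n`.
#' @return Data frame: parameter, prcc, p_value, p_adjusted, rank (by
#'   `|prcc|`, 1 = most influential).
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p + 2)
    stop("PRCC requires n > p + 2 (n = ", n, ", p = ", p, ")")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant design column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  RX <- rank_transform(X)
  if (qr(scale(RX))$rank < p)
    stop("rank-deficient design; collinear columns among: ",
         paste(colnames(X), collapse = ", "))
  R <- cbind(RX, y = rank(y))
  C <- stats::cor(R)
  iy <- p + 1
  P <- tryCatch(solve(C), error = function(e) NULL)
  if (!is.null(P)) {
    r <- -P[seq_len(p), iy] / sqrt(P[seq_len(p), seq_len(p)][cbind(1:p, 1:p)] *
                                     P[iy, iy])
  } else {
    # the output is perfectly rank-correlated with some input; compute the
    # partial correlations from explicit residual regressions, treating a
    # residual with no variance as zero association
    r <- vapply(seq_len(p), function(j) {
      others <- R[, setdiff(seq_len(p), j), drop = FALSE]
      rx_res <- stats::lm.fit(cbind(1, others), R[, j])$residuals
      ry_res <- stats::lm.fit(cbind(1, others), R[, iy])$residuals
      if (stats::sd(rx_res) < 1e-12 || stats::sd(ry_res) < 1e-12) return(0)
      stats::cor(rx_res, ry_res)
    }, 0)
  }
  df <- n - 2 - (p - 1)
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  out <- data.frame(parameter = colnames(X) %||% paste0("x", seq_len(p)),
                    prcc = unname(r), p_value = unname(pv),
                    p_adjusted = stats::p.adjust(pv, "BH"),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-abs(out$prcc), ties.method = "first")
  out
}

# module tag of the first reaction using each parameter
parameter_modules <- function(net) {
  out <- stats::setNames(rep(NA_character_, length(net$parameters)),
                         names(net$parameters))
  for (rx in net$reactions) {
    pid <- rx$law$rate_param
    if (is.na(out[[pid]])) {
      tag <- grep("^module:", rx$tags, value = TRUE)
      if (length(tag)) out[[pid]] <- sub("^module:", "", tag[1])
    }
  }
  out
}

#' Global sensitivity screen (LHS + PRCC)
#'
#' Samples kinetic parameters log-uniformly (default ten-fold around
#' nominal), simulates the given protocol for each sample, evaluates the
#' 24-h time-course integral of the log10 M1/M2 score, and ranks parameters
#' by PRCC. Parameters with `|PRCC| > threshold` (default 0.1) are flagged
#' influential.
#'
#' @param net An `mp_network`.
#' @param protocol Stimulation protocol (default 2% O2, 24 h).
#' @param params Parameter ids to perturb (default: all).
#' @param n Number of LHS samples (warns below `10 * length(params)`).
#' @param seed Integer seed.
#' @param fold Sampling half-range as a fold factor (default 10).
#' @param threshold Influence threshold on `|PRCC|`.
#' @param settings [solver_settings()].
#' @param window Integration window for the score metric.
#' @param panel Marker panel.
#' @return Data frame: parameter, module, prcc, p_value, p_adjusted, rank,
#'   influential; attribute `"metric"` holds the sampled outputs.
#' @export
sensitivity_screen <- function(net, protocol = NULL, params = NULL, n = 100,
                               seed = 1, fold = 10, threshold = 0.1,
                               settings = solver_settings(rel_tol = 1e-5),
                               window = c(0, 24), panel = NULL) {
  if (is.null(protocol))
    protocol <- stimulation_protocol(oxygen_percent = 2,
                                     duration = max(window),
                                     name = "hypoxia")
  if (is.null(params)) params <- names(net$parameters)
  if (n < 10 * length(params))
    warning("n = ", n, " is below the recommended 10 samples per parameter (p = ",
            length(params), ")", call. = FALSE)
  pv <- parameter_values(net)[params]
  ranges <- stats::setNames(lapply(pv, function(v) c(v / fold, v * fold)),
                            params)
  X <- lhs_sample(ranges, n, seed)
  y <- numeric(n)
  for (i in seq_len(n)) {
    neti <- set_parameters(net, X[i, ])
    y[i] <- tryCatch({
      sim <- simulate_protocol(neti, protocol, settings)
      score_integral(m_scores(sim, panel), window)
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(y)
  if (sum(ok) <= length(params) + 2)
    stop("too few successful simulations (", sum(ok), ") for PRCC")
  res <- prcc(X[ok, , drop = FALSE], y[ok])
  res$module <- unname(parameter_modules(net)[res$parameter])
  res$influential <- abs(res$prcc) > threshold
  res <- res[order(res$rank), c("parameter", "module", "prcc", "p_value",
                                "p_adjusted", "rank", "influential")]
  attr(res, "metric") <- y
  attr(res, "design") <- X
  res
}

#' Targeted intervention screen
#'
#' Simulates each candidate intervention on top of a base protocol and
#' returns the normalized log10 M1, M2 and M1/M2 score trajectories, the
#' presentation used for repolarization screening under hypoxia.
#'
#' @param net An `mp_network`.
#' @param candidates Named list of [intervention()] objects (or lists of
#'   them for combination treatments).
#' @param protocol Base protocol (default 2% O2, 48 h).
#' @param settings [solver_settings()].
#' @param panel Marker panel.
#' @param state Optional pre-equilibrated state.
#' @return Named list (one per candidate, plus `"(none)"` for the base
#'   protocol) of `mp_scores` objects.
#' @export
intervention_screen <- function(net, candidates, protocol = NULL,
                                settings = solver_settings(), panel = NULL,
                                state = NULL) {
  if (is.null(protocol))
    protocol <- stimulation_protocol(oxygen_percent = 2, duration = 48,
                                     name = "hypoxia")
  if (is.null(state)) state <- equilibrate(net, settings)
  out <- list()
  base <- simulate_protocol(net, protocol, settings, state = state)
  out[["(none)"]] <- m_scores(base, panel)
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    if (inherits(cand, "mp_intervention")) cand <- list(cand)
    p <- protocol
    p$interventions <- c(p$interventions, cand)
    p$name <- paste0(protocol$name, " + ", nm)
    sim <- simulate_protocol(net, p, settings, state = state)
    out[[nm]] <- m_scores(sim, panel)
  }
  out
}

#' The six reference targeted interventions
#'
#' SOCS1 inhibition (10x k101), PHD2 inhibition (0.1x kf62), STAT1
#' inhibition (0.1x kf3), IRF1 inhibition (10x k85), STAT3
#' deactivation inhibition (0.1x k127), STAT6 deactivation inhibition
#' (0.1x k26).
#'
#' @return Named list of [intervention()] objects.
#' @export
reference_interventions <- function() {
  list("SOCS1*" = intervention("k101", 10),
       "PHD2*" = intervention("kf62", 0.1),
       "STAT1*" = intervention("kf3", 0.1),
       "IRF1*" = intervention("k85", 10),
       "STAT3*" = intervention("k127", 0.1),
       "STAT6*" = intervention("k26", 0.1))
}
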