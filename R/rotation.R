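#' Unit-vector time series
#'
#' Container for one or more unit-vector trajectories sharing a frame
#' interval, the input to the P2 reorientational autocorrelation.
#'
#' @param vectors A single `n_frames x 3` matrix or a list of them (e.g.
#'   one per lipid). Rows must be unit vectors within 1e-6.
#' @param dt_ps Frame interval in ps.
#' @param label Mode label (e.g. "C71-H", "ring12").
#' @return Object of class `glyco_vector_series`.
#' @export
vector_series <- function(vectors, dt_ps = 1, label = "") {
  if (is.matrix(vectors)) vectors <- list(vectors)
  for (v in vectors) {
    stopifnot(is.matrix(v), ncol(v) == 3L)
    if (any(abs(row_norm(v) - 1) > 1e-6)) {
      stop("vector series rows must be unit vectors (within 1e-6)",
           call. = FALSE)
    }
  }
  structure(list(vectors = vectors, dt_ps = dt_ps, label = label),
            class = "glyco_vector_series")
}

#' @export
print.glyco_vector_series <- function(x, ...) {
  cat(sprintf("<glyco_vector_series> '%s': %d series of %d frames, dt %g ps\n",
              x$label, length(x$vectors), nrow(x$vectors[[1]]), x$dt_ps))
  invisible(x)
}

#' Extract unit-vector series from a trajectory
#'
#' Rotational modes:
#' \describe{
#'   \item{`CH`}{C-H bond vectors of one chain carbon (`carbon`); each
#'     hydrogen bonded to it contributes a series per lipid.}
#'   \item{`ring1`}{sugar-ring vector C1 -> C4.}
#'   \item{`ring2`}{C1p -> C4p (the primed ring).}
#'   \item{`ring12`}{combined headgroup vector C1p -> C4.}
#'   \item{`chain_axis`}{the chain tilt vector (first to last midpoint).}
#' }
#' Which primed/unprimed ring is the reducing sugar is a naming choice left
#' to the role map; modes are defined purely by the anchor atoms.
#'
#' @param traj A `glyco_trajectory`.
#' @param map A `glyco_rolemap`.
#' @param mode One of `"CH"`, `"ring1"`, `"ring2"`, `"ring12"`,
#'   `"chain_axis"`.
#' @param carbon Chain-carbon name, required for `mode = "CH"`.
#' @param window An [analysis_window()].
#' @return A `glyco_vector_series` with one matrix per lipid (per lipid and
#'   hydrogen for `"CH"`).
#' @export
build_vector_series <- function(traj, map,
                                mode = c("CH", "ring1", "ring2", "ring12",
                                         "chain_axis"),
                                carbon = NULL,
                                window = analysis_window(traj)) {
  mode <- match.arg(mode)
  resolved <- resolve_atoms(traj, map)
  fr <- window$frames
  get_series <- function(i_from, i_to) {
    # one matrix per lipid: frames x 3, normalized displacement
    lapply(seq_along(i_from), function(l) {
      v <- t(traj$coords[i_to[l], , fr] - traj$coords[i_from[l], , fr])
      n <- row_norm(v)
      if (any(n < 1e-8)) stop("zero-length mode vector", call. = FALSE)
      v / n
    })
  }
  if (mode == "CH") {
    if (is.null(carbon)) stop("mode 'CH' needs a carbon name", call. = FALSE)
    hyd <- resolved[resolved$role == "chain_hydrogen" &
                      resolved$parent == carbon, ]
    if (!nrow(hyd)) stop("no hydrogens on ", carbon, " in role map",
                         call. = FALSE)
    ci <- atom_index_by_lipid(resolved, carbon)
    lipids <- sort(unique(resolved$lipid))
    series <- list()
    for (h in unique(hyd$atom)) {
      hi <- atom_index_by_lipid(resolved, h)
      series <- c(series, get_series(ci, hi))
    }
    vs <- vector_series(series, dt_ps = frame_interval(traj, window),
                        label = paste0(carbon, "-H"))
    return(vs)
  }
  if (mode == "chain_axis") {
    cv <- compute_chain_vectors(traj, map, window = window)
    lips <- sort(unique(cv$lipid))
    series <- lapply(lips, function(l) {
      as.matrix(cv[cv$lipid == l, c("vx", "vy", "vz")])
    })
    return(vector_series(series, dt_ps = frame_interval(traj, window),
                         label = "chain_axis"))
  }
  pairs <- list(ring1 = c("C1", "C4"), ring2 = c("C1p", "C4p"),
                ring12 = c("C1p", "C4"))[[mode]]
  i_from <- atom_index_by_lipid(resolved, pairs[1])
  i_to <- atom_index_by_lipid(resolved, pairs[2])
  vector_series(get_series(i_from, i_to),
                dt_ps = frame_interval(traj, window), label = mode)
}

frame_interval <- function(traj, window) {
  t <- traj$time[window$frames]
  if (length(t) > 1L) mean(diff(t)) else 1
}

#' Second-rank reorientational autocorrelation C2(t)
#'
#' `C2(t) = < P2( mu(t0) . mu(t0 + t) ) >` with `P2(x) = (3 x^2 - 1) / 2`,
#' averaged over all valid time origins t0 (maximally overlapping windows)
#' and over the series in the input (e.g. over lipids). The average over
#' origins is evaluated through FFT correlation of the six quadratic
#' components of the unit vector, which is algebraically identical to the
#' brute-force double loop over origin pairs.
#'
#' @param series A `glyco_vector_series` (or a bare `n x 3` matrix).
#' @param max_lag Maximum lag in frames (must be < series length); default
#'   half the series length.
#' @return Tibble of class `glyco_acf`: `lag` (frames), `lag_ps`, `c2`,
#'   and `c2_se` (standard error over series, `NA` for a single series);
#'   attribute `per_series` holds the per-series C2 matrix.
#' @export
compute_acf_p2 <- function(series, max_lag = NULL) {
  if (is.matrix(series)) series <- vector_series(series)
  n <- nrow(series$vectors[[1]])
  if (is.null(max_lag)) max_lag <- max(1L, n %/% 2L)
  if (max_lag >= n) stop("max lag must be smaller than the series length",
                         call. = FALSE)
  per <- vapply(series$vectors, acf_p2_single, numeric(max_lag + 1L),
                max_lag = max_lag)
  per <- matrix(per, max_lag + 1L, length(series$vectors))
  c2 <- rowMeans(per)
  se <- if (ncol(per) > 1L) apply(per, 1L, stats::sd) / sqrt(ncol(per)) else
    rep(NA_real_, nrow(per))
  out <- tibble::tibble(lag = 0:max_lag,
                        lag_ps = (0:max_lag) * series$dt_ps,
                        c2 = c2, c2_se = se)
  class(out) <- c("glyco_acf", class(out))
  attr(out, "per_series") <- per
  attr(out, "dt_ps") <- series$dt_ps
  attr(out, "label") <- series$label
  out
}

# C2 for one unit-vector matrix via FFT: (u.u')^2 expands into the lagged
# products of the 6 unique quadratic components q_ab = u_a u_b.
acf_p2_single <- function(v, max_lag) {
  n <- nrow(v)
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  mult <- c(1, 1, 1, 2, 2, 2)
  m <- stats::nextn(2L * n)
  s <- numeric(max_lag + 1L)
  for (j in seq_along(pairs)) {
    q <- v[, pairs[[j]][1]] * v[, pairs[[j]][2]]
    fq <- stats::fft(c(q, rep(0, m - n)))
    corr <- Re(stats::fft(fq * Conj(fq), inverse = TRUE)) / m
    s <- s + mult[j] * corr[1:(max_lag + 1L)]
  }
  cnt <- n - (0:max_lag)
  dot2 <- s / cnt
  (3 * dot2 - 1) / 2
}

#' Fit a single-exponential correlation time
#'
#' Fits `a * exp(-t / tau_fit)` by unweighted least squares on lags up to
#' the point where C2 first drops below `c2_floor` (or the window end).
#' The reported correlation time is the trapezoidal integral of the fitted
#' curve on the lag grid, extended beyond the last lag by the analytic tail
#' `a * tau_fit * exp(-t_max / tau_fit)`; the closed-form integral
#' `a * tau_fit` is reported alongside. A curve whose fitted decay exceeds
#' 100x the fitting window is flagged as non-decaying rather than trusted.
#'
#' @param curve A `glyco_acf` (or tibble with `lag_ps` and `c2`).
#' @param c2_floor Fit cutoff on C2 (default 0.05).
#' @return One-row tibble of class `glyco_tau`: `label`, `tau_ns`,
#'   `sigma_ns`, `tau_analytic_ns`, `amplitude`, `tau_fit_ns`, `flag`
#'   (`"ok"` or `"non_decaying"`).
#' @export
fit_correlation_time <- function(curve, c2_floor = 0.05) {
  t <- curve$lag_ps
  y <- curve$c2
  stopifnot(length(t) >= 3L, all(is.finite(y)))
  below <- which(y < c2_floor)
  cut <- if (length(below)) max(3L, below[1]) else length(y)
  tf <- t[1:cut]; yf <- y[1:cut]
  fit <- fit_exp_decay(tf, yf)
  a <- fit$a; tau_fit <- fit$tau
  span <- max(tf) - min(tf)
  flag <- if (tau_fit > 100 * span) "non_decaying" else "ok"
  yy <- a * exp(-t / tau_fit)
  tau_ps <- pracma::trapz(t, yy) + a * tau_fit * exp(-max(t) / tau_fit)
  sigma_fit <- tau_sigma_from_fit(fit, t)
  per <- attr(curve, "per_series")
  sigma_spread <- NA_real_
  if (!is.null(per) && ncol(per) > 1L) {
    taus <- apply(per, 2L, function(yc) {
      f <- try(fit_exp_decay(tf, yc[1:cut]), silent = TRUE)
      if (inherits(f, "try-error")) NA_real_ else f$a * f$tau
    })
    taus <- taus[is.finite(taus)]
    if (length(taus) > 1L) {
      sigma_spread <- stats::sd(taus) / sqrt(length(taus))
    }
  }
  sig <- c(sigma_fit, sigma_spread)
  sig <- sig[is.finite(sig)]
  sigma_ps <- if (length(sig)) max(sig) else NA_real_
  out <- tibble::tibble(
    label = attr(curve, "label") %||% "",
    tau_ns = tau_ps / 1000,
    sigma_ns = sigma_ps / 1000,
    tau_analytic_ns = a * tau_fit / 1000,
    amplitude = a,
    tau_fit_ns = tau_fit / 1000,
    flag = flag)
  class(out) <- c("glyco_tau", class(out))
  out
}

# Nonlinear least squares for a * exp(-t / tau); log-linear start values.
fit_exp_decay <- function(t, y) {
  eps <- 1e-8
  pos <- y > eps
  if (sum(pos) >= 2L) {
    lf <- stats::lm(log(y[pos]) ~ t[pos])
    tau0 <- -1 / min(stats::coef(lf)[2], -1e-12)
    a0 <- exp(stats::coef(lf)[1])
  } else {
    tau0 <- max(t[2], 1); a0 <- max(y[1], eps)
  }
  tau0 <- min(max(tau0, t[2] + eps), 1e6 * max(t))
  a0 <- min(max(a0, 0.1), 2)
  df <- data.frame(t = t, y = y)
  fit <- try(minpack.lm::nlsLM(y ~ a * exp(-t / tau), data = df,
                               start = list(a = a0, tau = tau0),
                               lower = c(0, t[2] * 1e-3),
                               upper = c(2, 1e8 * max(t)),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    # near-degenerate curves (e.g. decorrelation within one frame): fall
    # back to the log-linear estimate
    return(list(a = a0, tau = tau0, fit = NULL))
  }
  cf <- stats::coef(fit)
  list(a = unname(cf["a"]), tau = unname(cf["tau"]), fit = fit)
}

# Delta-method sigma of the reported (trapezoid + tail) tau from the fit
# covariance of (a, tau_fit).
tau_sigma_from_fit <- function(fit, t_grid) {
  if (is.null(fit$fit)) return(NA_real_)
  V <- try(stats::vcov(fit$fit), silent = TRUE)
  if (inherits(V, "try-error") || anyNA(V)) return(NA_real_)
  f <- function(p) {
    yy <- p[1] * exp(-t_grid / p[2])
    pracma::trapz(t_grid, yy) + p[1] * p[2] * exp(-max(t_grid) / p[2])
  }
  p0 <- c(fit$a, fit$tau)
  g <- numeric(2)
  for (i in 1:2) {
    h <- max(1e-6, 1e-6 * abs(p0[i]))
    pp <- p0; pp[i] <- pp[i] + h
    pm <- p0; pm[i] <- pm[i] - h
    g[i] <- (f(pp) - f(pm)) / (2 * h)
  }
  sqrt(max(0, drop(t(g) %*% V %*% g)))
}

#' Correlation-time profile along the chain and headgroup
#'
#' Computes tau for every chain carbon's C-H vectors (hydrogens and lipids
#' averaged into one C2 curve per carbon) and for the three headgroup ring
#' vectors, the per-residue picture of how rotational mobility changes from
#' the sugar anchor to the chain tail.
#'
#' @param traj A `glyco_trajectory`.
#' @param map A `glyco_rolemap`.
#' @param window An [analysis_window()].
#' @param max_lag Maximum ACF lag in frames.
#' @param modes Ring modes to include alongside the per-carbon C-H set.
#' @return Tibble of class `glyco_tau` with one row per label.
#' @export
correlation_time_profile <- function(traj, map,
                                     window = analysis_window(traj),
                                     max_lag = NULL,
                                     modes = c("ring1", "ring2", "ring12")) {
  if (length(window$frames) < 2L) {
    stop("correlation analysis needs at least two frames", call. = FALSE)
  }
  resolved <- resolve_atoms(traj, map)
  carbons <- unique(resolved$atom[resolved$role == "chain_carbon"])
  carbons <- carbons[order(as.integer(sub("^C", "", carbons)))]
  have_h <- unique(resolved$parent[resolved$role == "chain_hydrogen"])
  rows <- list()
  for (cn in intersect(carbons, have_h)) {
    vs <- build_vector_series(traj, map, "CH", carbon = cn, window = window)
    acf <- compute_acf_p2(vs, max_lag = max_lag)
    rows[[length(rows) + 1L]] <- fit_correlation_time(acf)
  }
  anchors <- resolved$atom[resolved$role == "ring_anchor"]
  for (md in modes) {
    need <- list(ring1 = c("C1", "C4"), ring2 = c("C1p", "C4p"),
                 ring12 = c("C1p", "C4"))[[md]]
    if (!all(need %in% anchors)) next
    vs <- build_vector_series(traj, map, md, window = window)
    acf <- compute_acf_p2(vs, max_lag = max_lag)
    rows[[length(rows) + 1L]] <- fit_correlation_time(acf)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("glyco_tau", class(out))
  out
}
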