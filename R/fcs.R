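#' Triplet-3D FCS model parameter set
#'
#' Parameters of the correlation model used for nucleoplasmic lamin FCS: one
#' dark (triplet) blinking term multiplying a sum of 3D diffusion terms, plus
#' an offset. Fixed instrument constants default to the calibrated values
#' used in the study: axial-to-lateral focal ratio `k = 7.92` and effective
#' excitation volume `V_eff = 0.267` fl. The beam waist `w0` and per-species
#' diffusion coefficients `D = w0^2 / (4 tau_diff)` are derived on
#' construction.
#'
#' @param rho Per-species amplitude contributions (length `n_diff`, >= 0).
#' @param tau_diff Per-species diffusion times in seconds.
#' @param T_dark Dark (triplet) fraction in `[0, 1)` per triplet state.
#' @param tau_trip Triplet lifetime(s) in seconds.
#' @param g_inf Correlation offset.
#' @param a Anomaly exponent per species (default 1 = normal diffusion).
#' @param k Length-to-diameter ratio of the focal volume (> 1).
#' @param v_eff Effective excitation volume in femtolitres (1 fl = 1 um^3).
#' @return List of class `fcs_params` with derived `w0` (um) and `D`
#'   (um^2/s).
#' @export
fcs_params <- function(rho, tau_diff, T_dark = 0, tau_trip = 2e-6,
                       g_inf = 0, a = 1, k = 7.92, v_eff = 0.267) {
  if (length(rho) != length(tau_diff))
    stop("rho and tau_diff must have equal length", call. = FALSE)
  if (any(tau_diff <= 0) || any(tau_trip <= 0))
    stop("all tau must be positive", call. = FALSE)
  if (any(rho < 0)) stop("rho must be >= 0", call. = FALSE)
  if (any(T_dark < 0 | T_dark >= 1)) stop("T_dark must lie in [0, 1)", call. = FALSE)
  if (k <= 1) stop("k must be > 1", call. = FALSE)
  if (v_eff <= 0) stop("v_eff must be positive", call. = FALSE)
  if (length(a) == 1L) a <- rep(a, length(rho))
  w0 <- beam_waist(v_eff, k)
  structure(list(rho = rho, tau_diff = tau_diff, T_dark = T_dark,
                 tau_trip = tau_trip, g_inf = g_inf, a = a, k = k,
                 v_eff = v_eff, w0 = w0, D = w0^2 / (4 * tau_diff)),
            class = "fcs_params")
}

#' @export
print.fcs_params <- function(x, ...) {
  cat(sprintf("<fcs_params> %d species; tau_diff = %s ms; rho = %s; T = %s; G_inf = %.3g\n",
              length(x$rho), paste(signif(x$tau_diff * 1e3, 3), collapse = ", "),
              paste(signif(x$rho, 3), collapse = ", "),
              paste(signif(x$T_dark, 3), collapse = ", "), x$g_inf))
  cat(sprintf("  w0 = %.4g um; D = %s um^2/s (k = %.3g, V_eff = %.3g fl)\n",
              x$w0, paste(signif(x$D, 3), collapse = ", "), x$k, x$v_eff))
  invisible(x)
}

#' Evaluate the triplet-3D FCS model
#'
#' `G(t) = [1 + sum_j T_j (exp(-t / tau_trip_j) - 1)] *`
#' `sum_i rho_i [1 + (t/tau_diff_i)^a_i]^-1 [1 + (t/tau_diff_i)^a_i k^-2]^-1/2`
#' `+ G_inf`.
#'
#' @param params An [fcs_params()] set.
#' @param lag Lag times in seconds (> 0); vectorized.
#' @return Numeric vector of correlation amplitudes.
#' @export
eval_fcs_model <- function(params, lag) {
  stopifnot(inherits(params, "fcs_params"))
  if (any(lag <= 0)) stop("lags must be positive", call. = FALSE)
  trip <- 1
  for (j in seq_along(params$T_dark))
    trip <- trip + params$T_dark[j] * (exp(-lag / params$tau_trip[j]) - 1)
  diff_sum <- 0
  for (i in seq_along(params$rho)) {
    u <- (lag / params$tau_diff[i])^params$a[i]
    diff_sum <- diff_sum + params$rho[i] / (1 + u) / sqrt(1 + u / params$k^2)
  }
  trip * diff_sum + params$g_inf
}

#' Beam waist from the calibrated effective volume
#'
#' Inverts the confocal relation `V_eff = pi^{3/2} k w0^3` (with 1 fl =
#' 1 um^3), giving the effective lateral focal radius at 1/e^2 intensity.
#'
#' @param v_eff Effective excitation volume in femtolitres.
#' @param k Axial-to-lateral focal ratio.
#' @return `w0` in micrometres.
#' @export
beam_waist <- function(v_eff, k) {
  stop_if_not_number(v_eff, "v_eff", positive = TRUE)
  stop_if_not_number(k, "k", positive = TRUE)
  (v_eff / (pi^1.5 * k))^(1 / 3)
}

#' Diffusion coefficient from diffusion time
#'
#' `D = w0^2 / (4 tau_diff)`.
#'
#' @param tau_diff Diffusion (residence) time in seconds.
#' @param w0 Beam waist in micrometres.
#' @return `D` in um^2/s.
#' @export
diffusion_coefficient <- function(tau_diff, w0) {
  if (any(tau_diff <= 0)) stop("tau_diff must be positive", call. = FALSE)
  stop_if_not_number(w0, "w0", positive = TRUE)
  w0^2 / (4 * tau_diff)
}

#' Stokes-Einstein diffusion-ratio prediction from complex masses
#'
#' For spherical complexes of equal density the hydrodynamic radius scales as
#' the cube root of the mass, so `D_a / D_b = (m_b / m_a)^{1/3}`. With a
#' 175 kDa lamin + binding-partner complex versus the 100 kDa lamin alone
#' this predicts a ratio of 0.83.
#'
#' @param m_a,m_b Complex masses in kDa (or any common unit), positive.
#' @return Predicted `D_a / D_b` (dimensionless).
#' @export
predicted_d_ratio <- function(m_a, m_b) {
  stop_if_not_number(m_a, "m_a", positive = TRUE)
  stop_if_not_number(m_b, "m_b", positive = TRUE)
  (m_b / m_a)^(1 / 3)
}

#' Compute an autocorrelation curve from an intensity trace
#'
#' `G(tau) = <dI(t) dI(t + tau)> / <I>^2` evaluated on a multi-tau
#' (log-binned) lag grid: the first block of lags at full resolution, then
#' the trace is binned by two for each further block, as hardware correlators
#' do. Symmetric normalization by the segment means compensates slow drift.
#'
#' @param counts Intensity/photon-count samples at uniform spacing.
#' @param dt Sampling interval in seconds.
#' @param m Lags per block (default 16).
#' @param max_lag Largest lag evaluated, seconds (default an eighth of the
#'   trace).
#' @return Data frame of class `fcs_curve` (`lag_s`, `G`).
#' @export
autocorrelate <- function(counts, dt, m = 16L, max_lag = NULL) {
  x <- as.numeric(counts)
  n <- length(x)
  if (n < 100L) stop("trace too short", call. = FALSE)
  if (mean(x) == 0) stop("zero-mean trace", call. = FALSE)
  max_lag <- max_lag %||% (n * dt / 8)
  lags <- numeric(0)
  gs <- numeric(0)
  level <- 0L
  cur <- x
  cur_dt <- dt
  repeat {
    lag_idx <- if (level == 0L) seq_len(2L * m) else (m + 1L):(2L * m)
    for (k in lag_idx) {
      tau <- k * cur_dt
      if (tau > max_lag || k >= length(cur)) next
      a <- cur[seq_len(length(cur) - k)]
      b <- cur[(k + 1L):length(cur)]
      g <- mean(a * b) / (mean(a) * mean(b)) - 1
      lags <- c(lags, tau)
      gs <- c(gs, g)
    }
    # bin by two for the next block
    nn <- floor(length(cur) / 2L)
    if (nn < 4L * m || 2L * m * cur_dt * 2 > max_lag) break
    cur <- (cur[seq(1L, 2L * nn, by = 2L)] + cur[seq(2L, 2L * nn, by = 2L)]) / 2
    cur_dt <- cur_dt * 2
    level <- level + 1L
  }
  o <- order(lags)
  structure(data.frame(lag_s = lags[o], G = gs[o]),
            class = c("fcs_curve", "data.frame"))
}

#' Fit the triplet-3D model to a correlation curve
#'
#' Weighted nonlinear least squares in `G` with the instrument constants
#' (`k`, `v_eff`, anomaly exponents, numbers of states/species) held fixed
#' and `T`, `tau_trip`, `rho_i`, `tau_diff_i`, `G_inf` free. Uses
#' multi-start initialization over the lag range; species are returned
#' ordered fast first (`tau_diff_1 < tau_diff_2`), and derived `w0`/`D_i`
#' are filled in.
#'
#' @param curve An `fcs_curve` data frame (`lag_s`, `G`, optional `sd`).
#' @param n_diff Number of diffusing species (default 2).
#' @param k,v_eff,a Fixed instrument constants, as in [fcs_params()].
#' @param fit_triplet Include the dark-state term (default `TRUE`).
#' @param fit_g_inf Free the correlation offset (default `TRUE`; fix at 0
#'   when the curve is known to decay fully within the lag range).
#' @param n_starts Multi-start count.
#' @return An [fcs_params()] object with extra fields `converged`,
#'   `residual_rms` and `degenerate` (parsimony flag: a vanishing
#'   contribution or near-equal diffusion times suggests over-fitting with
#'   too many species).
#' @export
fit_fcs <- function(curve, n_diff = 2L, k = 7.92, v_eff = 0.267, a = 1,
                    fit_triplet = TRUE, fit_g_inf = TRUE, n_starts = 8L) {
  lag <- curve$lag_s
  g <- curve$G
  stopifnot(length(lag) > 10L, all(lag > 0))
  w <- if (!is.null(curve$sd)) 1 / pmax(curve$sd, 1e-12)^2 else rep(1, length(g))
  if (length(a) == 1L) a <- rep(a, n_diff)
  amp0 <- max(g) - min(g)
  # theta = (logit T, log tau_trip, log rho_1..n, log tau_1..n, g_inf)
  unpack <- function(th) {
    Td <- if (fit_triplet) 1 / (1 + exp(-th[1L])) else 0
    tt <- exp(th[2L])
    rho <- exp(th[2L + seq_len(n_diff)])
    td <- exp(th[2L + n_diff + seq_len(n_diff)])
    gi <- if (fit_g_inf) th[3L + 2L * n_diff] else 0
    list(T = Td, tt = tt, rho = rho, td = td, gi = gi)
  }
  obj <- function(th) {
    p <- unpack(th)
    trip <- 1 + p$T * (exp(-lag / p$tt) - 1)
    ds <- 0
    for (i in seq_len(n_diff)) {
      u <- (lag / p$td[i])^a[i]
      ds <- ds + p$rho[i] / (1 + u) / sqrt(1 + u / k^2)
    }
    r <- g - (trip * ds + p$gi)
    sum(w * r * r)
  }
  lo <- log(min(lag)); hi <- log(max(lag))
  best <- NULL
  for (s in seq_len(n_starts)) {
    qs <- sort(runif(n_diff, lo + 0.15 * (hi - lo), hi - 0.15 * (hi - lo)))
    if (s == 1L) qs <- lo + (seq_len(n_diff)) / (n_diff + 1) * (hi - lo)
    th <- c(qlogis(0.1), log(min(lag) * 3),
            rep(log(max(amp0, 1e-3) / n_diff), n_diff), qs, min(g))
    fit <- tryCatch(nlminb(th, obj, control = list(eval.max = 2000,
                                                   iter.max = 1000)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) stop("FCS fit failed from every start", call. = FALSE)
  p <- unpack(best$par)
  o <- order(p$td)
  out <- fcs_params(rho = p$rho[o], tau_diff = p$td[o],
                    T_dark = if (fit_triplet) p$T else 0,
                    tau_trip = p$tt, g_inf = p$gi, a = a[o], k = k,
                    v_eff = v_eff)
  out$residual_rms <- sqrt(best$objective / length(g))
  out$converged <- best$convergence == 0 || best$objective < 1e-10
  out$degenerate <- n_diff > 1L &&
    (min(out$rho) < 1e-2 * sum(out$rho) ||
       max(out$tau_diff) / min(out$tau_diff) < 1.5)
  out
}
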