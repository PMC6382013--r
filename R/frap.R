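# FRAP recovery normalization and exponential recovery fitting.  The fitted
# model partitions the mobile pool M between a fast and a slow component:
#   F(t) = M [ a (1 - exp(-k_f t)) + (1 - a) (1 - exp(-k_s t)) ]
# with t_half = ln(2)/k per pool; a = 1 gives the single-exponential model.

#' Normalize a raw FRAP trace to recovery fractions
#'
#' Full-scale normalization:
#' \deqn{F_{norm}(t) = (F(t) - F_{bleach}) / (F_{pre} - F_{bleach})}
#' where \eqn{F_{pre}} is the mean of the pre-bleach frames and
#' \eqn{F_{bleach}} the first post-bleach frame.  Time is rebased so the
#' bleach frame is \code{t = 0}.
#'
#' @param trace data.frame with columns \code{time}, \code{intensity} (raw).
#' @param prebleach_frames number of pre-bleach frames (>= 1, default 1).
#' @param bleach_index index of the first post-bleach frame (default
#'   \code{prebleach_frames + 1}).
#' @return data.frame with columns \code{time}, \code{intensity}
#'   (normalized; first value 0 by construction).
#' @export
normalizeRecovery <- function(trace, prebleach_frames = 1L,
                              bleach_index = prebleach_frames + 1L) {
  stopifnot(prebleach_frames >= 1L,
            bleach_index > prebleach_frames,
            bleach_index <= nrow(trace))
  f_pre <- mean(trace$intensity[seq_len(prebleach_frames)])
  f_bleach <- trace$intensity[bleach_index]
  if (f_pre == f_bleach)
    stop("degenerate trace: pre-bleach equals bleach intensity")
  idx <- bleach_index:nrow(trace)
  data.frame(
    time = trace$time[idx] - trace$time[bleach_index],
    intensity = (trace$intensity[idx] - f_bleach) / (f_pre - f_bleach))
}

# deterministic multi-start grid spanning halftime decades 10-1000 s
.frap_starts <- function(model) {
  if (model == "double") {
    list(c(thf = 10, ths = 100), c(thf = 10, ths = 1000),
         c(thf = 50, ths = 300), c(thf = 100, ths = 1000),
         c(thf = 30, ths = 150))
  } else {
    lapply(c(10, 50, 100, 300, 1000), function(th) c(th = th))
  }
}

#' Fit an exponential FRAP recovery model
#'
#' Bounded multi-start nonlinear least squares (Levenberg-Marquardt via
#' \code{minpack.lm}).  Five deterministic starts span halftime decades from
#' 10 to 1000 s; the lowest-SSE converged fit wins.  For the double model the
#' fast/slow roles are enforced by swapping so that
#' \code{t_half_fast <= t_half_slow}.  Bounds: mobile fraction in [0, 1.2]
#' (values above 1 are flagged \code{"super_recovery"} rather than failing),
#' fast fraction in [0, 1], rates positive.
#'
#' @param curve data.frame with columns \code{time}, \code{intensity}
#'   (normalized recovery fractions, \code{time[1] = 0}).
#' @param model \code{"double"} (default) or \code{"single"}.
#' @return a \linkS4class{FrapFit}.
#' @export
fitRecovery <- function(curve, model = c("double", "single")) {
  model <- match.arg(model)
  n_min <- if (model == "double") 12L else 8L
  if (nrow(curve) < n_min)
    stop("need >= ", n_min, " points for the ", model, " model")
  tt <- curve$time
  yy <- curve$intensity
  if (sd(yy) == 0) {                      # flat trace: immobile, M = plateau
    est <- c(mobile_fraction = max(0, yy[1L]), fast_fraction = 1,
             t_half_fast = NA_real_, t_half_slow = NA_real_)
    return(new("FrapFit", model = model, estimates = est, rmse = 0,
               converged = TRUE, flags = "flat_trace",
               curve = data.frame(curve, fitted = yy)))
  }
  m0 <- min(1.2, max(0.1, max(yy)))
  best <- NULL
  for (s in .frap_starts(model)) {
    fit <- try(suppressWarnings({
      if (model == "double") {
        minpack.lm::nlsLM(
          yy ~ M * (a * (1 - exp(-kf * tt)) + (1 - a) * (1 - exp(-ks * tt))),
          start = list(M = m0, a = 0.5,
                       kf = log(2) / s[["thf"]], ks = log(2) / s[["ths"]]),
          lower = c(0, 0, 1e-6, 1e-6), upper = c(1.2, 1, 10, 10),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          yy ~ M * (1 - exp(-k * tt)),
          start = list(M = m0, k = log(2) / s[["th"]]),
          lower = c(0, 1e-6), upper = c(1.2, 10),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ss <- sum(residuals(fit)^2)
    if (is.null(best) || ss < best$ss)
      best <- list(ss = ss, coef = coef(fit), fitted = fitted(fit))
  }
  if (is.null(best))
    stop("fit failure: no start converged (n = ", length(tt),
         ", range = [", min(yy), ", ", max(yy), "])")
  cf <- best$coef
  if (model == "double") {
    if (cf[["kf"]] < cf[["ks"]]) {        # enforce fast pool = faster rate
      cf[c("kf", "ks")] <- cf[c("ks", "kf")]
      cf[["a"]] <- 1 - cf[["a"]]
    }
    est <- c(mobile_fraction = cf[["M"]], fast_fraction = cf[["a"]],
             t_half_fast = log(2) / cf[["kf"]],
             t_half_slow = log(2) / cf[["ks"]])
  } else {
    est <- c(mobile_fraction = cf[["M"]], fast_fraction = 1,
             t_half_fast = log(2) / cf[["k"]],
             t_half_slow = log(2) / cf[["k"]])
  }
  flags <- character(0)
  if (est[["mobile_fraction"]] > 1) flags <- c(flags, "super_recovery")
  new("FrapFit", model = model, estimates = est,
      rmse = sqrt(best$ss / length(tt)), converged = TRUE, flags = flags,
      curve = data.frame(curve, fitted = as.numeric(best$fitted)))
}
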