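#' Exponential decay fitting with F-test model selection
#'
#' Fits the post-peak segment of a long line-scan profile (at least 7 s)
#' with a mono-exponential `A exp(-t/tau) + C` and a bi-exponential
#' `A1 exp(-t/tau1) + A2 exp(-t/tau2) + C`, and keeps the bi-exponential
#' only when the nested-model F-test favours it at `alpha_F`. For the
#' bi-exponential the reported time constant is the amplitude-weighted
#' `tau = (A1 tau1 + A2 tau2) / (A1 + A2)`.
#'
#' Fitting uses variable projection: amplitudes and offset are solved by
#' linear least squares for any candidate time constants, and only the
#' (log) time constants are optimized numerically — robust without
#' starting values.
#'
#' @param p a profile [trace()].
#' @param fit_start start of the decay segment in s (typically the
#'   transient peak); the segment from here to the end of the profile
#'   must be at least `min_duration` long.
#' @param alpha_F significance level of the nested F-test that promotes
#'   the bi-exponential model (default 0.01; a configuration key, not a
#'   measured value).
#' @param min_duration minimum segment duration in s (default 7).
#' @return An object of class `decay_fit`: `model` (`"mono"` or
#'   `"bi"`), `taus` (s), `amplitudes`, `offset`, `weighted_tau` (s),
#'   `F_statistic`, `F_p`, plus both candidate fits' residual sums of
#'   squares.
#' @examples
#' tt <- seq(0, 8, by = 0.01)
#' p <- trace(0.3 * exp(-tt / 3.16) + 1, dt = 0.01, units = "au")
#' fit_decay(p, 0)$taus
#' @export
fit_decay <- function(p, fit_start, alpha_F = 0.01, min_duration = 7) {
  stopifnot(inherits(p, "trace"))
  tt <- trace_times(p)
  keep <- tt >= fit_start - p$dt / 2
  t <- tt[keep] - fit_start
  y <- p$values[keep]
  if (length(t) < 8L || t[length(t)] < min_duration) {
    stop(sprintf("decay segment must span at least %g s", min_duration),
         call. = FALSE)
  }
  n <- length(y)

  # linear LS solve for amplitudes/offset given taus; returns RSS + coefs
  proj <- function(taus) {
    X <- cbind(vapply(taus, function(tau) exp(-t / tau), numeric(n)), 1)
    fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients))) {
      return(list(rss = Inf, coef = rep(NA_real_, length(taus) + 1L)))
    }
    list(rss = sum(fit$residuals^2), coef = fit$coefficients)
  }

  span <- t[length(t)]
  # mono: 1-D optimization over log tau
  om <- stats::optimize(function(lt) proj(exp(lt))$rss,
                        interval = log(c(span / 500, 5 * span)))
  tau_m <- exp(om$minimum)
  fm <- proj(tau_m)

  # bi: 2-D Nelder-Mead over log taus from a spread of starts
  obj2 <- function(lt) proj(exp(lt))$rss
  starts <- list(log(c(tau_m / 4, tau_m * 2)),
                 log(c(tau_m / 10, tau_m)),
                 log(c(tau_m / 2, tau_m * 4)))
  best <- NULL
  for (s in starts) {
    ob <- stats::optim(s, obj2, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || ob$value < best$value) best <- ob
  }
  taus_b <- sort(exp(best$par))
  fb <- proj(taus_b)
  if (!is.finite(fm$rss) || !is.finite(fb$rss)) {
    stop("decay fit failed to converge (singular design)", call. = FALSE)
  }

  # nested F-test: bi adds 2 parameters (one tau, one amplitude)
  df_b <- n - 5L
  Fstat <- ((fm$rss - fb$rss) / 2) / (fb$rss / df_b)
  Fp <- stats::pf(Fstat, 2, df_b, lower.tail = FALSE)
  use_bi <- is.finite(Fstat) && Fp < alpha_F
  # an (essentially) exact mono fit cannot be improved meaningfully; the
  # F statistic on machine-precision residuals is noise
  if (fm$rss <= 1e-12 * sum((y - mean(y))^2)) use_bi <- FALSE

  if (use_bi) {
    A <- fb$coef[1:2]
    wtau <- sum(A * taus_b) / sum(A)
    structure(list(model = "bi", taus = taus_b, amplitudes = A,
                   offset = fb$coef[3L], weighted_tau = wtau,
                   F_statistic = Fstat, F_p = Fp,
                   rss_mono = fm$rss, rss_bi = fb$rss),
              class = "decay_fit")
  } else {
    structure(list(model = "mono", taus = tau_m,
                   amplitudes = fm$coef[1L], offset = fm$coef[2L],
                   weighted_tau = tau_m,
                   F_statistic = Fstat, F_p = Fp,
                   rss_mono = fm$rss, rss_bi = fb$rss),
              class = "decay_fit")
  }
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s-exponential; weighted tau = %.3f s (F = %.3g, p = %.3g)\n",
              x$model, x$weighted_tau, x$F_statistic, x$F_p))
  invisible(x)
}
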