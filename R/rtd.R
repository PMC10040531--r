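# Residence-time-distribution analysis of washout curves.
#
# The appendage-averaged tracer concentration C(t) after unit
# initialization is fitted to a triple exponential with an asymptote,
#   C(t) = C_inf + a1 exp(-t/tau1) + a2 exp(-t/tau2) + a3 exp(-t/tau3),
# chosen to capture a fast early washout, a moderate middle phase and a
# slow tail. The RTD function is the negative derivative of the fitted C
# normalized by the washed-out fraction sum(a), so that it integrates to 1
# even when a fraction C_inf of tracer never leaves:
#   E(t) = sum_i (a_i/tau_i) exp(-t/tau_i) / sum_i a_i.
# Its first moment, the mean residence time, has the closed form
#   t_m = sum_i a_i tau_i / sum_i a_i.

#' Fit a washout curve to a triple exponential plus asymptote
#'
#' Constrained nonlinear least squares with a deterministic multi-start:
#' candidate time-constant triplets are taken from a log-spaced grid
#' spanning `[10 * dt_sample, 10 * window]`; for each triplet the
#' amplitudes and asymptote (all constrained nonnegative) are solved by
#' nonnegative linear least squares, and the best candidates are refined
#' by bounded Levenberg-Marquardt. A soft penalty keeps
#' `a1 + a2 + a3 + C_inf` near `C(0)` while tolerating early-time
#' discretization transients. Time constants are reported in canonical
#' increasing order.
#'
#' @param series A `concentration_series` (see [run_washout()]) or any
#'   list/data frame with numeric `t` and `c_laa`.
#' @param window Fit-window length in s; samples with `t <= window` are
#'   used. Default: the whole series.
#' @param n_tau Number of grid points for the multi-start time-constant
#'   grid (default 10; all increasing triplets are tried).
#' @param refine_top Number of best variable-projection candidates passed
#'   to the Levenberg-Marquardt refinement (default 6).
#' @param start Optional extra refinement candidate: a list (or `rtd_fit`)
#'   with `a`, `tau`, `c_inf`, e.g. the fit of a neighbouring window.
#' @param penalty Weight of the soft `C(0)` sum constraint (default 1).
#' @return An object of class `rtd_fit` with fields `a` (length 3),
#'   `tau` (length 3, increasing), `c_inf`, `rms` residual, `window`,
#'   `n` samples used and `c0`.
#' @examples
#' t <- seq(0, 50, by = 0.1)
#' fit <- fit_concentration(list(t = t, c_laa = 0.3 + 0.7 * exp(-t / 2)))
#' mean_residence_time(fit)
#' @export
fit_concentration <- function(series, window = NULL, n_tau = 10L,
                              refine_top = 6L, start = NULL, penalty = 1) {
  t <- series$t; c_ <- series$c_laa
  stopifnot(length(t) == length(c_), all(is.finite(c_)))
  if (is.null(window)) window <- max(t)
  keep <- t <= window + 1e-12
  t <- t[keep]; c_ <- c_[keep]
  if (length(t) < 50) stop("data error: fewer than 50 samples in window")
  c0 <- c_[which.min(t)]
  dt_sample <- min(diff(sort(unique(t))))
  tau_grid <- exp(seq(log(max(10 * dt_sample, 1e-9)), log(10 * window),
                      length.out = n_tau))

  model_cols <- function(tau) cbind(exp(-outer(t, 1 / tau)), 1)
  # nonnegative LS for (a1, a2, a3, c_inf) given taus, with the soft
  # sum-to-C(0) penalty appended as a pseudo-observation
  solve_amp <- function(tau) {
    A <- rbind(model_cols(tau), penalty)
    b <- c(c_, penalty * c0)
    fit <- pracma::lsqnonneg(A, b)
    list(x = fit$x, rss = sum((model_cols(tau) %*% fit$x - c_)^2))
  }

  combs <- utils::combn(n_tau, 3)
  cand <- lapply(seq_len(ncol(combs)), function(j) {
    tau <- tau_grid[combs[, j]]
    s <- solve_amp(tau)
    list(tau = tau, a = s$x[1:3], c_inf = s$x[4], rss = s$rss)
  })
  cand <- cand[order(vapply(cand, `[[`, 0, "rss"))]

  refine <- function(start) {
    # the penalty row is encoded as an extra residual whose model value is
    # penalty * (a1 + a2 + a3 + cinf)
    fn <- function(a1, a2, a3, l1, l2, l3, cinf) {
      tau <- exp(c(l1, l2, l3))
      m <- cinf + a1 * exp(-t / tau[1]) + a2 * exp(-t / tau[2]) +
        a3 * exp(-t / tau[3])
      c(m, penalty * (a1 + a2 + a3 + cinf))
    }
    y_all <- c(c_, penalty * c0)
    st <- list(a1 = max(start$a[1], 1e-8), a2 = max(start$a[2], 1e-8),
               a3 = max(start$a[3], 1e-8),
               l1 = log(start$tau[1]), l2 = log(start$tau[2]),
               l3 = log(start$tau[3]), c_inf = max(start$c_inf, 0))
    names(st)[7] <- "cinf"
    out <- try(minpack.lm::nlsLM(
      y_all ~ fn(a1, a2, a3, l1, l2, l3, cinf),
      start = st,
      lower = c(0, 0, 0, rep(log(dt_sample / 10), 3), 0),
      upper = c(2, 2, 2, rep(log(10 * window), 3), 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    p <- coef(out)
    tau <- exp(p[c("l1", "l2", "l3")])
    a <- p[c("a1", "a2", "a3")]
    m <- p["cinf"] + colSums(t(exp(-outer(t, 1 / tau))) * a)
    list(a = unname(a), tau = unname(tau), c_inf = unname(p["cinf"]),
         rss = sum((m - c_)^2))
  }

  starts <- cand[seq_len(min(refine_top, length(cand)))]
  if (!is.null(start))
    starts <- c(starts, list(list(
      a = pmax(start$a, 0), c_inf = max(start$c_inf, 0),
      tau = pmin(pmax(start$tau, dt_sample / 10), 10 * window))))
  best <- cand[[1]]
  for (s in starts) {
    r <- refine(s)
    if (!is.null(r) && r$rss < best$rss) best <- r
  }
  ord <- order(best$tau)
  structure(list(a = best$a[ord], tau = best$tau[ord], c_inf = best$c_inf,
                 rss = best$rss, rms = sqrt(best$rss / length(t)),
                 window = window, n = length(t), c0 = c0),
            class = "rtd_fit")
}

#' @export
print.rtd_fit <- function(x, ...) {
  cat("<rtd_fit> C(t) = ", signif(x$c_inf, 4), " + ",
      paste(sprintf("%.4g exp(-t/%.4g)", x$a, x$tau), collapse = " + "),
      "\n  t_m = ", signif(mean_residence_time(x), 5), " s,  C_inf = ",
      signif(x$c_inf, 4), ",  rms = ", signif(x$rms, 3), "\n", sep = "")
  invisible(x)
}

#' Evaluate the fitted washout model
#' @param fit An `rtd_fit`.
#' @param t Times, s.
#' @return Fitted concentration values.
#' @export
predict_concentration <- function(fit, t) {
  fit$c_inf + colSums(t(exp(-outer(t, 1 / fit$tau))) * fit$a)
}

#' Residence-time distribution function E(t)
#'
#' The probability density (s^-1) of the residence time of particles that
#' eventually leave the appendage: the negative derivative of the fitted
#' washout curve normalized by the washed-out fraction `sum(a)`, so that
#' `E` integrates to 1 even when `C_inf > 0`.
#'
#' @param fit An `rtd_fit`.
#' @param t Times, s (vectorized).
#' @return `E(t)` in s^-1.
#' @export
rtd_function <- function(fit, t) {
  s <- sum(fit$a)
  if (s <= 0) stop("degenerate RTD: nothing washes out (sum(a) = 0)")
  colSums(t(exp(-outer(t, 1 / fit$tau))) * (fit$a / fit$tau)) / s
}

#' Mean residence time from a fit (closed form)
#'
#' First moment of the RTD: `t_m = sum(a * tau) / sum(a)`.
#'
#' @param fit An `rtd_fit`.
#' @return `t_m` in s.
#' @export
mean_residence_time <- function(fit) {
  s <- sum(fit$a)
  if (s <= 0) stop("degenerate RTD: nothing washes out (sum(a) = 0)")
  sum(fit$a * fit$tau) / s
}

#' Asymptotic concentration from a fit
#' @param fit An `rtd_fit`.
#' @return The fitted asymptote `C_inf` (fraction of tracer that never
#'   washes out).
#' @export
asymptotic_concentration <- function(fit) fit$c_inf

#' Serialize an RTD fit as a JSON record
#'
#' @param fit An `rtd_fit`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  jsonlite::write_json(list(
    a = fit$a, tau = fit$tau, c_inf = fit$c_inf, rms = fit$rms,
    window = fit$window, n = fit$n,
    t_m = mean_residence_time(fit)), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Truncation-length sensitivity of the RTD indices
#'
#' Refits the washout curve on each prefix window and tabulates how the
#' mean residence time and asymptote depend on the simulation length.
#'
#' @param series A `concentration_series`.
#' @param lengths Strictly increasing window lengths, s (each within the
#'   series horizon).
#' @param ... Passed to [fit_concentration()].
#' @return A data frame with columns `length`, `t_m`, `c_inf`, `rms`,
#'   `status`.
#' @export
truncation_study <- function(series, lengths, ...) {
  stopifnot(all(diff(lengths) > 0), max(lengths) <= max(series$t) + 1e-9)
  rows <- vector("list", length(lengths))
  prev <- NULL    # chain the nested windows: warm-start from the last fit
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    f <- try(fit_concentration(series, window = L, start = prev, ...),
             silent = TRUE)
    if (inherits(f, "try-error")) {
      rows[[i]] <- data.frame(length = L, t_m = NA, c_inf = NA, rms = NA,
                              status = "fit-error")
    } else {
      prev <- f
      rows[[i]] <- data.frame(length = L, t_m = mean_residence_time(f),
                              c_inf = f$c_inf, rms = f$rms, status = "ok")
    }
  }
  do.call(rbind, rows)
}

#' Rank stability of per-subject indices across truncation lengths
#'
#' Spearman rank correlation between the subject ordering at each
#' truncation length and the ordering at a reference (normally the
#' longest) length.
#'
#' @param values Numeric matrix, subjects in rows and truncation lengths
#'   in (named or numbered) columns.
#' @param reference Column index or name of the reference length.
#' @return A data frame with one row per column: `length` (column name),
#'   `rho`, `p`.
#' @export
rank_stability <- function(values, reference = ncol(values)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 3)
  ref <- values[, reference]
  out <- lapply(seq_len(ncol(values)), function(j) {
    s <- spearman(values[, j], ref)
    data.frame(length = colnames(values)[j] %||% j, rho = s$rho, p = s$p)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
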