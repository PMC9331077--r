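# Continuous-endpoint benchmark-dose estimation with equal-weight model
# averaging.
#
# Six increasing dose-response families are fitted by maximum likelihood to
# summary data (per-dose arithmetic mean, SD, n) under a lognormal response
# with common log-scale variance. Writing a for the background level,
# b for the dose scale, c for the fold-increase amplitude and g for the
# shape power:
#
#   exp3       mu(d) = a * exp(b * d^g)
#   exp5       mu(d) = a * (c - (c - 1) * exp(-b * d^g)),        c > 1
#   hill3      mu(d) = a * (1 + c * d / (b + d)),                c > 0
#   hill5      mu(d) = a * (1 + c * d^g / (b^g + d^g))
#   inv_exp    mu(d) = a * (1 + c * exp(-b * d^(-g)))
#   log_normal mu(d) = a * (1 + c * pnorm(g * log(d / b)))
#
# mu(d) is the response median; the benchmark dose at benchmark response
# `bmr` solves mu(d) = (1 + bmr) * mu(0). The background a is profiled in
# closed form, which makes every BMD exactly invariant to rescaling the
# response. Arithmetic summary moments are converted to log-scale moments by
# sdlog^2 = log(1 + (sd/mean)^2), meanlog = log(mean) - sdlog^2 / 2.

BMD_MODELS <- c("exp3", "exp5", "hill3", "hill5", "inv_exp", "log_normal")

#' Dose-response summary data
#'
#' @param dose Dose levels (must include 0 and at least 3 distinct values).
#' @param mean Arithmetic mean response per dose.
#' @param sd Arithmetic SD per dose (non-negative).
#' @param n Number of animals per dose.
#' @return A validated `data.frame` of class `dose_response_summary`.
#' @export
#' @examples
#' ds <- dose_response_summary(c(0, 12.5, 25, 50),
#'                             c(1.3, 3.3, 6.8, 10.4) * 1e-7,
#'                             c(0.25, 0.3, 0.64, 0.7) * 1e-7, n = 6)
dose_response_summary <- function(dose, mean, sd, n) {
  df <- data.frame(dose = as.numeric(dose), mean = as.numeric(mean),
                   sd = as.numeric(sd), n = as.numeric(rep_len(n, length(dose))))
  if (length(unique(df$dose)) < 3L || !any(df$dose == 0)) {
    stop_fmt("need at least 3 distinct doses including 0")
  }
  if (any(df$mean <= 0)) stop_fmt("means must be positive for a lognormal response")
  if (any(df$sd < 0) || any(df$n < 1)) stop_fmt("invalid sd or n")
  df <- df[order(df$dose), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("dose_response_summary", "data.frame")
  df
}

# log-scale moments reconstructed from arithmetic mean/SD
log_moments <- function(summary) {
  v <- log(1 + (summary$sd / summary$mean)^2)
  list(meanlog = log(summary$mean) - v / 2, varlog = v)
}

# relative response h(d; par) = mu(d)/a per family, on the log scale
model_log_h <- function(model) {
  switch(model,
    exp3 = function(d, p) p["b"] * d^p["g"],
    exp5 = function(d, p) log(p["c"] - (p["c"] - 1) * exp(-p["b"] * d^p["g"])),
    hill3 = function(d, p) log1p(p["c"] * d / (p["b"] + d)),
    hill5 = function(d, p) log1p(p["c"] * d^p["g"] / (p["b"]^p["g"] + d^p["g"])),
    inv_exp = function(d, p) log1p(p["c"] * exp(-p["b"] * d^(-p["g"]))),
    log_normal = function(d, p) log1p(p["c"] * stats::pnorm(p["g"] * log(d / p["b"]))),
    stop_fmt("unknown model '%s'", model)
  )
}

# Free parameters per family and their transforms (all optimized on an
# unconstrained scale). The shape power g is constrained to [1, 4] for the
# x^g families (exp3, exp5, hill5), where g < 1 would give an infinite slope
# at dose 0; the inverse-exponential and log-normal curves are flat at dose 0
# for any positive g, so there g ranges over [0.25, 4].
model_par_info <- function(model) {
  switch(model,
    exp3 = list(names = c("b", "g"), g_lo = 1),
    exp5 = list(names = c("b", "c", "g"), g_lo = 1, c_offset = 1),
    hill3 = list(names = c("b", "c")),
    hill5 = list(names = c("b", "c", "g"), g_lo = 1),
    inv_exp = list(names = c("b", "c", "g"), g_lo = 0.25),
    log_normal = list(names = c("b", "c", "g"), g_lo = 0.25)
  )
}

g_from_t <- function(t, lo = 1) lo + (4 - lo) * stats::plogis(t)
t_from_g <- function(g, lo = 1) {
  stats::qlogis(pmin(pmax((g - lo) / (4 - lo), 1e-6), 1 - 1e-6))
}

par_from_theta <- function(theta, info) {
  p <- c()
  i <- 1L
  for (nm in info$names) {
    if (nm == "g") {
      p["g"] <- g_from_t(theta[i], info$g_lo %||% 1)
    } else if (nm == "c" && !is.null(info$c_offset)) {
      p["c"] <- info$c_offset + exp(theta[i])
    } else {
      p[nm] <- exp(theta[i])
    }
    i <- i + 1L
  }
  p
}

theta_from_par <- function(p, info) {
  th <- numeric(length(info$names))
  for (i in seq_along(info$names)) {
    nm <- info$names[i]
    th[i] <- if (nm == "g") {
      t_from_g(p["g"], info$g_lo %||% 1)
    } else if (nm == "c" && !is.null(info$c_offset)) {
      log(max(p["c"] - info$c_offset, 1e-8))
    } else {
      log(max(p[nm], 1e-12))
    }
  }
  th
}

# Linearization-based starts: for a candidate amplitude, each family's
# inverse link is linear in log dose, so (b, g) follow from a two-point OLS
# on the positive-dose group means. Deterministic; infeasible candidates are
# skipped.
linearized_starts <- function(model, summary, lm_) {
  pos <- summary$dose > 0
  x <- summary$dose[pos]
  fold <- exp(lm_$meanlog[pos] - lm_$meanlog[summary$dose == 0][1])
  if (any(fold <= 1)) return(list())
  fmax <- max(fold)
  g_lo <- model_par_info(model)$g_lo %||% 1
  clip_g <- function(g) min(max(g, g_lo + 1e-4), 3.999)
  out <- list()
  add <- function(p) out[[length(out) + 1L]] <<- p
  ols <- function(y, xx) {
    keep <- is.finite(y) & is.finite(xx)
    if (sum(keep) < 2L) return(NULL)
    stats::coef(stats::lm(y[keep] ~ xx[keep]))
  }
  if (model == "exp3") {
    co <- ols(log(log(fold)), log(x))
    if (!is.null(co) && co[2] > 0) add(c(b = exp(unname(co[1])),
                                         g = clip_g(unname(co[2]))))
  } else if (model == "exp5") {
    for (cc in (fmax - 1) * c(1.05, 1.3, 2) + 1) {
      z <- (cc - fold) / (cc - 1)
      co <- ols(log(-log(z)), log(x))
      if (!is.null(co) && co[2] > 0) {
        add(c(b = exp(unname(co[1])), c = cc, g = clip_g(unname(co[2]))))
      }
    }
  } else if (model == "hill3") {
    co <- ols(1 / (fold - 1), 1 / x)
    if (!is.null(co) && co[1] > 0 && co[2] > 0) {
      add(c(b = unname(co[2] / co[1]), c = unname(1 / co[1])))
    }
  } else if (model == "hill5") {
    for (cc in (fmax - 1) * c(1.05, 1.3, 2)) {
      z <- (fold - 1) / cc
      co <- ols(log(z / (1 - z)), log(x))
      if (!is.null(co) && co[2] > 0) {
        g <- clip_g(unname(co[2]))
        add(c(b = exp(-unname(co[1]) / unname(co[2])), c = cc, g = g))
      }
    }
  } else if (model == "inv_exp") {
    for (cc in (fmax - 1) * c(1.001, 1.05, 1.3, 2)) {
      z <- (fold - 1) / cc
      co <- ols(log(-log(z)), log(x))
      if (!is.null(co) && co[2] < 0) {
        add(c(b = exp(unname(co[1])), c = cc, g = clip_g(-unname(co[2]))))
      }
    }
  } else if (model == "log_normal") {
    for (cc in (fmax - 1) * c(1.001, 1.05, 1.3, 2)) {
      z <- (fold - 1) / cc
      co <- ols(stats::qnorm(z), log(x))
      if (!is.null(co) && co[2] > 0) {
        g <- clip_g(unname(co[2]))
        add(c(b = exp(-unname(co[1]) / unname(co[2])), c = cc, g = g))
      }
    }
  }
  out
}

# deterministic start grid per family, from crude data features
model_starts <- function(model, summary, lm_) {
  dmax <- max(summary$dose)
  pos <- summary$dose > 0
  fold <- exp(lm_$meanlog[pos] - lm_$meanlog[summary$dose == 0][1])
  c0 <- max(max(fold) - 1, 0.1)
  b_hill <- c(dmax / 8, dmax / 2, 2 * dmax)
  g0 <- c(1.01, 1.5, 2.5)
  first_pos <- min(summary$dose[pos])
  # slope scale for the exponential families
  b_exp <- pmax(log(pmax(fold[1], 1.05)) / first_pos, 1e-8)
  b_exp <- unique(c(b_exp, b_exp / 10, b_exp / 100))
  starts <- list()
  add <- function(p) starts[[length(starts) + 1L]] <<- p
  if (model == "exp3") {
    for (b in b_exp) for (g in g0) add(c(b = b, g = g))
  } else if (model == "exp5") {
    for (b in b_exp * 5) for (g in g0) for (cc in c(c0 + 1, 2 * c0 + 1)) {
      add(c(b = b, c = cc, g = g))
    }
  } else if (model == "hill3") {
    for (b in b_hill) for (cc in c(c0 / 2, c0, 2 * c0)) add(c(b = b, c = cc))
  } else if (model == "hill5") {
    for (b in b_hill) for (cc in c(c0, 2 * c0)) for (g in g0) {
      add(c(b = b, c = cc, g = g))
    }
  } else if (model == "inv_exp") {
    for (b in c(first_pos, dmax / 2, dmax)) for (cc in c(c0, 2 * c0)) {
      for (g in g0) add(c(b = b, c = cc, g = g))
    }
  } else if (model == "log_normal") {
    for (b in c(first_pos / 2, first_pos, dmax / 2)) for (cc in c(c0, 2 * c0)) {
      for (g in g0) add(c(b = b, c = cc, g = g))
    }
  }
  starts
}

#' Fit one continuous dose-response model to summary data
#'
#' Maximizes the lognormal-response likelihood (common log-scale variance)
#' over the family's parameters, profiling the background level `a` in
#' closed form, from a fixed deterministic grid of starting values.
#'
#' @param summary A [dose_response_summary()].
#' @param model One of `"exp3"`, `"exp5"`, `"hill3"`, `"hill5"`,
#'   `"inv_exp"`, `"log_normal"`.
#' @param extra_starts Optional list of extra named start vectors (used
#'   internally to nest hill3 inside hill5).
#' @return A `bmd_fit`: `model`, `par` (including the profiled `a`),
#'   `loglik`, `converged`, and the fitted median function `mu`.
#' @export
fit_dose_model <- function(summary, model = BMD_MODELS, extra_starts = NULL) {
  model <- match.arg(model)
  if (!inherits(summary, "dose_response_summary")) {
    summary <- dose_response_summary(summary$dose, summary$mean, summary$sd,
                                     summary$n)
  }
  lm_ <- log_moments(summary)
  info <- model_par_info(model)
  log_h <- model_log_h(model)
  d <- summary$dose
  n <- summary$n
  N <- sum(n)
  ss_within <- sum((n - 1) * lm_$varlog)

  objective <- function(theta) {
    p <- par_from_theta(theta, info)
    lh <- log_h(d, p)
    if (any(!is.finite(lh))) return(1e10)
    resid <- lm_$meanlog - lh
    ln_a <- sum(n * resid) / N # profiled background
    sum(n * (resid - ln_a)^2)
  }

  starts <- c(linearized_starts(model, summary, lm_),
              model_starts(model, summary, lm_), extra_starts)
  best <- NULL
  for (p0 in starts) {
    th0 <- theta_from_par(p0, info)
    fit <- tryCatch(
      stats::optim(th0, objective, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(model = model, par = NULL, loglik = -Inf,
                          converged = FALSE, mu = NULL, summary = summary),
                     class = "bmd_fit"))
  }
  # polish from the best start (quasi-Newton handles the flat ridges that
  # exhaust Nelder-Mead on saturated fits)
  for (meth in c("BFGS", "Nelder-Mead")) {
    polish <- tryCatch(
      suppressWarnings(stats::optim(best$par, objective, method = meth,
                                    control = list(maxit = 10000,
                                                   reltol = 1e-14))),
      error = function(e) NULL
    )
    if (!is.null(polish) && polish$value <= best$value + 1e-12) {
      improved <- best$value - polish$value
      if (polish$value <= best$value) best <- polish
      # a polish that can no longer improve the objective counts as converged
      if (best$convergence != 0 && improved < 1e-10 * max(1, best$value)) {
        best$convergence <- 0L
      }
    }
  }
  p <- par_from_theta(best$par, info)
  lh <- log_h(d, p)
  resid <- lm_$meanlog - lh
  ln_a <- sum(n * resid) / N
  ss <- ss_within + sum(n * (resid - ln_a)^2)
  sigma2 <- ss / N
  loglik <- -N / 2 * (log(2 * pi * sigma2) + 1)
  par <- c(a = exp(ln_a), p, sigma = sqrt(sigma2))
  mu <- function(dose) exp(ln_a + log_h(dose, p))
  n_par <- length(info$names) + 2L # family params + background + variance
  structure(
    list(model = model, par = par, loglik = loglik, n_par = n_par,
         aic = 2 * n_par - 2 * loglik,
         converged = best$convergence == 0, mu = mu, summary = summary),
    class = "bmd_fit"
  )
}

#' @export
print.bmd_fit <- function(x, ...) {
  cat(sprintf("%s fit: logLik %.3f (%s)\n", x$model, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$par)) print(signif(x$par, 4))
  invisible(x)
}

#' Benchmark dose at a benchmark response
#'
#' Solves `mu(d) = (1 + bmr) * mu(0)` by bracketing and bisection
#' (`uniroot`) on `(0, 10 * max observed dose]`.
#'
#' @param fit A `bmd_fit` (converged).
#' @param bmr Benchmark response as a relative increase over background
#'   (0.5 = a 50% increase).
#' @return The benchmark dose.
#' @export
bmd_at_bmr <- function(fit, bmr = 0.5) {
  if (is.null(fit$mu)) stop_fmt("model '%s' did not converge", fit$model)
  if (bmr < 0) stop_fmt("bmr must be non-negative")
  if (bmr == 0) return(0)
  target <- (1 + bmr) * fit$mu(0)
  hi <- 10 * max(fit$summary$dose)
  f <- function(dd) fit$mu(dd) - target
  if (f(hi) < 0) stop_fmt("BMR not reached within 10x the maximum dose")
  lo <- hi * 1e-12
  while (f(lo) > 0 && lo > .Machine$double.xmin * 1e6) lo <- lo / 10
  if (f(lo) > 0) stop_fmt("BMR reached already at dose ~0; fit is degenerate")
  stats::uniroot(f, c(lo, hi), tol = hi * 1e-10)$root
}

#' Equal-weight model-averaged benchmark dose
#'
#' Fits every requested model, computes each converged model's BMD at the
#' requested benchmark response, and averages the included models' BMDs with
#' strictly equal weights. Models that fail to converge or never reach the
#' BMR are excluded and reported. Optionally, `aic_window` restricts the
#' average to models within that many AIC units of the best fit (the common
#' continuous benchmark-dose screening rule); the default `Inf` averages
#' every converged model.
#'
#' @param summary A [dose_response_summary()].
#' @param bmr Benchmark response (default 0.5, a 50% increase).
#' @param models Model names (default all six).
#' @param aic_window Inclusion window above the minimum AIC.
#' @return A `bmd_result`: `per_model` table (model, BMD, logLik, AIC,
#'   inclusion), `averaged_bmd`, `bmr`, `fits`.
#' @export
#' @examples
#' ds <- dose_response_summary(c(0, 12.5, 25, 50),
#'                             c(1.3, 3.3, 6.8, 10.4) * 1e-7,
#'                             c(0.25, 0.3, 0.64, 0.7) * 1e-7, n = 6)
#' \donttest{model_average(ds)$averaged_bmd}
model_average <- function(summary, bmr = 0.5, models = BMD_MODELS,
                          aic_window = Inf) {
  if (!inherits(summary, "dose_response_summary")) {
    summary <- dose_response_summary(summary$dose, summary$mean, summary$sd,
                                     summary$n)
  }
  fits <- list()
  for (m in models) {
    extra <- NULL
    if (m == "hill5" && !is.null(fits$hill3) && !is.null(fits$hill3$par)) {
      # nest: start hill5 at the hill3 optimum with g -> 1
      p3 <- fits$hill3$par
      extra <- list(c(b = unname(p3["b"]), c = unname(p3["c"]), g = 1.0001))
    }
    fits[[m]] <- fit_dose_model(summary, m, extra_starts = extra)
  }
  rows <- lapply(models, function(m) {
    f <- fits[[m]]
    bmd <- if (f$converged) {
      tryCatch(bmd_at_bmr(f, bmr), error = function(e) NA_real_)
    } else NA_real_
    data.frame(model = m, bmd = bmd, loglik = f$loglik,
               aic = f$aic %||% NA_real_,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  per_model <- do.call(rbind, rows)
  ok <- is.finite(per_model$bmd)
  if (!any(ok)) stop_fmt("no model produced a benchmark dose")
  ok <- ok & per_model$aic <= min(per_model$aic[ok]) + aic_window
  per_model$included <- ok
  if (any(!ok)) {
    warn_fmt("excluding model(s) from the average (no BMD or AIC above window): %s",
             paste(per_model$model[!ok], collapse = ", "))
  }
  structure(
    list(per_model = per_model,
         averaged_bmd = mean(per_model$bmd[ok]),
         bmr = bmr,
         aic_window = aic_window,
         fits = fits),
    class = "bmd_result"
  )
}

#' @export
print.bmd_result <- function(x, ...) {
  cat(sprintf("Model-averaged BMD at BMR %.0f%%: %.4g\n", 100 * x$bmr,
              x$averaged_bmd))
  print(transform(x$per_model, bmd = signif(bmd, 4), loglik = signif(loglik, 6)))
  invisible(x)
}
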