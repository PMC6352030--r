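#' Goodness-of-fit statistics for a kinetic model fit
#'
#' Computes the four statistics used to judge a fitted dehydration model:
#' the coefficient of determination \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, the
#' reduced chi-squared \eqn{\chi^2 = \sum (Y_p - Y_e)^2 / (N - n)}, the root
#' mean square error \eqn{RMSE = \sqrt{\sum (Y_p - Y_e)^2 / N}} and the
#' coefficient of residual variation
#' \eqn{CRV = 100 \sqrt{\chi^2} / \bar{Y}_e} (percent). Fits with
#' CRV below 20\% are considered usable for prediction.
#'
#' `R2_ratio` is also returned as a diagnostic: the ratio form
#' \eqn{\sum (Y_{p,i} - \bar{Y}_p)^2 / \sum (Y_{e,i} - \bar{Y}_p)^2},
#' an alternative rendering sometimes seen in the dehydration literature.
#'
#' @param predicted model predictions.
#' @param experimental observed values, same length.
#' @param n_params number of free model parameters n; requires N > n.
#' @return list with elements `R2`, `chi2`, `RMSE`, `CRV` (percent),
#'   `R2_ratio`, `N`, `n`.
#' @export
goodness_of_fit <- function(predicted, experimental, n_params) {
  N <- length(experimental)
  if (length(predicted) != N) {
    stop("`predicted` and `experimental` must have equal length", call. = FALSE)
  }
  if (N <= n_params) {
    stop("need more points than parameters (N > n)", call. = FALSE)
  }
  ybar <- mean(experimental)
  if (ybar == 0) {
    stop("mean of `experimental` is zero: CRV undefined", call. = FALSE)
  }
  res <- predicted - experimental
  ss_res <- sum(res^2)
  ss_tot <- sum((experimental - ybar)^2)
  R2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  chi2 <- ss_res / (N - n_params)
  RMSE <- sqrt(ss_res / N)
  CRV <- 100 * sqrt(chi2) / abs(ybar)
  pbar <- mean(predicted)
  denom <- sum((experimental - pbar)^2)
  R2_ratio <- if (denom == 0) NA_real_ else sum((predicted - pbar)^2) / denom
  list(R2 = R2, chi2 = chi2, RMSE = RMSE, CRV = CRV,
       R2_ratio = R2_ratio, N = N, n = n_params)
}

#' Linearisation-based starting values for the model fitter
#'
#' Peleg: on exact data \eqn{\tau/|Y - Y_0|} is linear in tau with
#' intercept k1 and slope k2, so an ordinary regression recovers the truth
#' exactly. Kelvin-Voigt: on exact data the two points \eqn{(t_1, 2 t_1)}
#' determine the model in closed form through
#' \eqn{r = (Y_2 - Y_1)/Y_1 = e^{-t_1/B}}; when that ratio is unusable
#' (noise, non-saturating data) A falls back to 1.05 times the largest
#' response magnitude and B to a through-origin regression of
#' \eqn{\log(1 - Y/A)} on tau. Burgers: the Kelvin-Voigt seed plus the
#' excess slope of the last two points over the saturating component,
#' floored at 0.
#'
#' @param tau times (min).
#' @param y response values.
#' @param family model key, see [model_families()].
#' @param Y0,direction Peleg anchor and sign (ignored otherwise).
#' @return named numeric vector of starting values.
#' @export
initial_guess <- function(tau, y, family, Y0 = 0, direction = 1) {
  ord <- order(tau)
  tau <- tau[ord]; y <- y[ord]
  if (length(tau) < 3) stop("need at least 3 points to seed a fit", call. = FALSE)
  if (diff(range(y)) == 0) {
    stop("constant series: cannot seed model parameters", call. = FALSE)
  }
  family <- match.arg(family, model_families())
  if (family == "peleg") {
    d <- abs(y - Y0)
    keep <- tau > 0 & d > 0
    if (sum(keep) < 2) stop("too few informative points for a Peleg seed", call. = FALSE)
    fit <- stats::lm(u ~ t, data = data.frame(u = tau[keep] / d[keep], t = tau[keep]))
    k <- pmax(unname(stats::coef(fit)), 1e-6)
    return(c(k1 = k[1], k2 = k[2]))
  }
  A <- NA_real_; B <- NA_real_
  t1 <- min(tau[tau > 0])
  y1 <- y[match(t1, tau)]
  y2 <- stats::approx(tau, y, xout = 2 * t1, rule = 2)$y
  if (is.finite(y1) && y1 != 0) {
    r <- (y2 - y1) / y1
    if (is.finite(r) && r > 0 && r < 1) {
      B <- -t1 / log(r)
      A <- y1 / (1 - exp(-t1 / B))
    }
  }
  if (!is.finite(A) || !is.finite(B) || B <= 0) {
    A <- 1.05 * y[which.max(abs(y))]
    z <- 1 - y / A
    keep <- tau > 0 & z > 0
    if (sum(keep) < 1) stop("cannot seed Kelvin-Voigt time constant", call. = FALSE)
    slope <- sum(log(z[keep]) * tau[keep]) / sum(tau[keep]^2)
    B <- if (slope < 0) -1 / slope else max(tau) / 2
  }
  if (family == "kelvin_voigt") return(c(A = A, B = B))
  np <- length(tau)
  slope_last <- (y[np] - y[np - 1]) / (tau[np] - tau[np - 1])
  kv_slope <- (eval_kelvin_voigt(tau[np], A, B) -
                 eval_kelvin_voigt(tau[np - 1], A, B)) / (tau[np] - tau[np - 1])
  c(A = A, B = B, C = max(0, slope_last - kv_slope))
}

#' Fit a kinetic model to a dehydration time series
#'
#' Bounded Levenberg-Marquardt least squares (via \pkg{minpack.lm}) of one
#' of the three model families to (tau, Y) data. For the Peleg family the
#' anchor `Y0` is fixed by default to the known initial value (the measured
#' water content at tau = 0; 0 for WL/SG/WL_T; 1 for the dehydration
#' ratio), so only k1 and k2 are free. Rate and time constants are bounded
#' below at 1e-9 and the Burgers velocity C at 0 unless
#' `constrain_C = FALSE`. If the first start fails to converge the fit is
#' restarted from deterministically rescaled seeds, so results are
#' reproducible run-to-run.
#'
#' @param tau times (min); duplicated values are allowed (pooled fits).
#' @param y response values, same length.
#' @param family `"peleg"`, `"kelvin_voigt"` or `"burgers"`.
#' @param Y0 fixed Peleg anchor; required unless `fit_Y0 = TRUE`.
#' @param direction Peleg direction, +1 or -1.
#' @param fit_Y0 estimate Y0 as a third free Peleg parameter.
#' @param constrain_C keep the Burgers velocity non-negative (default).
#' @param start optional named start values overriding [initial_guess()].
#' @return an object of class `od_fit`: list with `family`, `params`
#'   (named list incl. fixed values), `N`, `n`, `data`, `fitted`,
#'   `residuals` (predicted - experimental), `stats`
#'   (R2/chi2/RMSE/CRV/R2_ratio), `usable` (CRV < 20) and `info`
#'   (optimizer diagnostics).
#' @export
fit_model <- function(tau, y, family, Y0 = NULL, direction = NULL,
                      fit_Y0 = FALSE, constrain_C = TRUE, start = NULL) {
  family <- match.arg(family, model_families())
  if (length(tau) != length(y)) stop("`tau` and `y` lengths differ", call. = FALSE)
  ord <- order(tau)
  tau <- tau[ord]; y <- y[ord]
  if (any(tau < 0)) stop("`tau` must be non-negative", call. = FALSE)

  if (family == "peleg") {
    if (is.null(direction)) {
      direction <- if (stats::cor(tau, y) < 0) -1 else 1
    }
    if (is.null(Y0)) {
      if (!fit_Y0) stop("supply `Y0` for the Peleg family or set fit_Y0 = TRUE",
                        call. = FALSE)
      Y0 <- y[1]
    }
  }

  n_free <- switch(family, peleg = 2L + fit_Y0, kelvin_voigt = 2L,
                   burgers = 3L)
  N <- length(y)
  if (N <= n_free) {
    stop("insufficient data: N = ", N, " points for n = ", n_free,
         " parameters", call. = FALSE)
  }

  seed <- if (!is.null(start)) start else {
    initial_guess(tau, y, family, Y0 = if (is.null(Y0)) 0 else Y0,
                  direction = if (is.null(direction)) 1 else direction)
  }
  if (family == "peleg" && fit_Y0) seed <- c(seed, Y0 = Y0)

  spec <- switch(family,
    peleg = list(
      lower = c(k1 = 1e-9, k2 = 1e-9, Y0 = -Inf)[seq_along(seed)],
      fn = function(p) {
        y0 <- if (fit_Y0) p[["Y0"]] else Y0
        y0 + direction * tau / (p[["k1"]] + p[["k2"]] * tau) - y
      }),
    kelvin_voigt = list(
      lower = c(A = -Inf, B = 1e-9),
      fn = function(p) p[["A"]] * (1 - exp(-tau / p[["B"]])) - y),
    burgers = list(
      lower = c(A = -Inf, B = 1e-9, C = if (constrain_C) 0 else -Inf),
      fn = function(p) p[["A"]] * (1 - exp(-tau / p[["B"]])) +
        p[["C"]] * tau - y)
  )
  stopifnot(length(seed) == n_free)
  # peleg fraction at tau = 0 is exactly 0: guard the residual fn
  if (family == "peleg" && any(tau == 0)) {
    fn_raw <- spec$fn
    spec$fn <- function(p) { r <- fn_raw(p); r[tau == 0] <- (if (fit_Y0) p[["Y0"]] else Y0) - y[tau == 0]; r }
  }

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)
  scales <- list(1, 0.3, 3, 10)  # deterministic restart ladder
  best <- NULL
  for (sc in scales) {
    p0 <- pmax(seed * sc, spec$lower + ifelse(is.finite(spec$lower), 1e-12, 0))
    p0[!is.finite(p0)] <- 1
    # a start pinned at a zero bound cannot be rescaled off it: nudge
    p0[p0 == 0] <- 1e-4 * sc
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = spec$lower, fn = spec$fn,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    ssr <- sum(res$fvec^2)
    if (ok && (is.null(best) || ssr < best$ssr - 1e-15)) {
      best <- list(fit = res, ssr = ssr)
    }
    if (!is.null(best) && best$ssr < 1e-20) break  # exact fit found
  }
  if (is.null(best)) {
    stop("model fit failed to converge for family '", family,
         "' after restarts (N = ", N, ")", call. = FALSE)
  }
  est <- as.list(stats::coef(best$fit))
  params <- switch(family,
    peleg = list(Y0 = if (fit_Y0) est$Y0 else Y0, k1 = est$k1, k2 = est$k2,
                 direction = direction),
    kelvin_voigt = list(A = est$A, B = est$B),
    burgers = list(A = est$A, B = est$B, C = est$C)
  )
  fitted <- eval_family(family, tau, params)
  stats <- goodness_of_fit(fitted, y, n_free)
  structure(list(
    family = family, params = params, N = N, n = n_free,
    data = data.frame(tau = tau, y = y),
    fitted = fitted, residuals = fitted - y,
    stats = stats, usable = is.finite(stats$CRV) && stats$CRV < 20,
    info = list(code = best$fit$info, message = best$fit$message,
                ssr = best$ssr)
  ), class = "od_fit")
}

#' @export
print.od_fit <- function(x, ...) {
  cat("Kinetic model fit:", x$family, "\n")
  est <- x$params[!names(x$params) %in% "direction"]
  cat("  parameters: ",
      paste(sprintf("%s = %.6g", names(est), unlist(est)), collapse = ", "),
      "\n", sep = "")
  if (x$family == "peleg") {
    cat("  initial rate 1/k1 =",
        format(peleg_initial_rate(x$params$k1, x$params$direction), digits = 4),
        "per min; equilibrium =",
        format(peleg_equilibrium(x$params$Y0, x$params$k2, x$params$direction),
               digits = 4), "\n")
  }
  with(x$stats, cat(sprintf(
    "  N = %d, n = %d | R2 = %.4f, chi2 = %.4g, RMSE = %.4g, CRV = %.2f%%\n",
    N, n, R2, chi2, RMSE, CRV)))
  cat("  usable for prediction (CRV < 20%):", x$usable, "\n")
  invisible(x)
}

# response -> Peleg anchor/direction conventions of the analysis
response_peleg_defaults <- function(response, series_tau, series_y) {
  switch(response,
    WC = list(Y0 = if (any(series_tau == 0)) series_y[series_tau == 0][1] else NULL,
              direction = -1),
    CR = list(Y0 = 1, direction = -1),
    list(Y0 = 0, direction = 1)  # WL, SG, WLT grow from zero
  )
}

#' Fit report across solutes, responses and model families
#'
#' Runs [fit_model()] for every requested combination and assembles one
#' table in the layout of a model-comparison report: one row per (solute,
#' response, family) with the fitted parameters, N, n, the four fit
#' statistics and the CRV < 20\% usability flag. Per-response conventions:
#' water content is fitted with Peleg only (Y0 = measured initial value,
#' decreasing); WL, SG and WL_T with all three families (anchored at 0,
#' increasing); the dehydration ratio CR with Peleg only (anchored at
#' CR = 1 at tau = 0, decreasing; the undefined tau = 0 ratio is replaced
#' by that anchor for fitting). Failed fits become flagged rows, not
#' errors.
#'
#' @param kinetics an `od_kinetics` object (the averaged table is used) or
#'   a data.frame with columns `solute`, `tau_min` and the responses.
#' @param responses subset of `c("WC","SG","WL","WLT","CR")`.
#' @param families optional family subset applied to every response,
#'   overriding the per-response defaults.
#' @param anchor_t0 include the tau = 0 anchor point in the fitted series
#'   (default TRUE).
#' @return data.frame of class `od_fit_report` with columns `solute`,
#'   `response`, `family`, `k1`, `k2`, `A`, `B`, `C`, `N`, `n`, `R2`,
#'   `chi2`, `RMSE`, `CRV_pct`, `usable`, `fit_ok`.
#' @export
fit_report <- function(kinetics,
                       responses = c("WC", "SG", "WL", "WLT", "CR"),
                       families = NULL, anchor_t0 = TRUE) {
  tab <- if (inherits(kinetics, "od_kinetics")) kinetics$averaged else kinetics
  responses <- match.arg(responses, several.ok = TRUE)
  default_fam <- list(WC = "peleg", CR = "peleg",
                      WL = model_families(), SG = model_families(),
                      WLT = model_families())
  rows <- list()
  for (sol in unique(tab$solute)) {
    sub <- tab[tab$solute == sol, , drop = FALSE]
    for (resp in responses) {
      if (!resp %in% names(sub)) next
      fams <- if (is.null(families)) default_fam[[resp]] else families
      tau <- sub$tau_min
      yv <- sub[[resp]]
      if (resp == "CR") {
        yv[tau == 0] <- 1  # Y0 = 1 anchor replaces the undefined 0/0 ratio
      }
      keep <- is.finite(yv) & (anchor_t0 | tau > 0)
      tau_f <- tau[keep]; y_f <- yv[keep]
      for (fam in fams) {
        row <- data.frame(solute = sol, response = resp, family = fam,
                          k1 = NA_real_, k2 = NA_real_, A = NA_real_,
                          B = NA_real_, C = NA_real_, N = NA_integer_,
                          n = NA_integer_, R2 = NA_real_, chi2 = NA_real_,
                          RMSE = NA_real_, CRV_pct = NA_real_,
                          usable = NA, fit_ok = FALSE,
                          stringsAsFactors = FALSE)
        fit <- tryCatch({
          if (fam == "peleg") {
            conv <- response_peleg_defaults(resp, tau_f, y_f)
            fit_model(tau_f, y_f, fam, Y0 = conv$Y0,
                      direction = conv$direction,
                      fit_Y0 = is.null(conv$Y0))
          } else {
            fit_model(tau_f, y_f, fam)
          }
        }, error = function(e) e)
        if (!inherits(fit, "error")) {
          for (pn in intersect(names(fit$params), c("k1", "k2", "A", "B", "C"))) {
            row[[pn]] <- fit$params[[pn]]
          }
          row$N <- fit$N; row$n <- fit$n
          row$R2 <- fit$stats$R2; row$chi2 <- fit$stats$chi2
          row$RMSE <- fit$stats$RMSE; row$CRV_pct <- fit$stats$CRV
          row$usable <- fit$usable; row$fit_ok <- TRUE
        } else {
          row$usable <- FALSE
          attr(row, "error") <- conditionMessage(fit)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(solute = character(), response = character(),
               family = character(), k1 = numeric(), k2 = numeric(),
               A = numeric(), B = numeric(), C = numeric(), N = integer(),
               n = integer(), R2 = numeric(), chi2 = numeric(),
               RMSE = numeric(), CRV_pct = numeric(), usable = logical(),
               fit_ok = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("od_fit_report", "data.frame")
  out
}

#' Best model family per solute and response
#'
#' Ranks the families of a [fit_report()] table by lowest CRV, breaking
#' ties by lowest RMSE, and returns the winning row per (solute, response).
#'
#' @param report an `od_fit_report` data.frame.
#' @return data.frame with the best-ranked row per group.
#' @export
best_model <- function(report) {
  ok <- report[report$fit_ok, , drop = FALSE]
  if (!nrow(ok)) return(ok)
  key <- interaction(ok$solute, ok$response, drop = TRUE)
  picked <- lapply(split(seq_len(nrow(ok)), key), function(idx) {
    sub <- ok[idx, , drop = FALSE]
    sub[order(sub$CRV_pct, sub$RMSE), , drop = FALSE][1, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}
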