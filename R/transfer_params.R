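#' Dry-basis water content from the dry-matter mass fraction
#'
#' Converts a dry-matter mass fraction \eqn{s} into water content on a dry
#' basis, \eqn{WC = (1 - s)/s}, in g water per g dry matter. A fraction of
#' 0.5 (equal water and solids) gives WC = 1; fully dry tissue (s = 1)
#' gives 0.
#'
#' @param s_tau dry-matter mass fraction(s), in (0, 1].
#' @return numeric vector of water contents (g H2O / g d.m.).
#' @examples
#' water_content(0.5)        # 1 g/g d.m.
#' water_content(1 / 6.69)   # fresh apple tissue, about 5.69 g/g d.m.
#' @export
water_content <- function(s_tau) {
  if (!is.numeric(s_tau) || any(!is.finite(s_tau))) {
    stop("`s_tau` must be finite numeric", call. = FALSE)
  }
  if (any(s_tau <= 0) || any(s_tau > 1)) {
    stop("`s_tau` must lie in (0, 1]", call. = FALSE)
  }
  (1 - s_tau) / s_tau
}

#' Solid gain per gram of initial dry matter
#'
#' \eqn{SG = (s_\tau m_\tau - s_0 m_0) / (s_0 m_0)}: the net uptake of
#' osmotic solute by the tissue, normalised by the initial dry matter.
#' Negative values (leaching of native solids) are retained, not clipped.
#'
#' @param s_tau dry-matter fraction at immersion time tau, in (0, 1].
#' @param m_tau sample mass at time tau (g, > 0).
#' @param m0 initial sample mass (g, > 0).
#' @param s0 initial dry-matter fraction, in (0, 1].
#' @return numeric vector of solid gains (g solids / g initial d.m.).
#' @export
solid_gain <- function(s_tau, m_tau, m0, s0) {
  check_raw_args(s_tau, m_tau, m0, s0)
  (s_tau * m_tau - s0 * m0) / (s0 * m0)
}

#' Water loss per gram of initial dry matter
#'
#' \eqn{WL = [(1 - s_0) m_0 - (1 - s_\tau) m_\tau] / (s_0 m_0)}: the water
#' removed from the tissue, normalised by the initial dry matter. Negative
#' values mean the sample took up water; they are kept as-is.
#'
#' @inheritParams solid_gain
#' @return numeric vector of water losses (g H2O / g initial d.m.).
#' @export
water_loss <- function(s_tau, m_tau, m0, s0) {
  check_raw_args(s_tau, m_tau, m0, s0)
  ((1 - s0) * m0 - (1 - s_tau) * m_tau) / (s0 * m0)
}

#' True water loss: water loss corrected for concurrent solid uptake
#'
#' \eqn{WL_T = WL / (1 + SG)} re-expresses water loss per gram of the
#' *current* dry matter, so that solute impregnation no longer inflates the
#' apparent dehydration. For SG >= 0, WL_T <= WL.
#'
#' @param WL water loss (g / g initial d.m.).
#' @param SG solid gain (g / g initial d.m.); must exceed -1.
#' @return numeric vector of true water losses.
#' @export
true_water_loss <- function(WL, SG) {
  if (any(!is.finite(WL)) || any(!is.finite(SG))) {
    stop("`WL` and `SG` must be finite numeric", call. = FALSE)
  }
  if (any(SG <= -1)) {
    stop("`SG` must be greater than -1", call. = FALSE)
  }
  WL / (1 + SG)
}

#' Dehydration-to-impregnation ratio
#'
#' The ratio \eqn{CR = WL_T / WL}, algebraically equal to \eqn{1/(1 + SG)}.
#' Values near 1 indicate dehydration with little solute uptake; heavy
#' impregnation drives the ratio towards 0. Undefined at WL = 0 (the ratio
#' is 0/0 at time zero); such points are returned as `NA`, never as 0.
#'
#' @param WL_T true water loss.
#' @param WL water loss; elements equal to 0 yield `NA_real_`.
#' @return numeric vector of ratios, `NA` where WL = 0.
#' @export
cr_ratio <- function(WL_T, WL) {
  if (any(!is.finite(WL_T)) || any(!is.finite(WL))) {
    stop("`WL_T` and `WL` must be finite numeric", call. = FALSE)
  }
  out <- rep(NA_real_, length(WL))
  ok <- WL != 0
  out[ok] <- WL_T[ok] / WL[ok]
  out
}

check_raw_args <- function(s_tau, m_tau, m0, s0) {
  vals <- list(s_tau = s_tau, m_tau = m_tau, m0 = m0, s0 = s0)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || any(!is.finite(vals[[nm]]))) {
      stop(sprintf("`%s` must be finite numeric", nm), call. = FALSE)
    }
  }
  if (any(s_tau <= 0) || any(s_tau > 1)) stop("`s_tau` must lie in (0, 1]", call. = FALSE)
  if (any(s0 <= 0) || any(s0 > 1)) stop("`s0` must lie in (0, 1]", call. = FALSE)
  if (any(m_tau <= 0)) stop("`m_tau` must be positive", call. = FALSE)
  if (any(m0 <= 0)) stop("`m0` must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Kinetic-parameter table from raw measurements
#'
#' Computes WC, SG, WL, WL_T and CR for every raw observation, per
#' replicate, then averages over replicates for each (solute, time). Both
#' tables are returned; model fitting normally consumes the averaged one.
#'
#' @param measurements data.frame with columns `solute`, `replicate`,
#'   `tau_min`, `mass_g`, `dry_fraction` and optionally `a_w`. Each
#'   (solute, replicate, tau_min) combination may appear once.
#' @param initial data.frame with columns `solute`, `replicate`, `m0_g`,
#'   `s0`: the initial state of every sample series.
#' @param wc_basis `"current"` (default) computes water content as
#'   (1 - s)/s on the current dry matter; `"initial"` uses
#'   (1 - s) m / (s0 m0), water mass per gram of initial dry matter.
#' @return an object of class `od_kinetics`: a list with elements
#'   `by_rep` (per-replicate table) and `averaged` (replicate means per
#'   solute and time), both data.frames with columns `solute`, `tau_min`,
#'   `WC`, `SG`, `WL`, `WLT`, `CR` (plus `replicate` in `by_rep`).
#' @export
kinetics_table <- function(measurements, initial,
                           wc_basis = c("current", "initial")) {
  wc_basis <- match.arg(wc_basis)
  need <- c("solute", "replicate", "tau_min", "mass_g", "dry_fraction")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("`measurements` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  need0 <- c("solute", "replicate", "m0_g", "s0")
  miss0 <- setdiff(need0, names(initial))
  if (length(miss0)) {
    stop("`initial` lacks column(s): ", paste(miss0, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(measurements$solute, measurements$replicate,
               measurements$tau_min)
  if (anyDuplicated(key)) {
    stop("duplicated (solute, replicate, tau_min) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  ikey <- paste(initial$solute, initial$replicate)
  mkey <- paste(measurements$solute, measurements$replicate)
  if (anyDuplicated(ikey)) {
    stop("duplicated (solute, replicate) rows in `initial`", call. = FALSE)
  }
  lost <- setdiff(unique(mkey), ikey)
  if (length(lost)) {
    stop("no initial state for replicate(s): ",
         paste(lost, collapse = "; "), call. = FALSE)
  }
  idx <- match(mkey, ikey)
  m0 <- initial$m0_g[idx]
  s0 <- initial$s0[idx]

  # a tau = 0 record, when present, is the initial state itself
  at0 <- measurements$tau_min == 0
  if (any(at0)) {
    bad <- at0 & (abs(measurements$mass_g - m0) > 1e-8 |
                    abs(measurements$dry_fraction - s0) > 1e-8)
    if (any(bad)) {
      warning("tau = 0 record(s) disagree with `initial` for: ",
              paste(unique(mkey[bad]), collapse = "; "), call. = FALSE)
    }
  }

  s <- measurements$dry_fraction
  m <- measurements$mass_g
  WC <- if (wc_basis == "current") water_content(s) else {
    check_raw_args(s, m, m0, s0)
    (1 - s) * m / (s0 * m0)
  }
  SG <- solid_gain(s, m, m0, s0)
  WL <- water_loss(s, m, m0, s0)
  if (any(WL < 0) || any(SG < 0)) {
    message(sum(WL < 0), " negative WL and ", sum(SG < 0),
            " negative SG value(s) retained")
  }
  WLT <- true_water_loss(WL, SG)
  CR <- cr_ratio(WLT, WL)

  by_rep <- data.frame(
    solute = measurements$solute, replicate = measurements$replicate,
    tau_min = measurements$tau_min,
    WC = WC, SG = SG, WL = WL, WLT = WLT, CR = CR,
    stringsAsFactors = FALSE
  )
  if ("a_w" %in% names(measurements)) by_rep$a_w <- measurements$a_w
  by_rep <- by_rep[order(by_rep$solute, by_rep$replicate, by_rep$tau_min), ,
                   drop = FALSE]
  rownames(by_rep) <- NULL

  value_cols <- intersect(c("WC", "SG", "WL", "WLT", "CR", "a_w"),
                          names(by_rep))
  averaged <- stats::aggregate(
    by_rep[value_cols],
    by = list(solute = by_rep$solute, tau_min = by_rep$tau_min),
    FUN = function(x) mean(x)  # NA (CR at tau=0) propagates: still NA
  )
  averaged <- averaged[order(averaged$solute, averaged$tau_min), ,
                       drop = FALSE]
  rownames(averaged) <- NULL

  structure(list(by_rep = by_rep, averaged = averaged, wc_basis = wc_basis),
            class = "od_kinetics")
}

#' @export
print.od_kinetics <- function(x, ...) {
  cat("Osmotic-dehydration kinetics (basis: ", x$wc_basis, " dry matter)\n",
      sep = "")
  cat("  solutes:   ", paste(unique(x$averaged$solute), collapse = ", "),
      "\n", sep = "")
  cat("  times:     ", paste(unique(x$averaged$tau_min), collapse = ", "),
      " min\n", sep = "")
  cat("  replicates:", length(unique(x$by_rep$replicate)), "\n")
  cat("\nReplicate-averaged table:\n")
  print(x$averaged, digits = 4, ...)
  invisible(x)
}
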