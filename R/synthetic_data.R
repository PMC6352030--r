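#' Published fitted kinetic parameters for the five osmotic agents
#'
#' The fitted model parameters reported for osmotic dehydration of apple
#' tissue in five hypertonic solutions (erythritol, xylitol, maltitol and
#' dihydroxyacetone at 30\%; sucrose at 50\%), for the five responses:
#' water content (WC, Peleg), water loss (WL), solid gain (SG), true water
#' loss (WLT) (each Peleg / Kelvin-Voigt / Burgers) and the dehydration
#' ratio (CR, Peleg). These serve as fitting targets for validation and as
#' ground-truth presets for the study simulator. Time is in minutes
#' throughout; the Peleg anchor Y0 is 5.69 g/g d.m. for WC (fresh apple),
#' 0 for WL/SG/WLT and 1 for CR.
#'
#' @return data.frame with columns `solute`, `response`, `family`, `Y0`,
#'   `direction`, `k1`, `k2`, `A`, `B`, `C`.
#' @export
od_reference_params <- function() {
  p <- function(solute, response, k1, k2, Y0, direction) {
    data.frame(solute = solute, response = response, family = "peleg",
               Y0 = Y0, direction = direction, k1 = k1, k2 = k2,
               A = NA_real_, B = NA_real_, C = NA_real_,
               stringsAsFactors = FALSE)
  }
  kv <- function(solute, response, A, B) {
    data.frame(solute = solute, response = response, family = "kelvin_voigt",
               Y0 = NA_real_, direction = NA_real_, k1 = NA_real_,
               k2 = NA_real_, A = A, B = B, C = NA_real_,
               stringsAsFactors = FALSE)
  }
  bu <- function(solute, response, A, B, C) {
    data.frame(solute = solute, response = response, family = "burgers",
               Y0 = NA_real_, direction = NA_real_, k1 = NA_real_,
               k2 = NA_real_, A = A, B = B, C = C,
               stringsAsFactors = FALSE)
  }
  sol <- c("erythritol", "xylitol", "maltitol", "DHA", "sucrose")
  wc0 <- 5.69
  rbind(
    # water content, Peleg, decreasing from the fresh-apple value
    p(sol[1], "WC", 10.892, 0.242, wc0, -1),
    p(sol[2], "WC", 10.804, 0.264, wc0, -1),
    p(sol[3], "WC", 22.588, 0.294, wc0, -1),
    p(sol[4], "WC",  6.591, 0.344, wc0, -1),
    p(sol[5], "WC",  4.498, 0.260, wc0, -1),
    # water loss
    p(sol[1], "WL", 16.714, 0.534, 0, 1), kv(sol[1], "WL", 1.557, 37.648),
    bu(sol[1], "WL", 1.555, 37.460, 0.000e-3),
    p(sol[2], "WL", 21.117, 0.558, 0, 1), kv(sol[2], "WL", 1.482, 41.120),
    bu(sol[2], "WL", 0.957, 19.818, 3.304e-3),
    p(sol[3], "WL", 45.191, 0.846, 0, 1), kv(sol[3], "WL", 0.932, 51.859),
    bu(sol[3], "WL", 0.574, 26.915, 2.038e-3),
    p(sol[4], "WL", 13.019, 0.658, 0, 1), kv(sol[4], "WL", 1.340, 28.683),
    bu(sol[4], "WL", 1.319, 27.946, 0.132e-3),
    p(sol[5], "WL", 28.202, 0.362, 0, 1), kv(sol[5], "WL", 2.113, 63.358),
    bu(sol[5], "WL", 0.941, 19.074, 6.332e-3),
    # solid gain
    p(sol[1], "SG", 103.136, 0.782, 0, 1), kv(sol[1], "SG", 0.871, 115.812),
    bu(sol[1], "SG", 0.863, 114.045, 0.000e-3),
    p(sol[2], "SG",  89.879, 1.108, 0, 1), kv(sol[2], "SG", 0.634, 77.564),
    bu(sol[2], "SG", 0.632, 77.055, 0.000e-3),
    p(sol[3], "SG", 138.805, 1.398, 0, 1), kv(sol[3], "SG", 0.456, 96.233),
    bu(sol[3], "SG", 0.455, 95.800, 0.000e-3),
    p(sol[4], "SG",  79.275, 1.975, 0, 1), kv(sol[4], "SG", 0.418, 45.490),
    bu(sol[4], "SG", 0.399, 44.420, 0.020e-3),
    p(sol[5], "SG",  22.821, 1.254, 0, 1), kv(sol[5], "SG", 0.699, 25.840),
    bu(sol[5], "SG", 0.599, 19.488, 0.704e-3),
    # true water loss
    p(sol[1], "WLT",  8.734, 0.993, 0, 1), kv(sol[1], "WLT", 0.944, 18.425),
    bu(sol[1], "WLT", 0.942, 18.163, 0.000e-3),
    p(sol[2], "WLT", 13.276, 0.982, 0, 1), kv(sol[2], "WLT", 0.923, 21.465),
    bu(sol[2], "WLT", 0.733, 11.139, 1.417e-3),
    p(sol[3], "WLT", 34.796, 1.338, 0, 1), kv(sol[3], "WLT", 0.646, 32.687),
    bu(sol[3], "WLT", 0.455, 15.824, 1.276e-3),
    p(sol[4], "WLT", 10.983, 0.966, 0, 1), kv(sol[4], "WLT", 0.953, 20.798),
    bu(sol[4], "WLT", 0.923, 19.484, 0.209e-3),
    p(sol[5], "WLT", 36.246, 0.696, 0, 1), kv(sol[5], "WLT", 1.174, 49.883),
    bu(sol[5], "WLT", 0.608, 14.691, 3.340e-3),
    # dehydration ratio, Peleg, decreasing from 1
    p(sol[1], "CR", 139.433, 1.645, 1, -1),
    p(sol[2], "CR", 124.570, 1.997, 1, -1),
    p(sol[3], "CR", 255.096, 2.046, 1, -1),
    p(sol[4], "CR",  77.326, 3.007, 1, -1),
    p(sol[5], "CR",  23.758, 2.260, 1, -1)
  )
}

# lowest-CRV family per solute for WL and SG, used as simulation truth
default_truth_families <- function() {
  list(
    erythritol = c(WL = "kelvin_voigt", SG = "kelvin_voigt"),
    xylitol    = c(WL = "burgers",      SG = "kelvin_voigt"),
    maltitol   = c(WL = "burgers",      SG = "kelvin_voigt"),
    DHA        = c(WL = "burgers",      SG = "kelvin_voigt"),
    sucrose    = c(WL = "burgers",      SG = "burgers")
  )
}

#' Configuration of a simulated osmotic-dehydration study
#'
#' Defines the design grid and error model of a simulated study matching
#' the laboratory protocol the analysis targets: five osmotic agents,
#' immersion times 30-180 min in 30-min steps (plus the tau = 0 initial
#' state), two technological replicates, nominal 20 g samples and fresh
#' tissue at 5.69 g water per g dry matter. Each solute carries a true
#' generating model for WL and for SG (defaults: the best-fitting
#' published family per solute, see [od_reference_params()]). Measurement
#' noise is additive Gaussian on the sample mass and on the dry-matter
#' fraction.
#'
#' @param solutes named list: for each solute, a list with elements `WL`
#'   and `SG`, each a list `(family, params)` where `params` is the named
#'   parameter list of the family. `NULL` uses the published presets.
#' @param time_grid immersion times in minutes, strictly increasing from 0.
#' @param replicates technological replicates per treatment (default 2).
#' @param m0 nominal initial sample mass, g (default 20).
#' @param m0_sd between-sample standard deviation of the initial mass, g
#'   (default 1, so most samples fall within 20 +/- 2 g).
#' @param s0 initial dry-matter fraction (default 1/6.69, i.e. an initial
#'   water content of 5.69 g/g d.m.).
#' @param noise_sd_mass measurement noise s.d. on mass, g (default 0.05).
#' @param noise_sd_s measurement noise s.d. on the dry fraction
#'   (default 0.002).
#' @param seed integer seed making [generate_study()] deterministic.
#' @return list of class `od_sim_config`.
#' @export
od_sim_config <- function(solutes = NULL, time_grid = seq(0, 180, by = 30),
                          replicates = 2, m0 = 20, m0_sd = 1,
                          s0 = 1 / 6.69, noise_sd_mass = 0.05,
                          noise_sd_s = 0.002, seed = 1L) {
  if (is.null(solutes)) {
    ref <- od_reference_params()
    fams <- default_truth_families()
    solutes <- lapply(names(fams), function(sol) {
      lapply(c(WL = "WL", SG = "SG"), function(resp) {
        fam <- fams[[sol]][[resp]]
        row <- ref[ref$solute == sol & ref$response == resp &
                     ref$family == fam, ]
        params <- switch(fam,
          peleg = list(Y0 = row$Y0, k1 = row$k1, k2 = row$k2,
                       direction = row$direction),
          kelvin_voigt = list(A = row$A, B = row$B),
          burgers = list(A = row$A, B = row$B, C = row$C))
        list(family = fam, params = params)
      })
    })
    names(solutes) <- names(fams)
  }
  if (time_grid[1] != 0 || is.unsorted(time_grid, strictly = TRUE)) {
    stop("`time_grid` must increase strictly from 0", call. = FALSE)
  }
  stopifnot(replicates >= 1, m0 > 0, m0_sd >= 0, s0 > 0, s0 <= 1,
            noise_sd_mass >= 0, noise_sd_s >= 0)
  structure(list(solutes = solutes, time_grid = time_grid,
                 replicates = replicates, m0 = m0, m0_sd = m0_sd, s0 = s0,
                 noise_sd_mass = noise_sd_mass, noise_sd_s = noise_sd_s,
                 seed = as.integer(seed)),
            class = "od_sim_config")
}

#' Noise-free true kinetics for one simulated solute
#'
#' Evaluates the configured generating models of WL and SG on the time
#' grid. Both are exactly 0 at tau = 0.
#'
#' @param config an [od_sim_config()] object.
#' @param solute solute name present in `config$solutes`.
#' @return data.frame with columns `tau_min`, `WL_true`, `SG_true`.
#' @export
simulate_true_kinetics <- function(config, solute) {
  stopifnot(inherits(config, "od_sim_config"))
  if (!solute %in% names(config$solutes)) {
    stop("unknown solute '", solute, "'", call. = FALSE)
  }
  truth <- config$solutes[[solute]]
  tau <- config$time_grid
  data.frame(
    tau_min = tau,
    WL_true = eval_family(truth$WL$family, tau, truth$WL$params),
    SG_true = eval_family(truth$SG$family, tau, truth$SG$params)
  )
}

#' Invert water loss and solid gain back to raw mass and dry fraction
#'
#' The algebraic inverse of the mass-balance definitions: given true WL
#' and SG and an initial state, reconstruct the sample mass and dry-matter
#' fraction that would produce them. Round-tripping through
#' [solid_gain()] and [water_loss()] is exact to machine precision.
#'
#' @param WL,SG kinetic values (SG > -1).
#' @param m0,s0 initial mass (g) and dry fraction.
#' @return data.frame with columns `m_tau`, `s_tau`.
#' @export
invert_to_raw <- function(WL, SG, m0, s0) {
  if (any(SG <= -1)) stop("`SG` must exceed -1", call. = FALSE)
  dm <- s0 * m0 * (1 + SG)                       # dry matter now
  water <- (1 - s0) * m0 - WL * s0 * m0          # water now
  m_tau <- dm + water
  if (any(m_tau <= 0)) {
    stop("infeasible kinetics: non-positive sample mass", call. = FALSE)
  }
  s_tau <- dm / m_tau
  if (any(s_tau <= 0) || any(s_tau > 1)) {
    stop("infeasible kinetics: dry fraction outside (0, 1]", call. = FALSE)
  }
  data.frame(m_tau = m_tau, s_tau = s_tau)
}

#' Generate a complete synthetic dehydration study
#'
#' For every solute x time x replicate cell the configured true kinetics
#' are inverted to a raw (mass, dry fraction) pair and independent
#' Gaussian measurement noise is added. Noisy values falling outside
#' validity (mass <= 0 or dry fraction outside (0, 1]) are redrawn up to
#' 100 times before being clipped with a warning, to avoid truncation bias
#' near the bounds. The tau = 0 record is the initial state of the sample
#' series itself and carries no measurement noise. Fully deterministic
#' under the configured seed.
#'
#' @param config an [od_sim_config()] object.
#' @return object of class `od_study`: list with `measurements` (columns
#'   `solute`, `replicate`, `tau_min`, `mass_g`, `dry_fraction`),
#'   `initial` (columns `solute`, `replicate`, `m0_g`, `s0`), `truth`
#'   (the generating models plus the noise-free kinetic table per solute)
#'   and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "od_sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  meas <- list(); init <- list(); truth <- list()
  n_clipped <- 0L
  for (sol in names(config$solutes)) {
    kin <- simulate_true_kinetics(config, sol)
    truth[[sol]] <- list(models = config$solutes[[sol]], kinetics = kin)
    for (rep_i in seq_len(config$replicates)) {
      m0 <- stats::rnorm(1, config$m0, config$m0_sd)
      if (m0 <= 0) m0 <- config$m0
      raw <- invert_to_raw(kin$WL_true, kin$SG_true, m0, config$s0)
      m_meas <- raw$m_tau
      s_meas <- raw$s_tau
      for (i in seq_along(kin$tau_min)) {
        if (kin$tau_min[i] == 0) next  # tau = 0 is the initial state
        ok <- FALSE
        for (try in seq_len(100)) {
          m_try <- raw$m_tau[i] + stats::rnorm(1, 0, config$noise_sd_mass)
          s_try <- raw$s_tau[i] + stats::rnorm(1, 0, config$noise_sd_s)
          if (m_try > 0 && s_try > 0 && s_try <= 1) { ok <- TRUE; break }
        }
        if (!ok) {
          m_try <- max(m_try, 1e-6)
          s_try <- min(max(s_try, 1e-6), 1)
          n_clipped <- n_clipped + 1L
        }
        m_meas[i] <- m_try
        s_meas[i] <- s_try
      }
      meas[[length(meas) + 1L]] <- data.frame(
        solute = sol, replicate = rep_i, tau_min = kin$tau_min,
        mass_g = m_meas, dry_fraction = s_meas, stringsAsFactors = FALSE)
      init[[length(init) + 1L]] <- data.frame(
        solute = sol, replicate = rep_i, m0_g = m0, s0 = config$s0,
        stringsAsFactors = FALSE)
    }
  }
  if (n_clipped > 0) {
    warning(n_clipped, " noisy draw(s) clipped to the validity bounds",
            call. = FALSE)
  }
  structure(list(measurements = do.call(rbind, meas),
                 initial = do.call(rbind, init),
                 truth = truth, config = config),
            class = "od_study")
}

#' @export
print.od_study <- function(x, ...) {
  cat("Simulated osmotic-dehydration study\n")
  cat("  solutes:     ", paste(names(x$config$solutes), collapse = ", "), "\n")
  cat("  time grid:   ", paste(x$config$time_grid, collapse = ", "), "min\n")
  cat("  replicates:  ", x$config$replicates, "\n")
  cat("  measurements:", nrow(x$measurements), "rows\n")
  cat("  noise sd:    ", x$config$noise_sd_mass, "g (mass), ",
      x$config$noise_sd_s, " (dry fraction)\n", sep = "")
  cat("  seed:        ", x$config$seed, "\n")
  invisible(x)
}
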