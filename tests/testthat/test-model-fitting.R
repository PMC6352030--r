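grid <- seq(0, 180, by = 30)

test_that("goodness-of-fit statistics match their definitions", {
  y <- c(0.2, 0.5, 0.9, 1.2, 1.3, 1.4, 1.45)
  g <- goodness_of_fit(y, y, 2)
  expect_equal(g$chi2, 0); expect_equal(g$RMSE, 0)
  expect_equal(g$CRV, 0); expect_equal(g$R2, 1)
  # constant prediction at the mean gives R2 = 0
  g0 <- goodness_of_fit(rep(mean(y), 7), y, 2)
  expect_equal(g0$R2, 0)
  # reduced chi2 of 0.009 at a mean response of 3.295 gives CRV 2.88%
  exper <- 3.295 + c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5)
  resid <- sqrt(0.009 * 5 / 7)   # SS = chi2 * (N - n) spread over N points
  pred <- exper + resid
  g1 <- goodness_of_fit(pred, exper, 2)
  expect_equal(g1$chi2, 0.009, tolerance = 1e-12)
  expect_equal(g1$CRV, 2.88, tolerance = 0.02 / 2.88)
  expect_error(goodness_of_fit(1:3 * 0, c(-1, 0, 1), 1), "zero")
  expect_error(goodness_of_fit(1:3, 1:3, 3), "N > n")
})

test_that("linearised initial guesses seed the optimiser well", {
  y <- eval_peleg(grid, 0, k1 = 10, k2 = 0.5, direction = 1)
  seed <- initial_guess(grid, y, "peleg", Y0 = 0, direction = 1)
  expect_equal(unname(seed), c(10, 0.5), tolerance = 1e-9)
  ykv <- eval_kelvin_voigt(grid, A = 1.5, B = 40)
  skv <- initial_guess(grid, ykv, "kelvin_voigt")
  expect_lt(abs(skv[["B"]] - 40) / 40, 0.10)
  expect_error(initial_guess(grid, rep(1, 7), "peleg"), "constant")
})

test_that("noise-free series return their generating parameters", {
  cases <- list(
    list(fam = "peleg", y = eval_peleg(grid, 0, 16.714, 0.534, 1),
         Y0 = 0, dir = 1, truth = c(k1 = 16.714, k2 = 0.534)),
    list(fam = "peleg", y = eval_peleg(grid, 5.69, 4.498, 0.26, -1),
         Y0 = 5.69, dir = -1, truth = c(k1 = 4.498, k2 = 0.26)),
    list(fam = "kelvin_voigt", y = eval_kelvin_voigt(grid, 1.482, 41.12),
         truth = c(A = 1.482, B = 41.12)),
    list(fam = "burgers", y = eval_burgers(grid, 0.957, 19.818, 3.304e-3),
         truth = c(A = 0.957, B = 19.818, C = 3.304e-3))
  )
  for (cs in cases) {
    fit <- if (cs$fam == "peleg") {
      fit_model(grid, cs$y, cs$fam, Y0 = cs$Y0, direction = cs$dir)
    } else fit_model(grid, cs$y, cs$fam)
    for (pn in names(cs$truth)) {
      expect_equal(fit$params[[pn]], cs$truth[[pn]],
                   tolerance = 1e-6, label = paste(cs$fam, pn))
    }
    expect_equal(fit$stats$R2, 1, tolerance = 1e-9)
    expect_lt(fit$stats$CRV, 1e-5)
  }
})

test_that("Burgers collapses to Kelvin-Voigt on nested data", {
  y <- eval_kelvin_voigt(grid, A = 1.557, B = 37.648)
  fit <- fit_model(grid, y, "burgers")
  expect_lte(fit$params$C, 1e-6)
  expect_equal(fit$params$A, 1.557, tolerance = 1e-4)
})

test_that("fitting is invariant to the row order of the series", {
  y <- eval_burgers(grid, 0.941, 19.074, 6.332e-3) +
    0.01 * sin(seq_along(grid))
  perm <- c(4, 1, 7, 2, 6, 3, 5)
  f1 <- fit_model(grid, y, "burgers")
  f2 <- fit_model(grid[perm], y[perm], "burgers")
  expect_equal(f1$params, f2$params, tolerance = 1e-12)
})

test_that("fitted SSR undercuts random parameter draws", {
  set.seed(402)
  y <- eval_peleg(grid, 0, 12, 0.7, 1) + rnorm(7, 0, 0.02)
  fit <- fit_model(grid, y, "peleg", Y0 = 0, direction = 1)
  draws <- cbind(k1 = runif(1e4, 0.5, 60), k2 = runif(1e4, 0.05, 5))
  ssr <- apply(draws, 1, function(p) {
    sum((eval_peleg(grid, 0, p[1], p[2], 1) - y)^2)
  })
  expect_lte(fit$info$ssr, min(ssr) + 1e-12)
})

test_that("the reduced-chi2 / RMSE identity holds on every fit", {
  set.seed(77)
  for (fam in model_families()) {
    for (rep_i in 1:5) {
      y <- eval_burgers(grid, 1.2, 30, 2e-3) + rnorm(7, 0, 0.03)
      fit <- if (fam == "peleg") {
        fit_model(grid, y, fam, Y0 = 0, direction = 1)
      } else fit_model(grid, y, fam)
      with(fit$stats, expect_equal(chi2 * (N - n), RMSE^2 * N,
                                   tolerance = 1e-10))
    }
  }
})

test_that("insufficient or degenerate data is rejected cleanly", {
  expect_error(fit_model(c(0, 30), c(0, 1), "peleg", Y0 = 0, direction = 1),
               "insufficient")
  expect_error(fit_model(grid, eval_peleg(grid, 0, 10, 0.5, 1), "peleg"),
               "Y0")
})

test_that("fit_report covers the study design and flags poor fits", {
  study <- generate_study(od_sim_config(seed = 5))
  kin <- suppressMessages(kinetics_table(study$measurements, study$initial))
  rep_tab <- fit_report(kin)
  # 5 solutes x (WC: 1 family, CR: 1, WL/SG/WLT: 3 each) = 55 rows
  expect_equal(nrow(rep_tab), 55)
  expect_equal(sort(unique(rep_tab$solute)), sort(names(study$truth)))
  expect_true(all(rep_tab$fit_ok))
  # usability flag is exactly the CRV < 20% rule
  expect_identical(rep_tab$usable, rep_tab$CRV_pct < 20)
  # empty input produces an empty report, not an error
  empty <- fit_report(data.frame(solute = character(), tau_min = numeric(),
                                 WL = numeric()))
  expect_equal(nrow(empty), 0)
})

test_that("a scattered series is flagged not usable for prediction", {
  y <- c(0, 0.62, 0.05, 0.71, 0.10, 0.80, 0.12)
  fit <- fit_model(grid, y, "peleg", Y0 = 0, direction = 1)
  expect_gte(fit$stats$CRV, 20)
  expect_false(fit$usable)
})

test_that("best_model ranks by CRV then RMSE", {
  study <- generate_study(od_sim_config(seed = 5))
  kin <- suppressMessages(kinetics_table(study$measurements, study$initial))
  rep_tab <- fit_report(kin, responses = "WL")
  best <- best_model(rep_tab)
  expect_equal(nrow(best), 5)
  for (i in seq_len(nrow(best))) {
    sub <- rep_tab[rep_tab$solute == best$solute[i], ]
    expect_equal(best$CRV_pct[i], min(sub$CRV_pct))
  }
})
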