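test_that("two-factor ANOVA reproduces a hand-computed decomposition", {
  # 2 solutes x 2 'replicate' times, values {1,1} vs {3,3}:
  # solute SS = 4, time SS = 0, error SS = 0 (degenerate, flagged)
  d <- data.frame(solute = rep(c("a", "b"), each = 2),
                  time = rep(c("t1", "t2"), 2),
                  value = c(1, 1, 3, 3))
  expect_warning(an <- two_way_anova(d), "degenerate")
  tab <- an$table
  expect_equal(tab$sumsq[tab$term == "solute"], 4)
  expect_equal(tab$sumsq[tab$term == "time"], 0, tolerance = 1e-12)
  expect_equal(tab$sumsq[tab$term == "residuals"], 0, tolerance = 1e-12)
})

test_that("constant data yields a degenerate, flagged ANOVA", {
  d <- expand.grid(solute = c("a", "b"), time = c("t1", "t2"), rep = 1:2)
  d$value <- 5
  expect_warning(an <- two_way_anova(d), "degenerate")
  expect_true(all(an$table$sumsq < 1e-16))
})

test_that("sums of squares decompose additively on balanced data", {
  set.seed(314)
  for (i in 1:20) {
    d <- expand.grid(solute = letters[1:5], time = paste0("t", 1:6),
                     rep = 1:2)
    d$value <- rnorm(nrow(d), sd = runif(1, 0.5, 2))
    an <- two_way_anova(d)
    tot <- sum((d$value - mean(d$value))^2)
    expect_equal(sum(an$table$sumsq), tot, tolerance = 1e-8)
  }
})

test_that("identical factor levels share one Tukey letter", {
  # solute means exactly equal; time effect and perturbation give MS_E > 0
  d <- two_factor_data(c(a = 1, b = 1, c = 1), time_effects = c(0, 0.5, 1))
  an <- two_way_anova(d)
  tk <- tukey_hsd(an, "solute")
  expect_true(all(tk$groups$letter == "a"))
  expect_true(all(!tk$contrasts$significant))
  expect_true(all(abs(tk$contrasts$difference) < 0.05))
})

test_that("well-separated levels get distinct letters in mean order", {
  d <- two_factor_data(c(lo = 0, mid = 10, hi = 20))
  an <- two_way_anova(d)
  tk <- tukey_hsd(an, "solute")
  expect_equal(tk$groups$level, c("hi", "mid", "lo"))
  expect_equal(tk$groups$letter, c("a", "b", "c"))
  expect_true(all(tk$contrasts$significant))
})

test_that("close levels merge into one letter group by limit arithmetic", {
  # means ~ {0, 0.1, 5}: the 0.1 gap is below the Tukey limit, 5 is not
  d <- two_factor_data(c(a = 0, b = 0.1, c = 5), time_effects = c(0, 0.2),
                       wiggle = 0.03)
  an <- two_way_anova(d)
  tk <- tukey_hsd(an, "solute")
  # independent limit arithmetic from the ANOVA components
  ms_e <- an$table$meansq[an$table$term == "residuals"]
  df_e <- an$table$df[an$table$term == "residuals"]
  limit <- qtukey(0.95, 3, df_e) * sqrt(ms_e / 2)
  expect_equal(unique(tk$contrasts$limit), limit)
  expect_gt(limit, 0.1)  # a-b not separable
  expect_lt(limit, 4.9)  # c separable from both
  expect_equal(tk$groups$letter, c("a", "b", "b"))  # hi=5 alone
})

test_that("contrasts agree with stats::TukeyHSD on balanced data", {
  set.seed(99)
  d <- expand.grid(solute = letters[1:4], time = paste0("t", 1:3), rep = 1:2)
  d$value <- rnorm(nrow(d)) + 2 * (d$solute == "d")
  an <- two_way_anova(d)
  tk <- tukey_hsd(an, "solute")
  ref <- TukeyHSD(an$fit, "f1")$f1
  # same pairs up to sign convention; compare |difference| and significance
  mine <- tk$contrasts
  key_mine <- vapply(strsplit(mine$contrast, "-"), function(p)
    paste(sort(p), collapse = "-"), "")
  key_ref <- vapply(strsplit(rownames(ref), "-"), function(p)
    paste(sort(p), collapse = "-"), "")
  idx <- match(key_mine, key_ref)
  expect_false(anyNA(idx))
  expect_equal(abs(mine$difference), abs(unname(ref[idx, "diff"])),
               tolerance = 1e-10)
  expect_equal(mine$significant, unname(ref[idx, "p adj"]) < 0.05)
})

test_that("letter display is consistent with the contrast table", {
  set.seed(2024)
  for (i in 1:10) {
    d <- expand.grid(solute = letters[1:5], time = paste0("t", 1:3),
                     rep = 1:2)
    d$value <- rnorm(nrow(d)) + runif(5)[as.integer(d$solute)] * 3
    tk <- tukey_hsd(two_way_anova(d), "solute")
    lets <- strsplit(tk$groups$letter, "")
    names(lets) <- tk$groups$level
    for (j in seq_len(nrow(tk$contrasts))) {
      pair <- strsplit(tk$contrasts$contrast[j], "-")[[1]]
      share <- length(intersect(lets[[pair[1]]], lets[[pair[2]]])) > 0
      expect_equal(share, !tk$contrasts$significant[j],
                   label = paste("pair", tk$contrasts$contrast[j], "sim", i))
    }
  }
})

test_that("Tukey quantiles match published studentized-range tables", {
  # q_{0.05} reference values (k, df): classical tables, 2 d.p.
  expect_equal(qtukey(0.95, 3, 10), 3.88, tolerance = 0.005 / 3.88)
  expect_equal(qtukey(0.95, 5, 20), 4.23, tolerance = 0.005 / 4.23)
  expect_equal(qtukey(0.95, 6, 30), 4.30, tolerance = 0.005 / 4.30)
})

test_that("Pearson correlation matches closed-form values", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  pr <- pearson_r(x, c(1, 2, 4))
  expect_equal(pr$r, 0.98198, tolerance = 1e-5 / 0.98198)
  expect_error(pearson_r(x, c(2, 2, 2)), "variance")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "3")
})

test_that("Pearson r is affine-invariant up to sign", {
  set.seed(8)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20, sd = 0.4)
  r0 <- pearson_r(x, y)$r
  expect_equal(pearson_r(3 * x + 2, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(x, -0.5 * y + 7)$r, -r0, tolerance = 1e-12)
})
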