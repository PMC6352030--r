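#' Two-factor ANOVA of a dehydration response
#'
#' Main-effects analysis of variance of one response against two crossed
#' treatment factors (by default the osmotic solute and the immersion
#' time). The report tables of a dehydration study list main effects only,
#' so no interaction term is fitted unless requested; with interaction the
#' design must be fully replicated.
#'
#' @param data data.frame of individual (replicate-level) observations.
#' @param response name of the response column.
#' @param factors character(2): the factor column names; values are coerced
#'   to factors.
#' @param interaction include the two-way interaction term.
#' @return object of class `od_anova`: list with `table` (term, df, sumsq,
#'   meansq, statistic, p.value), the underlying `aov` fit, and the design
#'   metadata used by [tukey_hsd()].
#' @export
two_way_anova <- function(data, response = "value",
                          factors = c("solute", "time"),
                          interaction = FALSE) {
  for (col in c(response, factors)) {
    if (!col %in% names(data)) stop("column '", col, "' not found", call. = FALSE)
  }
  df <- data.frame(y = data[[response]],
                   f1 = factor(data[[factors[1]]]),
                   f2 = factor(data[[factors[2]]]))
  if (nlevels(df$f1) < 2 || nlevels(df$f2) < 2) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  form <- if (interaction) y ~ f1 * f2 else y ~ f1 + f2
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)[[1]]
  term <- trimws(rownames(sm))
  term[term == "f1"] <- factors[1]
  term[term == "f2"] <- factors[2]
  term[term == "f1:f2"] <- paste(factors, collapse = ":")
  term[term == "Residuals"] <- "residuals"
  tab <- data.frame(term = term, df = sm$Df, sumsq = sm$`Sum Sq`,
                    meansq = sm$`Mean Sq`,
                    statistic = sm$`F value`, p.value = sm$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  err_df <- tab$df[tab$term == "residuals"]
  if (!length(err_df) || err_df < 1) {
    stop("zero residual degrees of freedom: add replication", call. = FALSE)
  }
  ss_res <- tab$sumsq[tab$term == "residuals"]
  if (ss_res <= 1e-10 * max(sum(tab$sumsq), .Machine$double.eps)) {
    warning("residual sum of squares is zero; F statistics are degenerate",
            call. = FALSE)
  }
  structure(list(table = tab, fit = fit, data = df, factors = factors,
                 response = response),
            class = "od_anova")
}

#' @export
print.od_anova <- function(x, ...) {
  cat("Two-factor ANOVA of", x$response, "(main effects",
      if (any(grepl(":", x$table$term))) "+ interaction)" else "only)", "\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD contrasts and homogeneous letter groups for one factor
#'
#' All pairwise contrasts of the level means of one factor, using the
#' pooled residual mean square of a main-effects ANOVA. Each pair gets a
#' common +/- limit \eqn{q_{\alpha,k,df} \sqrt{MS_E / \tilde n}}, where
#' \eqn{\tilde n} is the harmonic mean of the two level sizes
#' (Tukey-Kramer for unbalanced data); a difference is significant when it
#' exceeds the limit in magnitude. Levels are then labelled with a compact
#' letter display: levels sharing a letter are not significantly
#' different.
#'
#' @param anova an `od_anova` object from [two_way_anova()].
#' @param factor which of the two factors to compare (name or index).
#' @param alpha significance level (default 0.05).
#' @return object of class `od_tukey`: list with `contrasts` (data.frame
#'   `contrast`, `limit`, `difference`, `significant`), `groups`
#'   (data.frame `level`, `mean`, `n`, `letter`, ordered by descending
#'   mean), plus `q`, `ms_error`, `df_error`, `alpha`.
#' @export
tukey_hsd <- function(anova, factor = 1, alpha = 0.05) {
  stopifnot(inherits(anova, "od_anova"))
  if (is.character(factor)) factor <- match(factor, anova$factors)
  if (is.na(factor) || !factor %in% c(1, 2)) {
    stop("`factor` must name one of: ", paste(anova$factors, collapse = ", "),
         call. = FALSE)
  }
  f <- anova$data[[c("f1", "f2")[factor]]]
  y <- anova$data$y
  tab <- anova$table
  ms_e <- tab$meansq[tab$term == "residuals"]
  df_e <- tab$df[tab$term == "residuals"]
  means <- tapply(y, f, mean)
  ns <- tapply(y, f, length)
  k <- length(means)
  q <- stats::qtukey(1 - alpha, nmeans = k, df = df_e)

  lev <- names(means)
  pairs <- utils::combn(k, 2)
  n_tilde <- 2 / (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]])
  limit <- q * sqrt(ms_e / n_tilde)
  difference <- means[pairs[1, ]] - means[pairs[2, ]]
  contrasts <- data.frame(
    contrast = paste(lev[pairs[1, ]], lev[pairs[2, ]], sep = "-"),
    limit = unname(limit), difference = unname(difference),
    significant = unname(abs(difference) > limit),
    stringsAsFactors = FALSE
  )

  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sig[a, b] <- sig[b, a] <- contrasts$significant[j]
  }
  ord <- order(means, decreasing = TRUE)
  letters_vec <- compact_letters(sig[ord, ord, drop = FALSE])
  groups <- data.frame(level = lev[ord], mean = unname(means[ord]),
                       n = unname(ns[ord]), letter = letters_vec,
                       stringsAsFactors = FALSE)

  structure(list(contrasts = contrasts, groups = groups, q = q,
                 ms_error = ms_e, df_error = df_e, alpha = alpha,
                 factor = anova$factors[factor]),
            class = "od_tukey")
}

# Insert-and-absorb compact letter display from a logical significance
# matrix whose rows/cols are ordered by descending mean. Levels sharing a
# letter are not significantly different.
compact_letters <- function(sig) {
  k <- nrow(sig)
  groups <- list(seq_len(k))  # start: everyone shares one letter
  for (a in seq_len(k - 1)) {
    for (b in seq((a + 1), k)) {
      if (!sig[a, b]) next
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        if (a %in% g && b %in% g) {
          groups[[gi]] <- setdiff(g, a)
          groups[[length(groups) + 1L]] <- setdiff(g, b)
        }
      }
      # absorb groups contained in another
      keep <- rep(TRUE, length(groups))
      for (i in seq_along(groups)) {
        for (j in seq_along(groups)) {
          if (i != j && keep[j] && all(groups[[i]] %in% groups[[j]]) &&
              (length(groups[[i]]) < length(groups[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      groups <- groups[keep]
    }
  }
  # order letter columns by the first (highest-mean) member
  groups <- groups[order(vapply(groups, min, 1L))]
  out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(groups, function(g) i %in% g, TRUE))],
          collapse = "")
  }, "")
  out
}

#' @export
print.od_tukey <- function(x, ...) {
  cat(sprintf("Tukey HSD on factor '%s' (alpha = %g, q = %.4f, df = %d)\n",
              x$factor, x$alpha, x$q, x$df_error))
  cat("Homogeneous groups (levels sharing a letter do not differ):\n")
  print(x$groups, digits = 4, row.names = FALSE)
  cat("\nContrasts:\n")
  print(x$contrasts, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation between water activity and water content
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform, as used to relate the thermodynamic water activity of the
#' tissue to its dry-basis water content within one osmotic agent.
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
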