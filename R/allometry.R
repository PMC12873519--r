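# Column checks shared by the regression front-ends.
.check_traits <- function(table, cols) {
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("trait table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (cl in cols) {
    bad <- which(!is.na(table[[cl]]) & table[[cl]] <= 0)
    if (length(bad)) {
      who <- if ("species" %in% names(table)) table$species[bad] else bad
      stop("non-positive values of '", cl, "' for: ",
           paste(utils::head(who, 5), collapse = ", "),
           if (length(bad) > 5) ", ...",
           "; log10 scaling requires strictly positive traits", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Log-log allometric scaling fit
#'
#' Ordinary least squares of `log10(response)` on `log10(predictor)` — the
#' standard estimator of a power-law exponent from cross-species trait data
#' when the aim is prediction of the response (as opposed to standardized
#' major axis line fitting). Incomplete species pairs are dropped pairwise
#' and the count reported via a message. Confidence intervals use the t
#' distribution with the residual degrees of freedom.
#'
#' @param table Trait table (data frame) with a `species` column.
#' @param response,predictor Column names of strictly positive traits.
#' @return An object of class `loglog_fit`: slope/intercept with standard
#'   errors and 95\% CIs, `n`, `df_resid`, adjusted R2, F statistic and
#'   p-value, plus the underlying `lm` object in `$lm`.
#' @examples
#' tab <- generate_traits(generative_config(seed = 1))
#' fit <- fit_loglog(tab, "d_pet_um", "leaf_length_cm")
#' coef(fit)
#' @export
fit_loglog <- function(table, response, predictor) {
  .check_traits(table, c(response, predictor))
  ok <- stats::complete.cases(table[, c(response, predictor)])
  if (sum(!ok) > 0)
    message("dropping ", sum(!ok), " species with missing ", response,
            " or ", predictor)
  d <- data.frame(y = log10(table[[response]][ok]),
                  x = log10(table[[predictor]][ok]))
  if (nrow(d) < 3)
    stop("need at least 3 complete records, got ", nrow(d), call. = FALSE)
  fit <- stats::lm(y ~ x, data = d)
  # noise-free power-law inputs are legitimate here; silence the
  # "essentially perfect fit" warning from summary.lm
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit))
  fstat <- sm$fstatistic
  structure(list(
    response = response, predictor = predictor,
    n = nrow(d), df_resid = fit$df.residual,
    slope = unname(stats::coef(fit)["x"]),
    slope_se = sm$coefficients["x", "Std. Error"],
    slope_ci = unname(ci["x", ]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
    intercept_ci = unname(ci["(Intercept)", ]),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    F_statistic = unname(fstat[1]),
    p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
    lm = fit
  ), class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "log10(%s) ~ log10(%s): n = %d, df = %d\n", x$response, x$predictor,
    x$n, x$df_resid))
  cat(sprintf("  slope     %.3f  (%.3f, %.3f)\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.3f  (%.3f, %.3f)\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  adj R2 = %.2f, F = %.1f, p = %.3g\n",
              x$adj_r_squared, x$F_statistic, x$p_value))
  invisible(x)
}

#' @export
coef.loglog_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.loglog_fit <- function(object, ...) summary(object$lm, ...)

#' Welch test for a difference between two scaling exponents
#'
#' Two-sample t construction on the slope estimates of two independent
#' simple log-log fits: `t = (b1 - b2) / sqrt(SE1^2 + SE2^2)` with
#' Welch-Satterthwaite degrees of freedom computed from the two slope
#' variances and their residual dfs; the p-value is two-sided.
#'
#' @param fit1,fit2 `loglog_fit` objects (simple regressions).
#' @return An object of class `slope_comparison` with `t`, `df`, `p_value`.
#' @export
compare_slopes <- function(fit1, fit2) {
  for (f in list(fit1, fit2))
    if (!inherits(f, "loglog_fit"))
      stop("compare_slopes() needs two simple log-log fits", call. = FALSE)
  v1 <- fit1$slope_se^2; v2 <- fit2$slope_se^2
  t_stat <- (fit1$slope - fit2$slope) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / fit1$df_resid + v2^2 / fit2$df_resid)
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(t = t_stat, df = df, p_value = p,
                 slopes = c(fit1$slope, fit2$slope),
                 labels = c(paste(fit1$response, "~", fit1$predictor),
                            paste(fit2$response, "~", fit2$predictor))),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat("Slope comparison:", x$labels[1], "vs", x$labels[2], "\n")
  cat(sprintf("  slopes %.3f vs %.3f; t = %.3f, df = %.2f, p = %.4g\n",
              x$slopes[1], x$slopes[2], x$t, x$df, x$p_value))
  invisible(x)
}

#' Scaling fit with a grouping factor and its interaction
#'
#' Fits `log10(response) ~ log10(predictor) * group` and reports whether the
#' group shifts the slope (interaction) or the intercept (main effect),
#' each as a partial F test against the model without the term. Used to ask
#' whether, e.g., simple- and compound-leaved species, or different sites,
#' share a common scaling line.
#'
#' @inheritParams fit_loglog
#' @param group Name of a categorical column with >= 2 levels, each with at
#'   least 3 records.
#' @return An object of class `group_fit` with `interaction_p`, `group_p`
#'   and the full `lm` in `$lm`.
#' @export
fit_with_group <- function(table, response, predictor, group) {
  .check_traits(table, c(response, predictor))
  if (!group %in% names(table))
    stop("trait table lacks column '", group, "'", call. = FALSE)
  g <- factor(table[[group]])
  counts <- base::table(g)
  if (length(counts) < 2 || any(counts < 3))
    stop("'", group, "' needs >= 2 levels with >= 3 records each; counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         call. = FALSE)
  d <- data.frame(y = log10(table[[response]]),
                  x = log10(table[[predictor]]), g = g)
  d <- d[stats::complete.cases(d), ]
  full <- stats::lm(y ~ x * g, data = d)
  no_int <- stats::lm(y ~ x + g, data = d)
  no_grp <- stats::lm(y ~ x, data = d)
  interaction_p <- suppressWarnings(stats::anova(no_int, full)[2, "Pr(>F)"])
  group_p <- suppressWarnings(stats::anova(no_grp, no_int)[2, "Pr(>F)"])
  structure(list(response = response, predictor = predictor, group = group,
                 n = nrow(d), levels = levels(g),
                 interaction_p = interaction_p, group_p = group_p,
                 coefficients = stats::coef(full), lm = full),
            class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("log10(%s) ~ log10(%s) * %s  (n = %d; levels: %s)\n",
              x$response, x$predictor, x$group, x$n,
              paste(x$levels, collapse = ", ")))
  cat(sprintf("  common slope?     interaction p = %.4g\n", x$interaction_p))
  cat(sprintf("  common intercept? group main-effect p = %.4g\n", x$group_p))
  invisible(x)
}

# The scaling relations reported for a full trait table: vessel diameters
# against leaf length, wood density and height, plus the WD~L and L~H links.
.standard_relations <- function() {
  rbind(
    c("d_pet_um", "leaf_length_cm"),
    c("d_pet_um", "wood_density_g_cm3"),
    c("d_pet_um", "height_m"),
    c("d_twig_um", "leaf_length_cm"),
    c("d_twig_um", "wood_density_g_cm3"),
    c("d_twig_um", "height_m"),
    c("d_twig_um", "d_pet_um"),
    c("wood_density_g_cm3", "leaf_length_cm"),
    c("leaf_length_cm", "height_m")
  )
}

#' Descriptive statistics and the full scaling-regression table
#'
#' Runs the nine standard log-log scaling regressions among leaf length,
#' petiole and twig vessel diameters, wood density and plant height, and
#' computes per-variable descriptive statistics (min, max, mean, SD, with
#' the species attaining the extremes).
#'
#' @param table Complete trait table.
#' @return An object of class `allometry_summary`: `$descriptives` and
#'   `$scaling` data frames plus `$fits` (the `loglog_fit` objects).
#' @export
summary_table <- function(table) {
  num_cols <- c("leaf_length_cm", "d_twig_um", "d_pet_um",
                "wood_density_g_cm3", "height_m")
  if (!"species" %in% names(table))
    stop("trait table lacks a 'species' column", call. = FALSE)
  .check_traits(table, num_cols)
  desc <- do.call(rbind, lapply(num_cols, function(cl) {
    v <- table[[cl]]
    data.frame(variable = cl,
               min = min(v), species_min = table$species[which.min(v)],
               max = max(v), species_max = table$species[which.max(v)],
               mean = mean(v), sd = stats::sd(v))
  }))
  rel <- .standard_relations()
  fits <- lapply(seq_len(nrow(rel)),
                 function(i) fit_loglog(table, rel[i, 1], rel[i, 2]))
  scaling <- do.call(rbind, lapply(fits, function(f) data.frame(
    response = f$response, predictor = f$predictor, n = f$n,
    adj_r2 = f$adj_r_squared, df = f$df_resid, F = f$F_statistic,
    slope = f$slope, slope_lower = f$slope_ci[1], slope_upper = f$slope_ci[2],
    intercept = f$intercept, intercept_lower = f$intercept_ci[1],
    intercept_upper = f$intercept_ci[2], p_value = f$p_value
  )))
  structure(list(descriptives = desc, scaling = scaling, fits = fits),
            class = "allometry_summary")
}

#' @export
print.allometry_summary <- function(x, ...) {
  cat("Descriptive statistics:\n")
  print(transform(x$descriptives, min = signif(min, 4), max = signif(max, 4),
                  mean = signif(mean, 4), sd = signif(sd, 4)))
  cat("\nScaling regressions (log10-log10 OLS):\n")
  sc <- x$scaling
  sc[, sapply(sc, is.numeric)] <- lapply(sc[, sapply(sc, is.numeric)],
                                         function(v) signif(v, 3))
  print(sc)
  invisible(x)
}
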