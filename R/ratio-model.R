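# Mixed-effects comparison of SW:LW sensitivity ratios across temporal
# frequencies.

#' Compare SW:LW ratios across temporal frequencies
#'
#' Fits a linear mixed model to (reciprocal-transformed) SW:LW sensitivity
#' ratios with temporal frequency as a fixed effect and animal identity as a
#' random intercept: `transformed ~ frequency_hz + (1 | animal_id)`. The
#' reciprocal transform reduces the right skew of raw ratio data. The
#' frequency fixed effect is reported with its Satterthwaite-t p-value
#' (`p.value`) and the large-sample Wald normal approximation
#' (`p.value.wald`). With a single animal the random effect is degenerate and
#' an ordinary least-squares fit is used instead (flagged in the result).
#'
#' @param data Tibble with columns `animal_id`, `frequency_hz` and `ratio`
#'   (raw SW:LW ratios from [sw_lw_ratio()]), or a pre-transformed column
#'   named by `response`.
#' @param transform `"reciprocal"` (default; models `1/ratio`) or
#'   `"identity"`.
#' @param response Name of the column holding the raw ratios.
#' @return An object of class `eyespec_ratio_comparison`; see [tidy()] and
#'   [glance()] methods.
#' @examples
#' d <- tidyr::expand_grid(animal_id = letters[1:4], frequency_hz = c(3, 10, 30))
#' d$ratio <- 1.5 - 0.01 * d$frequency_hz + rnorm(nrow(d), 0, 0.02)
#' fit <- compare_ratios_across_frequencies(d)
#' tidy(fit)
#' @export
compare_ratios_across_frequencies <- function(data,
                                              transform = c("reciprocal", "identity"),
                                              response = "ratio") {
  transform <- match.arg(transform)
  need <- c("animal_id", "frequency_hz", response)
  if (!all(need %in% names(data))) {
    abort(paste0("`data` must have columns ", paste(need, collapse = ", "), "."),
          class = "eyespec_invalid_input")
  }
  if (length(unique(data$frequency_hz)) < 2L) {
    abort("Need at least two temporal frequencies.",
          class = "eyespec_invalid_input")
  }
  df <- tibble(
    animal_id = as.factor(data$animal_id),
    frequency_hz = as.numeric(data$frequency_hz),
    y = if (transform == "reciprocal") 1 / data[[response]] else data[[response]]
  )
  single_animal <- length(unique(df$animal_id)) < 2L
  if (single_animal) {
    warn("Single animal: random intercept is degenerate; falling back to OLS.",
         class = "eyespec_degenerate_random_effect")
    fit <- stats::lm(y ~ frequency_hz, data = df)
    sm <- summary(fit)$coefficients
    est <- sm["frequency_hz", "Estimate"]
    se <- sm["frequency_hz", "Std. Error"]
    tval <- sm["frequency_hz", "t value"]
    dfree <- fit$df.residual
    pval <- sm["frequency_hz", "Pr(>|t|)"]
  } else {
    fit <- suppressMessages(lmerTest::lmer(y ~ frequency_hz + (1 | animal_id),
                                           data = df))
    sm <- coef(summary(fit))
    est <- sm["frequency_hz", "Estimate"]
    se <- sm["frequency_hz", "Std. Error"]
    tval <- sm["frequency_hz", "t value"]
    dfree <- sm["frequency_hz", "df"]
    pval <- sm["frequency_hz", "Pr(>|t|)"]
  }
  structure(
    list(fit = fit, estimate = unname(est), std_error = unname(se),
         statistic = unname(tval), df = unname(dfree), p_value = unname(pval),
         p_value_wald = unname(2 * pnorm(-abs(tval))),
         transform = transform, single_animal = single_animal,
         n_obs = nrow(df), n_animals = length(unique(df$animal_id))),
    class = "eyespec_ratio_comparison"
  )
}

#' @export
print.eyespec_ratio_comparison <- function(x, ...) {
  cat("SW:LW ratio comparison across temporal frequencies\n")
  cat(sprintf("  model: %s ~ frequency_hz + %s\n",
              if (x$transform == "reciprocal") "1/ratio" else "ratio",
              if (x$single_animal) "1 (OLS fallback)" else "(1 | animal_id)"))
  cat(sprintf("  frequency effect: %.4g (se %.3g), t = %.3g, d.f. = %.3g, p = %.3g\n",
              x$estimate, x$std_error, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @method tidy eyespec_ratio_comparison
#' @export
tidy.eyespec_ratio_comparison <- function(x, ...) {
  tibble(term = "frequency_hz", estimate = x$estimate, std.error = x$std_error,
         statistic = x$statistic, df = x$df, p.value = x$p_value,
         p.value.wald = x$p_value_wald)
}

#' @method glance eyespec_ratio_comparison
#' @export
glance.eyespec_ratio_comparison <- function(x, ...) {
  tibble(nobs = x$n_obs, n_animals = x$n_animals, transform = x$transform,
         ols_fallback = x$single_animal,
         sigma = if (x$single_animal) summary(x$fit)$sigma else
           stats::sigma(x$fit),
         logLik = as.numeric(stats::logLik(x$fit)))
}
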