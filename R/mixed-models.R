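#' Gaussian random-intercept mixed model with optional backward elimination
#'
#' Fits `response ~ fixed terms + (1 | g)` for each grouping factor `g` by
#' REML (lme4), with Satterthwaite Wald t tests on the fixed effects
#' (lmerTest).  When `backward = TRUE` the fixed term with the largest
#' p >= `alpha` is dropped, one per step, until only significant terms (or
#' none) remain; random intercepts are never eliminated.  Grouping factors
#' that end up with a single level are dropped with a message, and a model
#' with no grouping factors falls back to ordinary least squares.
#'
#' @param data data.frame holding all variables.
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect terms (may be empty for an
#'   intercept-only model).
#' @param groups character vector of random-intercept grouping columns.
#' @param backward drop non-significant fixed terms (default FALSE).
#' @param alpha retention threshold for backward elimination (default 0.05).
#' @return list of class `model_fit`: `coefficients` (data.frame term,
#'   estimate, se, t, df, p_value), `random_variances` (named, incl.
#'   residual), `n`, `formula`, `criterion` (REML or deviance), `dropped`
#'   (terms eliminated), `model` (the fitted object).
#' @export
fit_random_intercept_model <- function(data, response, fixed = character(),
                                       groups = character(),
                                       backward = FALSE, alpha = 0.05) {
  data <- stats::na.omit(
    data[, unique(c(response, all.vars(stats::reformulate(
      c(fixed, groups, "1")))))])
  groups <- groups[vapply(groups, function(g)
    length(unique(data[[g]])) >= 2L, logical(1))]
  dropped <- character()
  repeat {
    fit <- fit_lmm_once(data, response, fixed, groups)
    if (!backward || !length(fixed)) break
    coefs <- fit$coefficients
    cand <- coefs[coefs$term %in% fixed, , drop = FALSE]
    if (!nrow(cand) || all(cand$p_value < alpha, na.rm = TRUE)) break
    worst <- cand$term[which.max(cand$p_value)]
    fixed <- setdiff(fixed, worst)
    dropped <- c(dropped, worst)
  }
  fit$dropped <- dropped
  fit
}

fit_lmm_once <- function(data, response, fixed, groups) {
  rhs <- c(if (length(fixed)) fixed else "1",
           sprintf("(1 | %s)", groups))
  fml <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  if (!length(groups)) {
    m <- stats::lm(fml, data = data)
    sm <- summary(m)$coefficients
    coefs <- data.frame(term = fixed_term_names(rownames(sm), data),
                        estimate = sm[, 1], se = sm[, 2], t = sm[, 3],
                        df = m$df.residual, p_value = sm[, 4],
                        row.names = NULL, stringsAsFactors = FALSE)
    return(structure(list(coefficients = coefs,
                          random_variances = c(residual = stats::sigma(m)^2),
                          n = nrow(data), formula = deparse(fml),
                          criterion = as.numeric(stats::logLik(m)),
                          model = m), class = "model_fit"))
  }
  m <- tryCatch(lmerTest::lmer(fml, data = data, REML = TRUE),
                error = function(e) e)
  if (inherits(m, "error")) {
    # degenerate fits (e.g. zero residual variance) can break the
    # Satterthwaite machinery; fall back to the fixed-effect OLS fit
    return(fit_lmm_once(data, response, fixed, character()))
  }
  sm <- stats::coef(summary(m))
  vc <- as.data.frame(lme4::VarCorr(m))
  rv <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                        vc$grp))
  coefs <- data.frame(term = fixed_term_names(rownames(sm), data),
                      estimate = sm[, "Estimate"], se = sm[, "Std. Error"],
                      t = sm[, "t value"], df = sm[, "df"],
                      p_value = sm[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, random_variances = rv,
                 n = nrow(data), formula = deparse(fml),
                 criterion = as.numeric(lme4::REMLcrit(m)), model = m),
            class = "model_fit")
}

# map coefficient rownames like "ageD15" back to the term "age" so backward
# elimination can match them; multi-level factors keep the contrast label
fixed_term_names <- function(rn, data) {
  out <- rn
  for (v in colnames(data)) {
    lev <- if (is.factor(data[[v]])) levels(data[[v]]) else
      if (is.character(data[[v]])) unique(data[[v]]) else character()
    for (l in lev) {
      hit <- rn == paste0(v, l)
      out[hit] <- v
    }
  }
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat("mixed model:", x$formula, "\n")
  print(x$coefficients, digits = 4)
  cat("random-effect variances:\n")
  print(round(x$random_variances, 5))
  invisible(x)
}
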