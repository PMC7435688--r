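#' Friedewald LDL cholesterol
#'
#' LDL = TC - HDL - TG/2.2 in mmol/L (divisor 5 for mg/dL).  The equation
#' is invalid above 4.5 mmol/L triglycerides (400 mg/dL) and such inputs
#' raise an error; negative results are returned but flagged via the
#' `"negative"` attribute rather than clipped.
#'
#' @param tc,hdl,tg total, HDL cholesterol and triglycerides (same units).
#' @param units "mmol" (default) or "mgdl".
#' @return LDL cholesterol, vectorized over the inputs.
#' @export
friedewald_ldl <- function(tc, hdl, tg, units = c("mmol", "mgdl")) {
  units <- match.arg(units)
  if (any(c(tc, hdl, tg) < 0)) stop("lipid values must be non-negative", call. = FALSE)
  limit <- if (units == "mmol") 4.5 else 400
  if (any(tg > limit)) {
    stop(sprintf("triglycerides above %s exceed the Friedewald validity bound",
                 format(limit)), call. = FALSE)
  }
  divisor <- if (units == "mmol") 2.2 else 5
  ldl <- tc - hdl - tg / divisor
  if (any(ldl < 0)) attr(ldl, "negative") <- which(ldl < 0)
  ldl
}

#' Per-study encoder effect on a serum lipid
#'
#' The study effect is the encoder coefficient (and its standard error)
#' from a covariate-adjusted linear model of the lipid, the design used for
#' each cohort before meta-analysis.  Default covariates: age, sex,
#' antibiotic usage and statin usage.
#'
#' @param data per-participant data.frame containing the lipid, a logical
#'   `encoder` column, and the covariates.
#' @param lipid outcome column name ("TC", "LDL", "HDL", ...).
#' @param covariates covariate column names (missing ones are dropped).
#' @param study label for the study.
#' @param cvd_sensitivity if `TRUE`, additionally adjust for CVD status and
#'   its interaction with encoder status (sensitivity analysis).
#' @return One-row data.frame: study, lipid, estimate, se, n.
#' @export
study_effect <- function(data, lipid = "TC",
                         covariates = c("age", "sex", "antibiotics", "statin"),
                         study = "study", cvd_sensitivity = FALSE) {
  if (!any(data$encoder) || all(data$encoder)) {
    stop("need both encoders and non-encoders to estimate a study effect",
         call. = FALSE)
  }
  covariates <- intersect(covariates, names(data))
  rhs <- c("encoder", covariates)
  if (cvd_sensitivity && "cvd" %in% names(data)) rhs <- c(rhs, "cvd", "encoder:cvd")
  f <- stats::reformulate(rhs, response = lipid)
  fit <- fit_linear(f, data)
  enc <- grep("^encoder(TRUE)?$", names(fit$coefficients))[1]
  data.frame(study = study, lipid = lipid,
             estimate = unname(fit$coefficients[enc]),
             se = unname(fit$se[enc]), n = fit$n,
             stringsAsFactors = FALSE)
}

#' Inverse-variance random-effects meta-analysis (DerSimonian-Laird)
#'
#' Pools per-study effects with the DerSimonian-Laird moment estimator of
#' the between-study variance: fixed weights w = 1/se^2 give the
#' heterogeneity statistic Q; tau^2 = max(0, (Q - (k-1)) / (sum w - sum
#' w^2 / sum w)); random-effects weights 1/(se^2 + tau^2) give the pooled
#' estimate and its normal interval.  I^2 = max(0, (Q - (k-1))/Q) x 100.
#' A REML estimate of tau^2 is available behind `method = "REML"`.
#'
#' @param estimates,se per-study effects and standard errors (se > 0).
#' @param labels optional study labels.
#' @param alpha two-sided interval error rate.
#' @param method "DL" (default) or "REML".
#' @return List of class `meta_result`: pooled, ci_low, ci_high, tau2, Q,
#'   I2, k, weights (normalized random-effects weights), and a `studies`
#'   data.frame usable as forest-plot input.
#' @export
meta_random_effects <- function(estimates, se, labels = NULL, alpha = 0.05,
                                method = c("DL", "REML")) {
  method <- match.arg(method)
  k <- length(estimates)
  if (k == 0) stop("need at least one study", call. = FALSE)
  if (length(se) != k || any(se <= 0)) {
    stop("each study needs a positive standard error", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("study_", seq_len(k))
  w <- 1 / se^2
  theta_fe <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - theta_fe)^2)
  tau2 <- if (k == 1) 0 else
    max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  if (method == "REML" && k > 1) {
    rll <- function(t2) {
      wi <- 1 / (se^2 + t2)
      mu <- sum(wi * estimates) / sum(wi)
      -0.5 * (sum(log(se^2 + t2)) + log(sum(wi)) +
                sum(wi * (estimates - mu)^2))
    }
    tau2 <- optimize(function(t2) -rll(t2),
                     interval = c(0, max(tau2, 1) * 20))$minimum
    if (rll(0) >= rll(tau2)) tau2 <- 0
  }
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * estimates) / sum(ws)
  z <- qnorm(1 - alpha / 2)
  half <- z / sqrt(sum(ws))
  I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  structure(list(
    pooled = pooled, ci_low = pooled - half, ci_high = pooled + half,
    tau2 = tau2, Q = Q, I2 = I2, k = k, method = method,
    studies = data.frame(study = labels, estimate = estimates, se = se,
                         ci_low = estimates - z * se,
                         ci_high = estimates + z * se,
                         weight = ws / sum(ws), stringsAsFactors = FALSE)),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("random-effects meta-analysis (%s), k = %d studies\n",
              x$method, x$k))
  print(x$studies, digits = 3)
  cat(sprintf("pooled = %.3f [%.3f, %.3f]; tau^2 = %.4f, Q = %.3f, I^2 = %.1f%%\n",
              x$pooled, x$ci_low, x$ci_high, x$tau2, x$Q, x$I2))
  invisible(x)
}

#' @export
summary.meta_result <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Convert a GWAS effect in SD units to concentration units
#'
#' Multiplies a per-allele effect reported in standard-deviation units by
#' the trait's standard deviation in a reference cohort; the result is
#' reported to three decimals (the convention for per-allele lipid
#' effects in mmol/L).
#'
#' @param beta_sd effect size in SD units.
#' @param cohort_sd trait standard deviation in mmol/L (> 0).
#' @return Effect in mmol/L, rounded to 3 decimal places.
#' @export
convert_sd_to_mmol <- function(beta_sd, cohort_sd) {
  if (any(cohort_sd <= 0)) stop("cohort_sd must be positive", call. = FALSE)
  round(beta_sd * cohort_sd, 3)
}
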