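#' Classify samples as encoders and converters
#'
#' A sample is an *encoder* when any of the listed enzyme-family clusters is
#' detected in it, and a *converter* when coprostanol is detected in its
#' metabolome.  Metadata are joined by sample id; samples with detection
#' data but no metadata are dropped with a warning.
#'
#' @param det cluster-by-sample logical detection matrix restricted to (or
#'   subset by) the enzyme-family clusters.
#' @param calls data.frame with sample_id and detected (coprostanol).
#' @param metadata data.frame keyed by sample_id with covariates.
#' @param clusters optional cluster ids (default: all rows of `det`).
#' @return data.frame: sample_id, encoder, converter, plus metadata columns.
#' @export
classify_samples <- function(det, calls, metadata = NULL, clusters = NULL) {
  if (!is.null(clusters)) det <- det[intersect(clusters, rownames(det)), , drop = FALSE]
  encoder <- colSums(det) > 0
  out <- data.frame(sample_id = colnames(det), encoder = unname(encoder),
                    stringsAsFactors = FALSE)
  out$converter <- calls$detected[match(out$sample_id, calls$sample_id)]
  if (!is.null(metadata)) {
    miss <- setdiff(out$sample_id, metadata$sample_id)
    if (length(miss) > 0) {
      warning(length(miss), " sample(s) missing metadata were excluded: ",
              paste(head(miss, 5), collapse = ", "), call. = FALSE)
      out <- out[!out$sample_id %in% miss, , drop = FALSE]
    }
    out <- merge(out, metadata, by = "sample_id", sort = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Encoder-converter contingency table
#'
#' @param classification output of [classify_samples()] (or any data.frame
#'   with logical encoder and converter columns).
#' @return Named counts a (encoder & converter), b (encoder only),
#'   c (converter only), d (neither).
#' @export
contingency_counts <- function(classification) {
  e <- classification$encoder; v <- classification$converter
  c(a = sum(e & v), b = sum(e & !v), c = sum(!e & v), d = sum(!e & !v))
}

#' Odds ratio for a 2x2 table with Woolf or exact confidence interval
#'
#' OR = ad/bc.  The default Woolf interval is
#' exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)); when any cell is zero
#' the Haldane-Anscombe correction adds 0.5 to every cell (flagged in the
#' result).  `method = "fisher"` returns the conditional maximum-likelihood
#' estimate and exact interval from [stats::fisher.test()].
#'
#' @param a,b,c,d cell counts: encoder&converter, encoder&non-converter,
#'   non-encoder&converter, non-encoder&non-converter.  `a` may also be a
#'   length-4 vector or 2x2 matrix.
#' @param method "woolf" (default) or "fisher".
#' @param alpha two-sided error rate for the interval.
#' @return List of class `odds_ratio_result`: odds_ratio, ci_low, ci_high,
#'   method, correction_applied, counts.
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL,
                       method = c("woolf", "fisher"), alpha = 0.05) {
  method <- match.arg(method)
  if (is.null(b)) {
    x <- as.numeric(a)
    stopifnot(length(x) == 4)
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  }
  cells <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  a <- cells[["a"]]; b <- cells[["b"]]; c <- cells[["c"]]; d <- cells[["d"]]
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)) {
    stop("a margin of the 2x2 table is zero; the odds ratio is undefined",
         call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (method == "fisher") {
    ft <- fisher.test(matrix(c(a, c, b, d), 2), conf.level = 1 - alpha)
    res <- list(odds_ratio = unname(ft$estimate), ci_low = ft$conf.int[1],
                ci_high = ft$conf.int[2], method = "fisher",
                correction_applied = FALSE, counts = cells)
  } else {
    w <- if (corrected) cells + 0.5 else cells
    or <- (w["a"] * w["d"]) / (w["b"] * w["c"])
    z <- qnorm(1 - alpha / 2)
    se <- sqrt(sum(1 / w))
    res <- list(odds_ratio = unname(or),
                ci_low = unname(exp(log(or) - z * se)),
                ci_high = unname(exp(log(or) + z * se)),
                method = "woolf", correction_applied = corrected,
                counts = cells)
  }
  structure(res, class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR = %.2f [95%% CI: %.2f, %.2f] (%s%s)\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$method,
              if (x$correction_applied) ", Haldane-Anscombe corrected" else ""))
  invisible(x)
}

#' Log10 + pseudo-count z-score transform for metabolite abundances
#'
#' Zeros are replaced by the pseudo-count (default 1e-5) before log10;
#' values are then standardized with the sample (n-1) standard deviation.
#'
#' @param values non-negative abundances, length >= 2.
#' @param pseudo pseudo-count substituted for zeros.
#' @return z-scores (mean 0, sample sd 1).
#' @export
transform_metabolite <- function(values, pseudo = 1e-5) {
  if (any(values < 0)) stop("metabolite values must be non-negative", call. = FALSE)
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  lg <- log10(ifelse(values == 0, pseudo, values))
  s <- sd(lg)
  if (s == 0) stop("values are constant after transformation; z-scores undefined",
                   call. = FALSE)
  (lg - mean(lg)) / s
}

# summary.lm warns on zero-residual fits; exact calibration data are a
# legitimate input here, so that specific warning is muffled
.quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

.design <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  X <- model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(y = y, X = X)
}

.fit_result <- function(coefficients, se, n, family, sigma2 = NULL,
                        tau2 = NULL, loglik = NULL) {
  stat <- coefficients / se
  structure(list(coefficients = coefficients, se = se, statistic = stat,
                 p_value = 2 * pnorm(-abs(stat)), n = n, family = family,
                 sigma2 = sigma2, tau2 = tau2, loglik = loglik),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("%s model, n = %d\n", x$family, x$n))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    statistic = x$statistic, p = x$p_value)
  print(tab, digits = 3)
  if (!is.null(x$tau2)) {
    cat(sprintf("residual sigma^2 = %.4f, random-intercept tau^2 = %.4f\n",
                x$sigma2, x$tau2))
  }
  invisible(x)
}

#' @export
coef.assoc_fit <- function(object, ...) object$coefficients

#' @export
summary.assoc_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Ordinary least squares with Wald tests
#'
#' Covariate-adjusted linear model (metabolite z-score or serum lipid as
#' outcome, encoder/converter status plus covariates as predictors).
#' Standard errors come from sigma-hat^2 (X'X)^-1; p-values are normal
#' Wald tests.
#'
#' @param formula,data model specification; categorical covariates are
#'   dummy-coded with the first (alphabetical) level as reference.
#' @return An `assoc_fit` (family "linear") with `sigma2`.
#' @export
fit_linear <- function(formula, data) {
  d <- .design(formula, data)
  if (nrow(d$X) <= ncol(d$X)) stop("need n > number of coefficients", call. = FALSE)
  fit <- lm(formula, data)
  s <- .quiet_perfect_fit(summary(fit))
  coefs <- coef(fit)
  se <- s$coefficients[, "Std. Error"]
  .fit_result(coefs, se, length(d$y), "linear", sigma2 = s$sigma^2)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum likelihood for a binary outcome; iterations stop when the
#' log-likelihood changes by less than 1e-8 (at most 100 iterations).
#' Diverging coefficients (complete separation) raise an error.
#'
#' @param formula,data model specification; outcome logical or 0/1 with
#'   both classes present.
#' @return An `assoc_fit` (family "logistic") with `loglik`.
#' @export
fit_logistic <- function(formula, data) {
  d <- .design(formula, data)
  y <- as.numeric(d$y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  if (length(unique(y)) < 2) stop("both outcome classes must be present", call. = FALSE)
  X <- d$X
  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  for (it in seq_len(100)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    if (max(abs(beta)) > 25) {
      stop("coefficients diverged; data are (quasi-)completely separated",
           call. = FALSE)
    }
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    beta <- qr.solve(sqrt(w) * X, sqrt(w) * z)
    ll <- sum(y * log(pmax(plogis(drop(X %*% beta)), 1e-300)) +
                (1 - y) * log(pmax(1 - plogis(drop(X %*% beta)), 1e-300)))
    if (abs(ll - ll_old) < 1e-8) break
    ll_old <- ll
  }
  eta <- drop(X %*% beta); p <- plogis(eta)
  sep <- (ncol(X) > 1) && all(p[y == 1] > 1 - 1e-6) && all(p[y == 0] < 1e-6)
  if (max(abs(beta)) > 25 || sep) {
    stop("coefficients diverged; data are (quasi-)completely separated",
         call. = FALSE)
  }
  w <- pmax(p * (1 - p), 1e-10)
  info <- crossprod(X, w * X)
  se <- sqrt(diag(solve(info)))
  .fit_result(setNames(drop(beta), colnames(X)), setNames(se, colnames(X)),
              length(y), "logistic", loglik = ll)
}

#' Linear model with a participant random intercept (profile ML)
#'
#' Fits y = X beta + u_group + e with u ~ N(0, tau^2), e ~ N(0, sigma^2) by
#' maximum likelihood, profiling the likelihood over lambda = tau^2/sigma^2
#' with a closed-form GLS solve at each lambda (Woodbury identity per
#' group).  Fixed-effect standard errors come from the GLS information
#' matrix.  Used for repeated stool measurements from the same participant.
#'
#' @param formula,data fixed-effects specification.
#' @param groups grouping factor (participant ids), one per row of `data`.
#' @return An `assoc_fit` (family "mixed") with `sigma2`, `tau2`, `loglik`.
#' @export
fit_random_intercept <- function(formula, data, groups) {
  d <- .design(formula, data)
  y <- d$y; X <- d$X
  groups <- as.factor(groups)
  if (length(groups) != length(y)) stop("groups must match data rows", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(droplevels(groups))
  if (all(sizes == 1)) {
    stop("all groups are singletons; tau^2 is not identifiable - use fit_linear",
         call. = FALSE)
  }
  idx <- split(seq_along(y), droplevels(groups))
  n <- length(y); p <- ncol(X)

  profile_fit <- function(lambda) {
    XtVX <- matrix(0, p, p); XtVy <- numeric(p); ytVy <- 0; logdet <- 0
    for (ii in idx) {
      Xg <- X[ii, , drop = FALSE]; yg <- y[ii]; ng <- length(ii)
      cc <- lambda / (1 + ng * lambda)
      sX <- colSums(Xg); sy <- sum(yg)
      XtVX <- XtVX + crossprod(Xg) - cc * tcrossprod(sX)
      XtVy <- XtVy + crossprod(Xg, yg) - cc * sX * sy
      ytVy <- ytVy + sum(yg^2) - cc * sy^2
      logdet <- logdet + log1p(ng * lambda)
    }
    beta <- solve(XtVX, XtVy)
    rss <- drop(ytVy - crossprod(beta, XtVy))
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + n + logdet)
    list(ll = ll, beta = drop(beta), sigma2 = sigma2, XtVX = XtVX)
  }
  opt <- optimize(function(lg) -profile_fit(exp(lg))$ll,
                  interval = c(-15, 15), tol = 1e-10)
  lambda <- exp(opt$minimum)
  # keep the boundary tau^2 = 0 in the feasible set
  at0 <- profile_fit(0)
  best <- profile_fit(lambda)
  if (at0$ll >= best$ll) { lambda <- 0; best <- at0 }
  se <- sqrt(diag(solve(best$XtVX)) * best$sigma2)
  .fit_result(setNames(best$beta, colnames(X)), setNames(se, colnames(X)),
              n, "mixed", sigma2 = best$sigma2,
              tau2 = lambda * best$sigma2, loglik = best$ll)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction; output order matches input.
#'
#' @param p p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}
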