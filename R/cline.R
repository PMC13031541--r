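#' Arrangement-S frequency per location with Wilson confidence interval
#'
#' p = (2 n_SS + n_SN) / (2 (n_SS + n_SN + n_NN)), the allele-scale
#' frequency of the S arrangement, with a Wilson score 95% interval on the
#' allele scale.
#'
#' @param counts data.frame with columns n_SS, n_SN, n_NN (and optionally
#'   location), one row per location; a numeric length-3 vector
#'   c(SS, SN, NN) is also accepted.
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns location, freqS, lower, upper, nAlleles.
#' @export
arrangementFrequency <- function(counts, conf = 0.95) {
  counts <- .asCountTable(counts)
  n2 <- 2 * (counts$n_SS + counts$n_SN + counts$n_NN)
  if (any(n2 == 0)) stop("all-zero karyotype counts")
  x <- 2 * counts$n_SS + counts$n_SN
  p <- x / n2
  z <- qnorm(1 - (1 - conf) / 2)
  centre <- (p + z^2 / (2 * n2)) / (1 + z^2 / n2)
  halfw <- z * sqrt(p * (1 - p) / n2 + z^2 / (4 * n2^2)) / (1 + z^2 / n2)
  data.frame(location = counts$location, freqS = p,
             lower = pmax(0, centre - halfw), upper = pmin(1, centre + halfw),
             nAlleles = n2)
}

.asCountTable <- function(counts) {
  if (is.numeric(counts) && length(counts) == 3) {
    counts <- data.frame(n_SS = counts[1], n_SN = counts[2],
                         n_NN = counts[3])
  }
  counts <- as.data.frame(counts)
  stopifnot(all(c("n_SS", "n_SN", "n_NN") %in% names(counts)))
  if (!"location" %in% names(counts))
    counts$location <- sprintf("L%02d", seq_len(nrow(counts)))
  counts
}

#' Chi-square test of Hardy-Weinberg equilibrium of karyotype counts
#'
#' Expected counts are (n p^2, 2 n p (1-p), n (1-p)^2) with p the estimated
#' S frequency; the statistic is the plain chi-square without continuity
#' correction, df = 1. Monomorphic samples (p = 0 or 1) are flagged as
#' untestable.
#'
#' @param counts as in [arrangementFrequency()].
#' @return data.frame with observed counts, freqS, expected counts, chisq,
#'   df, p.value, and a testable flag.
#' @export
hweTest <- function(counts) {
  counts <- .asCountTable(counts)
  out <- lapply(seq_len(nrow(counts)), function(i) {
    ss <- counts$n_SS[i]; sn <- counts$n_SN[i]; nn <- counts$n_NN[i]
    n <- ss + sn + nn
    if (n < 1) stop("empty location row")
    p <- (2 * ss + sn) / (2 * n)
    if (p == 0 || p == 1) {
      return(data.frame(location = counts$location[i], n_SS = ss, n_SN = sn,
                        n_NN = nn, freqS = p, expSS = NA, expSN = NA,
                        expNN = NA, chisq = NA_real_, df = 1L,
                        p.value = NA_real_, testable = FALSE))
    }
    expd <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
    chisq <- sum((c(ss, sn, nn) - expd)^2 / expd)
    data.frame(location = counts$location[i], n_SS = ss, n_SN = sn,
               n_NN = nn, freqS = p, expSS = expd[1], expSN = expd[2],
               expNN = expd[3], chisq = chisq, df = 1L,
               p.value = pchisq(chisq, 1, lower.tail = FALSE),
               testable = TRUE)
  })
  do.call(rbind, out)
}

#' Binomial-GLM cline of arrangement frequency
#'
#' Aggregated binomial regression with logit link: per location the response
#' is (successes = 2 n_SS + n_SN, failures = n_SN + 2 n_NN), so the fit
#' accounts for sample sizes. Reports the likelihood-ratio chi-square (null
#' minus residual deviance, df = 1) and the deviance R-squared
#' 1 - residual/null deviance.
#'
#' @param table location table (see [readLocationTable()]).
#' @param predictor "latitude" or "temperature" (any numeric column name of
#'   \code{table} is accepted).
#' @return A [ClineFit-class] object.
#' @export
fitBinomialCline <- function(table, predictor = c("latitude",
                                                  "temperature")) {
  predictor <- if (length(predictor) > 1) match.arg(predictor)
               else as.character(predictor)
  stopifnot(predictor %in% names(table))
  if (nrow(table) < 3) stop("need at least 3 locations")
  x <- table[[predictor]]
  if (length(unique(x)) < 2) stop("predictor is constant")
  dat <- data.frame(x = x,
                    successes = 2 * table$n_SS + table$n_SN,
                    failures = table$n_SN + 2 * table$n_NN)
  fit <- glm(cbind(successes, failures) ~ x, family = binomial("logit"),
             data = dat, control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) stop("IRLS did not converge")
  mu <- fitted(fit)
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(coef(fit)) > 30)
  if (separation)
    warning("quasi-complete separation: coefficients are unstable")
  lrt <- fit$null.deviance - fit$deviance
  co <- setNames(coef(fit), c("intercept", predictor))
  se <- setNames(sqrt(diag(vcov(fit))), c("intercept", predictor))
  new("ClineFit", predictor = predictor, coefficients = co, se = se,
      lrtChisq = lrt, lrtP = pchisq(lrt, 1, lower.tail = FALSE),
      devianceR2 = 1 - fit$deviance / fit$null.deviance,
      nullDeviance = fit$null.deviance, residDeviance = fit$deviance,
      separation = separation, model = fit, data = dat)
}

#' Predicted cline with 95% confidence ribbon
#'
#' Fitted arrangement frequency over a predictor grid, with a Wald 95%
#' interval computed on the linear predictor and mapped through the inverse
#' logit (the interval of the average prediction, which accounts for the
#' sample sizes behind the fit).
#'
#' @param fit a [ClineFit-class] object.
#' @param grid numeric vector of predictor values.
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns predictor value, fit, lower, upper.
#' @export
predictCline <- function(fit, grid, conf = 0.95) {
  stopifnot(is(fit, "ClineFit"))
  pr <- predict(fit@model, newdata = data.frame(x = grid), se.fit = TRUE,
                type = "link")
  z <- qnorm(1 - (1 - conf) / 2)
  out <- data.frame(grid, fit = invLogit(pr$fit),
                    lower = invLogit(pr$fit - z * pr$se.fit),
                    upper = invLogit(pr$fit + z * pr$se.fit))
  names(out)[1] <- fit@predictor
  out
}
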