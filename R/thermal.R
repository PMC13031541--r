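# closed-form thermal traits of viability = a T^2 + b T + c
.tpcTraits <- function(a, b, c) {
  traits <- c(rmax = NA_real_, Topt = NA_real_, CTmin = NA_real_,
              CTmax = NA_real_, tolerance = NA_real_, breadth = NA_real_)
  if (a >= 0) return(traits)  # non-concave fit: traits undefined
  traits["Topt"] <- -b / (2 * a)
  traits["rmax"] <- c - b^2 / (4 * a)
  disc <- b^2 - 4 * a * c
  if (disc >= 0) {
    roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
    traits["CTmin"] <- roots[1]
    traits["CTmax"] <- roots[2]
    traits["tolerance"] <- roots[2] - roots[1]
  }
  if (traits["rmax"] > 0)
    traits["breadth"] <- 2 * sqrt(0.2 * traits["rmax"] / (-a))
  traits
}

#' Fit a quadratic thermal performance curve to viability data
#'
#' Least-squares fit of the viability proportion (adults/eggs) on
#' (T^2, T, 1); replicate rows are weighted by eggs counted by default, so
#' the fit matches an aggregated per-temperature fit. The quadratic model
#' has a closed-form least-squares solution, making multi-start nonlinear
#' optimisation unnecessary. Derived thermal traits come from the closed
#' forms: rmax = c - b^2/(4a), Topt = -b/(2a), CTmin/CTmax the real roots of
#' the quadratic, tolerance = CTmax - CTmin, and breadth the width of the
#' interval where viability >= 0.8 rmax. Traits are NA when the fit is
#' non-concave or roots are complex.
#'
#' @param table viability data.frame with columns temperature, eggs, adults
#'   (and optionally karyotype/continent); see
#'   [simulateViabilityExperiment()].
#' @param group optional label stored in the result (rows are NOT filtered;
#'   subset beforehand).
#' @param weights "eggs" (default) or "none" for unweighted replicate-level
#'   fitting.
#' @param minMeanViability temperatures whose mean viability falls below
#'   this proportion are excluded before fitting (default 0: keep all).
#' @return A [TpcFit-class] object.
#' @export
fitQuadraticTpc <- function(table, group = "all",
                            weights = c("eggs", "none"),
                            minMeanViability = 0) {
  weights <- match.arg(weights)
  stopifnot(all(c("temperature", "eggs", "adults") %in% names(table)),
            all(table$adults <= table$eggs))
  table$viability <- table$adults / table$eggs
  if (minMeanViability > 0) {
    meanV <- tapply(table$viability, table$temperature, mean)
    keep <- names(meanV)[meanV >= minMeanViability]
    table <- table[as.character(table$temperature) %in% keep, ]
  }
  if (length(unique(table$temperature)) < 3)
    stop("need at least 3 distinct temperatures")
  w <- if (weights == "eggs") table$eggs else rep(1, nrow(table))
  fit <- lm(viability ~ I(temperature^2) + temperature, data = table,
            weights = w)
  co <- coef(fit)
  a <- unname(co["I(temperature^2)"])
  b <- unname(co["temperature"])
  cc <- unname(co["(Intercept)"])
  new("TpcFit", group = as.character(group),
      coefficients = c(a = a, b = b, c = cc),
      traits = .tpcTraits(a, b, cc),
      rss = sum(w * resid(fit)^2), n = nrow(table))
}

# terms contained in another term, marginality sense: A is contained in A:B
.termContains <- function(term, other) {
  tf <- strsplit(term, ":")[[1]]
  of <- strsplit(other, ":")[[1]]
  all(tf %in% of) && length(of) > length(tf)
}

#' Type-II deviance analysis of egg-to-adult viability
#'
#' Binomial GLM (logit link) of survivors/deaths on karyotype, temperature
#' and continent with all two-way interactions (higher-order interactions
#' are not included). Each term is tested by an explicit likelihood-ratio
#' model pair respecting marginality: the reference model holds every term
#' that does not contain the tested term, and the comparison adds the tested
#' term. Temperatures with mean viability below \code{minMeanViability} are
#' excluded first (the low-viability exclusion rule).
#'
#' @param table viability data.frame with columns karyotype, temperature,
#'   continent, eggs, adults.
#' @param factors factor names entering the model.
#' @param interactions maximum interaction order (default 2).
#' @param minMeanViability exclusion threshold on per-temperature mean
#'   viability (default 0.05, mirroring the removal of temperatures where
#'   almost nothing survives).
#' @return list with \code{anova} (data.frame: term, df, chisq, p.value),
#'   \code{devianceR2}, and \code{model} (the full glm fit).
#' @export
viabilityDevianceAnalysis <- function(table,
                                      factors = c("karyotype", "temperature",
                                                  "continent"),
                                      interactions = 2,
                                      minMeanViability = 0.05) {
  stopifnot(all(c(factors, "eggs", "adults") %in% names(table)))
  if (minMeanViability > 0 && "temperature" %in% factors) {
    meanV <- tapply(table$adults / table$eggs, table$temperature, mean)
    keep <- names(meanV)[meanV >= minMeanViability]
    table <- table[as.character(table$temperature) %in% keep, ]
  }
  for (f in factors) table[[f]] <- factor(table[[f]])
  nlev <- vapply(factors, function(f) length(levels(table[[f]])), integer(1))
  factors <- factors[nlev >= 2]
  if (!length(factors)) stop("no factor with >= 2 levels")
  rhs <- paste0("(", paste(factors, collapse = " + "), ")^", interactions)
  full <- glm(as.formula(paste("cbind(adults, eggs - adults) ~", rhs)),
              family = binomial("logit"), data = table)
  allTerms <- attr(terms(full), "term.labels")
  refit <- function(termSet) {
    rhs0 <- if (length(termSet)) paste(termSet, collapse = " + ") else "1"
    glm(as.formula(paste("cbind(adults, eggs - adults) ~", rhs0)),
        family = binomial("logit"), data = table)
  }
  rows <- lapply(allTerms, function(tm) {
    others <- allTerms[allTerms != tm]
    base <- others[!vapply(others, function(o) .termContains(tm, o),
                           logical(1))]
    m0 <- refit(base)
    m1 <- refit(c(base, tm))
    dev <- deviance(m0) - deviance(m1)
    df <- m0$df.residual - m1$df.residual
    data.frame(term = tm, df = df, chisq = dev,
               p.value = pchisq(dev, df, lower.tail = FALSE))
  })
  list(anova = do.call(rbind, rows),
       devianceR2 = 1 - full$deviance / full$null.deviance,
       model = full)
}
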