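#' @importFrom methods new validObject is as slot setValidity show callNextMethod
#' @importFrom stats glm binomial coef fitted pchisq qnorm rbinom rbeta runif
#'   rmultinom lm predict dnorm kmeans setNames resid deviance logLik
#'   as.formula terms reformulate vcov
#' @importFrom utils read.delim write.table
NULL

# logit link helpers used by the cline / viability machinery
logit <- function(p) log(p / (1 - p))

invLogit <- function(x) 1 / (1 + exp(-x))

# Deterministic sub-seed per pipeline stage so that independent generators do
# not share a stream.  Kept below 2^31 - 1.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# IUPAC nucleotide ambiguity sets (duplex alphabet, no U).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

isIupac <- function(x) {
  all(strsplit(toupper(x), "")[[1]] %in% names(IUPAC_SETS))
}
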