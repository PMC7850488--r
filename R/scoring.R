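#' Multiparametric mutation score (MMS)
#'
#' Signed sum of the binary parameters: every parameter contributes its
#' value times its sign (+1 for all but the conserved-substitution
#' parameter, which contributes -1). With `clamp = TRUE` scores below 0
#' are set to 0, the convention used for the all-theoretical tables.
#'
#' @param values 0/1 matrix (mutations x parameters) from
#'   [evaluateParameters()], or a single named 0/1 vector.
#' @param registry the [ParameterRegistry-class] the values were scored
#'   against; every registered parameter must be present.
#' @param clamp set negative scores to 0.
#' @return named integer vector of MMS values.
#' @examples
#' reg <- makeRegistry(c("a", "b", "c"), signs = c(1, 1, -1))
#' computeMMS(setNames(c(1, 1, 1), c("a", "b", "c")), reg)
#' @export
computeMMS <- function(values, registry, clamp = FALSE) {
  stopifnot(is(registry, "ParameterRegistry"))
  values <- .asParamMatrix(values, registry)
  signs <- parameterSigns(registry)[colnames(values)]
  mms <- as.integer(round(values %*% signs))
  if (clamp) mms <- pmax(mms, 0L)
  setNames(mms, rownames(values))
}

.asParamMatrix <- function(values, registry) {
  if (is.null(dim(values))) {
    values <- matrix(values, nrow = 1L,
                     dimnames = list("mutation", names(values)))
  }
  values <- as.matrix(values)
  need <- parameterNames(registry)
  missing <- setdiff(need, colnames(values))
  if (length(missing)) {
    stop("incomplete parameter vector; missing: ",
         paste(missing, collapse = ", "))
  }
  values <- values[, need, drop = FALSE]
  if (any(is.na(values)) || !all(values %in% c(0, 1))) {
    stop("parameter values must be binary 0/1 with no missing entries")
  }
  values
}

#' Train parameter weights against clinical outcome scores
#'
#' Ordinary least squares of the outcome score on the binary parameter
#' matrix, as used to derive the weighted score (WMMS) from homozygous
#' patient mutations (with their clinical outcome scores, 0-12) and
#' control polymorphisms (assigned outcome 0). Deterministic; exact
#' collinearity is detected and reported with the offending columns rather
#' than silently dropped.
#'
#' @param X numeric matrix (n x k) of 0/1 parameters, columns named.
#' @param y numeric outcome scores, length n.
#' @return a [WeightSet-class] with coefficients, intercept, standard
#'   errors and fit metadata (`nCases` counts y > 0, `nControls` y == 0).
#' @export
trainWeights <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("param_", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (nrow(X) <= ncol(X)) {
    stop("need more observations (", nrow(X), ") than parameters (",
         ncol(X), ") for least squares")
  }
  d <- data.frame(y = y, X, check.names = FALSE)
  fit <- lm(y ~ ., data = d)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient design; collinear column(s): ",
         paste(gsub("`", "", bad), collapse = ", "))
  }
  # summary.lm warns on exact fits; an exact fit is a valid training outcome
  sm <- suppressWarnings(summary(fit))
  w <- cf[-1L]
  names(w) <- colnames(X)
  se <- sm$coefficients[-1L, "Std. Error"]
  names(se) <- colnames(X)
  new("WeightSet", weights = w, intercept = unname(cf[1L]),
      details = list(n = nrow(X), nCases = sum(y > 0),
                     nControls = sum(y == 0), se = se,
                     sigma = sm$sigma, rSquared = sm$r.squared))
}

#' Construct a WeightSet directly
#'
#' For weights loaded from a table rather than trained.
#'
#' @param weights named numeric coefficients.
#' @param intercept intercept term (stored; excluded from the score by
#'   default).
#' @return a [WeightSet-class].
#' @export
weightSet <- function(weights, intercept = 0) {
  new("WeightSet", weights = weights, intercept = as.numeric(intercept),
      details = list())
}

#' Weighted multiparametric mutation score (WMMS)
#'
#' Sum of the trained coefficients over the parameters the mutation
#' scores 1 for: `sum_p w(p) * value(p)`. The intercept is excluded by
#' default, so an all-zero vector scores 0; `includeIntercept = TRUE`
#' adds it for sensitivity checks.
#'
#' @param values 0/1 matrix or named vector of parameter values.
#' @param w a [WeightSet-class]; its parameter names must match the
#'   columns of `values` exactly.
#' @param includeIntercept add the fitted intercept.
#' @return named numeric vector of WMMS values.
#' @export
computeWMMS <- function(values, w, includeIntercept = FALSE) {
  stopifnot(is(w, "WeightSet"))
  if (is.null(dim(values))) {
    values <- matrix(values, nrow = 1L,
                     dimnames = list("mutation", names(values)))
  }
  values <- as.matrix(values)
  if (!setequal(colnames(values), names(w@weights))) {
    stop("parameter names of values and weights do not match")
  }
  values <- values[, names(w@weights), drop = FALSE]
  out <- as.numeric(values %*% w@weights)
  if (includeIntercept) out <- out + w@intercept
  setNames(out, rownames(values))
}

#' Bin MMS values into severity bands
#'
#' Bands 0 (no indicator fired), 1-2 (mild), 3-4 (moderate) and >= 5
#' (severe).
#'
#' @param scores integer MMS values.
#' @return named integer vector of counts over the four bands; sums to
#'   `length(scores)`.
#' @examples
#' binMMS(c(0, 1, 2, 3, 4, 5))
#' @export
binMMS <- function(scores) {
  if (length(scores) && any(scores != round(scores))) {
    stop("MMS values must be integers")
  }
  if (length(scores) && any(scores < 0)) {
    stop("negative MMS values cannot be banded; clamp at 0 first ",
         "(computeMMS(..., clamp = TRUE))")
  }
  c("0" = sum(scores == 0),
    "1-2" = sum(scores >= 1 & scores <= 2),
    "3-4" = sum(scores >= 3 & scores <= 4),
    ">=5" = sum(scores >= 5))
}

#' Fraction of exactly corresponding scores between species
#'
#' Exact correspondence of human and mouse weighted scores, compared after
#' rounding (default 2 decimals, the precision of reported WMMS values).
#'
#' @param h,m paired numeric score vectors (human, mouse).
#' @param digits rounding applied before comparison.
#' @return fraction in `[0, 1]` of pairs with equal rounded scores.
#' @examples
#' scoreConcordance(c(1, 2), c(1, 3))
#' @export
scoreConcordance <- function(h, m, digits = 2) {
  if (length(h) != length(m)) stop("paired score vectors must match in length")
  if (length(h) == 0L) return(NaN)
  mean(round(h, digits) == round(m, digits))
}

#' @rdname accessors
#' @export
setMethod("weights", "WeightSet", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setMethod("intercept", "WeightSet", function(x) x@intercept)

setMethod("show", "WeightSet", function(object) {
  cat("WeightSet over ", length(object@weights), " parameters, intercept ",
      signif(object@intercept, 4), sep = "")
  if (length(object@details)) {
    cat("; trained on n = ", object@details$n, " (",
        object@details$nCases, " cases, ", object@details$nControls,
        " controls), R^2 = ", signif(object@details$rSquared, 3), sep = "")
  }
  cat("\n")
})
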