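#' Fit the clinical-outcome / weighted-score line
#'
#' Least-squares regression of WMMS on the clinical outcome score (COS,
#' 0-12) over homozygous mutations, yielding the line
#' `WMMS = slope * COS + intercept` and the WMMS value at the clinical
#' attenuated/severe cutoff (COS 5). The published line for the 15
#' homozygous GLDC mutations is `WMMS = 0.76 * COS - 2.5` (r^2 0.9), which
#' places the transition at WMMS 1.3.
#'
#' @param cos clinical outcome scores (x), length >= 3, non-constant.
#' @param wmms weighted scores (y), same length.
#' @param cosCutoff clinical cutoff on the COS scale (default 5).
#' @return an [OutcomeModel-class].
#' @export
fitCosWmms <- function(cos, wmms, cosCutoff = 5) {
  if (length(cos) != length(wmms)) stop("cos and wmms must be paired")
  if (length(cos) < 3L) stop("need at least 3 (COS, WMMS) pairs")
  if (var(cos) == 0) stop("COS values are constant; no line can be fitted")
  fit <- lm(wmms ~ cos)
  cf <- coef(fit)
  # summary.lm warns on exact fits; an exact line is a valid input
  outcomeModel(slope = unname(cf[2L]), intercept = unname(cf[1L]),
               rSquared = suppressWarnings(summary(fit))$r.squared,
               cosCutoff = cosCutoff, n = length(cos))
}

#' Construct an OutcomeModel from known coefficients
#'
#' For working with a published line rather than refitting it.
#'
#' @param slope,intercept the line `WMMS = slope * COS + intercept`.
#' @param rSquared coefficient of determination, if known.
#' @param cosCutoff clinical cutoff on the COS scale.
#' @param n number of pairs behind the fit (0 when supplied).
#' @return an [OutcomeModel-class].
#' @examples
#' wmmsThreshold(outcomeModel(0.76, -2.5))   # 1.3
#' @export
outcomeModel <- function(slope, intercept, rSquared = NA_real_,
                         cosCutoff = 5, n = 0L) {
  assertScalarNumber(slope, "slope")
  assertScalarNumber(intercept, "intercept")
  new("OutcomeModel", slope = slope, intercept = intercept,
      rSquared = as.numeric(rSquared), cosCutoff = as.numeric(cosCutoff),
      wmmsThreshold = slope * cosCutoff + intercept, n = as.integer(n))
}

#' @rdname accessors
#' @export
setMethod("wmmsThreshold", "OutcomeModel", function(x) x@wmmsThreshold)

setMethod("show", "OutcomeModel", function(object) {
  cat("OutcomeModel: WMMS = ", signif(object@slope, 4), " * COS ",
      ifelse(object@intercept < 0, "- ", "+ "),
      signif(abs(object@intercept), 4),
      if (!is.na(object@rSquared)) paste0(" (r^2 ", signif(object@rSquared, 3), ")"),
      "; attenuated/severe threshold ", signif(object@wmmsThreshold, 4),
      " at COS ", object@cosCutoff,
      if (object@n > 0L) paste0("; fitted on n = ", object@n), "\n", sep = "")
})

#' Classify a weighted score into the validated severity bands
#'
#' Attenuated for WMMS in `[-0.87, 1.3]` (both anchors validated in mice:
#' the attenuated A394V model at -0.87 and the regression threshold at
#' 1.3), severe for `(1.3, 10]`, and out of range outside `[-0.87, 10]`
#' (beyond the span validated in vivo).
#'
#' @param wmms numeric scores.
#' @param threshold attenuated/severe boundary (default 1.3; pass
#'   `wmmsThreshold(model)` to use a fitted line).
#' @param lower,upper validated WMMS range.
#' @return factor with levels attenuated, severe, out_of_range.
#' @examples
#' classifyWmms(c(-0.87, 3.5, 12))
#' @export
classifyWmms <- function(wmms, threshold = 1.3, lower = -0.87, upper = 10) {
  out <- ifelse(wmms < lower | wmms > upper, "out_of_range",
         ifelse(wmms <= threshold, "attenuated", "severe"))
  factor(out, levels = c("attenuated", "severe", "out_of_range"))
}

#' Construct colony genotype counts
#'
#' @param wildtype,het,hom progeny counts by genotype from a heterozygote
#'   intercross.
#' @param expectedRatio Mendelian expectation, default 1:2:1.
#' @return a [ColonyCounts-class].
#' @examples
#' ColonyCounts(17, 54, 16)
#' @export
ColonyCounts <- function(wildtype, het, hom, expectedRatio = c(1, 2, 1)) {
  new("ColonyCounts", wildtype = as.integer(wildtype),
      het = as.integer(het), hom = as.integer(hom),
      expectedRatio = as.numeric(expectedRatio))
}

#' @rdname accessors
#' @export
setMethod("nTotal", "ColonyCounts", function(x) x@wildtype + x@het + x@hom)

setMethod("show", "ColonyCounts", function(object) {
  y <- genotypeYields(object)
  cat("ColonyCounts: ", object@wildtype, " wt / ", object@het, " het / ",
      object@hom, " hom of ", nTotal(object), " (",
      paste(sprintf("%.1f%%", y), collapse = " / "), ")\n", sep = "")
})

#' Genotype yields as percentages of the colony
#'
#' @param counts a [ColonyCounts-class].
#' @return numeric vector of percentages (wildtype, het, hom).
#' @examples
#' genotypeYields(ColonyCounts(17, 54, 16))  # 19.5, 62.1, 18.4
#' @export
genotypeYields <- function(counts) {
  stopifnot(is(counts, "ColonyCounts"))
  n <- nTotal(counts)
  if (n == 0L) stop("colony has no progeny")
  100 * c(wildtype = counts@wildtype, het = counts@het,
          hom = counts@hom) / n
}

#' Prenatal lethality from homozygote shortfall
#'
#' Percentage shortfall of homozygous progeny relative to the Mendelian
#' expectation of 25%: `100 * (1 - (hom/total) / 0.25)`, floored at 0 (a
#' colony can at best meet the expectation).
#'
#' @param counts a [ColonyCounts-class], or the homozygote count when
#'   `total` is given.
#' @param total total progeny (only when `counts` is a bare number).
#' @return lethality percentage in `[0, 100]`.
#' @examples
#' prenatalLethality(ColonyCounts(17, 54, 16))  # ~26
#' prenatalLethality(10, 404)                   # ~90
#' @export
prenatalLethality <- function(counts, total = NULL) {
  if (is(counts, "ColonyCounts")) {
    hom <- counts@hom
    total <- nTotal(counts)
  } else {
    hom <- counts
    if (is.null(total)) stop("supply total progeny alongside the hom count")
  }
  if (total <= 0) stop("total progeny must be positive")
  max(0, 100 * (1 - (hom / total) / 0.25))
}

#' Chi-square test of Mendelian genotype ratios
#'
#' Pearson goodness-of-fit of the observed wildtype/het/hom counts against
#' the expected ratio (1:2:1 by default), df = 2.
#'
#' @param counts a [ColonyCounts-class].
#' @param alpha significance level for the reported conclusion.
#' @return list with `statistic`, `df`, `p.value`, `significant`,
#'   `conclusion` (text).
#' @examples
#' mendelianChisq(ColonyCounts(17, 54, 16))
#' @export
mendelianChisq <- function(counts, alpha = 0.05) {
  stopifnot(is(counts, "ColonyCounts"))
  obs <- c(counts@wildtype, counts@het, counts@hom)
  if (sum(obs) == 0L) stop("colony has no progeny")
  p <- counts@expectedRatio / sum(counts@expectedRatio)
  if (any(p * sum(obs) == 0)) stop("zero expected count")
  ht <- suppressWarnings(stats::chisq.test(obs, p = p))
  sig <- ht$p.value < alpha
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, significant = sig,
       conclusion = paste0(ifelse(sig, "significant", "not significant"),
                           " deviation from the expected ratio at ",
                           alpha))
}

#' Predict pre- and post-natal outcomes from a weighted score
#'
#' Linear interpolation of prenatal fatality between the two anchors
#' validated in mice: the attenuated model (WMMS -0.87, 26% prenatal
#' fatality, 31% postnatal hydrocephalus) and the severe cap (WMMS 10, 90%
#' prenatal fatality). Postnatal hydrocephalus is reported as the 31%
#' attenuated baseline for all in-range scores (no interpolant for it is
#' supportable; see the methods vignette). With `formate = TRUE` the
#' prediction is the formate-rescued state: 29% prenatal fatality and 34%
#' hydrocephalus, regardless of score. Scores outside `[-0.87, 10]` return
#' class `out_of_range` with no percentages.
#'
#' @param wmms numeric weighted scores.
#' @param formate logical; dams supplemented with dietary sodium formate.
#' @param threshold,lower,upper severity bands as in [classifyWmms()].
#' @return data.frame with columns `wmms`, `class`,
#'   `prenatal_fatality_pct`, `hydrocephalus_pct`, `formate`.
#' @examples
#' predictOutcomes(c(-0.87, 4.565, 10))
#' @export
predictOutcomes <- function(wmms, formate = FALSE, threshold = 1.3,
                            lower = -0.87, upper = 10) {
  cls <- classifyWmms(wmms, threshold = threshold, lower = lower,
                      upper = upper)
  inRange <- cls != "out_of_range"
  fatal <- rep(NA_real_, length(wmms))
  hydro <- rep(NA_real_, length(wmms))
  if (formate) {
    fatal[inRange] <- 29
    hydro[inRange] <- 34
  } else {
    fatal[inRange] <- 26 + (wmms[inRange] - lower) * (90 - 26) /
      (upper - lower)
    hydro[inRange] <- 31
  }
  data.frame(wmms = wmms, class = cls, prenatal_fatality_pct = fatal,
             hydrocephalus_pct = hydro, formate = formate)
}
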