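#' Rank candidate mutations for an attenuated disease model
#'
#' Two cohort-relative scores are combined. Score A rewards the highest
#' mouse WMMS: `(mWMMS - min) / (max - min)`, so the top candidate scores
#' 1 and the bottom 0. Score B rewards human/mouse agreement:
#' `1 - |mWMMS - hWMMS| / max|mWMMS - hWMMS|` over the cohort, so a
#' mutation whose scores agree exactly gets 1 and the most discordant gets
#' 0 (all 1 when every pair agrees). Candidates are ranked by descending
#' Score A + Score B; ties share the better rank and are ordered by label.
#'
#' @param candidates data.frame with columns `label`, `mwmms`, `hwmms`
#'   (n >= 2 rows).
#' @return the input with added `score_a`, `score_b`, `total`, `rank`,
#'   ordered by rank then label.
#' @examples
#' rankAttenuated(data.frame(label = c("A394V", "A807V", "S137L"),
#'                           mwmms = c(-0.87, 0.96, -7.77),
#'                           hwmms = c(-0.87, -0.8, -5.4)))
#' @export
rankAttenuated <- function(candidates) {
  need <- c("label", "mwmms", "hwmms")
  if (!is.data.frame(candidates) || !all(need %in% names(candidates))) {
    stop("candidates must be a data.frame with label, mwmms, hwmms")
  }
  n <- nrow(candidates)
  if (n < 2L) stop("need at least 2 candidates to rank")
  x <- candidates$mwmms
  rng <- range(x)
  scoreA <- if (rng[1] == rng[2]) rep(1, n) else (x - rng[1]) / diff(rng)
  d <- abs(candidates$mwmms - candidates$hwmms)
  maxd <- max(d)
  scoreB <- if (maxd == 0) rep(1, n) else 1 - d / maxd
  out <- candidates
  out$score_a <- scoreA
  out$score_b <- scoreB
  out$total <- scoreA + scoreB
  out$rank <- rank(-out$total, ties.method = "min")
  out <- out[order(out$rank, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Five-criterion model for severe-mutation candidates
#'
#' Scores each mutation 0/1 on five criteria and sums them: (i) mouse
#' WMMS at or above the threshold (9.94, the lead candidate S562F's
#' score); (ii) residue conserved between mouse and human; (iii) mouse and
#' human WMMS identical (at `digits` rounding); (iv) alternate residue is
#' not proline (proline substitutions are so destabilizing they risk
#' lethality); (v) position inside the active-site region. A
#' non-conserved residue has no human score, forcing criterion (iii) to 0.
#' Reachability by a single nucleotide substitution is implicit when the
#' candidates come from [enumerateMissense()].
#'
#' @param candidates data.frame with columns `label`, `mwmms`, and
#'   optionally `hwmms` (NA when unmappable) and `conserved` (logical;
#'   derived from `is.na(hwmms)` when absent).
#' @param activeSite an annotation from [computeActiveSite()] or an
#'   integer vector of active-site residue positions.
#' @param threshold WMMS threshold for criterion (i).
#' @param digits rounding for the score-identity criterion.
#' @return the input with the five 0/1 criteria columns
#'   (`wmms_threshold`, `species_conserved`, `wmms_aligned`, `no_proline`,
#'   `active_site`) and their `criteria_sum` (0-5).
#' @export
scoreSevereCriteria <- function(candidates, activeSite, threshold = 9.94,
                                digits = 2) {
  if (!is.data.frame(candidates) ||
      !all(c("label", "mwmms") %in% names(candidates))) {
    stop("candidates must be a data.frame with label and mwmms")
  }
  if (missing(activeSite) || is.null(activeSite)) {
    stop("missing active-site annotation")
  }
  positions <- if (is.list(activeSite)) activeSite$positions else activeSite
  positions <- as.integer(positions)
  parsed <- parseMutationLabel(candidates$label)
  if (!"hwmms" %in% names(candidates)) candidates$hwmms <- NA_real_
  conserved <- if ("conserved" %in% names(candidates)) {
    as.logical(candidates$conserved)
  } else {
    !is.na(candidates$hwmms)
  }
  out <- candidates
  out$wmms_threshold <- as.integer(candidates$mwmms >= threshold)
  out$species_conserved <- as.integer(conserved)
  aligned <- conserved & !is.na(candidates$hwmms) &
    round(candidates$mwmms, digits) == round(candidates$hwmms, digits)
  out$wmms_aligned <- as.integer(aligned)
  out$no_proline <- as.integer(parsed$alt_aa != "P")
  out$active_site <- as.integer(parsed$protein_position %in% positions)
  out$criteria_sum <- out$wmms_threshold + out$species_conserved +
    out$wmms_aligned + out$no_proline + out$active_site
  out
}

#' Compare scores inside vs outside the active site
#'
#' Welch's unpaired two-tailed t-test (Satterthwaite degrees of freedom)
#' between the weighted scores of active-site mutations and all others;
#' the two groups' variances generally differ, hence the Welch correction.
#'
#' @param scoresIn,scoresOut numeric score vectors, each n >= 2.
#' @return list with `meanIn`, `meanOut`, `nIn`, `nOut`, `t`, `df`,
#'   `p.value`.
#' @export
compareActiveSite <- function(scoresIn, scoresOut) {
  if (length(scoresIn) < 2L || length(scoresOut) < 2L) {
    stop("each group needs at least 2 scores")
  }
  ht <- stats::t.test(scoresIn, scoresOut, var.equal = FALSE,
                      alternative = "two.sided")
  list(meanIn = mean(scoresIn), meanOut = mean(scoresOut),
       nIn = length(scoresIn), nOut = length(scoresOut),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}
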