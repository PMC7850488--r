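#' @import methods
#' @importFrom stats lm coef pnorm qnorm rnorm runif setNames var
#' @importFrom utils read.delim write.table head
#' @importClassesFrom Biostrings DNAString
NULL

#' CodingSequence: a protein-coding DNA sequence
#'
#' Holds a coding DNA sequence together with the number of N-terminal
#' residues forming a targeting/leader peptide that is excluded from
#' mutation analysis (35 residues for the GLDC mitochondrial leader).
#' A trailing stop codon supplied with the sequence is trimmed at
#' construction and recorded in `trimmedStop`, so that every stored codon
#' encodes an amino acid. Coordinates are 1-based and inclusive throughout,
#' for both cDNA and protein positions.
#'
#' @slot id character label for the sequence.
#' @slot seq a [Biostrings::DNAString] of A/C/G/T, length divisible by 3.
#' @slot leaderLength integer count of N-terminal residues excluded from
#'   analysis; must be `>= 0` and smaller than the protein length.
#' @slot trimmedStop logical; `TRUE` when a trailing stop codon was removed
#'   from the input.
#' @exportClass CodingSequence
setClass("CodingSequence",
  representation(
    id = "character",
    seq = "DNAString",
    leaderLength = "integer",
    trimmedStop = "logical"
  )
)

setValidity("CodingSequence", function(object) {
  msg <- character()
  s <- as.character(object@seq)
  n <- nchar(s)
  if (n == 0L) msg <- c(msg, "sequence is empty")
  if (n %% 3L != 0L) msg <- c(msg, "sequence length is not a multiple of 3")
  if (grepl("[^ACGT]", s)) msg <- c(msg, "sequence contains bases other than A/C/G/T")
  if (length(object@leaderLength) != 1L || is.na(object@leaderLength) ||
      object@leaderLength < 0L) {
    msg <- c(msg, "leaderLength must be a single non-negative integer")
  } else if (n > 0L && object@leaderLength >= n %/% 3L) {
    msg <- c(msg, "leaderLength must be smaller than the protein length")
  }
  if (length(msg)) msg else TRUE
})

#' SubstitutionCensus: bookkeeping for saturation mutagenesis
#'
#' Partition of all `3 * length(cDNA)` single-nucleotide substitutions into
#' silent, nonsense, leader-excluded and raw missense changes, plus the
#' number of unique protein-level missense mutations after collapsing
#' duplicates. Substitutions are classified by protein effect first
#' (silent/nonsense), then the leader filter removes missense changes at
#' residues inside the leader peptide, so the four categories always
#' partition the total exactly.
#'
#' @slot nTotal total substitutions attempted (`3 *` sequence length).
#' @slot nSilent synonymous substitutions.
#' @slot nNonsense substitutions creating a premature stop codon.
#' @slot nLeaderExcluded missense substitutions at leader residues.
#' @slot nMissenseRaw missense substitutions kept, before deduplication.
#' @slot nMissenseUnique unique (position, ref, alt) missense mutations
#'   after deduplication, leader excluded.
#' @exportClass SubstitutionCensus
setClass("SubstitutionCensus",
  representation(
    nTotal = "integer",
    nSilent = "integer",
    nNonsense = "integer",
    nLeaderExcluded = "integer",
    nMissenseRaw = "integer",
    nMissenseUnique = "integer"
  )
)

setValidity("SubstitutionCensus", function(object) {
  msg <- character()
  parts <- object@nSilent + object@nNonsense + object@nLeaderExcluded +
    object@nMissenseRaw
  if (!isTRUE(parts == object@nTotal)) {
    msg <- c(msg, "categories do not partition the total substitution count")
  }
  if (!isTRUE(object@nMissenseUnique <= object@nMissenseRaw)) {
    msg <- c(msg, "unique missense count exceeds the raw count")
  }
  if (length(msg)) msg else TRUE
})

#' MissenseSet: enumerated missense mutations with their census
#'
#' Result of [enumerateMissense()]: a table of missense mutations (one row
#' per mutation, with cDNA provenance) and the [SubstitutionCensus-class]
#' of the enumeration that produced them.
#'
#' @slot id label of the source coding sequence.
#' @slot mutations data.frame with columns `label`, `protein_position`,
#'   `ref_aa`, `alt_aa`, `cdna_position`, `ref_base`, `alt_base`.
#' @slot census a [SubstitutionCensus-class].
#' @slot collapsed logical; `TRUE` when duplicate protein mutations from
#'   distinct nucleotide changes were collapsed to one row.
#' @exportClass MissenseSet
setClass("MissenseSet",
  representation(
    id = "character",
    mutations = "data.frame",
    census = "SubstitutionCensus",
    collapsed = "logical"
  )
)

#' CrossSpeciesMap: residue correspondence between two orthologues
#'
#' Column-by-column interpretation of a pairwise protein alignment: which
#' source position corresponds to which target position, which residues are
#' identical, and which source positions fall against a gap and are
#' therefore unmappable.
#'
#' @slot table data.frame with one row per alignment column: `source_pos`,
#'   `target_pos` (NA against a gap), `source_aa`, `target_aa`, `status`
#'   (one of `"identical"`, `"mismatch"`, `"insertion"`, `"deletion"`).
#' @slot identityFraction fraction of identical residues over columns where
#'   both sequences have a residue.
#' @slot sourceLength,targetLength ungapped sequence lengths.
#' @slot sourceId,targetId sequence labels.
#' @exportClass CrossSpeciesMap
setClass("CrossSpeciesMap",
  representation(
    table = "data.frame",
    identityFraction = "numeric",
    sourceLength = "integer",
    targetLength = "integer",
    sourceId = "character",
    targetId = "character"
  )
)

setValidity("CrossSpeciesMap", function(object) {
  msg <- character()
  tb <- object@table
  sp <- tb$source_pos[!is.na(tb$source_pos) & !is.na(tb$target_pos)]
  tp <- tb$target_pos[!is.na(tb$source_pos) & !is.na(tb$target_pos)]
  if (anyDuplicated(sp) || anyDuplicated(tp)) {
    msg <- c(msg, "mapping is not one-to-one on mapped positions")
  }
  if (length(sp) > 1L && (any(diff(sp) <= 0) || any(diff(tp) <= 0))) {
    msg <- c(msg, "mapped positions are not strictly increasing")
  }
  if (!is.na(object@identityFraction) &&
      (object@identityFraction < 0 || object@identityFraction > 1)) {
    msg <- c(msg, "identityFraction outside [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' ParameterRegistry: the catalogue of binary severity parameters
#'
#' Ordered list of binary mutation parameters, each with a category, a sign
#' (+1, or -1 for the conserved-substitution parameter, the only indicator
#' that argues for tolerance rather than damage) and a condition
#' specification evaluated by [evaluateParameters()]. The canonical
#' registry of 18 parameters ships with the package
#' (see [defaultRegistry()]); synthetic registries of any width can be
#' built for testing with [makeRegistry()].
#'
#' @slot parameters data.frame with columns `name`, `category`, `sign`,
#'   `condition` and a list column `config` of per-parameter settings.
#' @slot thresholds named list of numeric thresholds shared across
#'   parameters (ddG band edges, conservation grade cutoffs, codon-usage
#'   cutoff, BLOSUM cutoff for conserved substitutions).
#' @exportClass ParameterRegistry
setClass("ParameterRegistry",
  representation(
    parameters = "data.frame",
    thresholds = "list"
  )
)

setValidity("ParameterRegistry", function(object) {
  msg <- character()
  p <- object@parameters
  need <- c("name", "category", "sign", "condition")
  if (!all(need %in% names(p))) {
    msg <- c(msg, "parameters table must have name/category/sign/condition columns")
  } else {
    if (anyDuplicated(p$name)) msg <- c(msg, "duplicated parameter names")
    if (!all(p$sign %in% c(-1, 1))) msg <- c(msg, "signs must be +1 or -1")
    if (sum(p$sign == -1) > 1L) {
      msg <- c(msg, "at most one parameter may carry sign -1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' WeightSet: trained per-parameter coefficients
#'
#' Ordinary-least-squares coefficients regressing clinical outcome scores
#' on the binary parameter matrix. The intercept is stored but excluded
#' from the weighted score by default, so that an all-zero parameter
#' vector scores 0 (see [computeWMMS()]).
#'
#' @slot weights named numeric coefficients, one per registry parameter.
#' @slot intercept fitted intercept.
#' @slot details list of training metadata: `n`, `nCases`, `nControls`,
#'   `se` (coefficient standard errors), `sigma`, `rSquared`.
#' @exportClass WeightSet
setClass("WeightSet",
  representation(
    weights = "numeric",
    intercept = "numeric",
    details = "list"
  )
)

setValidity("WeightSet", function(object) {
  if (is.null(names(object@weights)) || anyDuplicated(names(object@weights))) {
    return("weights must be uniquely named by parameter")
  }
  TRUE
})

#' OutcomeModel: the linear clinical-outcome / weighted-score relation
#'
#' Linear model `WMMS = slope * COS + intercept` fitted (or supplied) for
#' homozygous mutations with a clinical outcome score (COS, 0-12), plus
#' the WMMS value at the clinical attenuated/severe COS cutoff.
#'
#' @slot slope,intercept regression line of WMMS on COS.
#' @slot rSquared coefficient of determination (NA when the line is
#'   supplied rather than fitted).
#' @slot cosCutoff clinical cutoff on the COS scale (default 5).
#' @slot wmmsThreshold `slope * cosCutoff + intercept`, the WMMS value
#'   separating attenuated from severe disease.
#' @slot n number of (COS, WMMS) pairs used in the fit (0 when supplied).
#' @exportClass OutcomeModel
setClass("OutcomeModel",
  representation(
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    cosCutoff = "numeric",
    wmmsThreshold = "numeric",
    n = "integer"
  )
)

setValidity("OutcomeModel", function(object) {
  thr <- object@slope * object@cosCutoff + object@intercept
  if (!isTRUE(all.equal(thr, object@wmmsThreshold, tolerance = 1e-8))) {
    return("wmmsThreshold inconsistent with slope, intercept and cosCutoff")
  }
  TRUE
})

#' ColonyCounts: genotype counts from a heterozygote intercross
#'
#' Counts of wild-type, heterozygous and homozygous-mutant progeny from a
#' breeding colony, with the Mendelian expectation (1:2:1 by default) used
#' by [mendelianChisq()] and [prenatalLethality()].
#'
#' @slot wildtype,het,hom non-negative progeny counts.
#' @slot expectedRatio numeric length-3 expected genotype ratio.
#' @exportClass ColonyCounts
setClass("ColonyCounts",
  representation(
    wildtype = "integer",
    het = "integer",
    hom = "integer",
    expectedRatio = "numeric"
  )
)

setValidity("ColonyCounts", function(object) {
  msg <- character()
  cts <- c(object@wildtype, object@het, object@hom)
  if (any(is.na(cts)) || any(cts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (length(object@expectedRatio) != 3L || any(object@expectedRatio <= 0)) {
    msg <- c(msg, "expectedRatio must be 3 positive numbers")
  }
  if (length(msg)) msg else TRUE
})
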