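#' Generate a deterministic synthetic fixture bundle
#'
#' Builds the synthetic study material the package's tests and examples
#' run on, emulating the structure (not the values) of the real data: a
#' pair of short orthologous coding sequences -- a "human-like" cDNA and a
#' "mouse-like" copy carrying one in-frame 15-nt (5-codon) insertion plus
#' a few point substitutions, mirroring the five-glycine insertion and
#' ~92% identity of real mouse GLDC -- a binary parameter table with
#' planted linear weights, and (COS, WMMS) pairs scattered around the
#' clinical regression line. Regeneration with the same seed is
#' byte-identical; the planted weights are recorded alongside for
#' recovery tests.
#'
#' @param seed integer RNG seed.
#' @param nMutations rows of the parameter table (n >= 2).
#' @param kParameters parameter columns (k >= 1); when 18, columns take
#'   the canonical registry names.
#' @param noiseSd Gaussian noise (COS units) around the regression line.
#' @param bernoulliP per-parameter probability of a 1.
#' @param nCodons length of the human-like cDNA, codons.
#' @param slope,intercept the planted WMMS = slope * COS + intercept line.
#' @return list with elements `seed`, `humanCds`, `mouseCds` (character
#'   cDNAs), `insertionAfter` (human codon after which the mouse insertion
#'   sits), `parameters` (0/1 matrix with mutation-label rownames),
#'   `labels`, `plantedWeights`, `wmms`, `cos`.
#' @examples
#' fx <- generateFixture(seed = 1, nMutations = 30)
#' dim(fx$parameters)
#' @export
generateFixture <- function(seed, nMutations = 40, kParameters = 18,
                            noiseSd = 0.5, bernoulliP = 0.3,
                            nCodons = 60, slope = 0.76, intercept = -2.5) {
  if (nMutations < 2L) stop("nMutations must be >= 2")
  if (kParameters < 1L) stop("kParameters must be >= 1")
  withSeed(seed, {
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    humanCodons <- c("ATG", sample(sense, nCodons - 1L, replace = TRUE))

    # mouse-like copy: 5-codon glycine insertion + ~8% missense codons
    insertAfter <- min(42L, nCodons - 1L)
    glyCodons <- c("GGA", "GGC", "GGT", "GGA", "GGG")
    nSub <- max(1L, round(0.08 * nCodons))
    subAt <- sample(setdiff(2:nCodons, insertAfter), nSub)
    mouseCodons <- humanCodons
    gc <- Biostrings::GENETIC_CODE
    for (i in subAt) {
      other <- sense[gc[sense] != gc[[mouseCodons[i]]]]
      mouseCodons[i] <- sample(other, 1L)
    }
    mouseCodons <- append(mouseCodons, glyCodons, after = insertAfter)

    # parameter table with planted weights
    X <- matrix(stats::rbinom(nMutations * kParameters, 1L, bernoulliP),
                nrow = nMutations, ncol = kParameters)
    colnames(X) <- if (kParameters == 18L) {
      parameterNames(defaultRegistry())
    } else {
      sprintf("param_%02d", seq_len(kParameters))
    }
    refs <- sample(setdiff(AA1, "P"), nMutations, replace = TRUE)
    positions <- sample(seq(36L, 999L), nMutations)
    alts <- vapply(refs, function(r) sample(setdiff(AA1, r), 1L),
                   character(1))
    labels <- paste0(refs, positions, alts)
    rownames(X) <- labels

    plantedWeights <- setNames(round(rnorm(kParameters, 0, 1.5), 3),
                               colnames(X))
    wmms <- as.numeric(X %*% plantedWeights)
    cos <- (wmms - intercept) / slope + rnorm(nMutations, 0, noiseSd)
    cos <- pmin(pmax(cos, 0), 12)

    list(seed = seed,
         humanCds = paste(humanCodons, collapse = ""),
         mouseCds = paste(mouseCodons, collapse = ""),
         insertionAfter = insertAfter,
         parameters = X,
         labels = labels,
         plantedWeights = plantedWeights,
         wmms = wmms,
         cos = cos)
  })
}

#' Write a fixture bundle to disk
#'
#' FASTA for the cDNA pair, tab-separated tables for parameters, planted
#' weights and (COS, WMMS) pairs.
#'
#' @param fx a bundle from [generateFixture()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
writeFixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "cdna_pair.fa")
  writeFasta(c(human_like = fx$humanCds, mouse_like = fx$mouseCds), fasta)
  params <- file.path(dir, "parameters.tsv")
  writeDelimTable(data.frame(label = rownames(fx$parameters),
                             fx$parameters, check.names = FALSE), params)
  wts <- file.path(dir, "planted_weights.tsv")
  writeDelimTable(data.frame(parameter = names(fx$plantedWeights),
                             weight = unname(fx$plantedWeights)), wts)
  outc <- file.path(dir, "cos_wmms.tsv")
  writeDelimTable(data.frame(label = fx$labels, cos = fx$cos,
                             wmms = fx$wmms), outc)
  invisible(c(fasta, params, wts, outc))
}
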