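STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a CodingSequence
#'
#' Builds a [CodingSequence-class] from a DNA string. The sequence must be
#' A/C/G/T only and a multiple of 3 long. A trailing stop codon is trimmed
#' (and recorded); an absent initial ATG raises a warning, not an error, so
#' that sequence fragments can be analysed.
#'
#' @param seq character string or [Biostrings::DNAString].
#' @param id sequence label.
#' @param leaderLength number of N-terminal residues excluded from mutation
#'   analysis (the GLDC mitochondrial leader peptide spans residues 1-35).
#' @return a [CodingSequence-class].
#' @examples
#' cds <- CodingSequence("ATGAAA", id = "toy")
#' translateCds(cds)
#' @export
CodingSequence <- function(seq, id = "cds", leaderLength = 0L) {
  s <- toupper(as.character(seq))
  if (nchar(s) == 0L) stop("empty sequence")
  if (nchar(s) %% 3L != 0L) stop("sequence length is not a multiple of 3")
  if (grepl("[^ACGT]", s)) stop("sequence contains bases other than A/C/G/T")
  trimmed <- FALSE
  last <- substr(s, nchar(s) - 2L, nchar(s))
  if (last %in% STOP_CODONS) {
    s <- substr(s, 1L, nchar(s) - 3L)
    trimmed <- TRUE
    if (nchar(s) == 0L) stop("sequence contains only a stop codon")
  }
  if (substr(s, 1L, 3L) != "ATG") {
    warning("sequence does not begin with ATG; treating it as a fragment",
            call. = FALSE)
  }
  new("CodingSequence", id = as.character(id),
      seq = Biostrings::DNAString(s),
      leaderLength = as.integer(leaderLength),
      trimmedStop = trimmed)
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA file with one or more DNA records.
#' @param leaderLength leader length applied to every record.
#' @return a list of [CodingSequence-class], named by record id.
#' @export
readCodingSequence <- function(path, leaderLength = 0L) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  out <- lapply(seq_along(set), function(i) {
    CodingSequence(as.character(set[[i]]), id = names(set)[i],
                   leaderLength = leaderLength)
  })
  names(out) <- names(set)
  out
}

#' Translate a coding sequence
#'
#' Standard genetic code; the trailing stop codon (if present on input) was
#' already dropped at construction. An internal stop codon is an error: the
#' reference frame must be intact.
#'
#' @param cds a [CodingSequence-class].
#' @return single character string of one-letter amino acids.
#' @export
translateCds <- function(cds) {
  stopifnot(is(cds, "CodingSequence"))
  aa <- as.character(Biostrings::translate(cds@seq, no.init.codon = TRUE))
  if (grepl("\\*", aa)) {
    stop("premature stop in reference at residue ",
         regexpr("\\*", aa)[1L])
  }
  aa
}

#' Enumerate all theoretical missense mutations of a coding sequence
#'
#' Substitutes each of the three alternative bases at every nucleotide
#' position, translates, and classifies each substitution as silent,
#' nonsense, leader-excluded (a missense change at a residue inside the
#' leader peptide) or missense. The four categories partition the
#' `3 * length(cDNA)` substitutions exactly. Duplicate protein mutations
#' arising from different nucleotide changes are collapsed to one row when
#' `collapse = TRUE` (the first cDNA provenance is kept); with
#' `collapse = FALSE` every provenance row is retained.
#'
#' @param cds a [CodingSequence-class].
#' @param collapse collapse duplicate (position, ref, alt) mutations.
#' @return a [MissenseSet-class].
#' @examples
#' ms <- enumerateMissense(CodingSequence("ATGAAA"))
#' census(ms)
#' mutations(ms)$label
#' @export
enumerateMissense <- function(cds, collapse = TRUE) {
  stopifnot(is(cds, "CodingSequence"))
  s <- as.character(cds@seq)
  L <- nchar(s)
  bases <- strsplit(s, "")[[1]]
  prot <- strsplit(translateCds(cds), "")[[1]]
  gc <- Biostrings::GENETIC_CODE

  # Long-format grid: each position x 3 alternative bases.
  pos <- rep(seq_len(L), each = 3L)
  refb <- bases[pos]
  alts <- c("A", "C", "G", "T")
  # for each position, the 3 bases != ref, in A<C<G<T order
  altMat <- vapply(bases, function(b) setdiff(alts, b), character(3))
  altb <- as.vector(altMat)

  codonIdx <- (pos - 1L) %/% 3L + 1L
  within <- (pos - 1L) %% 3L + 1L
  c1 <- bases[(codonIdx - 1L) * 3L + 1L]
  c2 <- bases[(codonIdx - 1L) * 3L + 2L]
  c3 <- bases[(codonIdx - 1L) * 3L + 3L]
  m1 <- ifelse(within == 1L, altb, c1)
  m2 <- ifelse(within == 2L, altb, c2)
  m3 <- ifelse(within == 3L, altb, c3)
  mutCodon <- paste0(m1, m2, m3)
  mutAA <- unname(gc[mutCodon])
  refAA <- prot[codonIdx]

  silent <- mutAA == refAA
  nonsense <- mutAA == "*"
  missense <- !silent & !nonsense
  inLeader <- codonIdx <= cds@leaderLength
  leaderExcluded <- missense & inLeader
  kept <- missense & !inLeader

  tab <- data.frame(
    label = paste0(refAA[kept], codonIdx[kept], mutAA[kept]),
    protein_position = codonIdx[kept],
    ref_aa = refAA[kept],
    alt_aa = mutAA[kept],
    cdna_position = pos[kept],
    ref_base = refb[kept],
    alt_base = altb[kept],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$cdna_position, tab$alt_base), , drop = FALSE]
  nUnique <- length(unique(tab$label))
  if (collapse) {
    tab <- tab[!duplicated(tab$label), , drop = FALSE]
  }
  rownames(tab) <- NULL

  cen <- new("SubstitutionCensus",
    nTotal = 3L * L,
    nSilent = sum(silent),
    nNonsense = sum(nonsense),
    nLeaderExcluded = sum(leaderExcluded),
    nMissenseRaw = sum(kept),
    nMissenseUnique = nUnique
  )
  new("MissenseSet", id = cds@id, mutations = tab, census = cen,
      collapsed = collapse)
}

#' @rdname accessors
#' @export
setMethod("mutations", "MissenseSet", function(x) x@mutations)

#' @rdname accessors
#' @export
setMethod("census", "MissenseSet", function(x) x@census)

#' Coerce a SubstitutionCensus to a one-row data.frame
#'
#' @param x a [SubstitutionCensus-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "SubstitutionCensus", function(x, ...) {
  data.frame(n_total = x@nTotal, n_silent = x@nSilent,
             n_nonsense = x@nNonsense, n_leader_excluded = x@nLeaderExcluded,
             n_missense_raw = x@nMissenseRaw,
             n_missense_unique = x@nMissenseUnique)
})

setMethod("show", "CodingSequence", function(object) {
  cat("CodingSequence '", object@id, "': ", length(object@seq),
      " nt (", length(object@seq) %/% 3L, " codons), leader ",
      object@leaderLength, " residues",
      if (object@trimmedStop) ", trailing stop trimmed" else "", "\n",
      sep = "")
})

setMethod("show", "SubstitutionCensus", function(object) {
  cat("SubstitutionCensus: ", object@nTotal, " substitutions = ",
      object@nSilent, " silent + ", object@nNonsense, " nonsense + ",
      object@nLeaderExcluded, " leader-excluded + ",
      object@nMissenseRaw, " missense (", object@nMissenseUnique,
      " unique)\n", sep = "")
})

setMethod("show", "MissenseSet", function(object) {
  cat("MissenseSet from '", object@id, "': ", nrow(object@mutations),
      " rows", if (object@collapsed) " (duplicates collapsed)", "\n",
      sep = "")
  show(object@census)
})
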