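#' Build a residue map from a pairwise protein alignment
#'
#' Walks the columns of a gapped pairwise alignment and derives the
#' one-to-one correspondence between ungapped source and target positions.
#' Gap columns contribute no mapping: an insertion in the target shifts all
#' downstream target numbering (as with the five-glycine insertion at mouse
#' GLDC positions 43-47), a deletion leaves source positions unmappable.
#'
#' @param alignment two aligned sequences of equal gapped length: a
#'   character vector of length 2, an [Biostrings::AAStringSet] of length 2,
#'   or a list of two single strings. `-` and `.` count as gaps.
#' @param sourceId,targetId labels; default to the alignment names.
#' @return a [CrossSpeciesMap-class].
#' @examples
#' m <- buildMap(c(human = "ARND-", mouse = "ARNDC"))
#' identityFraction(m)
#' @export
buildMap <- function(alignment, sourceId = NULL, targetId = NULL) {
  if (is(alignment, "AAStringSet") || is(alignment, "BStringSet")) {
    nms <- names(alignment)
    alignment <- as.character(alignment)
    names(alignment) <- nms
  }
  alignment <- unlist(alignment)
  if (length(alignment) != 2L) stop("alignment must contain exactly 2 sequences")
  if (nchar(alignment[1]) != nchar(alignment[2])) {
    stop("aligned sequences have unequal lengths")
  }
  if (is.null(sourceId)) sourceId <- names(alignment)[1] %||% "source"
  if (is.null(targetId)) targetId <- names(alignment)[2] %||% "target"

  sChars <- strsplit(toupper(alignment[[1]]), "")[[1]]
  tChars <- strsplit(toupper(alignment[[2]]), "")[[1]]
  sGap <- sChars %in% c("-", ".")
  tGap <- tChars %in% c("-", ".")
  if (any(sGap & tGap)) {
    keep <- !(sGap & tGap)   # all-gap columns carry no information
    sChars <- sChars[keep]; tChars <- tChars[keep]
    sGap <- sGap[keep]; tGap <- tGap[keep]
  }
  sPos <- ifelse(sGap, NA_integer_, cumsum(!sGap))
  tPos <- ifelse(tGap, NA_integer_, cumsum(!tGap))
  status <- ifelse(sGap, "insertion",
            ifelse(tGap, "deletion",
            ifelse(sChars == tChars, "identical", "mismatch")))
  tb <- data.frame(
    source_pos = sPos, target_pos = tPos,
    source_aa = ifelse(sGap, NA_character_, sChars),
    target_aa = ifelse(tGap, NA_character_, tChars),
    status = status, stringsAsFactors = FALSE
  )
  aligned <- !sGap & !tGap
  idf <- if (any(aligned)) mean(sChars[aligned] == tChars[aligned]) else NA_real_
  new("CrossSpeciesMap", table = tb, identityFraction = idf,
      sourceLength = sum(!sGap), targetLength = sum(!tGap),
      sourceId = sourceId, targetId = targetId)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a[1])) b else a

#' Align two protein sequences (global Needleman-Wunsch)
#'
#' Self-contained global alignment with BLOSUM62 and affine gap penalties
#' (opening 10, extension 0.5), for use when a pre-computed alignment is
#' not supplied. Pre-computed aligned FASTA (e.g. from Clustal Omega) can
#' be read with [readProteinAlignment()] instead; alignments from different
#' programs are not guaranteed identical.
#'
#' @param source,target plain (ungapped) amino-acid strings.
#' @param sourceId,targetId labels.
#' @return a named character vector of the two gapped sequences.
#' @export
alignProteins <- function(source, target, sourceId = "source",
                          targetId = "target") {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(source), Biostrings::AAString(target),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  out <- c(as.character(Biostrings::alignedPattern(pa)),
           as.character(Biostrings::alignedSubject(pa)))
  names(out) <- c(sourceId, targetId)
  out
}

#' Read a pairwise protein alignment from aligned FASTA
#'
#' @param path aligned FASTA with exactly two records of equal width.
#' @return named character vector of the two gapped sequences.
#' @export
readProteinAlignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) != 2L) stop("expected exactly 2 aligned sequences, got ",
                              length(set))
  out <- as.character(set)
  if (nchar(out[1]) != nchar(out[2])) stop("aligned sequences have unequal lengths")
  out
}

#' Map mutations onto the orthologous protein
#'
#' A mutation maps when its source position is aligned to a target residue
#' identical to the mutation's reference residue (strict conservation);
#' otherwise it is unmappable, either because the column is a gap or
#' because the residue is not conserved. Mapped mutations are renumbered in
#' target coordinates and keep their reference and alternate residues.
#'
#' @param labels mutation labels ("S132L") or a data.frame from
#'   [parseMutationLabel()] / [mutations()].
#' @param map a [CrossSpeciesMap-class].
#' @return data.frame with columns `label`, `status` (`"mapped"`,
#'   `"not_conserved"` or `"gap"`), `target_position`, `target_label` (NA
#'   when unmapped).
#' @examples
#' m <- buildMap(c(h = "ASD", m = "ASD"))
#' mapMutations("S2L", m)
#' @export
mapMutations <- function(labels, map) {
  stopifnot(is(map, "CrossSpeciesMap"))
  df <- if (is.data.frame(labels)) labels else parseMutationLabel(labels)
  if (any(df$protein_position < 1L | df$protein_position > map@sourceLength)) {
    bad <- df$label[df$protein_position < 1L |
                    df$protein_position > map@sourceLength]
    stop("position outside the source sequence: ", paste(bad, collapse = ", "))
  }
  tb <- map@table[!is.na(map@table$source_pos), , drop = FALSE]
  idx <- match(df$protein_position, tb$source_pos)
  srcAA <- tb$source_aa[idx]
  tgtPos <- tb$target_pos[idx]
  tgtAA <- tb$target_aa[idx]
  mismatchRef <- !is.na(srcAA) & srcAA != df$ref_aa
  if (any(mismatchRef)) {
    warning("reference residue differs from the aligned source sequence for: ",
            paste(df$label[mismatchRef], collapse = ", "), call. = FALSE)
  }
  status <- ifelse(is.na(tgtPos), "gap",
            ifelse(tgtAA == df$ref_aa, "mapped", "not_conserved"))
  mapped <- status == "mapped"
  data.frame(
    label = df$label,
    status = status,
    target_position = ifelse(mapped, tgtPos, NA_integer_),
    target_label = ifelse(mapped,
                          paste0(df$ref_aa, tgtPos, df$alt_aa),
                          NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Invert a cross-species map
#'
#' Swaps source and target; composing a map with its inverse is the
#' identity on mapped positions.
#'
#' @param map a [CrossSpeciesMap-class].
#' @return a [CrossSpeciesMap-class] with the roles exchanged.
#' @export
invertMap <- function(map) {
  stopifnot(is(map, "CrossSpeciesMap"))
  tb <- map@table
  new("CrossSpeciesMap",
      table = data.frame(
        source_pos = tb$target_pos, target_pos = tb$source_pos,
        source_aa = tb$target_aa, target_aa = tb$source_aa,
        status = ifelse(tb$status == "insertion", "deletion",
                 ifelse(tb$status == "deletion", "insertion", tb$status)),
        stringsAsFactors = FALSE),
      identityFraction = map@identityFraction,
      sourceLength = map@targetLength, targetLength = map@sourceLength,
      sourceId = map@targetId, targetId = map@sourceId)
}

#' @rdname accessors
#' @export
setMethod("mappingTable", "CrossSpeciesMap", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("identityFraction", "CrossSpeciesMap", function(x) x@identityFraction)

#' @rdname accessors
#' @export
setMethod("unmappedPositions", "CrossSpeciesMap", function(x) {
  tb <- x@table
  tb$source_pos[!is.na(tb$source_pos) & is.na(tb$target_pos)]
})

setMethod("show", "CrossSpeciesMap", function(object) {
  cat("CrossSpeciesMap ", object@sourceId, " -> ", object@targetId, ": ",
      object@sourceLength, " -> ", object@targetLength, " residues, ",
      "identity ", round(100 * object@identityFraction, 1), "%, ",
      length(unmappedPositions(object)), " unmappable source positions\n",
      sep = "")
})
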