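AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

#' Parse mutation labels of the form "A394V"
#'
#' Accepts the single-letter dialect used throughout the package
#' (`<refAA><1-based position><altAA>`, e.g. `"A394V"`, `"S562F"`).
#' Three-letter amino-acid codes are rejected with guidance.
#'
#' @param labels character vector of labels.
#' @return data.frame with columns `label`, `ref_aa`, `protein_position`,
#'   `alt_aa`.
#' @examples
#' parseMutationLabel(c("A394V", "S562F"))
#' @export
parseMutationLabel <- function(labels) {
  labels <- as.character(labels)
  if (any(grepl("^[A-Za-z]{3}[0-9]+[A-Za-z]{3}$", labels))) {
    stop("three-letter amino-acid codes are not supported; use the ",
         "single-letter form, e.g. \"A394V\" instead of \"Ala394Val\"")
  }
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", labels)
  if (!all(ok)) {
    stop("malformed mutation label(s): ",
         paste(labels[!ok], collapse = ", "),
         " (expected single-letter form like \"A394V\")")
  }
  ref <- substr(labels, 1L, 1L)
  alt <- substring(labels, nchar(labels))
  pos <- as.integer(gsub("[A-Z]", "", labels))
  bad <- !(ref %in% AA1) | !(alt %in% AA1)
  if (any(bad)) {
    stop("unknown amino-acid code in label(s): ",
         paste(labels[bad], collapse = ", "))
  }
  if (any(ref == alt)) {
    stop("reference and alternate amino acid are identical in: ",
         paste(labels[ref == alt], collapse = ", "))
  }
  data.frame(label = labels, ref_aa = ref, protein_position = pos,
             alt_aa = alt, stringsAsFactors = FALSE)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Single numeric scalar check.
assertScalarNumber <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(what, " must be a single finite number")
  }
  invisible(x)
}
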