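#' Load a parameter registry from a YAML config
#'
#' The registry file lists the binary mutation parameters in order, each
#' with a category, sign and condition specification, plus shared numeric
#' thresholds (ddG band edges, conservation grade sets, codon-usage and
#' BLOSUM cutoffs). See the shipped
#' `system.file("extdata", "parameter_registry.yaml", package = "wmms")`
#' for the canonical 18-parameter layout.
#'
#' @param path YAML registry file.
#' @return a [ParameterRegistry-class].
#' @export
readRegistry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$parameters)) stop("registry file has no 'parameters' list")
  p <- do.call(rbind, lapply(cfg$parameters, function(x) {
    data.frame(name = x$name,
               category = x$category %||% "uncategorised",
               sign = as.numeric(x$sign %||% 1),
               condition = x$condition,
               stringsAsFactors = FALSE)
  }))
  p$config <- lapply(cfg$parameters, function(x) {
    x[setdiff(names(x), c("name", "category", "sign", "condition"))]
  })
  new("ParameterRegistry", parameters = p,
      thresholds = cfg$thresholds %||% list())
}

#' The canonical 18-parameter registry
#'
#' Loads the registry shipped with the package: 4 stability parameters
#' (ddG class), 4 position parameters (helix, sheet, dimerization
#' interface, active site), 3 conservation parameters (ConSurf grades 9,
#' 8, 7), 5 property-change parameters (proline, glycine, size, polarity,
#' charge), the negatively signed conserved-substitution parameter, and a
#' codon/tRNA availability parameter.
#'
#' @return a [ParameterRegistry-class] of width 18.
#' @examples
#' r <- defaultRegistry()
#' parameterNames(r)
#' @export
defaultRegistry <- function() {
  readRegistry(system.file("extdata", "parameter_registry.yaml",
                           package = "wmms"))
}

#' Build a synthetic registry of arbitrary width
#'
#' Every parameter uses the generic `table` condition, i.e. its 0/1 value
#' is looked up directly from a provider table. Used for fixtures and for
#' testing the scoring machinery at widths other than 18.
#'
#' @param names parameter names.
#' @param signs numeric vector of +1/-1, recycled; at most one -1.
#' @return a [ParameterRegistry-class].
#' @export
makeRegistry <- function(names, signs = 1) {
  signs <- rep_len(signs, length(names))
  p <- data.frame(name = names, category = "synthetic", sign = signs,
                  condition = "table", stringsAsFactors = FALSE)
  p$config <- rep(list(list()), length(names))
  new("ParameterRegistry", parameters = p, thresholds = list())
}

#' @rdname accessors
#' @export
setMethod("parameterNames", "ParameterRegistry", function(x) x@parameters$name)

#' @rdname accessors
#' @export
setMethod("parameterSigns", "ParameterRegistry", function(x) {
  setNames(x@parameters$sign, x@parameters$name)
})

setMethod("show", "ParameterRegistry", function(object) {
  p <- object@parameters
  cat("ParameterRegistry with ", nrow(p), " parameters (",
      paste(sprintf("%s: %d", names(table(p$category)), table(p$category)),
            collapse = ", "),
      "); ", sum(p$sign == -1), " negatively signed\n", sep = "")
})
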