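# Built-in residue property tables used by the property-change parameters.
# Size classes cut residue volume (Zamyatnin, A^3) at 110 and 160; polarity
# follows the usual polar / nonpolar split; charge is the physiological
# assignment (His counted positive). Swapping tables is a registry config
# change, not a code change.

AA_VOLUME <- c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0
)

#' Built-in amino-acid property classes
#'
#' One row per standard residue: size class (`small` < 110 A^3, `medium`
#' 110-160, `large` > 160), polarity (`polar`/`nonpolar`) and charge
#' (`positive`/`negative`/`neutral`). These back the size-, polarity- and
#' charge-change parameters of the canonical registry.
#'
#' @return data.frame with columns `aa`, `volume`, `size`, `polarity`,
#'   `charge`.
#' @examples
#' aaProperties()[aaProperties()$aa %in% c("G", "W"), ]
#' @export
aaProperties <- function() {
  aa <- names(AA_VOLUME)
  nonpolar <- c("G", "A", "V", "L", "I", "P", "F", "M", "W")
  data.frame(
    aa = aa,
    volume = unname(AA_VOLUME),
    size = cut(AA_VOLUME, c(-Inf, 110, 160, Inf),
               labels = c("small", "medium", "large")),
    polarity = ifelse(aa %in% nonpolar, "nonpolar", "polar"),
    charge = ifelse(aa %in% c("K", "R", "H"), "positive",
             ifelse(aa %in% c("D", "E"), "negative", "neutral")),
    stringsAsFactors = FALSE
  )
}

# property-change indicators for a ref/alt pair
.propertyChange <- function(ref, alt, property) {
  props <- aaProperties()
  iR <- match(ref, props$aa)
  iA <- match(alt, props$aa)
  if (anyNA(iR) || anyNA(iA)) stop("unknown amino acid in property lookup")
  switch(property,
    proline  = as.integer(ref == "P" | alt == "P"),
    glycine  = as.integer(ref == "G" | alt == "G"),
    size     = as.integer(as.character(props$size[iR]) !=
                          as.character(props$size[iA])),
    polarity = as.integer(props$polarity[iR] != props$polarity[iA]),
    charge   = as.integer(props$charge[iR] != props$charge[iA]),
    stop("unknown property class: ", property)
  )
}

# BLOSUM62 lookup for the conserved-substitution parameter
.blosumScore <- function(ref, alt) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  B[cbind(ref, alt)]
}
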