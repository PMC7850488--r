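DDG_LEVELS <- c("very_destabilizing", "destabilizing", "unchanged",
                "stabilizing", "very_stabilizing")

#' Categorize a predicted folding free-energy change
#'
#' Bands a ddG (kcal/mol, negative = destabilizing) into five categories:
#' very destabilizing (`< -5`), destabilizing (`[-5, -1.5)`), unchanged
#' (`[-1.5, 1.5]`), stabilizing (`(1.5, 5]`) and very stabilizing
#' (`> 5`). The destabilizing-side edges are the published ones; the
#' stabilizing side mirrors them and can be overridden via `thresholds`.
#'
#' @param ddg numeric vector of ddG values, kcal/mol.
#' @param thresholds named list overriding any of `ddg_very_destabilizing`
#'   (-5), `ddg_destabilizing` (-1.5), `ddg_stabilizing` (1.5),
#'   `ddg_very_stabilizing` (5).
#' @return factor with levels very_destabilizing < destabilizing <
#'   unchanged < stabilizing < very_stabilizing.
#' @examples
#' categorizeDdg(c(-6, -2, 0, 2, 6))
#' @export
categorizeDdg <- function(ddg, thresholds = list()) {
  if (!is.numeric(ddg) || any(!is.finite(ddg))) {
    stop("ddG values must be finite numbers")
  }
  th <- function(name, default) as.numeric(thresholds[[name]] %||% default)
  vd <- th("ddg_very_destabilizing", -5.0)
  d  <- th("ddg_destabilizing", -1.5)
  s  <- th("ddg_stabilizing", 1.5)
  vs <- th("ddg_very_stabilizing", 5.0)
  out <- ifelse(ddg < vd, "very_destabilizing",
         ifelse(ddg < d, "destabilizing",
         ifelse(ddg <= s, "unchanged",
         ifelse(ddg <= vs, "stabilizing", "very_stabilizing"))))
  factor(out, levels = DDG_LEVELS, ordered = TRUE)
}

#' Evaluate the binary parameters for a set of mutations
#'
#' Runs every parameter of the registry through its condition and returns
#' a 0/1 matrix (mutations x parameters). Data come from pluggable
#' providers; a mutation missing from a provider table is an error, never a
#' silent zero.
#'
#' Providers, by condition type:
#' \describe{
#'   \item{`ddg_class`}{`providers$ddg`: data.frame `label`, `ddg`
#'     (kcal/mol). Indicator is 1 when [categorizeDdg()] assigns the
#'     parameter's class.}
#'   \item{`residue_flag`}{`providers$residue`: data.frame `position` plus
#'     the named logical/0-1 `field` column (`helix`, `sheet`,
#'     `dimer_interface`, `active_site`).}
#'   \item{`consurf_grade`}{`providers$residue$consurf_grade` (1-9);
#'     indicator is 1 when the grade is in the parameter's `grades` set.}
#'   \item{`property`}{built-in [aaProperties()] tables on the ref/alt
#'     residues; no provider needed.}
#'   \item{`conserved_substitution`}{BLOSUM62 score of ref->alt at or above
#'     `blosum_conserved_min` (default 1, i.e. score > 0); no provider
#'     needed. The only negatively signed parameter.}
#'   \item{`rare_codon`}{`providers$codon_usage`: data.frame `codon`,
#'     `per_thousand`. The mutant codon (derived from `cds` and the
#'     mutation's cDNA provenance) is rare when its usage is below
#'     `rare_codon_max_per_thousand`.}
#'   \item{`table`}{`providers[[<parameter name>]]`: data.frame `label`,
#'     `value` with pre-computed 0/1 values (synthetic registries).}
#' }
#'
#' @param muts data.frame with at least `label`; `ref_aa`, `alt_aa`,
#'   `protein_position` are parsed from the label when absent. `rare_codon`
#'   additionally needs `cdna_position`/`alt_base` columns (as produced by
#'   [enumerateMissense()]) together with `cds`.
#' @param registry a [ParameterRegistry-class].
#' @param providers named list of provider tables (see above).
#' @param cds the source [CodingSequence-class]; only needed for
#'   `rare_codon`.
#' @return integer matrix (labels x parameter names) of 0/1 values, with a
#'   `provenance` attribute naming the provider used per parameter.
#' @export
evaluateParameters <- function(muts, registry, providers = list(),
                               cds = NULL) {
  stopifnot(is(registry, "ParameterRegistry"))
  if (is.character(muts)) muts <- parseMutationLabel(muts)
  if (!"label" %in% names(muts)) stop("mutation table needs a 'label' column")
  if (!all(c("ref_aa", "alt_aa", "protein_position") %in% names(muts))) {
    parsed <- parseMutationLabel(muts$label)
    for (col in c("ref_aa", "alt_aa", "protein_position")) {
      if (!col %in% names(muts)) muts[[col]] <- parsed[[col]]
    }
  }
  p <- registry@parameters
  th <- registry@thresholds
  n <- nrow(muts)
  out <- matrix(0L, nrow = n, ncol = nrow(p),
                dimnames = list(muts$label, p$name))
  provenance <- setNames(character(nrow(p)), p$name)

  ddgClass <- NULL
  getDdgClass <- function() {
    if (is.null(providers$ddg)) {
      stop("parameter unavailable: no 'ddg' provider table supplied")
    }
    idx <- match(muts$label, providers$ddg$label)
    if (anyNA(idx)) {
      stop("parameter unavailable: no ddG value for mutation(s) ",
           paste(muts$label[is.na(idx)], collapse = ", "))
    }
    as.character(categorizeDdg(providers$ddg$ddg[idx], th))
  }
  getResidue <- function(field) {
    if (is.null(providers$residue)) {
      stop("parameter unavailable: no 'residue' provider table supplied")
    }
    if (!field %in% names(providers$residue)) {
      stop("parameter unavailable: residue table lacks column '", field, "'")
    }
    idx <- match(muts$protein_position, providers$residue$position)
    if (anyNA(idx)) {
      stop("parameter unavailable: no residue annotation for position(s) ",
           paste(unique(muts$protein_position[is.na(idx)]), collapse = ", "))
    }
    providers$residue[[field]][idx]
  }

  for (j in seq_len(nrow(p))) {
    cond <- p$condition[j]
    cfg <- p$config[[j]]
    val <- switch(cond,
      ddg_class = {
        if (is.null(ddgClass)) ddgClass <- getDdgClass()
        provenance[j] <- "ddg"
        as.integer(ddgClass == cfg$value)
      },
      residue_flag = {
        provenance[j] <- "residue"
        as.integer(as.logical(getResidue(cfg$field)))
      },
      consurf_grade = {
        provenance[j] <- "residue"
        as.integer(getResidue("consurf_grade") %in% unlist(cfg$grades))
      },
      property = {
        provenance[j] <- "builtin:aaProperties"
        .propertyChange(muts$ref_aa, muts$alt_aa, cfg$property)
      },
      conserved_substitution = {
        provenance[j] <- "builtin:BLOSUM62"
        minScore <- as.numeric(th$blosum_conserved_min %||% 1)
        as.integer(.blosumScore(muts$ref_aa, muts$alt_aa) >= minScore)
      },
      rare_codon = {
        provenance[j] <- "codon_usage"
        .rareCodon(muts, providers$codon_usage, cds,
                   as.numeric(th$rare_codon_max_per_thousand %||% 8))
      },
      table = {
        provenance[j] <- paste0("table:", p$name[j])
        tb <- providers[[p$name[j]]]
        if (is.null(tb)) {
          stop("parameter unavailable: no provider table for '",
               p$name[j], "'")
        }
        idx <- match(muts$label, tb$label)
        if (anyNA(idx)) {
          stop("parameter unavailable: '", p$name[j],
               "' missing for mutation(s) ",
               paste(muts$label[is.na(idx)], collapse = ", "))
        }
        as.integer(tb$value[idx])
      },
      stop("unknown parameter condition: ", cond)
    )
    if (any(is.na(val)) || !all(val %in% c(0L, 1L))) {
      stop("parameter '", p$name[j], "' produced non-binary values")
    }
    out[, j] <- val
  }
  attr(out, "provenance") <- provenance
  out
}

.rareCodon <- function(muts, usage, cds, cutoff) {
  if (is.null(usage)) {
    stop("parameter unavailable: no 'codon_usage' provider table supplied")
  }
  if (is.null(cds) || !all(c("cdna_position", "alt_base") %in% names(muts))) {
    stop("parameter unavailable: rare_codon needs the coding sequence and ",
         "cDNA provenance columns (cdna_position, alt_base)")
  }
  s <- strsplit(as.character(cds@seq), "")[[1]]
  codonIdx <- (muts$cdna_position - 1L) %/% 3L
  within <- (muts$cdna_position - 1L) %% 3L + 1L
  mutCodon <- vapply(seq_len(nrow(muts)), function(i) {
    cod <- s[codonIdx[i] * 3L + 1:3]
    cod[within[i]] <- muts$alt_base[i]
    paste(cod, collapse = "")
  }, character(1))
  idx <- match(mutCodon, usage$codon)
  if (anyNA(idx)) {
    stop("parameter unavailable: codon usage missing for codon(s) ",
         paste(unique(mutCodon[is.na(idx)]), collapse = ", "))
  }
  as.integer(usage$per_thousand[idx] < cutoff)
}

#' Derive the active-site region from 3-D coordinates
#'
#' A residue belongs to the active-site region when any of its atoms lies
#' within `cutoff` angstroms of any atom of a center residue (the
#' catalytic, PLP-bound lysine -- K759 in mouse GLDC) or of a named bound
#' cofactor/ligand present in the coordinate file.
#'
#' @param structure a bio3d `pdb` object, a path to a PDB file, or a
#'   data.frame of atoms with columns `resno`, `resid`, `x`, `y`, `z`.
#' @param centers integer residue numbers of the center residue(s).
#' @param cutoff distance cutoff in angstroms (default 5).
#' @param ligands character residue names (e.g. `"PLP"`, `"GLY"` substrate)
#'   whose atoms also count as centers; ligand residues themselves are not
#'   reported as positions.
#' @return list with `positions` (sorted residue numbers, centers
#'   included), `cutoff` and `centers`.
#' @export
computeActiveSite <- function(structure, centers, cutoff = 5,
                              ligands = NULL) {
  atoms <- .atomTable(structure)
  assertScalarNumber(cutoff, "cutoff")
  if (cutoff < 0) stop("cutoff must be non-negative")
  centers <- as.integer(centers)
  if (!all(centers %in% atoms$resno)) {
    stop("center residue(s) absent from structure: ",
         paste(setdiff(centers, atoms$resno), collapse = ", "))
  }
  if (!is.null(ligands) && !all(ligands %in% atoms$resid)) {
    stop("ligand(s) absent from structure: ",
         paste(setdiff(ligands, atoms$resid), collapse = ", "))
  }
  isCenter <- atoms$resno %in% centers |
    (if (is.null(ligands)) FALSE else atoms$resid %in% ligands)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  cen <- xyz[isCenter, , drop = FALSE]
  # squared distance of every atom to its nearest center atom
  cross <- xyz %*% t(cen)
  d2 <- outer(rowSums(xyz^2), rep(1, nrow(cen))) - 2 * cross +
    outer(rep(1, nrow(xyz)), rowSums(cen^2))
  mind <- sqrt(pmax(apply(d2, 1L, min), 0))
  near <- mind <= cutoff + 1e-9
  isLigand <- if (is.null(ligands)) rep(FALSE, nrow(atoms)) else
    atoms$resid %in% ligands
  positions <- sort(unique(atoms$resno[near & !isLigand]))
  list(positions = as.integer(positions), cutoff = cutoff,
       centers = centers)
}

.atomTable <- function(structure) {
  if (is.character(structure) && length(structure) == 1L) {
    structure <- bio3d::read.pdb(structure)
  }
  if (inherits(structure, "pdb")) {
    a <- structure$atom
    structure <- data.frame(resno = a$resno, resid = a$resid,
                            x = a$x, y = a$y, z = a$z,
                            stringsAsFactors = FALSE)
  }
  if (!is.data.frame(structure) ||
      !all(c("resno", "x", "y", "z") %in% names(structure))) {
    stop("structure must be a PDB path, a bio3d pdb object, or an atom ",
         "table with resno/x/y/z columns")
  }
  if (!"resid" %in% names(structure)) structure$resid <- NA_character_
  structure
}

#' Phi coefficient between two binary vectors
#'
#' `phi = (n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)`, the Pearson
#' correlation of two 0/1 indicators. A constant vector leaves phi
#' undefined; `NA` is returned with a warning.
#'
#' @param a,b equal-length vectors of 0/1 values, length >= 2.
#' @return phi in `[-1, 1]`, or `NA` when either vector is constant.
#' @examples
#' phiCorrelation(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
phiCorrelation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 2L) stop("vectors must have length >= 2")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    stop("inputs must be binary 0/1 vectors")
  }
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  denom <- sqrt(as.numeric(n11 + n10) * (n01 + n00) *
                (n11 + n01) * (n10 + n00))
  if (denom == 0) {
    warning("phi undefined for a constant vector", call. = FALSE)
    return(NA_real_)
  }
  (n11 * n00 - n10 * n01) / denom
}

#' Phi correlation matrix of a binary parameter matrix
#'
#' @param X 0/1 matrix (mutations x parameters).
#' @return symmetric k x k matrix with unit diagonal over non-constant
#'   columns; `NA` where either column is constant.
#' @export
phiMatrix <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      v <- suppressWarnings(phiCorrelation(X[, i], X[, j]))
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}
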