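#' Load and validate a supplementary-style mutation table
#'
#' Reads a delimited text table (delimiter auto-detected between tab and
#' comma), checks that required columns are present (a missing column is
#' named in the error), parses declared numeric columns, and quarantines
#' rows with malformed mutation labels instead of failing: rejected rows
#' are returned in the `"rejected"` attribute and reported via a message.
#'
#' @param path delimited text file.
#' @param required character vector of required column names.
#' @param numeric character vector of columns parsed as numeric; rows
#'   whose values do not parse are quarantined.
#' @param labelCol name of the mutation-label column checked against the
#'   single-letter `"A394V"` dialect; `NULL` to skip label validation.
#' @return validated data.frame with attribute `rejected` (the quarantined
#'   rows, possibly empty).
#' @export
readSupplementaryTable <- function(path, required = "label",
                                   numeric = character(),
                                   labelCol = "label") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  bad <- rep(FALSE, nrow(tab))
  for (col in intersect(numeric, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- bad | (is.na(v) & !is.na(tab[[col]]) & tab[[col]] != "")
    tab[[col]] <- v
  }
  if (!is.null(labelCol) && labelCol %in% names(tab)) {
    okLabel <- grepl("^[A-Z][0-9]+[A-Z]$", tab[[labelCol]])
    bad <- bad | !okLabel
  }
  rejected <- tab[bad, , drop = FALSE]
  tab <- tab[!bad, , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(rejected)) {
    message(nrow(rejected), " malformed row(s) quarantined from ",
            basename(path))
  }
  message("loaded ", nrow(tab), " validated row(s) from ", basename(path))
  attr(tab, "rejected") <- rejected
  tab
}

#' Write a delimited table (tab-separated by default)
#'
#' @param x data.frame.
#' @param path output file.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
writeDelimTable <- function(x, path, sep = "\t") {
  write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value config collecting the thresholds and paths a full run
#' needs. Unspecified thresholds fall back to the validated defaults:
#' severe-candidate threshold 9.94, COS cutoff 5, WMMS band edges
#' -0.87 / 1.3 / 10, leader length 35, rounding 2 decimals.
#'
#' @param path YAML file; `NULL` returns pure defaults.
#' @return named list of settings.
#' @export
readRunConfig <- function(path = NULL) {
  defaults <- list(
    registry = system.file("extdata", "parameter_registry.yaml",
                           package = "wmms"),
    severe_threshold = 9.94,
    cos_cutoff = 5,
    wmms_lower = -0.87,
    wmms_threshold = 1.3,
    wmms_upper = 10,
    leader_length = 35,
    rounding = 2,
    seed = 1
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(defaults, cfg)
  numKeys <- c("severe_threshold", "cos_cutoff", "wmms_lower",
               "wmms_threshold", "wmms_upper", "leader_length",
               "rounding", "seed")
  for (k in numKeys) {
    if (!is.numeric(out[[k]]) || !is.finite(out[[k]])) {
      stop("config value '", k, "' must be a finite number")
    }
  }
  for (k in intersect(names(cfg), "registry")) {
    if (!file.exists(out[[k]])) stop("config path does not exist: ", out[[k]])
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences (DNA or protein,
#'   gapped or not).
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  lines <- unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), gsub("(.{60})", "\\1\n", seqs[[nm]]))
  }))
  writeLines(sub("\n$", "", lines), path)
  invisible(path)
}
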