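# Independent oracles, deliberately written in a different style from the
# implementation they check.

# Codon table built from the standard-code strings (TCAG base order),
# independent of Biostrings' GENETIC_CODE.
oracle_codon_table <- local({
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  bases <- c("T", "C", "A", "G")
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracle_translate <- function(dna) {
  n <- nchar(dna)
  stopifnot(n %% 3 == 0)
  aa <- character(n / 3)
  for (i in seq_along(aa)) {
    aa[i] <- oracle_codon_table[[substr(dna, 3 * i - 2, 3 * i)]]
  }
  paste(aa, collapse = "")
}

# random in-frame CDS with no internal stop, ATG start
random_cds_string <- function(n_codons, seed) {
  withr::with_seed(seed, {
    sense <- names(oracle_codon_table)[oracle_codon_table != "*"]
    paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)),
          collapse = "")
  })
}

# Brute force: mutate the string naively, translate whole, diff.
oracle_enumerate <- function(dna, leader = 0L) {
  ref_prot <- oracle_translate(dna)
  out <- character(0)
  census <- c(silent = 0L, nonsense = 0L, leader = 0L, missense = 0L)
  for (pos in seq_len(nchar(dna))) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(dna, pos, pos))) {
      mut <- dna
      substr(mut, pos, pos) <- alt
      mut_prot <- oracle_translate(mut)
      codon <- (pos - 1) %/% 3 + 1
      ref_aa <- substr(ref_prot, codon, codon)
      alt_aa <- substr(mut_prot, codon, codon)
      if (alt_aa == ref_aa) {
        census["silent"] <- census["silent"] + 1L
      } else if (alt_aa == "*") {
        census["nonsense"] <- census["nonsense"] + 1L
      } else if (codon <= leader) {
        census["leader"] <- census["leader"] + 1L
      } else {
        census["missense"] <- census["missense"] + 1L
        out <- c(out, paste0(ref_aa, codon, alt_aa))
      }
    }
  }
  list(labels = sort(unique(out)), census = census)
}

# Column-counting mapper: locate each source position's column by scanning,
# then count target residues up to it.
oracle_map_position <- function(src_gapped, tgt_gapped, p) {
  s <- strsplit(src_gapped, "")[[1]]
  t <- strsplit(tgt_gapped, "")[[1]]
  seen <- 0L
  for (col in seq_along(s)) {
    if (s[col] != "-") seen <- seen + 1L
    if (seen == p && s[col] != "-") {
      if (t[col] == "-") return(NA_integer_)
      return(sum(t[seq_len(col)] != "-"))
    }
  }
  stop("position beyond sequence")
}

random_gapped_alignment <- function(seed, n_cols = 40) {
  withr::with_seed(seed, {
    aas <- setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], NULL)
    repeat {
      s <- sample(c(aas, "-"), n_cols, replace = TRUE,
                  prob = c(rep(1, 20), 4))
      t <- sample(c(aas, "-"), n_cols, replace = TRUE,
                  prob = c(rep(1, 20), 4))
      keep <- !(s == "-" & t == "-")
      s <- s[keep]; t <- t[keep]
      if (sum(s != "-") > 2 && sum(t != "-") > 2) break
    }
    c(paste(s, collapse = ""), paste(t, collapse = ""))
  })
}

# closed-form normal equations
oracle_ols <- function(X, y) {
  Z <- cbind(1, X)
  as.numeric(solve(t(Z) %*% Z, t(Z) %*% y))
}

# textbook Welch t / Satterthwaite df
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df)
}

# chi-square upper tail at df = 2 has the closed form exp(-x/2)
oracle_chisq_p_df2 <- function(x) exp(-x / 2)

# all-pairs O(n^2) distance scan for the active-site oracle
oracle_active_site <- function(atoms, centers, cutoff) {
  hit <- integer(0)
  cen <- atoms[atoms$resno %in% centers, , drop = FALSE]
  for (i in seq_len(nrow(atoms))) {
    for (j in seq_len(nrow(cen))) {
      d <- sqrt((atoms$x[i] - cen$x[j])^2 + (atoms$y[i] - cen$y[j])^2 +
                (atoms$z[i] - cen$z[j])^2)
      if (d <= cutoff) hit <- c(hit, atoms$resno[i])
    }
  }
  sort(unique(hit))
}

# small random atom table grouped into residues
random_structure <- function(seed, n_res = 10, atoms_per_res = 3) {
  withr::with_seed(seed, {
    data.frame(
      resno = rep(seq_len(n_res), each = atoms_per_res),
      resid = rep("ALA", n_res * atoms_per_res),
      x = runif(n_res * atoms_per_res, 0, 15),
      y = runif(n_res * atoms_per_res, 0, 15),
      z = runif(n_res * atoms_per_res, 0, 15)
    )
  })
}
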