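test_that("ddG categorization follows the published bands", {
  expect_identical(as.character(categorizeDdg(-6)), "very_destabilizing")
  expect_identical(as.character(categorizeDdg(-2)), "destabilizing")
  expect_identical(as.character(categorizeDdg(0)), "unchanged")
  # band edges: destabilizing is strictly below -1.5; -5 itself is
  # destabilizing, not very destabilizing; mirrored on the plus side
  expect_identical(as.character(categorizeDdg(c(-5, -1.5, 1.5, 5, 5.01))),
                   c("destabilizing", "unchanged", "unchanged",
                     "stabilizing", "very_stabilizing"))
  expect_error(categorizeDdg(NA_real_), "finite")
  expect_error(categorizeDdg(Inf), "finite")
})

test_that("ddG categorization is a total monotone step function", {
  x <- sort(withr::with_seed(11, runif(400, -10, 10)))
  lv <- as.integer(categorizeDdg(x))
  expect_true(all(diff(lv) >= 0))
  expect_false(anyNA(lv))
})

test_that("the canonical registry has 18 parameters, one negatively signed", {
  reg <- defaultRegistry()
  expect_length(parameterNames(reg), 18L)
  signs <- parameterSigns(reg)
  expect_identical(sum(signs == -1), 1L)
  expect_identical(names(signs)[signs == -1], "conserved_substitution")
  expect_setequal(unique(reg@parameters$category),
                  c("stability", "position", "conservation", "property",
                    "evolution", "translation"))
})

make_providers <- function(labels, ddg, positions) {
  list(
    ddg = data.frame(label = labels, ddg = ddg),
    residue = data.frame(position = positions,
                         helix = positions %% 2 == 0,
                         sheet = positions %% 3 == 0,
                         dimer_interface = FALSE,
                         active_site = positions > 700,
                         consurf_grade = 1 + positions %% 9),
    codon_usage = NULL
  )
}

test_that("parameter evaluation is binary, provider-driven and strict", {
  reg <- defaultRegistry()
  # registry without the codon parameter: no cDNA provenance needed
  reg18 <- reg
  reg18@parameters <- reg@parameters[reg@parameters$name != "rare_codon", ]
  muts <- c("A100V", "G561R", "S562F", "L759P")
  prov <- make_providers(muts, c(-6, -2, 0.5, 2),
                         c(100, 561, 562, 759))
  X <- evaluateParameters(muts, reg18, prov)
  expect_true(all(X %in% c(0L, 1L)))
  expect_identical(colnames(X), parameterNames(reg18))
  # ddG -6 -> very destabilizing only
  expect_identical(unname(X["A100V", c("ddg_very_destabilizing",
                                       "ddg_destabilizing")]), c(1L, 0L))
  expect_identical(unname(X["G561R", "ddg_destabilizing"]), 1L)
  expect_identical(unname(X["S562F", "ddg_stabilizing"]), 0L)
  # X -> P substitution fires the proline-change parameter
  expect_identical(unname(X["L759P", "proline_change"]), 1L)
  expect_identical(unname(X["S562F", "proline_change"]), 0L)
  # G561R also fires glycine change and charge change
  expect_identical(unname(X["G561R", c("glycine_change", "charge_change")]),
                   c(1L, 1L))
  # provenance records the provider per parameter
  prov_attr <- attr(X, "provenance")
  expect_identical(unname(prov_attr["ddg_very_destabilizing"]), "ddg")
  expect_identical(unname(prov_attr["proline_change"]), "builtin:aaProperties")
})

test_that("missing provider data is an error, never a silent zero", {
  reg <- defaultRegistry()
  reg@parameters <- reg@parameters[reg@parameters$name != "rare_codon", ]
  prov <- make_providers("A100V", -6, 100)
  expect_error(evaluateParameters(c("A100V", "Q200K"), reg, prov),
               "parameter unavailable.*Q200K")
  expect_error(evaluateParameters("A100V", reg, list(ddg = prov$ddg)),
               "parameter unavailable")
})

test_that("the codon-availability parameter reads the mutant codon", {
  reg <- defaultRegistry()
  reg@parameters <- reg@parameters[reg@parameters$condition %in%
                                     c("property", "conserved_substitution",
                                       "rare_codon"), ]
  cds <- CodingSequence("ATGAAA")
  tab <- mutations(enumerateMissense(cds))
  tab <- tab[tab$label %in% c("K2Q", "K2E"), ]
  usage <- data.frame(codon = names(Biostrings::GENETIC_CODE),
                      per_thousand = 20)
  usage$per_thousand[usage$codon == "CAA"] <- 2   # rare Gln codon
  X <- evaluateParameters(tab, reg, list(codon_usage = usage), cds = cds)
  expect_identical(unname(X[tab$label == "K2Q", "rare_codon"]), 1L)
  expect_identical(unname(X[tab$label == "K2E", "rare_codon"]), 0L)
  expect_error(evaluateParameters(tab["label"], reg,
                                  list(codon_usage = usage)),
               "parameter unavailable")
})

test_that("active-site derivation matches the brute-force distance scan", {
  for (seed in 1:5) {
    atoms <- random_structure(seed)
    centers <- sample(unique(atoms$resno), 1)
    got <- computeActiveSite(atoms, centers, cutoff = 6)
    expect_identical(got$positions, oracle_active_site(atoms, centers, 6))
    expect_true(centers %in% got$positions)
  }
})

test_that("active-site edge cases behave", {
  atoms <- data.frame(resno = c(1, 1, 2, 3), resid = "ALA",
                      x = c(0, 1, 1, 50), y = 0, z = 0)
  # residue 2 shares an atom position with residue 1's second atom
  as1 <- computeActiveSite(atoms, centers = 1, cutoff = 0)
  expect_identical(as1$positions, c(1L, 2L))
  expect_identical(computeActiveSite(atoms, 1, cutoff = 5)$positions,
                   c(1L, 2L))
  expect_error(computeActiveSite(atoms, centers = 9), "absent")
  # ligand atoms extend the center set but are not reported
  atoms2 <- rbind(atoms,
                  data.frame(resno = 99, resid = "PLP", x = 49, y = 0, z = 0))
  got <- computeActiveSite(atoms2, centers = 1, cutoff = 2, ligands = "PLP")
  expect_true(3L %in% got$positions)
  expect_false(99L %in% got$positions)
})

test_that("phi equals the Pearson correlation of 0/1 vectors", {
  a <- c(1, 1, 1, 0, 0, 0)
  b <- c(1, 1, 0, 1, 0, 0)   # counts (2, 1, 1, 2)
  expect_equal(phiCorrelation(a, b), cor(a, b), tolerance = 1e-12)
  expect_identical(phiCorrelation(a, a), 1)
  expect_identical(phiCorrelation(a, 1 - a), -1)
  expect_warning(v <- phiCorrelation(rep(1, 4), c(0, 1, 0, 1)), "constant")
  expect_true(is.na(v))
  expect_error(phiCorrelation(c(0, 1), c(0, 1, 1)), "equal length")
  for (seed in 1:10) {
    x <- withr::with_seed(seed, matrix(rbinom(40, 1, 0.5), ncol = 2))
    v <- suppressWarnings(phiCorrelation(x[, 1], x[, 2]))
    if (!is.na(v)) {
      expect_gte(v, -1); expect_lte(v, 1)
      expect_equal(v, cor(x[, 1], x[, 2]), tolerance = 1e-12)
    }
  }
})

test_that("the phi matrix is symmetric with unit diagonal", {
  X <- withr::with_seed(5, matrix(rbinom(200, 1, 0.4), ncol = 5,
                                  dimnames = list(NULL, letters[1:5])))
  M <- suppressWarnings(phiMatrix(X))
  expect_identical(M, t(M))
  nonconst <- apply(X, 2, function(v) length(unique(v)) > 1)
  expect_true(all(diag(M)[nonconst] == 1))
  expect_true(all(abs(M[!is.na(M)]) <= 1))
})
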