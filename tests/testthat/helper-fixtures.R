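# Shared fixtures: a random-formula generator for parser/mass property tests
# and a tiny registry written on the fly for validation tests.

random_formula_string <- function() {
  elements <- c("C", "H", "N", "O", "S", "P", "Cl", "Na")
  isotopes <- c("13C", "15N", "2H")
  n_tok <- sample(2:6, 1)
  toks <- character(n_tok)
  for (i in seq_len(n_tok)) {
    if (stats::runif(1) < 0.25) {
      toks[i] <- sprintf("[%s]%d ", sample(isotopes, 1), sample(1:12, 1))
    } else {
      toks[i] <- sprintf("%s%d", sample(elements, 1), sample(1:12, 1))
    }
  }
  paste(toks, collapse = "")
}

# A labeled/unlabeled isotopologue pair with known substitution counts.
random_isotopologue_pair <- function() {
  nC <- sample(2:12, 1); nH <- sample(2:14, 1); nN <- sample(1:4, 1)
  nO <- sample(1:4, 1)
  k13C <- sample(0:nC, 1); k15N <- sample(0:nN, 1); kD <- sample(0:nH, 1)
  tok <- function(sym, n) if (n > 0) sprintf("%s%d", sym, n) else ""
  btok <- function(iso, n) if (n > 0) sprintf("[%s]%d ", iso, n) else ""
  unlabeled <- paste0(tok("C", nC), tok("H", nH), tok("N", nN), tok("O", nO))
  labeled <- paste0(btok("13C", k13C), tok("C", nC - k13C),
                    btok("2H", kD), tok("H", nH - kD),
                    btok("15N", k15N), tok("N", nN - k15N), tok("O", nO))
  list(unlabeled = unlabeled, labeled = labeled,
       n13C = k13C, n15N = k15N, nD = kD)
}

write_registry_fixture <- function(rows) {
  header <- paste(c("name", "category", "formula", "molar_mass_g_per_mol",
                    "final_amount", "final_amount_unit", "stock_multiplier",
                    "solvent", "storage", "light_sensitive", "notes"),
                  collapse = ",")
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(header, rows), path)
  path
}
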