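# Isotope-aware molecular formulas: parsing, rendering, monoisotopic mass and
# protonated m/z for identifying labeled tracers (e.g. Trp-13C11,15N2) by
# accurate mass.

# Monoisotopic masses in Da, IUPAC/AME atomic mass evaluation values.
.isotope_masses <- c(
  "1H"   = 1.0078250319,
  "2H"   = 2.0141017780,
  "12C"  = 12.0,
  "13C"  = 13.0033548378,
  "14N"  = 14.0030740052,
  "15N"  = 15.0001088984,
  "16O"  = 15.9949146221,
  "18O"  = 17.9991604,
  "19F"  = 18.9984032,
  "23Na" = 22.9897692809,
  "24Mg" = 23.9850417,
  "28Si" = 27.9769265,
  "31P"  = 30.97376151,
  "32S"  = 31.97207069,
  "35Cl" = 34.96885271,
  "39K"  = 38.9637069,
  "40Ca" = 39.9625912,
  "56Fe" = 55.9349421,
  "79Br" = 78.9183376,
  "127I" = 126.904468
)

# Most abundant isotope for each supported unqualified element.
.principal_isotope <- c(
  H = "1H", C = "12C", N = "14N", O = "16O", F = "19F", Na = "23Na",
  Mg = "24Mg", Si = "28Si", P = "31P", S = "32S", Cl = "35Cl", K = "39K",
  Ca = "40Ca", Fe = "56Fe", Br = "79Br", I = "127I"
)

# Mass of the proton (hydrogen-atom mass minus the electron mass): the [M+H]+
# convention under which computed m/z matches accurate-mass instrument output.
.proton_mass <- 1.0072765

# All recognized element symbols (full periodic table), so that an unknown
# symbol ("Xq") is reported as such rather than as a missing isotope mass.
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U"
)

#' Isotope mass table
#'
#' Monoisotopic masses (Da) of the isotopes supported by the exact-mass
#' functions, named by isotope token (e.g. `"13C"`), plus the proton mass used
#' for \\[M+H\\]+ computation.
#'
#' @return A list with elements `entries` (named numeric vector of isotope
#'   masses in Da) and `proton_mass` (Da).
#' @examples
#' isotope_masses()$entries["13C"] - isotope_masses()$entries["12C"]
#' @export
isotope_masses <- function() {
  list(entries = .isotope_masses, proton_mass = .proton_mass)
}

parse_error <- function(message, token, position) {
  stop_mediaforge("mediaforge_parse_error",
                  sprintf("%s: token '%s' at position %d", message, token, position),
                  token = token, position = position)
}

# A known isotope token ("15N") - used to disambiguate digits after "]".
.is_isotope_token <- function(tok) tok %in% names(.isotope_masses)

#' Parse a molecular formula with heavy-isotope annotations
#'
#' Accepts plain formulas (`"C11H12N2O2"`), isotope prefixes at a token
#' boundary (`"13C11H12 15N2O2"`), bracketed isotopes valid anywhere
#' (`"[13C]11"`), and `D` as an alias for `2H`. Sub/superscript markup
#' characters (`_`, `^`) as they appear in typeset formulas are treated as
#' token boundaries, so `"^13^C_11_H_12_^15^N_2_O_2_"` parses identically to
#' the plain form. A digit run is read as an isotope prefix only at the string
#' start, after whitespace/markup, or after a closing bracket when the
#' digits+element name a known isotope; otherwise digits are a count.
#'
#' @param text a single non-empty formula string.
#' @return A `molecular_formula`: a named integer vector of per-token counts
#'   (unqualified elements kept distinct from isotope-qualified ones), in
#'   canonical Hill order.
#' @examples
#' parse_formula("C11H12N2O2")
#' parse_formula("13C11H12 15N2O2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop_mediaforge("mediaforge_parse_error", "formula must be a non-empty string")
  }
  # Markup stripping: '_' (subscript) vanishes so counts stay attached to
  # their element; '^' (superscript) becomes whitespace, a token boundary.
  s <- gsub("_", "", gsub("\\^", " ", text))
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  comp <- integer(0)
  i <- 1L
  boundary <- TRUE      # at start / after whitespace: bare isotope prefix valid
  after_bracket <- FALSE
  add <- function(tok, count) {
    comp[tok] <<- if (tok %in% names(comp)) comp[tok] + count else count
  }
  read_digits <- function(i) {
    j <- i
    while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
    list(value = if (j > i) paste(chars[i:(j - 1L)], collapse = "") else NULL,
         next_i = j)
  }
  read_symbol <- function(i) {
    if (i > n || !grepl("[A-Z]", chars[i])) return(NULL)
    sym <- chars[i]
    j <- i + 1L
    if (j <= n && grepl("[a-z]", chars[j])) {
      sym <- paste0(sym, chars[j])
      j <- j + 1L
    }
    list(symbol = sym, next_i = j)
  }
  while (i <= n) {
    ch <- chars[i]
    if (grepl("\\s", ch)) {
      boundary <- TRUE
      after_bracket <- FALSE
      i <- i + 1L
      next
    }
    pos0 <- i - 1L  # 0-based position for error messages
    if (ch == "[") {
      d <- read_digits(i + 1L)
      sy <- read_symbol(d$next_i)
      close_ok <- !is.null(sy) && sy$next_i <= n && chars[sy$next_i] == "]"
      if (is.null(d$value) || is.null(sy) || !close_ok) {
        parse_error("malformed bracketed isotope", substr(s, i, min(n, i + 5L)), pos0)
      }
      if (!(sy$symbol %in% .element_symbols)) {
        parse_error("unknown element symbol", sy$symbol, d$next_i - 1L)
      }
      tok <- paste0(d$value, sy$symbol)
      i <- sy$next_i + 1L
      cnt <- 1L
      d2 <- read_digits(i)
      if (!is.null(d2$value)) {
        # Digits after "]" are a count unless digits+element form a known
        # isotope token (then they are the next token's prefix).
        sy2 <- read_symbol(d2$next_i)
        if (!is.null(sy2) && .is_isotope_token(paste0(d2$value, sy2$symbol))) {
          # leave digits in place as the next token's isotope prefix
          after_bracket <- TRUE
        } else {
          cnt <- as.integer(d2$value)
          if (cnt == 0L) parse_error("zero count", tok, i - 1L)
          i <- d2$next_i
          after_bracket <- FALSE
        }
      }
      add(tok, cnt)
      boundary <- after_bracket
      next
    }
    iso_prefix <- NULL
    if (boundary && grepl("[0-9]", ch)) {
      d <- read_digits(i)
      j <- d$next_i
      while (j <= n && grepl("\\s", chars[j])) j <- j + 1L  # "^13^C" -> "13 C"
      sy <- read_symbol(j)
      if (is.null(sy)) {
        parse_error("isotope prefix with no following element", d$value, pos0)
      }
      iso_prefix <- d$value
      i <- j
    }
    sy <- read_symbol(i)
    if (is.null(sy)) {
      parse_error("expected element symbol", ch, i - 1L)
    }
    sym <- sy$symbol
    if (!(sym %in% .element_symbols) && sym != "D") {
      # try the one-letter reading before giving up (e.g. "Cx" in "CxH"? no:
      # lowercase follower means a two-letter symbol was intended)
      parse_error("unknown element symbol", sym, i - 1L)
    }
    i <- sy$next_i
    if (sym == "D") {
      if (!is.null(iso_prefix)) parse_error("isotope prefix on alias D", sym, pos0)
      tok <- "2H"
    } else if (!is.null(iso_prefix)) {
      tok <- paste0(iso_prefix, sym)
    } else {
      tok <- sym
    }
    d <- read_digits(i)
    cnt <- 1L
    if (!is.null(d$value)) {
      cnt <- as.integer(d$value)
      if (cnt == 0L) parse_error("zero count", tok, i - 1L)
      i <- d$next_i
    }
    add(tok, cnt)
    boundary <- FALSE
    after_bracket <- FALSE
  }
  if (length(comp) == 0L) {
    stop_mediaforge("mediaforge_parse_error", "formula contains no atoms")
  }
  new_molecular_formula(comp)
}

# token -> element symbol ("13C" -> "C", "H" -> "H")
.token_element <- function(tok) sub("^[0-9]*", "", tok)
.token_massnum <- function(tok) {
  m <- sub("([0-9]*).*", "\\1", tok)
  ifelse(nzchar(m), suppressWarnings(as.integer(m)), NA_integer_)
}

new_molecular_formula <- function(comp) {
  stopifnot(all(comp >= 1))
  elems <- .token_element(names(comp))
  massn <- .token_massnum(names(comp))
  # Hill order: C, H, then alphabetical; within an element the unqualified
  # token first, then isotopes by ascending mass number.
  elem_rank <- match(elems, c("C", "H"))
  elem_rank[is.na(elem_rank)] <- 3L
  ord <- order(elem_rank, elems, !is.na(massn), massn)
  structure(as.integer(comp[ord]), names = names(comp)[ord],
            class = "molecular_formula")
}

#' Render a molecular formula canonically
#'
#' Hill order (C, H, then alphabetical), isotope-qualified tokens written in
#' bracket notation adjacent to their element (`"C10[13C]H12N2O2"` style), so
#' that `parse_formula(render_formula(f))` reproduces `f` exactly.
#'
#' @param f a `molecular_formula` or formula string.
#' @return A single string.
#' @export
render_formula <- function(f) {
  f <- as_formula(f)
  toks <- names(f)
  massn <- .token_massnum(toks)
  shown <- paste0(ifelse(is.na(massn), toks, paste0("[", toks, "]")),
                  ifelse(f > 1L, f, ""))
  # Disambiguate: after a bracketed token's count, a following unqualified
  # element must not re-read those digits as its isotope prefix
  # ("[13C]15N9" is 13C x 15 then N, so render it "[13C]15 N9").
  n <- length(shown)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      ambiguous <- !is.na(massn[i]) && f[i] > 1L && is.na(massn[i + 1L]) &&
        .is_isotope_token(paste0(f[i], toks[i + 1L]))
      if (ambiguous) shown[i] <- paste0(shown[i], " ")
    }
  }
  paste0(shown, collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ", render_formula(x), "\n", sep = "")
  invisible(x)
}

#' Coerce to a molecular formula
#'
#' @param f a `molecular_formula` or a formula string to parse.
#' @return A `molecular_formula`.
#' @export
as_formula <- function(f) {
  if (inherits(f, "molecular_formula")) return(f)
  if (is.character(f) && length(f) == 1L) return(parse_formula(f))
  stop_mediaforge("mediaforge_parse_error",
                  "expected a molecular_formula or formula string")
}

.resolve_token <- function(tok) {
  if (tok %in% names(.isotope_masses)) return(tok)
  if (tok %in% names(.principal_isotope)) return(.principal_isotope[[tok]])
  stop_mediaforge("mediaforge_unsupported_isotope",
                  sprintf("no monoisotopic mass for token '%s'", tok))
}

#' Monoisotopic mass of a formula
#'
#' Sum of per-token counts times isotope masses; unqualified elements resolve
#' to their most abundant isotope.
#'
#' @param f a `molecular_formula` or formula string.
#' @return Mass in Da (full double precision; display at >= 5 decimals).
#' @examples
#' monoisotopic_mass("C11H12N2O2")  # tryptophan, 204.08988 Da
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  masses <- vapply(names(f), function(tok) .isotope_masses[[.resolve_token(tok)]],
                   numeric(1))
  sum(masses * as.numeric(f))
}

#' m/z of the singly protonated ion
#'
#' `monoisotopic_mass(f)` plus the proton mass (1.0072765 Da; the proton, not
#' the hydrogen atom, since \\[M+H\\]+ carries no extra electron).
#'
#' @inheritParams monoisotopic_mass
#' @return m/z in Th (display rounding: 5 decimals, round-half-even).
#' @examples
#' mz_protonated("C6H6N2O")  # nicotinamide, 123.05529
#' @export
mz_protonated <- function(f) {
  monoisotopic_mass(f) + .proton_mass
}

#' Mass shift between a compound and its isotopologue
#'
#' @param unlabeled,labeled `molecular_formula`s (or strings) that are
#'   isotopologues: identical per-element atom totals once isotope qualifiers
#'   are collapsed.
#' @return Mass difference labeled - unlabeled, in Da.
#' @examples
#' label_mass_shift("C11H12N2O2", "13C11H12 15N2O2")  # 13.03098 Da
#' @export
label_mass_shift <- function(unlabeled, labeled) {
  u <- as_formula(unlabeled)
  l <- as_formula(labeled)
  collapse <- function(f) {
    el <- .token_element(names(f))
    tapply(as.integer(f), el, sum)
  }
  cu <- collapse(u)
  cl <- collapse(l)
  same <- length(cu) == length(cl) &&
    setequal(names(cu), names(cl)) &&
    all(cu[names(cl)] == cl)
  if (!same) {
    stop_mediaforge("mediaforge_not_isotopologue",
                    "formulas differ in per-element atom totals; not isotopologues")
  }
  monoisotopic_mass(l) - monoisotopic_mass(u)
}
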