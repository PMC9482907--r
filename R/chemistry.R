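# Exact-mass chemistry of the NAPS homologous series.
#
# NAPS (N-alkylpyridinium-3-sulfonates) are zwitterionic reference standards
# carrying a quaternary pyridinium nitrogen and a sulfonate group. The neutral
# reference mass M used throughout is the zwitterion (net charge 0), so
# "[M+H]+" denotes protonation of the zwitterion. Homologue n (alkyl chain of
# n carbons, n = 1..20) has composition C(5+n)H(5+2n)NO3S and is assigned
# retention index RI = 100 * n.

# Monoisotopic masses of the most abundant isotopes (CODATA/AME, >= 6 decimals)
.monoisotopic <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.00307400443,
  O  = 15.99491461957,
  S  = 31.9720711744,
  Na = 22.9897692820,
  P  = 30.97376199842,
  Cl = 34.968852682,
  F  = 18.99840316273
)

.electron_mass <- 0.000548579909

#' Proton mass (Da)
#'
#' Monoisotopic mass of the proton (hydrogen atom minus one electron),
#' used for protonation/deprotonation adduct arithmetic.
#' @keywords internal
.proton_mass <- .monoisotopic[["H"]] - .electron_mass

#' Elemental composition of a NAPS homologue
#'
#' Returns the elemental composition of the neutral (zwitterionic)
#' N-alkylpyridinium-3-sulfonate with an alkyl chain of `n_carbons` carbons:
#' C(5+n)H(5+2n)NO3S. The homologous series used for retention indexing spans
#' n = 1 (N-methyl) to n = 20 (N-eicosyl); values outside that range are
#' chemically valid homologues but are not part of the standard mixture, so a
#' warning is emitted.
#'
#' @param n_carbons Integer (vectorised), number of carbons in the N-alkyl
#'   chain; must be >= 1.
#' @return For a single `n_carbons`, a named integer vector of element counts
#'   (an `elemental_composition`); for several, a list of such vectors.
#' @examples
#' naps_formula(1)   # C6H7NO3S, the N-methyl homologue
#' naps_formula(20)  # C25H45NO3S
#' @export
naps_formula <- function(n_carbons) {
  if (length(n_carbons) == 0L) stop("`n_carbons` must have length >= 1")
  if (any(is.na(n_carbons)) || any(n_carbons != as.integer(n_carbons)))
    stop("`n_carbons` must be whole numbers")
  if (any(n_carbons < 1))
    stop("`n_carbons` must be >= 1 (no alkyl chain, no homologue)")
  if (any(n_carbons > 20))
    warning("homologues beyond C20 are outside the standard NAPS mixture")
  one <- function(n) {
    comp <- c(C = 5L + n, H = 5L + 2L * n, N = 1L, O = 3L, S = 1L)
    class(comp) <- "elemental_composition"
    comp
  }
  if (length(n_carbons) == 1L) one(as.integer(n_carbons))
  else lapply(as.integer(n_carbons), one)
}

#' Parse a molecular formula string
#'
#' Parses formulas such as `"C7H6O3"` or `"C5H6NO3S"` into a named element
#' count vector. Only single-letter or capital+lowercase element symbols with
#' optional integer counts are supported (no parentheses, no isotope labels).
#'
#' @param formula Character scalar molecular formula.
#' @return Named integer vector of element counts (`elemental_composition`).
#' @examples
#' parse_formula("C7H6O3")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]+$", toks),
                          sub("^[A-Za-z]+", "", toks), "1"))
  comp <- tapply(ct, el, sum)
  comp <- stats::setNames(as.integer(comp), names(comp))
  class(comp) <- "elemental_composition"
  comp
}

#' Monoisotopic mass of an elemental composition
#'
#' Sums most-abundant-isotope atomic masses and applies the electron-mass
#' correction for charged species: a cation of charge +z is lighter than the
#' neutral by z electrons, an anion heavier. For charge != 0 the returned
#' value is the mass of the ion (equal to m/z for singly charged species).
#'
#' @param composition Named numeric vector of element counts, an
#'   `elemental_composition`, or a formula string.
#' @param charge Signed integer charge of the species (default 0, the
#'   neutral molecule).
#' @return Mass in Da (monoisotopic).
#' @examples
#' monoisotopic_mass("C5H6NO3S", charge = 1)  # 160.0063, the NAPS fragment
#' monoisotopic_mass(c(H = 2, O = 1))         # water, 18.0106
#' @export
monoisotopic_mass <- function(composition, charge = 0L) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named vector of element counts")
  if (any(composition < 0)) stop("element counts must be non-negative")
  if (all(composition == 0)) stop("composition must contain at least one atom")
  unknown <- setdiff(names(composition), names(.monoisotopic))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  stopifnot(length(charge) == 1L, charge == as.integer(charge))
  sum(.monoisotopic[names(composition)] * as.numeric(composition)) -
    charge * .electron_mass
}

# Adduct catalogue. mass_delta is the full charge-carrier composition change,
# electron-mass corrected; m/z = (multimer * M + mass_delta) / |charge|.
.adduct_table <- local({
  proton <- .proton_mass
  sodium_cat <- .monoisotopic[["Na"]] - .electron_mass
  formate <- 12 + .monoisotopic[["H"]] + 2 * .monoisotopic[["O"]] +
    .electron_mass
  tab <- rbind(
    data.frame(name = c("[M+H]+", "[2M+H]+", "[3M+H]+"),
               multimer = 1:3, charge = 1L, mass_delta = proton,
               polarity = "pos", stringsAsFactors = FALSE),
    data.frame(name = c("[M+Na]+", "[2M+Na]+", "[3M+Na]+"),
               multimer = 1:3, charge = 1L, mass_delta = sodium_cat,
               polarity = "pos", stringsAsFactors = FALSE),
    data.frame(name = c("[M-H]-", "[2M-H]-", "[3M-H]-"),
               multimer = 1:3, charge = -1L, mass_delta = -proton,
               polarity = "neg", stringsAsFactors = FALSE),
    data.frame(name = c("[M+HCOO]-", "[2M+HCOO]-", "[3M+HCOO]-"),
               multimer = 1:3, charge = -1L, mass_delta = formate,
               polarity = "neg", stringsAsFactors = FALSE)
  )
  rownames(tab) <- tab$name
  tab
})

#' Supported adduct definitions
#'
#' The ESI adduct catalogue observed for NAPS: protonated ions and their
#' multimers, sodium adducts and sodiated multimers in positive mode;
#' deprotonated and formate adduct ions and their multimers in negative mode.
#'
#' @param polarity `"pos"`, `"neg"` or `"both"` (default).
#' @return data.frame with columns `name`, `multimer`, `charge`,
#'   `mass_delta` (Da), `polarity`.
#' @export
adduct_catalogue <- function(polarity = c("both", "pos", "neg")) {
  polarity <- match.arg(polarity)
  tab <- .adduct_table
  if (polarity != "both") tab <- tab[tab$polarity == polarity, ]
  rownames(tab) <- NULL
  tab
}

.lookup_adduct <- function(name) {
  hit <- .adduct_table[.adduct_table$name == name, ]
  if (nrow(hit) == 0L)
    stop("unsupported adduct '", name, "'; supported: ",
         paste(.adduct_table$name, collapse = ", "))
  hit
}

#' m/z of an adduct of a neutral molecule
#'
#' Computes (multimer * M + mass_delta) / |charge| for an adduct from the
#' supported catalogue (see [adduct_catalogue()]).
#'
#' @param neutral_mass Neutral monoisotopic mass M in Da (vectorised).
#' @param adduct Adduct name, e.g. `"[M+H]+"`, `"[2M+Na]+"`, `"[M+HCOO]-"`.
#' @return m/z in Da.
#' @examples
#' adduct_mz(monoisotopic_mass(naps_formula(1)), "[M+H]+")  # 174.0219
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  a <- .lookup_adduct(adduct)
  mz <- (a$multimer * neutral_mass + a$mass_delta) / abs(a$charge)
  if (any(mz <= 0)) stop("non-positive m/z; check neutral mass and adduct")
  mz
}

#' NAPS m/z reference table
#'
#' Builds the (homologue, adduct) m/z table for the NAPS series: one row per
#' combination, with the retention index RI = 100 * n. Homologues C1-C3
#' (RI 100-300) elute in or close to the void volume under typical
#' reversed-phase conditions and are flagged `low_retention`.
#'
#' @param n_range Integer vector of length 2, first and last homologue
#'   (default `c(1, 20)`, the full standard mixture).
#' @param adducts Character vector of adduct names; default is the full
#'   catalogue for `polarity`.
#' @param polarity `"pos"`, `"neg"` or `"both"`; used to select default
#'   adducts and reported per row.
#' @return data.frame with columns `n_carbons`, `ri`, `adduct`, `polarity`,
#'   `mz`, `low_retention`, sorted by `n_carbons` then adduct.
#' @examples
#' head(naps_mz_table(c(1, 5), adducts = "[M+H]+"))
#' @export
naps_mz_table <- function(n_range = c(1L, 20L), adducts = NULL,
                          polarity = c("both", "pos", "neg")) {
  polarity <- match.arg(polarity)
  stopifnot(length(n_range) == 2L, n_range[1] <= n_range[2])
  if (is.null(adducts)) adducts <- adduct_catalogue(polarity)$name
  if (length(adducts) == 0L) stop("`adducts` must not be empty")
  spec <- do.call(rbind, lapply(adducts, .lookup_adduct))
  n <- seq.int(n_range[1], n_range[2])
  masses <- vapply(n, function(i) monoisotopic_mass(naps_formula(i)),
                   numeric(1))
  out <- do.call(rbind, lapply(seq_along(n), function(i) {
    data.frame(
      n_carbons = n[i],
      ri = 100L * n[i],
      adduct = spec$name,
      polarity = spec$polarity,
      mz = (spec$multimer * masses[i] + spec$mass_delta) / abs(spec$charge),
      low_retention = n[i] <= 3L,
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$n_carbons, out$adduct), ]
  rownames(out) <- NULL
  out
}

#' Diagnostic fragment masses of NAPS
#'
#' NAPS yield a common positive-mode fragment, the methylenepyridinium
#' sulfonate cation [C5H6NO3S]+ at m/z 160.0063, and the sulfur trioxide
#' radical anion [SO3]- in negative mode. Masses are theoretical
#' (electron-mass corrected); the negative fragment is commonly reported at
#' 79.9579 on ToF instruments, ~0.5 mDa above the theoretical value, likely
#' a calibration/rounding artefact of the reporting instrument.
#'
#' @return data.frame with columns `fragment`, `polarity`, `mz`.
#' @export
naps_fragments <- function() {
  data.frame(
    fragment = c("[C5H6NO3S]+", "[SO3]-"),
    polarity = c("pos", "neg"),
    mz = c(monoisotopic_mass("C5H6NO3S", charge = 1L),
           monoisotopic_mass(c(S = 1, O = 3), charge = -1L)),
    stringsAsFactors = FALSE
  )
}
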