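# Composition-level glycan mass arithmetic and the diagnostic-ion registry.
#
# All masses are monoisotopic, in amu. Residue masses are dehydrated
# (glycosidic-bond) masses; an intact glycan adds one water. Released
# N-glycans handled here are chemically reduced at the innermost GlcNAc
# (alditol, +2 H). Ions are protonated (+1.007276 per charge).

## IUPAC/CODATA monoisotopic atom masses
.ATOM <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
           S = 31.97207069)

#: proton mass (charge carrier), amu
PROTON_MASS <- 1.00727646688
#: water, amu (added once per intact glycan)
WATER_MASS <- 2 * .ATOM[["H"]] + .ATOM[["O"]]
#: two hydrogens added by borohydride reduction of the reducing end
REDUCTION_MASS <- 2 * .ATOM[["H"]]

## dehydrated residue masses, amu
.RESIDUES <- c(
  hex    = 6 * .ATOM[["C"]] + 10 * .ATOM[["H"]] + 5 * .ATOM[["O"]],  # C6H10O5
  hexnac = 8 * .ATOM[["C"]] + 13 * .ATOM[["H"]] + .ATOM[["N"]] + 5 * .ATOM[["O"]],
  dhex   = 6 * .ATOM[["C"]] + 10 * .ATOM[["H"]] + 4 * .ATOM[["O"]],  # fucose
  neu5ac = 11 * .ATOM[["C"]] + 17 * .ATOM[["H"]] + .ATOM[["N"]] + 8 * .ATOM[["O"]],
  neu5gc = 11 * .ATOM[["C"]] + 17 * .ATOM[["H"]] + .ATOM[["N"]] + 9 * .ATOM[["O"]],
  hexa   = 6 * .ATOM[["C"]] + 8 * .ATOM[["H"]] + 6 * .ATOM[["O"]],   # hexuronic acid
  sulfate = .ATOM[["S"]] + 3 * .ATOM[["O"]],                          # SO3
  acetyl  = 2 * .ATOM[["C"]] + 2 * .ATOM[["H"]] + .ATOM[["O"]]        # C2H2O
)

.RESIDUE_ORDER <- names(.RESIDUES)

## canonical rendering tokens, in rendering order
.RENDER_TOKENS <- c(hex = "Hex", hexnac = "HexNAc", dhex = "Fuc",
                    neu5ac = "Neu5Ac", neu5gc = "Neu5Gc", hexa = "HexA",
                    sulfate = "SO4", acetyl = "Ac")

## accepted input tokens -> residue slot (longest-first for the tokenizer)
.PARSE_TOKENS <- c(HexNAc = "hexnac", HexA = "hexa", Hex = "hex",
                   dHex = "dhex", Fuc = "dhex",
                   Neu5Ac = "neu5ac", Neu5Gc = "neu5gc",
                   SO4 = "sulfate", Sulf = "sulfate", Ac = "acetyl")

#' Monoisotopic residue mass
#'
#' Dehydrated (residue) monoisotopic mass of a monosaccharide or glycan
#' modification, i.e. the mass the unit contributes inside a glycan chain.
#'
#' @param residue token: one of `"Hex"`, `"HexNAc"`, `"Fuc"`/`"dHex"`,
#'   `"Neu5Ac"`, `"Neu5Gc"`, `"HexA"`, `"SO4"`/`"Sulf"`, `"Ac"` (case
#'   sensitive), or a lower-case internal slot name.
#' @return mass in amu.
#' @examples
#' residue_mass("Hex")     # 162.05282
#' residue_mass("HexNAc")  # 203.07937
#' @export
residue_mass <- function(residue) {
  stopifnot(is.character(residue), length(residue) == 1L)
  slot <- if (residue %in% names(.PARSE_TOKENS)) .PARSE_TOKENS[[residue]]
          else if (residue %in% .RESIDUE_ORDER) residue
          else stop("unknown residue token: '", residue, "'", call. = FALSE)
  unname(.RESIDUES[[slot]])
}

#' Construct a glycan composition
#'
#' A composition is a count vector over the eight residue classes handled by
#' the package. It identifies a glycan at composition level only (no
#' topology or linkage).
#'
#' @param hex,hexnac,dhex,neu5ac,neu5gc,hexa,sulfate,acetyl non-negative
#'   integer counts. `dhex` counts fucoses; `acetyl` counts O-acetyl groups
#'   on sialic acids (so `acetyl <= neu5ac + neu5gc` is enforced).
#' @return an object of class `glycan_composition` (named integer vector).
#' @examples
#' composition(hex = 5, hexnac = 4, dhex = 1, neu5ac = 2)
#' @export
composition <- function(hex = 0L, hexnac = 0L, dhex = 0L, neu5ac = 0L,
                        neu5gc = 0L, hexa = 0L, sulfate = 0L, acetyl = 0L) {
  x <- c(hex = hex, hexnac = hexnac, dhex = dhex, neu5ac = neu5ac,
         neu5gc = neu5gc, hexa = hexa, sulfate = sulfate, acetyl = acetyl)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("composition counts must be non-negative integers", call. = FALSE)
  x <- as.integer(round(x))
  names(x) <- .RESIDUE_ORDER
  if (x[["acetyl"]] > x[["neu5ac"]] + x[["neu5gc"]])
    stop("acetyl count exceeds available sialic acids", call. = FALSE)
  structure(x, class = "glycan_composition")
}

#' Parse a composition string
#'
#' Reads the compact `Hex5HexNAc4Fuc1Neu5Ac2` notation. Accepted tokens:
#' `Hex`, `HexNAc`, `Fuc`/`dHex`, `Neu5Ac`, `Neu5Gc`, `HexA`, `SO4`/`Sulf`,
#' `Ac`. A token without a trailing count means 1. The alias `"Man5"` parses
#' as `Hex5HexNAc2`. Repeated tokens accumulate.
#'
#' @param text composition string.
#' @return a `glycan_composition`.
#' @examples
#' parse_composition("Hex5HexNAc4Fuc1Neu5Ac2")
#' parse_composition("Man5")
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty composition string", call. = FALSE)
  if (text == "Man5") return(composition(hex = 5L, hexnac = 2L))
  counts <- stats::setNames(integer(length(.RESIDUE_ORDER)), .RESIDUE_ORDER)
  rest <- text
  pat <- paste0("^(", paste(names(.PARSE_TOKENS), collapse = "|"), ")([0-9]*)")
  while (nzchar(rest)) {
    m <- regexec(pat, rest)[[1]]
    if (m[1] == -1L) {
      bad <- sub("([A-Za-z0-9]{1,8}).*", "\\1", rest)
      stop("unknown composition token at '", bad, "' in \"", text, "\"",
           call. = FALSE)
    }
    len <- attr(m, "match.length")
    tok <- substr(rest, m[2], m[2] + len[2] - 1L)
    n <- substr(rest, m[3], m[3] + len[3] - 1L)
    n <- if (nzchar(n)) as.integer(n) else 1L
    slot <- .PARSE_TOKENS[[tok]]
    counts[[slot]] <- counts[[slot]] + n
    rest <- substr(rest, len[1] + 1L, nchar(rest))
  }
  do.call(composition, as.list(counts))
}

#' Render a composition in canonical text form
#'
#' Canonical form lists residues in the fixed order Hex, HexNAc, Fuc,
#' Neu5Ac, Neu5Gc, HexA, SO4, Ac with explicit counts, omitting zero
#' counts; it round-trips through [parse_composition()].
#'
#' @param comp a `glycan_composition`.
#' @return a string, e.g. `"Hex5HexNAc4Fuc1Neu5Ac2"`.
#' @export
format_composition <- function(comp) {
  comp <- as_composition(comp)
  keep <- comp > 0L
  if (!any(keep)) return("")
  paste0(.RENDER_TOKENS[names(comp)[keep]], comp[keep], collapse = "")
}

#' @export
format.glycan_composition <- function(x, ...) format_composition(x)

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", format_composition(x), "\n", sep = "")
  invisible(x)
}

#' Coerce to a glycan composition
#'
#' @param x a `glycan_composition`, a composition string, or a named count
#'   vector.
#' @return a `glycan_composition`.
#' @export
as_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_composition(x))
  if (is.numeric(x) && !is.null(names(x)))
    return(do.call(composition, as.list(x)))
  stop("cannot interpret object as a glycan composition", call. = FALSE)
}

.residue_sum <- function(comp) {
  comp <- as_composition(comp)
  if (sum(comp) == 0L) stop("empty composition has no mass", call. = FALSE)
  sum(.RESIDUES * as.numeric(comp))
}

#' Precursor m/z of a released glycan
#'
#' Mass of an intact, optionally reduced glycan as observed at charge `z`:
#' `(sum of residue masses + water [+ 2H if reduced] + z protons) / z`.
#' At `z = 1` this is the `[M+H]+` mass used throughout for precursor
#' histograms.
#'
#' @param comp composition (object or string).
#' @param reduced logical; `TRUE` for borohydride-reduced glycans (the
#'   default sample preparation for released N-glycans here).
#' @param z charge state, integer >= 1.
#' @return m/z in amu.
#' @examples
#' precursor_mass("Hex5HexNAc4Fuc1Neu5Ac2")       # 2371.86 -> prints as 2371.9
#' precursor_mass("Man5")                          # 1237.456
#' @export
precursor_mass <- function(comp, reduced = TRUE, z = 1L) {
  if (length(z) != 1L || is.na(z) || z < 1 || z != round(z))
    stop("charge z must be an integer >= 1", call. = FALSE)
  m <- .residue_sum(comp) + WATER_MASS + if (reduced) REDUCTION_MASS else 0
  (m + z * PROTON_MASS) / z
}

#' Fragment (oxonium / reduced-end) ion m/z
#'
#' Singly charged glycan fragment masses: non-reduced B-type oxonium ions
#' are `sum of residues + proton`; reduced-end Y-type fragments retain the
#' alditol terminus and are `sum of residues + water + 2H + proton`.
#'
#' @param comp composition (object or string).
#' @param reduced_end logical; does the fragment retain the reduced
#'   innermost GlcNAc?
#' @return m/z in amu.
#' @examples
#' fragment_mz("Hex1HexNAc1Fuc1")                 # 512.1974
#' fragment_mz("HexNAc1", reduced_end = TRUE)     # 224.113
#' @export
fragment_mz <- function(comp, reduced_end = FALSE) {
  m <- .residue_sum(comp)
  if (reduced_end) m <- m + WATER_MASS + REDUCTION_MASS
  m + PROTON_MASS
}

## ---- diagnostic-ion registry ------------------------------------------

.FEATURE_VOCAB <- c("n_glycan", "neu5ac", "neu5gc", "fucose_antenna",
                    "bisecting", "alpha_gal", "hnk1", "hnk1_sulfo",
                    "sulfo_hexnac", "lacdinac_fuc", "lewis_y",
                    "disialyl_lewis_c_ac", "disialyl_lewis_c_gc",
                    "oac_neu5ac", "oac_neu5gc", "sda", "sia_hexnac_ac",
                    "sia_hexnac_gc", "hexose_oligomer", "other")

.validate_registry <- function(reg) {
  need <- c("name", "mz", "composition", "reduced_end", "feature",
            "esnog_cutoff")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop("registry is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(reg$name))
    stop("registry ion names must be unique", call. = FALSE)
  if (any(!is.finite(reg$mz)) || any(reg$mz <= 0))
    stop("registry m/z values must be positive", call. = FALSE)
  if (any(reg$esnog_cutoff < 0 | reg$esnog_cutoff > 1))
    stop("eSNOG cut-offs must lie in [0, 1]", call. = FALSE)
  bad <- setdiff(unique(reg$feature), .FEATURE_VOCAB)
  if (length(bad))
    stop("unknown feature tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  reg$composition <- as.character(reg$composition)
  reg$composition[is.na(reg$composition)] <- ""
  reg$reduced_end <- as.logical(reg$reduced_end)
  class(reg) <- c("ion_registry", "data.frame")
  reg
}

#' Read a diagnostic-ion registry TSV
#'
#' Tab-separated with header columns `name`, `mz`, `composition` (canonical
#' composition string, empty when the generating composition is not
#' assignable), `reduced_end` (logical), `feature` (controlled vocabulary),
#' `esnog_cutoff` (fraction in `[0, 1]`). Decimal separator is `.`.
#'
#' @param path file path.
#' @return a `data.frame` of class `ion_registry`.
#' @export
read_registry <- function(path) {
  reg <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "")
  .validate_registry(reg)
}

#' Write a diagnostic-ion registry TSV
#'
#' @param registry an `ion_registry` data.frame.
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
write_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Built-in diagnostic-ion registry
#'
#' The 49 glycan-diagnostic fragment masses used for MS/MS filtering, each
#' with its sub-structural feature tag and default eSNOG cut-off (0.03 for
#' the N-glycan reporter, the reduced-end GlcNAc ion at 224.1118 amu; 0.01
#' for all other ions). Cut-offs are defaults meant to be overridden with
#' empirically calibrated values via [read_registry()].
#'
#' @return a `data.frame` of class `ion_registry` with 49 rows.
#' @examples
#' reg <- default_registry()
#' reg[reg$feature == "n_glycan", ]
#' @export
default_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "diagnostic_ions.tsv",
                          package = "snoglyc", mustWork = TRUE)
      cache <<- read_registry(path)
    }
    cache
  }
})

#' Look up a registry ion by m/z or name
#'
#' @param registry an `ion_registry`.
#' @param ion ion name (character) or m/z (numeric, matched within `tol`).
#' @param tol matching tolerance in amu for numeric lookup.
#' @return the matching one-row registry entry.
#' @export
registry_ion <- function(registry, ion, tol = 0.005) {
  if (is.character(ion)) {
    hit <- registry[registry$name == ion, , drop = FALSE]
  } else {
    hit <- registry[abs(registry$mz - ion) <= tol, , drop = FALSE]
  }
  if (nrow(hit) != 1L)
    stop("registry lookup for '", ion, "' matched ", nrow(hit), " ions",
         call. = FALSE)
  hit
}
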