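# In-silico enumeration of canonical N-glycan compositions under
# biosynthetic constraints, mass indexing on the precursor grid, and
# annotation of histogram bins.
#
# The constraint model: an N-glycan has a chitobiose core (2 HexNAc) and a
# trimannosyl core (3 Hex). HexNAc beyond the core forms antennae (capped
# at max_antennae) plus at most one bisecting GlcNAc. Each antenna can
# carry a galactose and an alpha-galactose (2 Hex per antenna); bi- or
# lower-antennary structures may additionally retain up to two unprocessed
# hybrid-arm mannoses. Sialic acids cap antennae; fucose decorates
# antennae plus one core position. Oligomannose series: HexNAc 2 with
# Hex 4-9 (paucimannose Hex 3, optionally core-fucosylated, included).

#' Enumeration constraints for the canonical N-glycome
#'
#' @param hexnac_range,hex_range,dhex_range,neu5ac_range,neu5gc_range
#'   inclusive `c(min, max)` count bounds per residue.
#' @param max_antennae maximum number of antennae (GlcNAc branches beyond
#'   the core); one extra non-core HexNAc is allowed for a bisecting
#'   GlcNAc.
#' @param allow_disialyl when `TRUE`, one extra sialic acid beyond the
#'   antenna count is allowed (di-sialyl antenna motifs).
#' @param mass_range reduced `[M+H]+` window in amu.
#' @return an object of class `glyco_constraints`.
#' @export
glyco_constraints <- function(hexnac_range = c(2L, 8L),
                              hex_range = c(3L, 12L),
                              dhex_range = c(0L, 6L),
                              neu5ac_range = c(0L, 4L),
                              neu5gc_range = c(0L, 4L),
                              max_antennae = 4L,
                              allow_disialyl = FALSE,
                              mass_range = c(1000, 5000)) {
  ranges <- list(hexnac = hexnac_range, hex = hex_range, dhex = dhex_range,
                 neu5ac = neu5ac_range, neu5gc = neu5gc_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0)
      stop("invalid range for ", nm, call. = FALSE)
  }
  if (mass_range[1] >= mass_range[2] || mass_range[1] <= 0)
    stop("invalid mass range", call. = FALSE)
  structure(c(ranges, list(max_antennae = as.integer(max_antennae),
                           allow_disialyl = isTRUE(allow_disialyl),
                           mass_range = mass_range)),
            class = "glyco_constraints")
}

## vectorized structural predicate over count columns
.satisfies_constraints <- function(hex, hexnac, dhex, neu5ac, neu5gc, cons) {
  non_core <- hexnac - 2L
  antennae <- pmin(non_core, cons$max_antennae)
  sia <- neu5ac + neu5gc
  ok <- non_core >= 0L & non_core <= cons$max_antennae + 1L
  ## oligomannose / paucimannose series at hexnac == 2
  om <- hexnac == 2L
  ok <- ok & ifelse(om,
                    hex <= 9L & sia == 0L & dhex <= 1L,
                    TRUE)
  ## complex/hybrid hexose budget: trimannosyl core + 2 Hex per antenna
  ## (Gal + alpha-Gal), plus 2 hybrid-arm mannoses for <= bi-antennary
  hex_max <- 3L + 2L * antennae + ifelse(non_core <= 2L, 2L, 0L)
  ok <- ok & ifelse(om, TRUE, hex >= 3L & hex <= hex_max)
  ## sialic acids cap antennae (+1 for di-sialyl motifs when allowed)
  ok <- ok & ifelse(om, TRUE,
                    sia <= antennae + as.integer(cons$allow_disialyl))
  ## fucose: one per antenna plus the core position
  ok & dhex <= antennae + 1L
}

#' Enumerate the canonical N-glycan composition database
#'
#' Exhaustively enumerates all count vectors inside the constraint box,
#' keeps those satisfying the structural rules and whose reduced `[M+H]+`
#' mass lies in the mass window, deduplicates and sorts by mass.
#'
#' @param constraints a [glyco_constraints()].
#' @return a `data.frame` of class `glycodb` with columns `composition`
#'   (canonical string), `hex`, `hexnac`, `dhex`, `neu5ac`, `neu5gc`,
#'   `monoisotopic_mass` (neutral, reduced) and `mplush` (reduced
#'   `[M+H]+`), sorted by mass; the constraint set is kept as attribute
#'   `constraints`.
#' @export
enumerate_glycodb <- function(constraints = glyco_constraints()) {
  cons <- constraints
  grid <- expand.grid(hex = seq(cons$hex[1], cons$hex[2]),
                      hexnac = seq(cons$hexnac[1], cons$hexnac[2]),
                      dhex = seq(cons$dhex[1], cons$dhex[2]),
                      neu5ac = seq(cons$neu5ac[1], cons$neu5ac[2]),
                      neu5gc = seq(cons$neu5gc[1], cons$neu5gc[2]))
  ok <- .satisfies_constraints(grid$hex, grid$hexnac, grid$dhex,
                               grid$neu5ac, grid$neu5gc, cons)
  db <- grid[ok, , drop = FALSE]
  residue_sum <- db$hex * .RESIDUES[["hex"]] +
    db$hexnac * .RESIDUES[["hexnac"]] + db$dhex * .RESIDUES[["dhex"]] +
    db$neu5ac * .RESIDUES[["neu5ac"]] + db$neu5gc * .RESIDUES[["neu5gc"]]
  db$monoisotopic_mass <- residue_sum + WATER_MASS + REDUCTION_MASS
  db$mplush <- db$monoisotopic_mass + PROTON_MASS
  db <- db[db$mplush >= cons$mass_range[1] & db$mplush <= cons$mass_range[2],
           , drop = FALSE]
  db$composition <- apply(db[, c("hex", "hexnac", "dhex", "neu5ac",
                                 "neu5gc")], 1L, function(r)
    format_composition(composition(hex = r[["hex"]], hexnac = r[["hexnac"]],
                                   dhex = r[["dhex"]],
                                   neu5ac = r[["neu5ac"]],
                                   neu5gc = r[["neu5gc"]])))
  db <- db[!duplicated(db$composition), , drop = FALSE]
  db <- db[order(db$mplush, db$composition), , drop = FALSE]
  db <- db[, c("composition", "hex", "hexnac", "dhex", "neu5ac", "neu5gc",
               "monoisotopic_mass", "mplush")]
  rownames(db) <- NULL
  if (!nrow(db)) warning("constraint set yields no compositions")
  attr(db, "constraints") <- cons
  class(db) <- c("glycodb", "data.frame")
  db
}

#' Map database compositions to precursor-grid mass bins
#'
#' Assigns each composition's reduced `[M+H]+` to its bin center on the
#' precursor mass grid; isobaric compositions share a bin.
#'
#' @param db a `glycodb`.
#' @param cfg a [run_config()] defining the grid.
#' @return a named list: bin center (as character of the numeric center)
#'   -> character vector of composition strings.
#' @export
build_mass_index <- function(db, cfg = run_config()) {
  if (!nrow(db)) return(structure(list(), names = character(0)))
  centers <- .grid_center(db$mplush, cfg)
  split(db$composition, format(centers, trim = TRUE, scientific = FALSE))
}

#' Annotate histogram bins with candidate compositions
#'
#' Attaches to every bin the database compositions whose reduced `[M+H]+`
#' lies within `tol` of the bin's measured mass (the intensity-weighted
#' mean feature mass; the grid center is used for bins lacking one).
#' Matching against the measured mass rather than the center keeps
#' annotation robust for masses that fall near a bin boundary. Bins with
#' no candidate are labeled `"unknown"`.
#'
#' @param hist a SNOG-filtered `glyco_histogram`.
#' @param db a `glycodb`.
#' @param tol annotation tolerance in amu (default 0.05).
#' @return the annotated histogram; attribute `unknown_tic_fraction` gives
#'   the TIC fraction carried by unannotated bins.
#' @export
annotate_bins <- function(hist, db, tol = 0.05) {
  ord <- order(db$mplush)
  masses <- db$mplush[ord]
  comps <- db$composition[ord]
  query <- if ("mass" %in% names(hist$bins))
    ifelse(is.na(hist$bins$mass), hist$bins$center, hist$bins$mass)
  else hist$bins$center
  hist$bins$annotations <- lapply(query, function(ctr) {
    lo <- findInterval(ctr - tol, masses) + 1L
    hi <- findInterval(ctr + tol, masses)
    if (hi < lo) character(0) else comps[lo:hi]
  })
  unknown <- lengths(hist$bins$annotations) == 0L
  hist$bins$labels <- mapply(function(lab, unk) {
    if (unk) union(lab, "unknown") else setdiff(lab, "unknown")
  }, hist$bins$labels, unknown, SIMPLIFY = FALSE)
  attr(hist, "unknown_tic_fraction") <-
    if (hist$tic > 0) sum(hist$bins$intensity[unknown]) / hist$tic
    else NA_real_
  hist
}

#' Write / read a glycan composition database as TSV
#'
#' @param db a `glycodb`.
#' @param path file path.
#' @return `write_glycodb` returns `path` invisibly; `read_glycodb`
#'   returns a `glycodb`.
#' @export
write_glycodb <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_glycodb
#' @export
read_glycodb <- function(path) {
  db <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  class(db) <- c("glycodb", "data.frame")
  db
}
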