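# eSNOG-based multi-label classification of precursor mass bins into
# sub-structural categories, TIC-fraction accounting, and screens for
# rare / non-canonical epitopes.

#' Default category rules for sub-structural stratification
#'
#' Five positive ion-based categories plus the composition-based
#' oligomannose class; the complement of the positives is reported as
#' `undecorated`. Water-loss sialic-acid ions qualify alongside the intact
#' oxonium ions. Per-ion cut-offs come from the registry.
#'
#' @param registry an `ion_registry` supplying ion names and eSNOG
#'   cut-offs.
#' @return a `data.frame` of class `category_rules` with columns `label`,
#'   `ions` (list of ion names), `cutoffs` (list, parallel to `ions`).
#' @export
default_category_rules <- function(registry = default_registry()) {
  feats <- list(distal_fucose = "fucose_antenna",
                neu5gc = "neu5gc",
                neu5ac = "neu5ac",
                alpha_gal = "alpha_gal")
  rules <- data.frame(label = names(feats), stringsAsFactors = FALSE)
  rules$ions <- lapply(feats, function(f) registry$name[registry$feature %in% f])
  rules$cutoffs <- lapply(rules$ions, function(nms)
    registry$esnog_cutoff[match(nms, registry$name)])
  class(rules) <- c("category_rules", "data.frame")
  rules
}

## labels that count as "positive" for the undecorated complement
.POSITIVE_LABELS <- c("distal_fucose", "neu5gc", "neu5ac", "alpha_gal",
                      "oligomannose")

.is_oligomannose <- function(comp_string) {
  comp <- parse_composition(comp_string)
  comp[["hexnac"]] == 2L && comp[["hex"]] >= 4L && comp[["hex"]] <= 9L &&
    sum(comp) == comp[["hexnac"]] + comp[["hex"]]
}

## bins x rules presence matrix: bin gets a label when >= min_spectra of
## its attached spectra pass any of the rule's ion cut-offs
.rule_hits <- function(hist, scores, rules, min_spectra = 1L) {
  hits <- matrix(FALSE, nrow(hist$bins), nrow(rules),
                 dimnames = list(NULL, rules$label))
  for (b in seq_len(nrow(hist$bins))) {
    att <- hist$bins$spectra[[b]]
    if (is.null(att) || !nrow(att)) next
    rows <- match(att$id, scores$id)
    for (r in seq_len(nrow(rules))) {
      ions <- rules$ions[[r]]
      cuts <- rules$cutoffs[[r]]
      pass <- rep(FALSE, length(rows))
      for (k in seq_along(ions))
        pass <- pass | scores[[ions[k]]][rows] >= cuts[k]
      hits[b, r] <- sum(pass) >= min_spectra
    }
  }
  hits
}

#' Classify histogram bins into sub-structural categories
#'
#' A bin receives an ion-based label when at least `min_spectra` of its
#' attached spectra reach the eSNOG cut-off for any of the label's ions
#' (multi-label: categories may overlap). `oligomannose` is assigned from
#' bin annotations (composition HexNAc 2, Hex 4-9). Bins carrying none of
#' the five positive labels are labeled `undecorated`.
#'
#' @param hist an annotated `glyco_histogram` with spectra attached.
#' @param scores [score_spectra()] result covering the attached spectra.
#' @param rules [default_category_rules()] or a compatible rules table.
#' @param min_spectra qualifying-spectrum quorum per bin (default 1).
#' @return the histogram with bin `labels` filled.
#' @export
classify_bins <- function(hist, scores, rules = default_category_rules(),
                          min_spectra = 1L) {
  if (is.null(scores) || !nrow(scores))
    stop("classify_bins requires spectrum scores", call. = FALSE)
  hits <- .rule_hits(hist, scores, rules, min_spectra)
  hist$bins$labels <- lapply(seq_len(nrow(hist$bins)), function(b) {
    labs <- colnames(hits)[hits[b, ]]
    ann <- hist$bins$annotations[[b]]
    if (length(ann) && any(vapply(ann, .is_oligomannose, logical(1))))
      labs <- c(labs, "oligomannose")
    if (!any(labs %in% .POSITIVE_LABELS))
      labs <- c(labs, "undecorated")
    keep_unknown <- "unknown" %in% hist$bins$labels[[b]]
    if (keep_unknown) labs <- c(labs, "unknown")
    unique(labs)
  })
  hist
}

#' TIC fractions per category label
#'
#' For every label, the fraction of the histogram's total ion current
#' carried by bins bearing that label. Labels overlap, so fractions need
#' not sum to 1.
#'
#' @param hist a classified `glyco_histogram`.
#' @param labels labels to report; default: the five positive categories
#'   plus `undecorated`.
#' @return a list of class `stratification_report`: `sample`, `fractions`
#'   (named numeric), `bins` (named list of bin centers per label),
#'   `top_compositions` (named list of annotation strings of the highest-
#'   intensity bins per label).
#' @export
tic_fractions <- function(hist, labels = c(.POSITIVE_LABELS, "undecorated")) {
  if (!isTRUE(hist$tic > 0)) stop("histogram TIC is zero", call. = FALSE)
  has <- function(lab) vapply(hist$bins$labels, function(l) lab %in% l,
                              logical(1))
  fr <- vapply(labels, function(lab)
    sum(hist$bins$intensity[has(lab)]) / hist$tic, numeric(1))
  bins <- lapply(labels, function(lab) hist$bins$center[has(lab)])
  top <- lapply(labels, function(lab) {
    sel <- which(has(lab))
    sel <- sel[order(hist$bins$intensity[sel], decreasing = TRUE)]
    sel <- utils::head(sel, 5L)
    unique(unlist(hist$bins$annotations[sel]))
  })
  names(bins) <- names(top) <- labels
  structure(list(sample = hist$sample, fractions = fr, bins = bins,
                 top_compositions = top),
            class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat("<stratification report> ", x$sample, "\n", sep = "")
  for (lab in names(x$fractions))
    cat(sprintf("  %-16s %5.1f%% of TIC (%d bins)\n", lab,
                100 * x$fractions[[lab]], length(x$bins[[lab]])))
  invisible(x)
}

## rare / non-canonical epitope feature tags screened by rare_screen()
.RARE_FEATURES <- c("hnk1", "hnk1_sulfo", "sulfo_hexnac", "lacdinac_fuc",
                    "lewis_y", "disialyl_lewis_c_ac", "disialyl_lewis_c_gc",
                    "oac_neu5ac", "oac_neu5gc", "sda", "sia_hexnac_ac",
                    "sia_hexnac_gc")

#' Screen a sample for rare / non-canonical glycan epitopes
#'
#' For each rare-feature tag in the registry (HNK-1 and its sulfated form,
#' sulfated HexNAc, fucosylated LacdiNAc, Lewis Y, di-sialyl Lewis C
#' variants, O-acetylated sialic acids, Sda, sialylated HexNAc), reports
#' the TIC fraction of bins with at least one qualifying spectrum and the
#' contributing precursor compositions.
#'
#' @param hist an annotated `glyco_histogram` with spectra attached.
#' @param scores [score_spectra()] result.
#' @param registry the `ion_registry` holding the rare-feature ions and
#'   cut-offs.
#' @param features feature tags to screen (default: all rare tags).
#' @return a `data.frame`: `feature`, `tic_fraction`, `n_bins`,
#'   `compositions` (list column).
#' @export
rare_screen <- function(hist, scores, registry = default_registry(),
                        features = .RARE_FEATURES) {
  rules <- data.frame(label = features, stringsAsFactors = FALSE)
  rules$ions <- lapply(features, function(f)
    registry$name[registry$feature == f])
  rules$cutoffs <- lapply(rules$ions, function(nms)
    registry$esnog_cutoff[match(nms, registry$name)])
  empty <- lengths(rules$ions) == 0L
  if (any(empty))
    stop("registry lacks ions for feature(s): ",
         paste(features[empty], collapse = ", "), call. = FALSE)
  hits <- .rule_hits(hist, scores, rules)
  tic <- hist$tic
  out <- data.frame(feature = features,
                    tic_fraction = vapply(seq_along(features), function(r)
                      if (tic > 0) sum(hist$bins$intensity[hits[, r]]) / tic
                      else NA_real_, numeric(1)),
                    n_bins = colSums(hits),
                    stringsAsFactors = FALSE)
  out$compositions <- lapply(seq_along(features), function(r)
    unique(unlist(hist$bins$annotations[hits[, r]])))
  rownames(out) <- NULL
  out
}
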