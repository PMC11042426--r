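# Precursor-independent MS/MS profiling: diagnostic-ion intensities,
# SNOG/eSNOG spectrum scores, RT-binned spectral counts.
#
# The SNOG score of a spectrum is the relative intensity of the N-glycan
# reporter ion (the oxonium ion of the reduced-end GlcNAc, 224.1118 amu);
# eSNOG is the same quantity computed for any other sub-structure-specific
# diagnostic ion. Spectra from reduced N-glycan precursors carry the
# reporter; hexose-oligomer contaminants and peptides do not.

N_GLYCAN_ION_MZ <- 224.1118

#' Summed intensity of a diagnostic ion in a spectrum
#'
#' Sums all peaks within `mz +/- tol`. Summing (rather than taking the
#' maximum) is robust to split centroids.
#'
#' @param spec a `spectrum`.
#' @param mz query m/z in amu.
#' @param tol matching tolerance in amu (default 0.05).
#' @return summed intensity; 0 when no peak falls in the window.
#' @export
ion_intensity <- function(spec, mz, tol = 0.05) {
  stopifnot(tol > 0)
  lo <- findInterval(mz - tol, spec$mz) + 1L
  hi <- findInterval(mz + tol, spec$mz)
  if (hi < lo) return(0)
  sum(spec$intensity[lo:hi])
}

.score_denominator <- function(spec, denominator = "tic") {
  d <- switch(denominator,
              tic = sum(spec$intensity),
              base_peak = if (length(spec$intensity)) max(spec$intensity) else 0,
              stop("unknown score denominator: ", denominator, call. = FALSE))
  if (!is.finite(d) || d <= 0)
    stop("spectrum '", spec$id, "' has no positive intensity; ",
         "SNOG/eSNOG scores are undefined", call. = FALSE)
  d
}

#' eSNOG score of a spectrum for one diagnostic ion
#'
#' Relative intensity of the ion: its summed in-window intensity divided by
#' the spectrum's total intensity (or base peak, per `denominator`). Lies
#' in `[0, 1]` for the default TIC denominator.
#'
#' @param spec a `spectrum` with at least one positive-intensity peak.
#' @param ion one-row registry entry (see [registry_ion()]), a numeric m/z,
#'   or an ion name resolved against [default_registry()].
#' @param tol matching tolerance in amu.
#' @param denominator `"tic"` or `"base_peak"`.
#' @return score fraction.
#' @export
esnog <- function(spec, ion, tol = 0.05, denominator = "tic") {
  mz <- if (is.numeric(ion)) ion
        else if (is.data.frame(ion)) ion$mz[1]
        else registry_ion(default_registry(), ion)$mz
  ion_intensity(spec, mz, tol) / .score_denominator(spec, denominator)
}

#' SNOG score of a spectrum
#'
#' The eSNOG score of the N-glycan reporter ion (reduced-end GlcNAc
#' oxonium, 224.1118 amu). Spectra scoring below 0.03 are treated as not
#' N-glycan derived downstream.
#'
#' @inheritParams esnog
#' @return score fraction in `[0, 1]`.
#' @export
snog <- function(spec, tol = 0.05, denominator = "tic") {
  esnog(spec, N_GLYCAN_ION_MZ, tol = tol, denominator = denominator)
}

#' Score a set of spectra against a diagnostic-ion registry
#'
#' Computes, per spectrum, the SNOG score and the eSNOG score of every
#' registry ion.
#'
#' @param spectra list of `spectrum` objects.
#' @param registry an `ion_registry` (default: built-in).
#' @param tol matching tolerance in amu.
#' @param denominator `"tic"` or `"base_peak"`.
#' @return a `data.frame` of class `spectrum_scores`: columns `id`,
#'   `sample`, `rt`, `snog`, then one eSNOG column per registry ion
#'   (named by ion name).
#' @export
score_spectra <- function(spectra, registry = default_registry(),
                          tol = 0.05, denominator = "tic") {
  if (!length(spectra)) {
    out <- data.frame(id = character(), sample = character(),
                      rt = numeric(), snog = numeric())
    class(out) <- c("spectrum_scores", "data.frame")
    return(out)
  }
  es <- t(vapply(spectra, function(sp) {
    d <- .score_denominator(sp, denominator)
    vapply(registry$mz, function(m) ion_intensity(sp, m, tol), numeric(1)) / d
  }, numeric(nrow(registry))))
  colnames(es) <- registry$name
  out <- data.frame(id = vapply(spectra, `[[`, character(1), "id"),
                    sample = vapply(spectra, `[[`, character(1), "sample"),
                    rt = vapply(spectra, `[[`, numeric(1), "rt"),
                    snog = es[, registry$name[registry$feature == "n_glycan"][1]],
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(es, check.names = FALSE))
  rownames(out) <- NULL
  class(out) <- c("spectrum_scores", "data.frame")
  out
}

#' Precursor-independent MS/MS profile of one sample
#'
#' Counts, per registry ion, the spectra containing that ion (eSNOG >= its
#' registry cut-off), reports fractions normalized to the number of
#' N-glycan spectra (those containing the 224.1118 reporter), and bins the
#' counts over retention time.
#'
#' @param spectra list of `spectrum` objects from one sample.
#' @param registry an `ion_registry`.
#' @param rt_bin retention-time bin size in seconds.
#' @param tol matching tolerance in amu.
#' @param scores optional precomputed [score_spectra()] result.
#' @return a list of class `profile_report`: `sample`, `total_spectra`,
#'   `n_glycan_spectra`, `counts` (data.frame: ion, feature, n_spectra,
#'   fraction_of_nglycan, fraction_of_total) and `rt_histogram`
#'   (data.frame: ion, rt_bin_start, count). When no spectrum contains the
#'   reporter ion, `fraction_of_nglycan` is `NA` and the report carries
#'   `degenerate = TRUE`.
#' @export
profile_spectra <- function(spectra, registry = default_registry(),
                            rt_bin = 10, tol = 0.05, scores = NULL) {
  samples <- unique(vapply(spectra, `[[`, character(1), "sample"))
  if (length(samples) > 1L)
    stop("profile_spectra expects spectra from a single sample; got: ",
         paste(samples, collapse = ", "), call. = FALSE)
  if (!length(spectra)) {
    return(structure(list(sample = NA_character_, total_spectra = 0L,
                          n_glycan_spectra = 0L,
                          counts = data.frame(), rt_histogram = data.frame(),
                          degenerate = TRUE),
                     class = "profile_report"))
  }
  if (is.null(scores))
    scores <- score_spectra(spectra, registry, tol = tol)
  present <- vapply(registry$name, function(nm)
    scores[[nm]] >= registry$esnog_cutoff[registry$name == nm],
    logical(nrow(scores)))
  present <- matrix(present, nrow = nrow(scores),
                    dimnames = list(NULL, registry$name))
  n_gly <- sum(present[, registry$name[registry$feature == "n_glycan"][1]])
  counts <- data.frame(ion = registry$name, feature = registry$feature,
                       n_spectra = colSums(present),
                       stringsAsFactors = FALSE)
  counts$fraction_of_nglycan <- if (n_gly > 0) counts$n_spectra / n_gly
                                else NA_real_
  counts$fraction_of_total <- counts$n_spectra / nrow(scores)
  rownames(counts) <- NULL
  rt_start <- floor(scores$rt / rt_bin) * rt_bin
  rt_hist <- do.call(rbind, lapply(registry$name, function(nm) {
    if (!any(present[, nm])) return(NULL)
    tab <- table(rt_start[present[, nm]])
    data.frame(ion = nm, rt_bin_start = as.numeric(names(tab)),
               count = as.integer(tab), stringsAsFactors = FALSE)
  }))
  if (is.null(rt_hist))
    rt_hist <- data.frame(ion = character(), rt_bin_start = numeric(),
                          count = integer())
  structure(list(sample = samples, total_spectra = nrow(scores),
                 n_glycan_spectra = n_gly, counts = counts,
                 rt_histogram = rt_hist, degenerate = n_gly == 0L),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("<profile report> %s: %d spectra, %d N-glycan derived (%.1f%%)\n",
              x$sample, x$total_spectra, x$n_glycan_spectra,
              if (x$total_spectra) 100 * x$n_glycan_spectra / x$total_spectra
              else 0))
  if (isTRUE(x$degenerate))
    cat("  [degenerate: no spectrum contains the N-glycan reporter ion]\n")
  invisible(x)
}
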