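# Aggregation of charge-deconvoluted MS1 features into precursor-mass
# histograms, MS/MS attachment, SNOG filtering, intensity thresholding and
# TIC normalization.
#
# The mass grid is fixed: bin centers sit at bin_low + k * (2 * half_width)
# so the default configuration places centers at 1000.0 + k * 0.1 amu and
# one-decimal precursor masses coincide with centers.

.grid_center <- function(mass, cfg) {
  w <- 2 * cfg$bin_half_width
  ## round to a canonical double so centers compare exactly across code paths
  round(cfg$bin_low + round((mass - cfg$bin_low) / w) * w, 6)
}

.new_histogram <- function(sample, bins, cfg) {
  structure(list(sample = sample, bins = bins,
                 tic = sum(bins$intensity), config = cfg),
            class = "glyco_histogram")
}

#' @export
print.glyco_histogram <- function(x, ...) {
  cat(sprintf("<glycome histogram> %s: %d mass bins, TIC %.3g\n",
              x$sample, nrow(x$bins), x$tic))
  invisible(x)
}

#' Bin MS1 features into a precursor-mass histogram
#'
#' Assigns every in-range feature to the nearest center of the fixed mass
#' grid and sums intensities over the whole chromatographic time range.
#' Features outside `[bin_low, bin_high]` are dropped (count reported via
#' message). Binning is independent of input order.
#'
#' @param features data.frame from [read_features()] or
#'   [simulate_sample()] (`mass` on the `[M+H]+` scale, `rt`, `intensity`,
#'   `sample`).
#' @param cfg a [run_config()].
#' @return a `glyco_histogram`: `sample`, `bins` (data.frame with
#'   `center`, `intensity`, `mass` — the intensity-weighted mean feature
#'   mass of the bin, used for annotation — `snog`, `n_spectra` plus list
#'   columns `spectra`, `annotations`, `labels`), `tic`, `config`.
#' @export
bin_features <- function(features, cfg = run_config()) {
  sample <- unique(features$sample)
  if (length(sample) > 1L)
    stop("bin_features expects features from a single sample", call. = FALSE)
  if (length(sample) == 0L) sample <- NA_character_
  keep <- features$mass >= cfg$bin_low & features$mass <= cfg$bin_high
  if (any(!keep))
    message("bin_features: dropped ", sum(!keep),
            " feature(s) outside the mass range")
  f <- features[keep, , drop = FALSE]
  centers <- .grid_center(f$mass, cfg)
  agg <- tapply(f$intensity, centers, sum)
  wmass <- tapply(f$mass * f$intensity, centers, sum) / agg
  ord <- order(as.numeric(names(agg)))
  bins <- data.frame(center = as.numeric(names(agg))[ord],
                     intensity = as.numeric(agg)[ord],
                     mass = as.numeric(wmass)[ord],
                     snog = NA_real_, n_spectra = 0L)
  bins$spectra <- replicate(nrow(bins), NULL, simplify = FALSE)
  bins$annotations <- replicate(nrow(bins), character(0), simplify = FALSE)
  bins$labels <- replicate(nrow(bins), character(0), simplify = FALSE)
  .new_histogram(sample, bins, cfg)
}

#' Remove mass bins below a cumulative intensity threshold
#'
#' @param hist a `glyco_histogram`.
#' @param min_intensity bins with summed intensity strictly below this are
#'   removed (default 5e6).
#' @return the filtered histogram with TIC recomputed.
#' @export
threshold_bins <- function(hist, min_intensity = 5e6) {
  keep <- hist$bins$intensity >= min_intensity
  if (!any(keep)) warning("all mass bins fall below the intensity threshold")
  hist$bins <- hist$bins[keep, , drop = FALSE]
  rownames(hist$bins) <- NULL
  hist$tic <- sum(hist$bins$intensity)
  hist
}

#' Singly-protonated precursor mass of an MS/MS spectrum
#'
#' `(precursor m/z - proton) * z + proton`, i.e. the `[M+H]+` mass implied
#' by the instrument's precursor m/z and charge assignment.
#'
#' @param spec a `spectrum` with known charge.
#' @return mass in amu.
#' @export
spectrum_mplush <- function(spec) {
  if (is.na(spec$charge))
    stop("spectrum '", spec$id, "' has unknown charge", call. = FALSE)
  (spec$precursor_mz - PROTON_MASS) * spec$charge + PROTON_MASS
}

#' Attach MS/MS spectra (and their SNOG scores) to histogram bins
#'
#' Each spectrum's `[M+H]+` precursor mass is assigned to the nearest grid
#' bin center present in the histogram, provided the distance is within
#' `tol`. Spectra with unknown charge, out-of-tolerance masses, or masses
#' landing on absent bins are skipped and counted. Per-bin SNOG is the
#' weighted mean of attached spectra's SNOG scores (uniform weights unless
#' `weights` supplies per-spectrum precursor intensities).
#'
#' @param hist a `glyco_histogram`.
#' @param spectra list of `spectrum` objects.
#' @param scores [score_spectra()] result covering `spectra`.
#' @param tol assignment tolerance in amu (default 0.05).
#' @param weights optional numeric vector (parallel to `spectra`) of
#'   precursor intensities used as aggregation weights.
#' @param aggregate `"weighted_mean"` (default) or `"max"` for the per-bin
#'   SNOG aggregation.
#' @return the histogram with `spectra`, `snog`, `n_spectra` filled;
#'   attribute `n_unassigned` counts skipped spectra.
#' @export
attach_spectra <- function(hist, spectra, scores, tol = 0.05,
                           weights = NULL,
                           aggregate = c("weighted_mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (is.null(weights)) weights <- rep(1, length(spectra))
  stopifnot(length(weights) == length(spectra))
  idx <- match(vapply(spectra, `[[`, character(1), "id"), scores$id)
  if (anyNA(idx))
    stop("scores do not cover all spectra", call. = FALSE)
  snogs <- scores$snog[idx]
  unassigned <- 0L
  per_bin <- vector("list", nrow(hist$bins))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (is.na(sp$charge)) { unassigned <- unassigned + 1L; next }
    mass <- spectrum_mplush(sp)
    center <- .grid_center(mass, hist$config)
    if (abs(mass - center) > tol) { unassigned <- unassigned + 1L; next }
    j <- match(center, hist$bins$center)
    if (is.na(j)) { unassigned <- unassigned + 1L; next }
    per_bin[[j]] <- rbind(per_bin[[j]],
                          data.frame(id = sp$id, snog = snogs[i],
                                     weight = weights[i],
                                     stringsAsFactors = FALSE))
  }
  hist$bins$spectra <- per_bin
  hist$bins$n_spectra <- vapply(per_bin, function(d)
    if (is.null(d)) 0L else nrow(d), integer(1))
  hist$bins$snog <- vapply(per_bin, function(d) {
    if (is.null(d)) return(NA_real_)
    if (aggregate == "max") max(d$snog)
    else stats::weighted.mean(d$snog, d$weight)
  }, numeric(1))
  attr(hist, "n_unassigned") <- unassigned
  hist
}

#' Reject mass bins that lack N-glycan MS/MS evidence
#'
#' Removes bins with no attached spectra and bins whose aggregated SNOG
#' score falls below the cut-off. This is the step that discards, e.g.,
#' hexose-oligomer contaminant signals whose spectra lack the 224.1118
#' reporter ion.
#'
#' @param hist a `glyco_histogram` with spectra attached.
#' @param cutoff SNOG cut-off (default 0.03).
#' @return the filtered histogram; attribute `n_rejected` counts removed
#'   bins.
#' @export
snog_filter <- function(hist, cutoff = 0.03) {
  keep <- !is.na(hist$bins$snog) & hist$bins$snog >= cutoff
  n_rej <- sum(!keep)
  hist$bins <- hist$bins[keep, , drop = FALSE]
  rownames(hist$bins) <- NULL
  hist$tic <- sum(hist$bins$intensity)
  attr(hist, "n_rejected") <- n_rej
  hist
}

#' Normalize bin intensities to the total ion current
#'
#' @param hist a `glyco_histogram` with positive TIC.
#' @return histogram whose bin intensities sum to 1 (idempotent).
#' @export
tic_normalize <- function(hist) {
  if (!isTRUE(hist$tic > 0)) stop("histogram TIC is zero", call. = FALSE)
  hist$bins$intensity <- hist$bins$intensity / hist$tic
  hist$tic <- sum(hist$bins$intensity)
  hist
}

#' Export histogram bins as a plain data.frame
#'
#' @param hist a `glyco_histogram`.
#' @return data.frame with `center_mass`, `intensity`, `snog`,
#'   `n_spectra`, `labels`, `annotations` (the latter two collapsed with
#'   `;`).
#' @export
histogram_table <- function(hist) {
  data.frame(center_mass = hist$bins$center,
             intensity = hist$bins$intensity,
             snog = hist$bins$snog,
             n_spectra = hist$bins$n_spectra,
             labels = vapply(hist$bins$labels, paste, character(1),
                             collapse = ";"),
             annotations = vapply(hist$bins$annotations, paste, character(1),
                                  collapse = ";"),
             stringsAsFactors = FALSE)
}
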