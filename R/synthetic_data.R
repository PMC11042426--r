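# Seeded synthetic-data generator: MS1 feature tables and DDA MS/MS
# spectra with known ground truth (composition abundances, sub-structural
# feature tags, isomer retention modes, hexose-oligomer contaminants), so
# every pipeline stage is testable without instrument data.
#
# What it emulates: per-sample composition abundance profiles; MS/MS
# spectra whose fragment content reflects each glycan's sub-structural
# features (always including the reduced-end GlcNAc reporter ion for
# N-glycans); retention-time structure with isomer peaks relative to the
# Man5 reference; and non-glycan hexose-oligomer background (glycogen- /
# dextran-like ladders) whose spectra lack the reporter ion. It does NOT
# emulate chromatographic peak shapes, isotope envelopes or adducts.

#' One glycan entry of a synthetic sample
#'
#' @param composition composition string.
#' @param intensity total MS1 intensity of the glycan (all isomer modes
#'   summed); keep above the 5e6 bin threshold for end-to-end runs.
#' @param tags character vector of sub-structural feature tags (registry
#'   feature vocabulary, e.g. `"fucose_antenna"`, `"neu5gc"`); each tag
#'   adds that feature's diagnostic ion to the glycan's MS/MS spectra.
#' @param modes list of `c(rel_rt, weight)` pairs: isomer elution modes as
#'   Man5-relative retention and intensity weight (weights sum to 1).
#' @return a list of class `glycan_entry`.
#' @export
glycan_entry <- function(composition, intensity, tags = character(0),
                         modes = list(c(1.2, 1))) {
  w <- vapply(modes, `[`, numeric(1), 2)
  if (abs(sum(w) - 1) > 1e-9)
    stop("isomer mode weights must sum to 1", call. = FALSE)
  if (intensity <= 0) stop("glycan intensity must be > 0", call. = FALSE)
  structure(list(composition = composition, intensity = intensity,
                 tags = tags, modes = modes), class = "glycan_entry")
}

#' Specification of one synthetic sample
#'
#' @param sample sample label.
#' @param glycans list of [glycan_entry()] objects. A Man5 entry is added
#'   automatically (mode at relative retention 1.0) unless already
#'   present, so the retention reference always exists.
#' @param man5_rt Man5 apex retention time in seconds.
#' @param man5_intensity intensity of the auto-added Man5 entry.
#' @param contaminant_intensity total intensity of the hexose-oligomer
#'   contaminant ladder (0 disables it).
#' @param contaminant_lengths hexose counts of the ladder members.
#' @param features_per_mode MS1 features generated per isomer mode.
#' @param spectra_per_mode MS/MS spectra generated per isomer mode.
#' @param noise_cv coefficient of variation of feature intensities (the
#'   per-glycan total is preserved exactly).
#' @param mz_jitter_sd m/z jitter SD in amu (<= 0.01; default 0.005, well
#'   inside the 0.05 matching tolerance).
#' @param rt_jitter_sd retention-time jitter SD in seconds.
#' @param seed integer seed fixing all randomness of this sample.
#' @return a list of class `sample_spec`.
#' @export
sample_spec <- function(sample, glycans, man5_rt = 840,
                        man5_intensity = 2e7, contaminant_intensity = 0,
                        contaminant_lengths = 7:25,
                        features_per_mode = 3L, spectra_per_mode = 2L,
                        noise_cv = 0.1, mz_jitter_sd = 0.005,
                        rt_jitter_sd = 1, seed = 1L) {
  if (mz_jitter_sd > 0.01)
    stop("m/z jitter SD must be <= 0.01 amu", call. = FALSE)
  has_man5 <- any(vapply(glycans, function(g)
    format_composition(parse_composition(g$composition)) ==
      "Hex5HexNAc2", logical(1)))
  if (!has_man5)
    glycans <- c(glycans, list(glycan_entry("Man5", man5_intensity,
                                            modes = list(c(1, 1)))))
  structure(list(sample = sample, glycans = glycans, man5_rt = man5_rt,
                 contaminant_intensity = contaminant_intensity,
                 contaminant_lengths = contaminant_lengths,
                 features_per_mode = as.integer(features_per_mode),
                 spectra_per_mode = as.integer(spectra_per_mode),
                 noise_cv = noise_cv, mz_jitter_sd = mz_jitter_sd,
                 rt_jitter_sd = rt_jitter_sd, seed = as.integer(seed)),
            class = "sample_spec")
}

## diagnostic ion m/z used for a feature tag (first registry ion of that
## feature)
.tag_ion_mz <- function(tag, registry) {
  mz <- registry$mz[registry$feature == tag]
  if (!length(mz)) stop("no registry ion for tag '", tag, "'", call. = FALSE)
  mz[1]
}

## hexose-oligomer oxonium ladder (Hex1..Hex3 B ions)
.HEXOSE_LADDER <- c(163.0601, 325.1129, 487.1657)

#' Simulate one sample
#'
#' Generates MS1 features and DDA MS/MS spectra for a [sample_spec()],
#' together with a ground-truth record. Glycan MS/MS spectra always
#' contain the 224.1118 reporter (SNOG >= 0.05 by construction) plus one
#' diagnostic ion per feature tag; contaminant spectra carry the hexose
#' ladder and no reporter. Feature intensities are noisy but rescaled so
#' each glycan's (and each isomer mode's) total is exact.
#'
#' @param spec a `sample_spec`.
#' @return list with `features` (data.frame: mass, rt, intensity, sample),
#'   `spectra` (list of `spectrum`), and `truth` (list: `sample`,
#'   `glycans` data.frame with composition/center/intensity/tags/fraction,
#'   `glycan_bins`, `contaminant_bins`, `label_fractions` named vector,
#'   `modes` named list of true mode positions per composition,
#'   `man5_rt`).
#' @export
simulate_sample <- function(spec) {
  set.seed(spec$seed)
  cfg <- run_config()
  feats <- list(); spectra <- list(); scan <- 0L
  gl_rows <- list()
  for (g in spec$glycans) {
    comp <- parse_composition(g$composition)
    mass <- precursor_mass(comp, reduced = TRUE, z = 1L)
    center <- .grid_center(mass, cfg)
    centers_seen <- numeric(0)
    for (m in g$modes) {
      rel <- m[1]; w <- m[2]
      rt0 <- rel * spec$man5_rt
      ## observed (deconvoluted consensus) mass of this feature cluster:
      ## one calibration draw shared by its MS1 slices and DDA triggers
      obs_mass <- mass + stats::rnorm(1, 0, spec$mz_jitter_sd)
      centers_seen <- c(centers_seen, .grid_center(obs_mass, cfg))
      ## MS1 features: noisy split of the mode intensity, total exact
      n <- spec$features_per_mode
      raw <- abs(stats::rnorm(n, 1, spec$noise_cv))
      ints <- raw / sum(raw) * g$intensity * w
      feats[[length(feats) + 1L]] <- data.frame(
        mass = rep(obs_mass, n),
        rt = rt0 + stats::rnorm(n, 0, spec$rt_jitter_sd),
        intensity = ints, sample = spec$sample)
      ## MS/MS spectra (charge 2 DDA triggers on the observed ion)
      for (k in seq_len(spec$spectra_per_mode)) {
        scan <- scan + 1L
        mz <- c(204.0867, 366.1395, N_GLYCAN_ION_MZ, mass)
        it <- c(100, 60, 50, 80)
        for (tag in g$tags) {
          mz <- c(mz, .tag_ion_mz(tag, default_registry()))
          it <- c(it, 40)
        }
        mz <- mz + stats::rnorm(length(mz), 0, spec$mz_jitter_sd)
        it <- it * abs(stats::rnorm(length(it), 1, spec$noise_cv))
        spectra[[scan]] <- spectrum(
          id = sprintf("%s.scan%04d", spec$sample, scan),
          precursor_mz = (obs_mass + PROTON_MASS) / 2,
          charge = 2L,
          rt = rt0 + stats::rnorm(1, 0, spec$rt_jitter_sd),
          mz = mz, intensity = it, sample = spec$sample)
      }
    }
    gl_rows[[length(gl_rows) + 1L]] <- data.frame(
      composition = format_composition(comp), center = center,
      observed_centers = paste(unique(centers_seen), collapse = ";"),
      intensity = g$intensity, tags = paste(g$tags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  glycans <- do.call(rbind, gl_rows)
  ## contaminant hexose-oligomer ladder (no reporter ion in MS/MS)
  contaminant_bins <- numeric(0)
  if (spec$contaminant_intensity > 0) {
    lens <- spec$contaminant_lengths
    w <- 0.85^seq_along(lens); w <- w / sum(w)
    for (i in seq_along(lens)) {
      mass <- precursor_mass(composition(hex = lens[i]))
      obs_mass <- mass + stats::rnorm(1, 0, spec$mz_jitter_sd)
      contaminant_bins <- c(contaminant_bins, .grid_center(obs_mass, cfg))
      n <- spec$features_per_mode
      raw <- abs(stats::rnorm(n, 1, spec$noise_cv))
      rt0 <- stats::runif(1, 0.3, 2.2) * spec$man5_rt
      feats[[length(feats) + 1L]] <- data.frame(
        mass = rep(obs_mass, n),
        rt = rt0 + stats::rnorm(n, 0, spec$rt_jitter_sd),
        intensity = raw / sum(raw) * spec$contaminant_intensity * w[i],
        sample = spec$sample)
      for (k in seq_len(spec$spectra_per_mode)) {
        scan <- scan + 1L
        mz <- c(.HEXOSE_LADDER, 183.0863, mass)
        it <- c(100, 70, 40, 30, 60) *
          abs(stats::rnorm(5, 1, spec$noise_cv))
        spectra[[scan]] <- spectrum(
          id = sprintf("%s.scan%04d", spec$sample, scan),
          precursor_mz = (obs_mass + PROTON_MASS) / 2, charge = 2L,
          rt = rt0 + stats::rnorm(1, 0, spec$rt_jitter_sd),
          mz = mz + stats::rnorm(5, 0, spec$mz_jitter_sd),
          intensity = it, sample = spec$sample)
      }
    }
  }
  contaminant_bins <- setdiff(contaminant_bins, glycans$center)
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  glycans$fraction <- glycans$intensity / sum(glycans$intensity)
  truth <- list(sample = spec$sample, glycans = glycans,
                glycan_bins = sort(unique(as.numeric(unlist(
                  strsplit(glycans$observed_centers, ";", fixed = TRUE))))),
                contaminant_bins = sort(unique(contaminant_bins)),
                label_fractions = .truth_label_fractions(glycans),
                modes = stats::setNames(
                  lapply(spec$glycans, function(g)
                    vapply(g$modes, `[`, numeric(1), 1)),
                  vapply(spec$glycans, function(g)
                    format_composition(parse_composition(g$composition)),
                    character(1))),
                man5_rt = spec$man5_rt)
  list(features = features, spectra = spectra, truth = truth)
}

## expected TIC fraction per stratification label, from the generator's
## own bookkeeping (glycan intensities are exact by construction)
.truth_label_fractions <- function(glycans) {
  tags <- strsplit(glycans$tags, ";", fixed = TRUE)
  total <- sum(glycans$intensity)
  oligo <- vapply(glycans$composition, .is_oligomannose, logical(1))
  tag2label <- c(fucose_antenna = "distal_fucose", neu5gc = "neu5gc",
                 neu5ac = "neu5ac", alpha_gal = "alpha_gal")
  labels <- lapply(seq_len(nrow(glycans)), function(i) {
    labs <- unname(tag2label[intersect(tags[[i]], names(tag2label))])
    labs <- c(labs, tags[[i]][!(tags[[i]] %in% names(tag2label)) &
                                nzchar(tags[[i]])])
    if (oligo[i]) labs <- c(labs, "oligomannose")
    if (!any(labs %in% .POSITIVE_LABELS)) labs <- c(labs, "undecorated")
    unique(labs)
  })
  all_labs <- unique(c(.POSITIVE_LABELS, "undecorated",
                       unlist(labels)))
  vapply(stats::setNames(all_labs, all_labs), function(lab)
    sum(glycans$intensity[vapply(labels, function(l) lab %in% l,
                                 logical(1))]) / total,
    numeric(1))
}

#' Six-tissue synthetic mouse panel
#'
#' A toy panel echoing headline organ contrasts: a serum-like sample
#' dominated by Neu5Gc sialylation, a brain-like sample with Neu5Ac,
#' bisecting GlcNAc and a di-sialyl antenna species, a kidney-like sample
#' rich in antennary fucose with an HNK-1 glycan, a pancreas-like sample
#' with alpha-Gal and sulfated HexNAc, a seminal-vesicle-like sample with
#' Lewis Y, and a liver-like sample carrying a heavy hexose-oligomer
#' contaminant ladder.
#'
#' @param seed integer master seed.
#' @param replicates replicate samples per tissue (labels get a `_r`
#'   suffix when `replicates > 1`).
#' @return list of [sample_spec()] objects (length `6 * replicates`).
#' @export
mouse_panel <- function(seed = 1L, replicates = 1L) {
  tissues <- list(
    serum = list(glycans = list(
      glycan_entry("Hex5HexNAc4Neu5Gc1", 4.0e7, "neu5gc", list(c(1.35, 1))),
      glycan_entry("Hex5HexNAc4Neu5Gc2", 3.2e7, "neu5gc", list(c(1.55, 1))),
      glycan_entry("Hex5HexNAc4Fuc1Neu5Gc2", 1.4e7, "neu5gc",
                   list(c(1.6, 1))),
      glycan_entry("Hex5HexNAc4Neu5Ac2", 0.8e7, "neu5ac", list(c(1.5, 1)))),
      contaminant = 0),
    brain = list(glycans = list(
      glycan_entry("Hex5HexNAc4Fuc1Neu5Ac2", 3.0e7, "neu5ac",
                   list(c(0.9, 0.5), c(1.3, 0.5))),
      glycan_entry("Hex5HexNAc5Fuc1Neu5Ac2", 1.8e7,
                   c("neu5ac", "bisecting"), list(c(1.45, 1))),
      glycan_entry("Hex5HexNAc4Fuc1Neu5Ac4", 0.9e7,
                   c("neu5ac", "disialyl_lewis_c_ac"), list(c(1.7, 1))),
      glycan_entry("Hex3HexNAc5Fuc1", 1.2e7, "bisecting",
                   list(c(1.1, 1)))),
      contaminant = 0),
    kidney = list(glycans = list(
      glycan_entry("Hex6HexNAc5Fuc3", 3.4e7, "fucose_antenna",
                   list(c(1.25, 1))),
      glycan_entry("Hex5HexNAc4Fuc1Neu5Gc2", 2.0e7, "neu5gc",
                   list(c(1.6, 1))),
      glycan_entry("Hex6HexNAc6Fuc3HexA1", 1.0e7,
                   c("fucose_antenna", "hnk1"), list(c(1.4, 1))),
      glycan_entry("Hex7HexNAc4Fuc1", 0.9e7, "alpha_gal", list(c(1.2, 1))),
      glycan_entry("Hex5HexNAc4Fuc1", 1.6e7, character(0),
                   list(c(1.05, 1)))),
      contaminant = 0),
    pancreas = list(glycans = list(
      glycan_entry("Hex7HexNAc4", 2.6e7, "alpha_gal", list(c(1.3, 1))),
      glycan_entry("Hex6HexNAc4Fuc1", 2.2e7, "alpha_gal", list(c(1.35, 1))),
      glycan_entry("Hex5HexNAc4Fuc1SO41", 0.8e7, "sulfo_hexnac",
                   list(c(1.5, 1))),
      glycan_entry("Hex5HexNAc4Neu5Ac1", 0.7e7, "neu5ac", list(c(1.4, 1)))),
      contaminant = 0),
    seminal_vesicle = list(glycans = list(
      glycan_entry("Hex6HexNAc5Fuc4", 3.6e7,
                   c("fucose_antenna", "lewis_y"), list(c(1.2, 1))),
      glycan_entry("Hex5HexNAc4Fuc3", 2.4e7,
                   c("fucose_antenna", "lewis_y"),
                   list(c(1.0, 0.6), c(1.15, 0.4))),
      glycan_entry("Hex7HexNAc5Fuc3", 1.8e7,
                   c("fucose_antenna", "alpha_gal"), list(c(1.3, 1)))),
      contaminant = 0),
    liver = list(glycans = list(
      glycan_entry("Hex5HexNAc4Neu5Gc2", 2.8e7, "neu5gc", list(c(1.55, 1))),
      glycan_entry("Hex5HexNAc4Fuc1Neu5Gc2", 1.5e7, "neu5gc",
                   list(c(1.6, 1))),
      glycan_entry("Hex5HexNAc4Fuc1", 1.1e7, character(0),
                   list(c(1.05, 1)))),
      contaminant = 1.8e8))
  specs <- list()
  for (i in seq_along(tissues)) {
    for (r in seq_len(replicates)) {
      lab <- if (replicates > 1L)
        sprintf("%s_%d", names(tissues)[i], r) else names(tissues)[i]
      specs[[length(specs) + 1L]] <- sample_spec(
        sample = lab, glycans = tissues[[i]]$glycans,
        contaminant_intensity = tissues[[i]]$contaminant,
        seed = seed + 100L * i + r)
    }
  }
  specs
}

#' Run the full pipeline on one simulated sample
#'
#' Convenience wrapper: simulate, score spectra, bin features, apply the
#' intensity threshold, attach spectra, SNOG-filter, annotate, classify.
#'
#' @param spec a `sample_spec`.
#' @param db a `glycodb` (default: canonical enumeration).
#' @param cfg a [run_config()].
#' @return list with `sim` (the [simulate_sample()] output), `scores`,
#'   `raw` (histogram before SNOG filtering), `hist` (filtered, annotated,
#'   classified histogram), `report` (the [tic_fractions()] result).
#' @export
run_pipeline <- function(spec, db = enumerate_glycodb(),
                         cfg = run_config()) {
  sim <- simulate_sample(spec)
  scores <- score_spectra(sim$spectra, tol = cfg$match_tolerance)
  hist <- bin_features(sim$features, cfg)
  hist <- threshold_bins(hist, cfg$intensity_threshold)
  raw <- hist <- attach_spectra(hist, sim$spectra, scores,
                                tol = cfg$match_tolerance)
  hist <- snog_filter(hist, cfg$snog_cutoff)
  hist <- annotate_bins(hist, db, tol = cfg$match_tolerance)
  hist <- classify_bins(hist, scores)
  list(sim = sim, scores = scores, raw = raw, hist = hist,
       report = tic_fractions(hist))
}
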