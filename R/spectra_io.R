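# MGF tandem-spectra I/O, deconvoluted MS1 feature tables, run configuration.

#' Construct an MS/MS spectrum
#'
#' @param id scan identifier (string).
#' @param precursor_mz precursor m/z in amu.
#' @param charge integer charge state (1-6) or `NA` when the instrument did
#'   not assign one.
#' @param rt retention time in seconds (>= 0).
#' @param mz,intensity parallel numeric peak vectors; peaks are stored
#'   sorted by ascending m/z, intensities must be finite and >= 0.
#' @param sample sample label.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(id, precursor_mz, charge = NA_integer_, rt, mz,
                     intensity, sample = "sample") {
  stopifnot(length(mz) == length(intensity))
  if (length(rt) != 1L || is.na(rt) || rt < 0)
    stop("spectrum '", id, "': retention time must be a single value >= 0",
         call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("spectrum '", id, "': intensities must be finite and >= 0",
         call. = FALSE)
  ord <- order(mz)
  structure(list(id = as.character(id),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
                 rt = as.numeric(rt),
                 mz = as.numeric(mz[ord]),
                 intensity = as.numeric(intensity[ord]),
                 sample = as.character(sample)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> m/z %.4f%s, rt %.1f s, %d peaks (%s)\n",
              x$id, x$precursor_mz,
              if (is.na(x$charge)) "" else sprintf(" (%d+)", x$charge),
              x$rt, length(x$mz), x$sample))
  invisible(x)
}

#' Read an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. `PEPMASS` (first value = precursor
#' m/z) and `RTINSECONDS` are required; `CHARGE` (form `N+`) and `TITLE` are
#' optional. Peaks are sorted by ascending m/z.
#'
#' @param path MGF file path.
#' @param sample sample label attached to every spectrum; defaults to the
#'   file name without extension.
#' @return a list of `spectrum` objects, in file order.
#' @export
read_mgf <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sample))
    sample <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) == 0L) {
    warning("no spectra in ", path)
    return(list())
  }
  if (length(starts) != length(ends) || any(ends < starts))
    stop("unbalanced BEGIN IONS/END IONS in ", path, call. = FALSE)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getval <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pepmass <- getval("PEPMASS")
    if (is.na(pepmass))
      stop("MGF block ", i, " in ", path, " has no PEPMASS", call. = FALSE)
    rt <- getval("RTINSECONDS")
    if (is.na(rt))
      stop("MGF block ", i, " in ", path, " has no RTINSECONDS ",
           "(retention time is required by this workflow)", call. = FALSE)
    charge <- getval("CHARGE")
    charge <- if (is.na(charge)) NA_integer_
              else as.integer(sub("[+-]$", "", charge))
    title <- getval("TITLE")
    id <- if (is.na(title)) sprintf("%s.%d", sample, i) else title
    peak_lines <- block[!is_kv & nzchar(trimws(block))]
    pk <- if (length(peak_lines)) {
      do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t]+"),
                            function(f) as.numeric(f[1:2])))
    } else matrix(numeric(0), ncol = 2)
    out[[i]] <- spectrum(id = id,
                         precursor_mz = as.numeric(strsplit(trimws(pepmass),
                                                            "[ \t]+")[[1]][1]),
                         charge = charge,
                         rt = as.numeric(rt),
                         mz = pk[, 1], intensity = pk[, 2],
                         sample = sample)
  }
  out
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: fields and peaks round-trip to at least four
#' decimals. Spectra with unknown charge are written without a CHARGE line.
#'
#' @param spectra list of `spectrum` objects.
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.na(sp$charge))
      writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    writeLines(sprintf("RTINSECONDS=%.4f", sp$rt), con)
    if (length(sp$mz))
      writeLines(sprintf("%.6f %.6f", sp$mz, sp$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read a charge-deconvoluted MS1 feature table
#'
#' Accepts the package's generic CSV dialect (columns `rt_seconds`,
#' `neutral_monoisotopic_mass`, `charge`, `abundance`) or the DeCon2
#' `_isos.csv` dialect (columns `scan_time`/`rt`, `monoisotopic_mw`,
#' `charge`, `abundance`). Neutral monoisotopic masses are converted to the
#' singly-protonated `[M+H]+` scale used throughout. Rows with abundance
#' <= 0 are dropped (count reported via message).
#'
#' @param path CSV path.
#' @param sample sample label; defaults to file name without extension.
#' @return a `data.frame` with columns `mass` (`[M+H]+`, amu), `rt`
#'   (seconds), `intensity`, `sample`.
#' @export
read_features <- function(path, sample = NULL) {
  if (is.null(sample))
    sample <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(choices) {
    hit <- intersect(choices, names(df))
    if (length(hit)) hit[1] else NA_character_
  }
  mass_col <- pick(c("neutral_monoisotopic_mass", "monoisotopic_mw"))
  rt_col <- pick(c("rt_seconds", "scan_time", "rt"))
  ab_col <- pick(c("abundance", "intensity"))
  for (col in c(mass = mass_col, rt = rt_col, abundance = ab_col)) {
    if (is.na(col))
      stop("feature table ", path, " lacks a recognised ",
           "mass/rt/abundance column", call. = FALSE)
  }
  out <- data.frame(mass = df[[mass_col]] + PROTON_MASS,
                    rt = df[[rt_col]],
                    intensity = df[[ab_col]],
                    sample = rep(sample, nrow(df)),
                    stringsAsFactors = FALSE)
  drop <- out$intensity <= 0
  if (any(drop))
    message("read_features: dropped ", sum(drop),
            " feature(s) with non-positive abundance")
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an MS1 feature table (generic dialect)
#'
#' @param features data.frame as returned by [read_features()] (masses on
#'   the `[M+H]+` scale; written back as neutral masses).
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
write_features <- function(features, path) {
  out <- data.frame(rt_seconds = features$rt,
                    neutral_monoisotopic_mass = features$mass - PROTON_MASS,
                    charge = 1L,
                    abundance = features$intensity)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the workflow constants: the precursor mass-bin range and half
#' width, the cumulative intensity threshold, the SNOG cut-off, the
#' fragment matching tolerance and the retention-time bin size.
#'
#' @param bin_low,bin_high precursor histogram range in amu (`[M+H]+`).
#' @param bin_half_width half width of a mass bin in amu (bin width is
#'   twice this).
#' @param intensity_threshold cumulative intensity threshold below which
#'   mass bins are removed.
#' @param snog_cutoff SNOG score below which mass bins are rejected.
#' @param match_tolerance fragment/bin matching tolerance in amu.
#' @param rt_bin retention-time bin size in seconds for spectral counting.
#' @param registry_path optional path to a diagnostic-ion registry TSV
#'   overriding the built-in one.
#' @param score_denominator `"tic"` (total spectrum intensity; default) or
#'   `"base_peak"` for SNOG/eSNOG denominators.
#' @return an object of class `run_config` (a list).
#' @export
run_config <- function(bin_low = 1000, bin_high = 5000,
                       bin_half_width = 0.05, intensity_threshold = 5e6,
                       snog_cutoff = 0.03, match_tolerance = 0.05,
                       rt_bin = 10, registry_path = NULL,
                       score_denominator = c("tic", "base_peak")) {
  score_denominator <- match.arg(score_denominator)
  if (bin_low >= bin_high) stop("bin_low must be < bin_high", call. = FALSE)
  if (bin_half_width <= 0) stop("bin_half_width must be > 0", call. = FALSE)
  if (snog_cutoff < 0 || snog_cutoff > 1)
    stop("snog_cutoff must lie in [0, 1]", call. = FALSE)
  structure(list(bin_low = bin_low, bin_high = bin_high,
                 bin_half_width = bin_half_width,
                 intensity_threshold = intensity_threshold,
                 snog_cutoff = snog_cutoff,
                 match_tolerance = match_tolerance,
                 rt_bin = rt_bin, registry_path = registry_path,
                 score_denominator = score_denominator),
            class = "run_config")
}

#' Read a run configuration from a YAML-style key-value file
#'
#' Keys mirror the arguments of [run_config()]; absent keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

#' Registry for a run configuration
#'
#' @param cfg a `run_config`.
#' @return the ion registry named by `cfg$registry_path`, or the built-in
#'   default.
#' @export
config_registry <- function(cfg) {
  if (is.null(cfg$registry_path)) default_registry()
  else read_registry(cfg$registry_path)
}
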