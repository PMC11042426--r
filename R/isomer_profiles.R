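# Isomer-sensitive elution profiling: Man5-normalized retention times,
# per-mass elution profiles on a common relative-retention grid, and
# profile similarity.
#
# PGC chromatography separates isobaric glycan isomers; retention times
# are expressed relative to the Man5 (Hex5HexNAc2) apex of the same run,
# which cancels run-to-run gradient drift.

#' Man5 reference retention time of a run
#'
#' Retention time of the intensity apex of the Man5 (reduced Hex5HexNAc2
#' `[M+H]+`) mass trace in an MS1 feature table.
#'
#' @param features feature data.frame (`mass`, `rt`, `intensity`).
#' @param tol mass tolerance in amu.
#' @return apex retention time in seconds.
#' @export
man5_rt <- function(features, tol = 0.05) {
  m5 <- precursor_mass("Man5")
  sel <- abs(features$mass - m5) <= tol
  if (!any(sel))
    stop("no Man5 signal within ", tol, " amu; supply the reference ",
         "retention time manually", call. = FALSE)
  f <- features[sel, , drop = FALSE]
  f$rt[which.max(f$intensity)]
}

#' Normalize a retention time to the Man5 reference
#'
#' Relative retention: `rt / man5`.
#'
#' @param rt retention time(s) in seconds.
#' @param man5 Man5 apex retention time in seconds (> 0).
#' @return relative retention (dimensionless).
#' @export
normalize_rt <- function(rt, man5) {
  if (!isTRUE(man5 > 0)) stop("Man5 reference must be > 0", call. = FALSE)
  rt / man5
}

#' Elution profile of one precursor mass
#'
#' Intensity versus Man5-normalized retention time for all MS1 features
#' within `tol` of the target mass, resampled onto a fixed relative-
#' retention grid by local summation (each feature's intensity is added to
#' the nearest grid point). Profiles built on the same grid are directly
#' comparable across samples.
#'
#' @param features feature data.frame (`mass`, `rt`, `intensity`,
#'   optionally `sample`).
#' @param mass target `[M+H]+` mass in amu (or a composition, from which
#'   the reduced `[M+H]+` is taken).
#' @param man5 Man5 apex retention time in seconds.
#' @param tol mass tolerance in amu.
#' @param grid_step grid spacing in relative-retention units (default
#'   0.005).
#' @param grid_range relative-retention span of the grid.
#' @param smooth apply a centered moving average (window 3) to the gridded
#'   intensities.
#' @return a list of class `elution_profile`: `sample`, `mass`, `man5`,
#'   `grid` (relative retention), `intensity` (same length).
#' @export
elution_profile <- function(features, mass, man5, tol = 0.05,
                            grid_step = 0.005, grid_range = c(0, 3),
                            smooth = FALSE) {
  if (!is.numeric(mass)) mass <- precursor_mass(mass)
  sel <- abs(features$mass - mass) <= tol
  grid <- seq(grid_range[1], grid_range[2], by = grid_step)
  intens <- numeric(length(grid))
  sample <- if ("sample" %in% names(features) && nrow(features))
    features$sample[1] else NA_character_
  if (!any(sel)) {
    warning("no features within ", tol, " amu of ", round(mass, 4))
  } else {
    f <- features[sel, , drop = FALSE]
    rel <- normalize_rt(f$rt, man5)
    idx <- round((rel - grid_range[1]) / grid_step) + 1L
    ok <- idx >= 1L & idx <= length(grid)
    for (i in which(ok)) intens[idx[i]] <- intens[idx[i]] + f$intensity[i]
    if (any(!ok))
      warning(sum(!ok), " feature(s) outside the relative-retention grid")
  }
  if (smooth)
    intens <- stats::filter(intens, rep(1 / 3, 3), sides = 2) |>
      (\(x) { x[is.na(x)] <- intens[is.na(x)]; as.numeric(x) })()
  structure(list(sample = sample, mass = mass, man5 = man5, grid = grid,
                 intensity = intens),
            class = "elution_profile")
}

#' @export
print.elution_profile <- function(x, ...) {
  cat(sprintf("<elution profile> %s @ %.4f amu: %d grid points, area %.3g\n",
              x$sample, x$mass, length(x$grid), sum(x$intensity)))
  invisible(x)
}

#' Modes (local apices) of an elution profile
#'
#' @param profile an `elution_profile`.
#' @param min_fraction a grid point counts as a mode when it is a local
#'   maximum holding at least this fraction of the profile's top
#'   intensity.
#' @return numeric vector of relative retention positions.
#' @export
profile_modes <- function(profile, min_fraction = 0.1) {
  y <- profile$intensity
  if (!any(y > 0)) return(numeric(0))
  thr <- min_fraction * max(y)
  n <- length(y)
  left <- c(-Inf, y[-n]); right <- c(y[-1], -Inf)
  profile$grid[y >= thr & y > left & y >= right]
}

#' Cosine similarity of two elution profiles
#'
#' Scale-invariant similarity on the shared relative-retention grid; 0
#' when either profile is all-zero.
#'
#' @param p,q `elution_profile` objects on identical grids.
#' @return similarity in `[0, 1]` (non-negative intensities).
#' @export
profile_similarity <- function(p, q) {
  if (length(p$grid) != length(q$grid) ||
      any(abs(p$grid - q$grid) > 1e-12))
    stop("profiles are not on a common grid", call. = FALSE)
  np <- sqrt(sum(p$intensity^2)); nq <- sqrt(sum(q$intensity^2))
  if (np == 0 || nq == 0) return(0)
  sum(p$intensity * q$intensity) / (np * nq)
}
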