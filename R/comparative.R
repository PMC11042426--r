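# Cross-sample comparison: sample x mass-bin matrix, Pearson correlation,
# Ward hierarchical clustering with Newick export.

#' Assemble a sample x mass-bin intensity matrix
#'
#' Takes the union of bin centers over all histograms, TIC-normalizes each
#' sample, and fills absent bins with 0.
#'
#' @param histograms list of (SNOG-filtered) `glyco_histogram` objects
#'   with unique sample labels; at least two.
#' @return numeric matrix, rows = samples (sorted by label), columns =
#'   bin centers; each row sums to 1.
#' @export
build_sample_matrix <- function(histograms) {
  if (length(histograms) < 2L)
    stop("need at least two histograms to compare", call. = FALSE)
  labs <- vapply(histograms, `[[`, character(1), "sample")
  if (anyDuplicated(labs))
    stop("duplicate sample labels: ",
         paste(labs[duplicated(labs)], collapse = ", "), call. = FALSE)
  centers <- sort(unique(unlist(lapply(histograms, function(h)
    h$bins$center))))
  m <- matrix(0, nrow = length(histograms), ncol = length(centers),
              dimnames = list(labs, format(centers, trim = TRUE,
                                           scientific = FALSE)))
  for (i in seq_along(histograms)) {
    h <- tic_normalize(histograms[[i]])
    m[i, match(h$bins$center, centers)] <- h$bins$intensity
  }
  m[order(rownames(m)), , drop = FALSE]
}

#' Pearson correlation between samples
#'
#' @param mat matrix from [build_sample_matrix()] (rows = samples).
#' @return symmetric correlation matrix with unit diagonal; rows with zero
#'   variance yield `NA` entries (with a warning).
#' @export
sample_correlation <- function(mat) {
  v <- apply(mat, 1L, stats::var)
  if (any(v == 0))
    warning("zero-variance sample(s): ",
            paste(rownames(mat)[v == 0], collapse = ", "),
            "; correlations set to NA")
  suppressWarnings(stats::cor(t(mat), method = "pearson"))
}

#' Ward clustering of samples
#'
#' Agglomerative clustering (Ward's method, `"ward.D2"`) on Euclidean
#' distances between TIC-normalized bin vectors. Rows are pre-sorted by
#' label so leaf order is deterministic.
#'
#' @param mat matrix from [build_sample_matrix()].
#' @return an `hclust` object.
#' @export
cluster_samples <- function(mat) {
  d <- stats::dist(mat[order(rownames(mat)), , drop = FALSE])
  if (any(!is.finite(d)))
    stop("non-finite distances between samples", call. = FALSE)
  stats::hclust(d, method = "ward.D2")
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths.
#'
#' @param hc an `hclust` object.
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
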