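# Cross-validated principal-component spectra and participation-ratio
# dimensionality.

#' Cross-validated variance spectrum
#'
#' Randomly splits the patterns into two non-overlapping subsets, finds
#' the principal axes of the first, and estimates the variance explained
#' by each axis as the variance of the second subset projected onto it.
#' Patterns are mean-centered per pixel (column) across the whole
#' ensemble before splitting.
#'
#' @param x N x P matrix (rows = patterns) or a [pattern_ensemble()]
#' @param split_fraction fraction of patterns in the training subset
#' @param seed RNG seed for the split
#' @param center mean-center columns first? (default TRUE)
#' @return an object of class `spectrum_estimate`: list with `lambda`
#'   (projected variances, ordered by training-axis eigenvalue), `idx_train`,
#'   `n_train`, `n_test`, `seed`
#' @export
crossval_spectrum <- function(x, split_fraction = 0.5, seed = 1L, center = TRUE) {
  if (inherits(x, "pattern_ensemble")) x <- ens_matrix(x)$A
  n <- nrow(x)
  stopif(n < 4, "need at least 4 patterns for a cross-validated spectrum")
  keep <- colSums(!is.finite(x)) == 0
  x <- x[, keep, drop = FALSE]
  if (center) x <- sweep(x, 2, colMeans(x))
  idx1 <- with_seed(derive_seed(seed, "split"),
                    sort(sample(n, max(2, floor(n * split_fraction)))))
  x1 <- x[idx1, , drop = FALSE]
  x2 <- x[-idx1, , drop = FALSE]
  sv <- svd(x1, nu = 0)
  proj <- x2 %*% sv$v
  lambda <- apply(proj, 2, stats::var)
  structure(list(lambda = lambda, idx_train = idx1,
                 n_train = nrow(x1), n_test = nrow(x2), seed = seed),
            class = "spectrum_estimate")
}

#' Participation ratio
#'
#' Effective dimensionality of a variance spectrum:
#' `d_eff = (sum lambda)^2 / sum(lambda^2)`. Equals the number of
#' components when all variances are equal, and 1 for a rank-1 spectrum.
#' Negative entries (possible for cross-validated projected variances)
#' are clipped to zero before evaluation.
#'
#' @param lambda numeric vector of variances (or a `spectrum_estimate`)
#' @return the participation ratio (scalar)
#' @export
participation_ratio <- function(lambda) {
  if (inherits(lambda, "spectrum_estimate")) lambda <- lambda$lambda
  lambda <- pmax(lambda, 0)
  s <- sum(lambda)
  stopif(s <= 0, "all-zero variance spectrum")
  s^2 / sum(lambda^2)
}

#' Components needed for 75% of the variance
#'
#' Smallest number of components (in descending variance order) whose
#' cumulative share reaches `fraction` of the total.
#'
#' @param lambda numeric vector of variances (or a `spectrum_estimate`)
#' @param fraction cumulative variance fraction (default 0.75)
#' @return integer count
#' @export
variance_75_count <- function(lambda, fraction = 0.75) {
  if (inherits(lambda, "spectrum_estimate")) lambda <- lambda$lambda
  lambda <- pmax(lambda, 0)
  s <- sum(lambda)
  stopif(s <= 0, "all-zero variance spectrum")
  cs <- cumsum(sort(lambda, decreasing = TRUE)) / s
  which(cs >= fraction - 1e-12)[1]
}

#' Cross-validated dimensionality of a pattern ensemble
#'
#' Averages the participation ratio of [crossval_spectrum()] over several
#' random splits.
#'
#' @param x N x P matrix or [pattern_ensemble()]
#' @param n_splits number of random splits to average over
#' @param seed RNG seed
#' @return list with `d_eff` (mean over splits), `n_variance_75` (mean),
#'   `per_split` (data.frame), `n_splits`
#' @export
widefield_dimensionality <- function(x, n_splits = 20, seed = 1L) {
  per <- vapply(seq_len(n_splits), function(s) {
    sp <- crossval_spectrum(x, seed = derive_seed(seed, paste0("wfdim", s)))
    c(participation_ratio(sp), variance_75_count(sp))
  }, numeric(2))
  list(d_eff = mean(per[1, ]), n_variance_75 = mean(per[2, ]),
       per_split = data.frame(split = seq_len(n_splits),
                              d_eff = per[1, ], n_variance_75 = per[2, ]),
       n_splits = n_splits)
}

#' Cross-validated dimensionality of cellular activity
#'
#' Draws random samples of cells and event frames (without replacement),
#' computes the cross-validated participation ratio on each sample, and
#' averages, controlling for sample size across recordings.
#'
#' @param cell_event_matrix events x cells matrix of event-frame activity
#' @param n_cells_subset cells per sample (reduced with a warning if the
#'   recording has fewer)
#' @param n_frames_subset event frames per sample (reduced likewise)
#' @param n_samples number of random samples
#' @param seed RNG seed
#' @return list with `d_eff` (mean over samples), `n_variance_75`,
#'   `per_sample`, `n_cells_used`, `n_frames_used`
#' @export
cellular_dimensionality <- function(cell_event_matrix, n_cells_subset = 50,
                                    n_frames_subset = 100, n_samples = 100,
                                    seed = 1L) {
  m <- as.matrix(cell_event_matrix)
  stopif(nrow(m) < 4, "need at least 4 events")
  stopif(stats::sd(m) == 0, "degenerate (constant) cell-event matrix")
  nc <- ncol(m); ne <- nrow(m)
  if (nc < n_cells_subset) {
    warning("only ", nc, " cells available; using all")
    n_cells_subset <- nc
  }
  if (ne < n_frames_subset) {
    warning("only ", ne, " event frames available; using all")
    n_frames_subset <- ne
  }
  per <- with_seed(derive_seed(seed, "celldim"), {
    vapply(seq_len(n_samples), function(s) {
      cells <- sample(nc, n_cells_subset)
      frames <- sample(ne, n_frames_subset)
      sp <- crossval_spectrum(m[frames, cells, drop = FALSE],
                              seed = derive_seed(seed, paste0("cdsplit", s)))
      c(participation_ratio(sp), variance_75_count(sp))
    }, numeric(2))
  })
  list(d_eff = mean(per[1, ]), n_variance_75 = mean(per[2, ]),
       per_sample = data.frame(sample = seq_len(n_samples),
                               d_eff = per[1, ], n_variance_75 = per[2, ]),
       n_cells_used = n_cells_subset, n_frames_used = n_frames_subset)
}
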