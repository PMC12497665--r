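#' Equal-frequency discretization for mutual-information estimation
#'
#' Cuts a continuous feature at its empirical quantiles into (up to)
#' `nbins` bins; ties can merge bins, constant features collapse to one.
#'
#' @param x numeric vector.
#' @param nbins number of bins.
#' @return integer vector of bin ids (1-based).
#' @export
discretize_equal_frequency <- function(x, nbins = 10) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nbins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Mutual information of two discrete variables
#'
#' Plug-in estimate from the joint contingency table, in bits.
#'
#' @param a,b integer/factor vectors of equal length.
#' @return scalar MI >= 0.
#' @export
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' mRMR feature ranking (MID scheme)
#'
#' Greedy minimum-redundancy maximum-relevance ranking: the first feature
#' maximizes mutual information with the binary target; feature k maximizes
#' `I(f; target) - mean over selected s of I(f; s)`. Mutual information is
#' estimated after discretizing each feature into 10 equal-frequency bins.
#' Constant features have zero relevance and fall to the tie-break, which
#' is deterministic lexicographic feature-name order.
#'
#' @param x numeric matrix or data.frame of candidate features (columns).
#' @param target binary vector (0/1) of length `nrow(x)`.
#' @param max_features ranking length cap (default 20, for model
#'   interpretability).
#' @param nbins equal-frequency bins for MI estimation.
#' @return A `mrmr_ranking`: `features` (ordered names) and `scores`
#'   (relevance minus redundancy at each step).
#' @export
mrmr_rank <- function(x, target, max_features = 20, nbins = 10) {
  x <- as.matrix(x)
  if (ncol(x) < 1) stop("need at least one candidate feature")
  if (length(unique(target)) < 2) stop("binary target required")
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(x)))
  disc <- lapply(seq_len(ncol(x)), function(j)
    discretize_equal_frequency(x[, j], nbins))
  names(disc) <- nm
  relevance <- vapply(disc, function(d) mutual_information(d, target), 0)

  k <- min(max_features, ncol(x))
  selected <- character(0)
  scores <- numeric(0)
  redundancy_sum <- stats::setNames(numeric(length(nm)), nm)
  remaining <- nm[order(nm)]                 # lexicographic tie-break base
  for (step in seq_len(k)) {
    score <- relevance[remaining]
    if (step > 1)
      score <- score - redundancy_sum[remaining] / length(selected)
    best <- remaining[which.max(score)]      # first max = lexicographic tie
    selected <- c(selected, best)
    scores <- c(scores, unname(score[best]))
    remaining <- setdiff(remaining, best)
    if (length(remaining) == 0) break
    for (f in remaining)
      redundancy_sum[f] <- redundancy_sum[f] +
        mutual_information(disc[[f]], disc[[best]])
  }
  structure(list(features = selected, scores = scores), class = "mrmr_ranking")
}
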