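#' Pairwise probe correlation matrix
#'
#' Pearson correlations across samples on pairwise-complete observations.
#' Pairs with fewer than `min_overlap` shared samples, and pairs where a
#' probe has zero variance within the overlap, are set to 0 (counted in the
#' `n_zeroed` attribute, with a warning when nonzero).
#'
#' @param residuals probe x sample residual matrix.
#' @param min_overlap minimum shared non-missing samples per pair.
#' @return probe x probe correlation matrix, unit diagonal.
#' @export
pairwise_correlation <- function(residuals, min_overlap = 3) {
  residuals <- as.matrix(residuals)
  cc <- suppressWarnings(cor(t(residuals), use = "pairwise.complete.obs"))
  n_zeroed <- 0L
  if (anyNA(residuals)) {
    obs <- crossprod(!is.na(t(residuals)))
    low <- obs < min_overlap
    diag(low) <- FALSE
    n_zeroed <- n_zeroed + sum(low)
    cc[low] <- 0
  }
  bad <- is.na(cc)
  diag(bad) <- FALSE
  n_zeroed <- n_zeroed + sum(bad)
  cc[bad] <- 0
  diag(cc) <- 1
  if (n_zeroed > 0)
    warning(n_zeroed, " correlation entries set to 0 (low overlap or zero variance)")
  attr(cc, "n_zeroed") <- n_zeroed
  cc
}

#' Soft-thresholded adjacency
#'
#' Unsigned weighted adjacency `a_ij = |cor_ij|^beta`, diagonal zeroed so
#' connectivity sums exclude self-edges.
#'
#' @param cor correlation matrix.
#' @param power soft-threshold exponent beta.
#' @return adjacency matrix in \[0,1\] with attribute `power_beta`.
#' @export
adjacency_matrix <- function(cor, power) {
  stopifnot(power > 0)
  a <- abs(cor)^power
  diag(a) <- 0
  attr(a, "power_beta") <- power
  a
}

#' Scale-free topology fit index
#'
#' Bins connectivities into `n_bins` equal-width bins and regresses
#' log10(frequency) on log10(mean connectivity) over non-empty bins. The
#' returned index is the regression R^2 signed so that a negative slope
#' (scale-free-like decay) gives a positive value.
#'
#' @param k vector of positive connectivities.
#' @param n_bins number of bins (>= 3).
#' @return signed R^2 in \[-1, 1\].
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (n_bins < 3) stop("n_bins must be >= 3")
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_bins) stop("too few positive connectivities")
  if (diff(range(k)) == 0)
    stop("fewer than 3 non-empty bins; connectivity range degenerate")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-12
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mean_k <- vapply(seq_len(n_bins),
                   function(b) mean(k[as.integer(bin) == b]), numeric(1))
  ok <- freq > 0 & is.finite(mean_k) & mean_k > 0
  if (sum(ok) < 3) stop("fewer than 3 non-empty bins; connectivity range degenerate")
  x <- log10(mean_k[ok]); y <- log10(freq[ok] / sum(freq))
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  -sign(stats::coef(fit)[["x"]]) * r2
}

#' Scan candidate soft powers for scale-free fit
#'
#' @param cor correlation matrix.
#' @param powers ascending candidate exponents.
#' @param n_bins bins for [scale_free_fit()].
#' @return data.frame: power, scale_free_r2, mean_connectivity.
#' @export
soft_power_scan <- function(cor, powers = 1:20, n_bins = 10) {
  ac <- abs(cor); diag(ac) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(ac^b)
    r2 <- tryCatch(scale_free_fit(k, n_bins), error = function(e) NA_real_)
    data.frame(power = b, scale_free_r2 = r2, mean_connectivity = mean(k))
  })
  do.call(rbind, rows)
}

#' Choose the soft-threshold power
#'
#' Smallest power whose scale-free fit R^2 exceeds `r2_threshold`; if none
#' qualifies, the power with maximal R^2 is returned with
#' `attr(, "below_threshold") = TRUE` and a warning.
#'
#' @param cor correlation matrix (or pass a precomputed `scan`).
#' @param powers ascending candidate exponents.
#' @param r2_threshold fit threshold (default 0.9).
#' @param scan optional precomputed [soft_power_scan()] table.
#' @return chosen power (numeric scalar) with attributes `scan` and
#'   `below_threshold`.
#' @export
pick_soft_power <- function(cor = NULL, powers = 1:20, r2_threshold = 0.9,
                            scan = NULL) {
  if (is.null(scan)) scan <- soft_power_scan(cor, powers)
  if (is.unsorted(scan$power)) stop("powers must be ascending")
  ok <- which(!is.na(scan$scale_free_r2) & scan$scale_free_r2 > r2_threshold)
  if (length(ok) > 0) {
    beta <- scan$power[ok[1]]
    below <- FALSE
  } else {
    if (all(is.na(scan$scale_free_r2))) stop("no usable scale-free fit at any power")
    beta <- scan$power[which.max(scan$scale_free_r2)]
    below <- TRUE
    warning("no power reached R^2 > ", r2_threshold,
            "; using argmax R^2 (power ", beta, ")")
  }
  attr(beta, "scan") <- scan
  attr(beta, "below_threshold") <- below
  beta
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j, with unit diagonal; shared-neighbour agreement augments the direct
#' adjacency so weak spurious edges are down-weighted.
#'
#' @param adjacency symmetric matrix in \[0,1\] with zero diagonal.
#' @return TOM matrix in \[0,1\], unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  check_square_symmetric(a, tol = 1e-10, what = "adjacency")
  if (min(a) < -1e-12 || max(a) > 1 + 1e-12) stop("adjacency values outside [0,1]")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by tree cutting of the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `d = 1 - TOM`, followed by a
#' height-scan tree cut: candidate static cuts are taken between successive
#' merge heights and the cut producing the most clusters of size
#' `>= min_module_size` is kept (ties broken toward the higher cut). Clusters
#' below the size floor are left unassigned (label 0). Labels are renumbered
#' in descending order of module size and given color aliases.
#'
#' @param tom TOM matrix (or set `dissimilarity` directly).
#' @param min_module_size minimum probes per module (>= 2).
#' @param dissimilarity optional precomputed dissimilarity matrix overriding
#'   `1 - tom`.
#' @return a `cometh_modules` list: `labels` (named integer vector, 0 =
#'   unassigned), `colors`, `tree` (hclust), `cut_height`, `sizes`.
#' @export
detect_modules <- function(tom, min_module_size = 30, dissimilarity = NULL) {
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  d <- if (is.null(dissimilarity)) 1 - as.matrix(tom) else as.matrix(dissimilarity)
  n <- nrow(d)
  if (n < min_module_size) stop("fewer probes than min_module_size")
  ids <- rownames(d) %||% paste0("p", seq_len(n))
  hc <- hclust(stats::as.dist(d), method = "average")

  h <- sort(unique(hc$height))
  cand <- if (length(h) > 1) (h[-1] + h[-length(h)]) / 2 else h
  cand <- c(cand, max(h) * (1 - 1e-9))
  # lowest cut achieving the maximal number of size-qualified branches:
  # later merges attach loose probes/background, which stay unassigned
  best_k <- -1L; best_h <- NA_real_; best_cl <- rep(1L, n)
  for (cut_h in cand) {
    cl <- cutree(hc, h = cut_h)
    k_big <- sum(table(cl) >= min_module_size)
    if (k_big > best_k) {
      best_k <- k_big; best_h <- cut_h; best_cl <- cl
    }
  }

  sizes <- table(best_cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- integer(n)
  if (length(keep) > 0) {
    ord <- keep[order(-sizes[as.character(keep)])]
    for (j in seq_along(ord)) labels[best_cl == ord[j]] <- j
  }
  names(labels) <- ids
  structure(list(labels = labels, colors = module_colors(labels),
                 tree = hc, cut_height = best_h,
                 sizes = if (any(labels > 0)) table(labels[labels > 0]) else table(integer(0))),
            class = "cometh_modules")
}
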