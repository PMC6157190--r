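#' Binarize a correlation matrix into a (0,1)-adjacency
#'
#' Edge between i and j iff `|cor_ij| >= tau` (inclusive by default; a
#' threshold of 0.2 gives a nearly scale-free network on this kind of data).
#'
#' @param cor correlation matrix.
#' @param tau threshold in (0,1).
#' @param inclusive compare with `>=` (default) or `>`.
#' @return binary 0/1 matrix, zero diagonal, attribute `tau`.
#' @export
binarize_network <- function(cor, tau = 0.2, inclusive = TRUE) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0,1)")
  b <- if (inclusive) (abs(cor) >= tau) * 1 else (abs(cor) > tau) * 1
  diag(b) <- 0
  attr(b, "tau") <- tau
  b
}

#' One-step topological overlap weights of a binary network
#'
#' `w_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 - a_ij)` for i != j
#' and `w_ii = 0`; a disconnected pair with no shared neighbours gets weight
#' 0. These weights carry the local neighbourhood structure into the GHD.
#'
#' @param net binary adjacency (from [binarize_network()]).
#' @return weight matrix in \[0,1\], zero diagonal.
#' @export
binary_tom_weights <- function(net) {
  a <- as.matrix(net)
  check_square_symmetric(a, tol = 1e-10, what = "binary adjacency")
  diag(a) <- 0
  k <- rowSums(a)
  w <- (a %*% a + a) / (outer(k, k, pmin) + 1 - a)
  diag(w) <- 0
  dimnames(w) <- dimnames(a)
  w
}

#' Generalized Hamming distance between two weighted networks
#'
#' Each weight matrix is centered by its off-diagonal mean (location
#' invariance), then
#' `GHD = (1/(n(n-1))) * sum_{i != j} (wA_ij - wB_ij)^2`.
#'
#' @param W_A,W_B weight matrices on the same probes in the same order.
#' @return nonnegative scalar.
#' @export
ghd_statistic <- function(W_A, W_B) {
  n <- nrow(W_A)
  if (n < 3) stop("need at least 3 nodes")
  if (!all(dim(W_A) == dim(W_B))) stop("weight matrices must match")
  off <- !diag(TRUE, n)
  a <- W_A[off] - mean(W_A[off])
  b <- W_B[off] - mean(W_B[off])
  sum((a - b)^2) / (n * (n - 1))
}

#' Permutation-null moments of the GHD
#'
#' Node labels of network A are permuted (simultaneous row/column
#' permutation of the weight matrix — relabeling a graph commutes with the
#' topological-overlap weights, so the weights need not be recomputed) and
#' the GHD against B recomputed per permutation; the sample mean and
#' variance define the approximately normal null.
#'
#' @param W_A,W_B weight matrices.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list: `mu_pi`, `sigma2_pi`, `n_perm`, `ghds` (the permuted values).
#' @export
ghd_null_moments <- function(W_A, W_B, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- nrow(W_A)
  set.seed(seed)
  ghds <- vapply(seq_len(n_perm), function(b) {
    pi <- sample.int(n)
    ghd_statistic(W_A[pi, pi], W_B)
  }, numeric(1))
  s2 <- var(ghds)
  if (!is.finite(s2) || s2 == 0)
    stop(structure(class = c("cometh_ghd_degenerate", "error", "condition"),
                   list(message = "degenerate permutation null: GHD variance is zero",
                        call = sys.call(-1))))
  list(mu_pi = mean(ghds), sigma2_pi = s2, n_perm = n_perm, ghds = ghds)
}

#' GHD test of per-module topological change
#'
#' For each pre-treatment module, both correlation matrices are restricted to
#' the module's probes, binarized at `tau`, converted to one-step topological
#' overlap weights, and compared by GHD. The observed GHD is standardized
#' against the permutation null, `z = (GHD - mu_pi)/sigma_pi`, with two-sided
#' normal p-value `2 * (1 - Phi(|z|))`. Under the null the two module
#' networks are independent; a small p (below the Bonferroni level
#' `alpha / m`) rejects independence, i.e. the module shows no structural
#' change ("preserved"). Modules with fewer than 3 probes after restriction
#' are skipped with a warning; a degenerate null (e.g. an empty network)
#' yields NA statistics.
#'
#' @param pre_cor,post_cor probe correlation matrices on the same probes.
#' @param modules `cometh_modules` or named label vector (0 ignored).
#' @param tau binarization threshold.
#' @param alpha family-wise error level for the Bonferroni decision.
#' @param n_perm permutations per module.
#' @param seed global seed (per-module seeds are derived from it).
#' @return data.frame: module, color, n_probes, ghd, mu_pi, sigma_pi, z,
#'   p_value, preserved; attribute `bonferroni` = alpha/m.
#' @export
ghd_test <- function(pre_cor, post_cor, modules, tau = 0.2, alpha = 0.05,
                     n_perm = 1000, seed = 1) {
  labels <- if (inherits(modules, "cometh_modules")) modules$labels else modules
  probe_ids <- rownames(pre_cor)
  stopifnot(identical(probe_ids, rownames(post_cor)))
  labs <- sort(setdiff(unique(labels), 0L))
  m <- length(labs)
  cols <- module_colors(labels)
  rows <- lapply(seq_along(labs), function(j) {
    l <- labs[j]
    member <- names(labels)[labels == l]
    idx <- if (is.null(probe_ids)) which(labels == l) else which(probe_ids %in% member)
    row <- data.frame(module = l, color = cols[which(labels == l)[1]],
                      n_probes = length(idx), ghd = NA_real_,
                      mu_pi = NA_real_, sigma_pi = NA_real_,
                      z = NA_real_, p_value = NA_real_, preserved = NA)
    if (length(idx) < 3) {
      warning("module ", l, " has fewer than 3 probes after restriction; skipped")
      return(row)
    }
    wa <- binary_tom_weights(binarize_network(pre_cor[idx, idx], tau))
    wb <- binary_tom_weights(binarize_network(post_cor[idx, idx], tau))
    g <- ghd_statistic(wa, wb)
    mom <- tryCatch(
      ghd_null_moments(wa, wb, n_perm, seed = spawn_seed(seed, paste0("ghd", l))),
      cometh_ghd_degenerate = function(e) { warning(conditionMessage(e)); NULL })
    row$ghd <- g
    if (!is.null(mom)) {
      row$mu_pi <- mom$mu_pi
      row$sigma_pi <- sqrt(mom$sigma2_pi)
      row$z <- (g - mom$mu_pi) / row$sigma_pi
      row$p_value <- 2 * pnorm(-abs(row$z))
      row$preserved <- row$p_value < alpha / m
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- alpha / m
  out
}
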