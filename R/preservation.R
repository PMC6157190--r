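#' Build a weighted correlation network from residuals
#'
#' Computes the probe correlation matrix, chooses the soft power (smallest
#' with scale-free R^2 above the threshold, unless given), and forms the
#' unsigned adjacency.
#'
#' @param residuals probe x sample residual matrix.
#' @param power "auto" or a fixed exponent.
#' @param powers candidate powers for the auto scan.
#' @param r2_threshold scale-free fit threshold.
#' @return a `cometh_network` list: `cor`, `adjacency`, `power`, `scan`.
#' @export
build_network <- function(residuals, power = "auto", powers = 1:20,
                          r2_threshold = 0.9) {
  cc <- pairwise_correlation(residuals)
  scan <- NULL
  if (identical(power, "auto")) {
    beta <- suppressWarnings(pick_soft_power(cc, powers, r2_threshold))
    scan <- attr(beta, "scan")
    power <- as.numeric(beta)
  }
  structure(list(cor = cc, adjacency = adjacency_matrix(cc, power),
                 power = power, scan = scan),
            class = "cometh_network")
}

# the four preservation statistics for one probe set:
# density (test network): mean within-set correlation and adjacency;
# connectivity (ref vs test): correlation of intramodular connectivities and
# of the vectorized within-set correlation entries.
preservation_stats <- function(ref, test, idx) {
  lower <- lower.tri(matrix(0, length(idx), length(idx)))
  rc <- ref$cor[idx, idx]; tc <- test$cor[idx, idx]
  ra <- ref$adjacency[idx, idx]; ta <- test$adjacency[idx, idx]
  kim_r <- rowSums(ra); kim_t <- rowSums(ta)
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  c(mean_cor = mean(tc[lower]),
    mean_adj = mean(ta[lower]),
    cor_kIM = safe_cor(kim_r, kim_t),
    cor_cor = safe_cor(rc[lower], tc[lower]))
}

#' Observed preservation statistics per module
#'
#' @param ref,test `cometh_network` objects on the same probes (reference =
#'   pre-treatment, test = post-treatment).
#' @param modules a `cometh_modules` object or named label vector.
#' @return matrix (modules x 4 statistics).
#' @export
observed_stats <- function(ref, test, modules) {
  labels <- if (inherits(modules, "cometh_modules")) modules$labels else modules
  stopifnot(identical(rownames(ref$cor), rownames(test$cor)))
  labs <- sort(setdiff(unique(labels), 0L))
  out <- t(vapply(labs, function(l) {
    idx <- which(labels == l)
    if (length(idx) < 3) stop("module ", l, " has fewer than 3 probes")
    preservation_stats(ref, test, idx)
  }, numeric(4)))
  rownames(out) <- labs
  out
}

#' Permutation-based module preservation (Z_summary, medianRank)
#'
#' For each permutation every module is assigned a random probe set of its
#' own size; the four preservation statistics are recomputed on that set in
#' both networks, giving a null mean and SD per module and statistic.
#' `Z = (observed - mean_null) / sd_null`; `Z_density` is the median of the
#' two density Zs, `Z_connectivity` the median of the two connectivity Zs,
#' and `Z_summary` their average. `medianRank` is the median across
#' statistics of the module's rank (1 = highest observed value; ties get
#' average ranks) and does not depend on the permutations. Interpretation:
#' Z_summary > 10 strong evidence of preservation, 2-10 weak, < 2 none.
#'
#' @inheritParams observed_stats
#' @param n_perm number of permutations (>= 50).
#' @param seed RNG seed.
#' @return data.frame per module: module, color, n_probes, Z for each
#'   statistic, Z_density, Z_connectivity, Z_summary, median_rank, category.
#' @export
module_preservation <- function(ref, test, modules, n_perm = 200, seed = 1) {
  if (n_perm < 50) stop("n_perm must be >= 50")
  labels <- if (inherits(modules, "cometh_modules")) modules$labels else modules
  obs <- observed_stats(ref, test, labels)
  labs <- as.integer(rownames(obs))
  sizes <- vapply(labs, function(l) sum(labels == l), integer(1))
  n <- nrow(ref$cor)

  set.seed(seed)
  null_arr <- array(NA_real_, c(n_perm, length(labs), 4))
  for (b in seq_len(n_perm)) {
    for (j in seq_along(labs)) {
      idx <- sample.int(n, sizes[j])
      null_arr[b, j, ] <- preservation_stats(ref, test, idx)
    }
  }
  mu <- apply(null_arr, c(2, 3), mean, na.rm = TRUE)
  sdv <- apply(null_arr, c(2, 3), sd, na.rm = TRUE)
  Z <- (obs - mu) / sdv
  deg <- !is.na(sdv) & sdv <= 1e-12
  if (any(deg)) {
    warning("degenerate permutation null (sd ~ 0); Z set to +/-Inf")
    Z[deg] <- ifelse(obs[deg] >= mu[deg], Inf, -Inf)
  }

  z_density <- apply(Z[, c("mean_cor", "mean_adj"), drop = FALSE], 1,
                     median, na.rm = TRUE)
  z_conn <- apply(Z[, c("cor_kIM", "cor_cor"), drop = FALSE], 1,
                  median, na.rm = TRUE)
  z_summary <- (z_density + z_conn) / 2

  # rank 1 = highest observed statistic; median over the four statistics
  ranks <- apply(-obs, 2, rank, ties.method = "average", na.last = "keep")
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  median_rank <- apply(ranks, 1, median, na.rm = TRUE)

  category <- ifelse(z_summary > 10, "strong",
                     ifelse(z_summary >= 2, "weak", "none"))
  cols <- module_colors(labels)
  data.frame(module = labs,
             color = vapply(labs, function(l) cols[which(labels == l)[1]], character(1)),
             n_probes = sizes,
             Z_mean_cor = Z[, "mean_cor"], Z_mean_adj = Z[, "mean_adj"],
             Z_cor_kIM = Z[, "cor_kIM"], Z_cor_cor = Z[, "cor_cor"],
             Z_density = z_density, Z_connectivity = z_conn,
             Z_summary = z_summary, median_rank = median_rank,
             category = category, row.names = NULL)
}
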