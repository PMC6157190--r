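#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two labelings of the same items, corrected for
#' chance; 1 = identical partitions, ~0 = independent.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

# derive a per-stage seed from a global seed; kept < 2^31
spawn_seed <- function(seed, stage) {
  stage_num <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + stage_num) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

check_square_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(what, " is not symmetric (tolerance ", tol, ")", call. = FALSE)
  invisible(TRUE)
}

# subset a kinship matrix to the given sample ids; unnamed matrices must
# already align
align_kinship <- function(K, ids) {
  if (!is.null(dimnames(K))) return(K[ids, ids, drop = FALSE])
  if (nrow(K) != length(ids)) stop("kinship matrix does not align with samples")
  K
}
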