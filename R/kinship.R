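#' Expected-relatedness matrix from a pedigree
#'
#' Computes the additive relationship matrix (twice the kinship coefficient)
#' by the standard tabular recursion. Founders have unknown parents (NA, "0"
#' or ""). The diagonal is 1 for non-inbred individuals; parent-offspring and
#' full-sib entries are 0.5.
#'
#' @param pedigree data.frame with columns `id`, `father`, `mother`.
#' @return symmetric PSD numeric matrix with dimnames = ids.
#' @export
build_kinship <- function(pedigree) {
  stopifnot(is.data.frame(pedigree),
            all(c("id", "father", "mother") %in% names(pedigree)))
  id <- as.character(pedigree$id)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  norm_parent <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p %in% c("0", "")] <- NA_character_
    p
  }
  fa <- norm_parent(pedigree$father)
  mo <- norm_parent(pedigree$mother)
  known <- c(fa, mo)
  known <- known[!is.na(known)]
  if (!all(known %in% id)) {
    stop("unknown parent id(s): ", paste(unique(setdiff(known, id)), collapse = ", "))
  }

  # topological order: parents before children
  n <- length(id)
  order_idx <- integer(0)
  placed <- logical(n)
  names(placed) <- id
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(fa[i]) || placed[fa[i]]) && (is.na(mo[i]) || placed[mo[i]])
    }, logical(1))]
    if (length(ready) == 0) stop("pedigree contains a cycle")
    order_idx <- c(order_idx, ready)
    placed[id[ready]] <- TRUE
    remaining <- setdiff(remaining, ready)
  }

  A <- matrix(0, n, n, dimnames = list(id, id))
  pos <- setNames(seq_len(n), id)
  for (i in order_idx) {
    fi <- if (is.na(fa[i])) 0L else pos[fa[i]]
    mi <- if (is.na(mo[i])) 0L else pos[mo[i]]
    # A_ii = 1 + 0.5 * A(father, mother)
    A[i, i] <- 1 + if (fi > 0 && mi > 0) 0.5 * A[fi, mi] else 0
    for (j in order_idx) {
      if (j == i) break
      aij <- 0
      if (fi > 0) aij <- aij + 0.5 * A[j, fi]
      if (mi > 0) aij <- aij + 0.5 * A[j, mi]
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}
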