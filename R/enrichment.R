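#' Map probes to gene symbols
#'
#' Deduplicated genes for a probe list; unannotated probes are dropped and
#' counted in the `n_unannotated` attribute.
#'
#' @param probes character vector of probe ids.
#' @param annotation data.frame with columns `probe_id`, `gene`.
#' @return character vector of unique gene symbols.
#' @export
map_probes_to_genes <- function(probes, annotation) {
  stopifnot(all(c("probe_id", "gene") %in% names(annotation)))
  hit <- annotation[annotation$probe_id %in% probes &
                      !is.na(annotation$gene) & annotation$gene != "", ]
  genes <- unique(hit$gene)
  n_unannot <- length(unique(setdiff(probes, hit$probe_id)))
  if (n_unannot > 0)
    message(n_unannot, " probe(s) had no gene annotation and were dropped")
  structure(genes, n_unannotated = n_unannot)
}

#' Hypergeometric over-representation of gene sets
#'
#' Per pathway with `K = |pathway intersect background|`, `N = |background|`,
#' `n = |module genes|` and overlap `k`:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, i.e. the chance a
#' random draw of the module's genes from the background hits the pathway at
#' least `k` times. Benjamini-Hochberg FDR across pathways; pathways with an
#' empty background intersection are dropped. Results are sorted by p.
#'
#' @param module_genes genes of the module (subset of the background).
#' @param background_genes the gene universe (all genes mapped from the
#'   screened probe set).
#' @param sets named list of gene-symbol vectors (e.g. from [read_gmt()]).
#' @return data.frame: pathway, n_de (overlap), n_pathway (K), p_value, fdr.
#' @export
hypergeom_enrichment <- function(module_genes, background_genes, sets) {
  background_genes <- unique(background_genes)
  if (length(background_genes) == 0) stop("background gene set is empty")
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% background_genes))
    stop("module_genes must be a subset of background_genes")
  N <- length(background_genes)
  n <- length(module_genes)
  rows <- lapply(names(sets), function(nm) {
    pw <- intersect(unique(sets[[nm]]), background_genes)
    K <- length(pw)
    if (K == 0) return(NULL)
    k <- length(intersect(module_genes, pw))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, n_de = k, n_pathway = K, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway overlaps the background")
  out$fdr <- p.adjust(out$p_value, "BH")
  out[order(out$p_value, out$pathway), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then gene symbols.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-c(1, 2)][nzchar(f[-c(1, 2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}
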