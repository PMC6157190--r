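open_device <- function(path, width = 9, height = 6) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 100, height = height * 100),
         stop("unsupported figure format: .", ext))
  invisible(TRUE)
}

#' Clustering dendrogram with module color bars
#'
#' Draws the probe dendrogram with one horizontal color bar per assignment
#' (e.g. pre- and post-treatment module colors), aligned to the leaves.
#' Unassigned probes render grey.
#'
#' @param tree an `hclust` over probes (e.g. `detect_modules(...)$tree`).
#' @param color_bars named list of color vectors (one entry per bar), each
#'   aligned to the probes in original input order.
#' @param path output figure path (.pdf, .svg or .png).
#' @return `path`, invisibly.
#' @export
plot_module_dendrogram <- function(tree, color_bars, path) {
  stopifnot(inherits(tree, "hclust"))
  color_bars <- lapply(color_bars, function(cb) {
    if (length(cb) != length(tree$order)) stop("color bar length != number of probes")
    cb
  })
  open_device(path)
  on.exit(grDevices::dev.off())
  nb <- length(color_bars)
  graphics::layout(matrix(seq_len(nb + 1)), heights = c(4, rep(0.6, nb)))
  op <- graphics::par(mar = c(0, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(as.dendrogram(tree), leaflab = "none",
                 main = "Probe clustering (1 - TOM)", ylab = "Height")
  for (nm in names(color_bars)) {
    graphics::par(mar = c(1, 4, 0.2, 1))
    cols <- color_bars[[nm]][tree$order]
    graphics::image(matrix(seq_along(cols)), col = cols, axes = FALSE)
    graphics::mtext(nm, side = 2, las = 2, cex = 0.7)
  }
  invisible(path)
}

#' Side-by-side pre/post module network plots
#'
#' Binarizes both correlation matrices restricted to one module at `tau` and
#' draws the two graphs with a common node layout, so edge loss/gain after
#' treatment is visible directly.
#'
#' @param pre_cor,post_cor probe correlation matrices.
#' @param module_probes probe ids of the module.
#' @param tau binarization threshold.
#' @param path output figure path.
#' @param seed layout seed.
#' @return `path` invisibly, with attribute `edge_counts`.
#' @export
plot_module_network <- function(pre_cor, post_cor, module_probes, tau = 0.2,
                                path, seed = 1) {
  idx <- match(module_probes, rownames(pre_cor))
  if (anyNA(idx)) stop("module probes missing from correlation matrix")
  a_pre <- binarize_network(pre_cor[idx, idx], tau)
  a_post <- binarize_network(post_cor[idx, idx], tau)
  g_pre <- igraph::graph_from_adjacency_matrix(a_pre, mode = "undirected")
  g_post <- igraph::graph_from_adjacency_matrix(a_post, mode = "undirected")
  set.seed(seed)
  lay <- igraph::layout_with_fr(g_pre)
  open_device(path, width = 10, height = 5)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (panel in list(list(g = g_pre, t = "Pre-treatment"),
                     list(g = g_post, t = "Post-treatment"))) {
    igraph::plot.igraph(panel$g, layout = lay, vertex.size = 5,
                        vertex.label = NA, vertex.color = "steelblue",
                        edge.color = "grey40", main = panel$t)
  }
  out <- invisible(path)
  attr(out, "edge_counts") <- c(pre = sum(a_pre) / 2, post = sum(a_post) / 2)
  out
}
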