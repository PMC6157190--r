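#' Pipeline configuration
#'
#' Bundles stage parameters and the global seed. Either an in-memory
#' `cometh_study` or an input directory of TSVs (see [write_study()]) feeds
#' the pipeline; a GMT path enables the enrichment stage.
#'
#' @param study a `cometh_study`, or NULL to read from `input_dir`.
#' @param input_dir directory of study TSVs (ignored when `study` given).
#' @param out_dir run directory to create.
#' @param gmt optional GMT gene-set file for enrichment.
#' @param alpha_screen nominal TG-screen level.
#' @param n_pcs principal components in the residualization design.
#' @param cut_height sample-outlier cut height or "auto".
#' @param min_module_size minimum module size.
#' @param powers candidate soft powers.
#' @param r2_threshold scale-free fit threshold.
#' @param tau GHD binarization threshold.
#' @param alpha family-wise level for the Bonferroni GHD decision.
#' @param n_perm_preservation,n_perm_ghd permutation counts.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param make_plots write dendrogram / module network figures (pdf).
#' @return a `cometh_pipeline_config` list.
#' @export
pipeline_config <- function(study = NULL, input_dir = NULL, out_dir,
                            gmt = NULL,
                            alpha_screen = 0.05, n_pcs = 10,
                            cut_height = "auto", min_module_size = 30,
                            powers = 1:20, r2_threshold = 0.9,
                            tau = 0.2, alpha = 0.05,
                            n_perm_preservation = 200, n_perm_ghd = 1000,
                            seed = 1, make_plots = TRUE) {
  stopifnot(alpha_screen > 0, alpha_screen <= 1, tau > 0, tau < 1,
            min_module_size >= 2, n_pcs >= 0, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "cometh_pipeline_config")
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con); message(msg)
}

#' Run the full differential co-methylation pipeline
#'
#' Stages: TG association screen on pre-treatment betas -> per-probe kinship
#' LMM residualization of both time points -> variance / missingness /
#' outlier QC -> pre-treatment network and module detection -> module
#' preservation (Z_summary, medianRank) and GHD test -> enrichment of
#' changed modules (if gene sets supplied). Writes per-stage TSVs, figures,
#' `summary.json` and `run_log.txt` into the run directory.
#'
#' @param config a `cometh_pipeline_config`.
#' @return the summary list, invisibly; outputs under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cometh_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "run_log.txt"), "w")
  on.exit(close(logf))
  log_line(logf, "comethnet ", as.character(utils::packageVersion("comethnet")),
           " | R ", R.version.string, " | seed ", config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(logf, "FAILED at stage ", name, ": ", conditionMessage(e))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  study <- config$study %||% stage("input", read_study(config$input_dir))
  pre <- study$pre_betas; post <- study$post_betas
  sheet <- study$sample_sheet; K <- study$kinship

  # 1. nominal TG screen on pre-treatment betas
  screen <- stage("screen", tg_association_screen(
    pre, sheet, K, alpha_screen = config$alpha_screen, n_pcs = config$n_pcs))
  write_table_tsv(screen, file.path(config$out_dir, "screen.tsv"))
  keep <- screen$probe_id[screen$retained]
  log_line(logf, "screen: ", length(keep), "/", nrow(pre),
           " probes at p < ", config$alpha_screen)
  if (length(keep) < config$min_module_size)
    stop("stage screen: fewer retained probes than min_module_size", call. = FALSE)
  pre <- pre[keep, , drop = FALSE]
  post <- post[intersect(keep, rownames(post)), , drop = FALSE]

  # 2. kinship LMM residualization, per cohort
  res_pre <- stage("residualize", residualize_matrix(pre, sheet, K, config$n_pcs))
  res_post <- stage("residualize", residualize_matrix(post, sheet, K, config$n_pcs))
  log_line(logf, "residualized ", nrow(res_pre), " probes; pre n=",
           ncol(res_pre), ", post n=", ncol(res_post))

  # 3. QC: variance + missingness filters and outlier samples, both cohorts
  qc <- stage("qc", {
    rp <- missingness_filter(variance_filter(res_pre))
    rq <- missingness_filter(variance_filter(res_post))
    common <- intersect(rownames(rp), rownames(rq))
    rp <- rp[common, , drop = FALSE]; rq <- rq[common, , drop = FALSE]
    out_pre <- detect_outlier_samples(rp, config$cut_height)
    out_post <- detect_outlier_samples(rq, config$cut_height)
    drop <- union(out_pre, out_post)
    list(pre = rp[, setdiff(colnames(rp), drop), drop = FALSE],
         post = rq[, setdiff(colnames(rq), drop), drop = FALSE],
         outliers = drop)
  })
  res_pre <- qc$pre; res_post <- qc$post
  log_line(logf, "qc: ", nrow(res_pre), " probes, dropped ",
           length(qc$outliers), " outlier sample(s)")
  write_matrix_tsv(res_pre, file.path(config$out_dir, "residuals_pre.tsv"))
  write_matrix_tsv(res_post, file.path(config$out_dir, "residuals_post.tsv"))

  # 4. pre-treatment network + modules; post network at the same power
  net_pre <- stage("network", build_network(res_pre, "auto", config$powers,
                                            config$r2_threshold))
  net_post <- stage("network", build_network(res_post, net_pre$power))
  if (!is.null(net_pre$scan))
    write_table_tsv(net_pre$scan, file.path(config$out_dir, "soft_power_scan.tsv"))
  log_line(logf, "network: soft power ", net_pre$power)
  tom <- stage("network", topological_overlap(net_pre$adjacency))
  modules <- stage("network", detect_modules(tom, config$min_module_size))
  mod_df <- data.frame(probe_id = names(modules$labels),
                       module = unname(modules$labels),
                       color = unname(modules$colors))
  write_table_tsv(mod_df, file.path(config$out_dir, "modules.tsv"))
  n_mod <- max(modules$labels)
  log_line(logf, "modules: ", n_mod, " detected; sizes ",
           paste(as.integer(modules$sizes), collapse = ", "))
  if (n_mod == 0) stop("stage network: no modules detected", call. = FALSE)

  # 5a. permutation module preservation
  pres_seed <- spawn_seed(config$seed, "preservation")
  pres <- stage("preservation", module_preservation(
    net_pre, net_post, modules, config$n_perm_preservation, pres_seed))
  write_table_tsv(pres, file.path(config$out_dir, "preservation.tsv"))
  log_line(logf, "preservation: seed ", pres_seed)

  # 5b. GHD test
  ghd_seed <- spawn_seed(config$seed, "ghd")
  ghd <- stage("ghd", ghd_test(net_pre$cor, net_post$cor, modules,
                               tau = config$tau, alpha = config$alpha,
                               n_perm = config$n_perm_ghd, seed = ghd_seed))
  write_table_tsv(ghd, file.path(config$out_dir, "ghd.tsv"))
  log_line(logf, "ghd: seed ", ghd_seed, ", bonferroni ",
           signif(attr(ghd, "bonferroni"), 3))

  # 6. enrichment of changed modules (GHD verdict)
  changed <- ghd$module[!is.na(ghd$preserved) & !ghd$preserved]
  enr <- NULL
  if (!is.null(config$gmt) && length(changed) > 0) {
    enr <- stage("enrichment", {
      sets <- read_gmt(config$gmt)
      bg <- map_probes_to_genes(rownames(res_pre), study$probe_annotation)
      lapply(setNames(changed, changed), function(l) {
        probes <- names(modules$labels)[modules$labels == l]
        genes <- map_probes_to_genes(probes, study$probe_annotation)
        r <- hypergeom_enrichment(genes, bg, sets)
        write_table_tsv(r, file.path(config$out_dir,
                                     paste0("enrichment_module", l, ".tsv")))
        r
      })
    })
    log_line(logf, "enrichment: modules ", paste(changed, collapse = ", "))
  }

  # 7. figures
  if (isTRUE(config$make_plots)) {
    stage("plots", {
      post_cols <- module_colors(greedy_match_labels(net_post, modules,
                                                     config$min_module_size))
      plot_module_dendrogram(modules$tree,
                      list(pre = unname(modules$colors), post = unname(post_cols)),
                      file.path(config$out_dir, "dendrogram.pdf"))
      for (l in ghd$module) {
        probes <- names(modules$labels)[modules$labels == l]
        plot_module_network(net_pre$cor, net_post$cor, probes, config$tau,
                            file.path(config$out_dir,
                                      paste0("network_module", l, ".pdf")),
                            seed = spawn_seed(config$seed, "layout"))
      }
    })
  }

  summary <- list(
    n_probes_screened = length(keep),
    n_modules = n_mod,
    module_sizes = as.integer(modules$sizes),
    soft_power = net_pre$power,
    bonferroni = attr(ghd, "bonferroni"),
    modules = lapply(seq_len(n_mod), function(l) {
      pr <- pres[pres$module == l, ]; gr <- ghd[ghd$module == l, ]
      list(module = l, color = modules$colors[modules$labels == l][1],
           size = sum(modules$labels == l),
           Z_summary = pr$Z_summary, median_rank = pr$median_rank,
           preservation_verdict = pr$category,
           ghd = gr$ghd, ghd_z = gr$z, ghd_p = gr$p_value,
           ghd_preserved = gr$preserved,
           concordant = (pr$category != "none") == isTRUE(gr$preserved))
    }),
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(logf, "done")
  invisible(summary)
}

# crude post-network module labels for the dendrogram's second color bar:
# detect modules in the post network and relabel them to best match the
# pre-treatment assignment (by overlap), on the pre-network probe order
greedy_match_labels <- function(net_post, modules_pre, min_module_size) {
  post_mod <- tryCatch(
    detect_modules(topological_overlap(net_post$adjacency), min_module_size),
    error = function(e) NULL)
  if (is.null(post_mod)) return(setNames(rep(0L, length(modules_pre$labels)),
                                         names(modules_pre$labels)))
  lab <- setNames(rep(0L, length(modules_pre$labels)), names(modules_pre$labels))
  lab[names(post_mod$labels)] <- post_mod$labels
  pre <- modules_pre$labels
  remap <- setNames(rep(0L, max(lab) + 1L), 0:max(lab))
  for (l in setdiff(unique(lab), 0L)) {
    ov <- table(pre[lab == l & pre > 0])
    remap[as.character(l)] <- if (length(ov)) as.integer(names(ov)[which.max(ov)]) else l
  }
  setNames(remap[as.character(lab)], names(lab))
}
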