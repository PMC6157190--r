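#' Configuration for a synthetic pre/post methylation study
#'
#' Describes the stated world of the generator: family structure, planted
#' co-methylation modules with a target within-module latent correlation,
#' a kinship-heritable component per probe, covariate effects, a
#' log-triglyceride phenotype coupled to the module factors, and a set of
#' modules whose co-methylation is destroyed ("rewired") at the second time
#' point while the rest keep their loadings.
#'
#' @param n_families number of nuclear families (2 founders + children).
#' @param family_size individuals per family (>= 2).
#' @param n_probes total number of probes; must be >= sum(module_sizes).
#'   The default leaves a majority of probes outside modules, echoing a
#'   screened array where most probes belong to no module.
#' @param module_sizes integer vector of planted module sizes, any order.
#' @param module_correlation target within-module latent correlation in \[0,1).
#' @param rewired_modules indices (into `module_sizes`) of modules whose
#'   structure is re-randomized post-treatment.
#' @param heritability fraction of latent probe variance attributable to the
#'   kinship random effect, in \[0,1).
#' @param covariate_effects named list of fixed-effect sizes on the latent
#'   scale for `age`, `sex`, `center`, `smoking`.
#' @param phenotype_module index of the module most strongly driving logTG.
#' @param phenotype_effect logTG loading of the `phenotype_module` factor.
#' @param shared_effect logTG loading of every other module factor; nonzero
#'   by default so a nominal TG screen retains all planted modules.
#' @param noise_sd residual standard deviation of logTG.
#' @param loading_min lower bound of the per-probe loading multiplier:
#'   probe i in a module has loading `sqrt(module_correlation) * u_i` with
#'   `u_i ~ Uniform(loading_min, 1)`. Heterogeneous loadings give modules
#'   hub structure (and a nearly scale-free thresholded network) instead of
#'   a saturated compound-symmetric block; hub pairs correlate at the
#'   module_correlation scale.
#' @param post_fraction fraction of pretreatment samples retained at the
#'   second time point (default 0.55, mirroring a 530/995 dropout pattern).
#' @param n_batches number of planted technical batch components (rank of
#'   the batch structure; default 0 = no batch). When nonzero, the top PCs
#'   of the beta matrix capture these components and the n_pcs adjustment in
#'   residualization removes them.
#' @param batch_var total per-probe latent variance contributed by batch
#'   (split evenly across components).
#' @param seed integer RNG seed.
#' @return a `cometh_config` list.
#' @export
simulation_config <- function(n_families = 50,
                              family_size = 4,
                              n_probes = 600,
                              module_sizes = c(60, 50, 45, 40, 35, 30),
                              module_correlation = 0.7,
                              rewired_modules = c(3, 5, 6),
                              heritability = 0.3,
                              covariate_effects = list(age = 0.01, sex = 0.25,
                                                       center = 0.2, smoking = 0.3),
                              phenotype_module = 1,
                              phenotype_effect = 0.6,
                              shared_effect = 0.4,
                              noise_sd = 0.5,
                              loading_min = 0.5,
                              post_fraction = 0.55,
                              n_batches = 0,
                              batch_var = 1,
                              seed = 1) {
  if (sum(module_sizes) > n_probes)
    stop("sum(module_sizes) exceeds n_probes")
  if (module_correlation < 0 || module_correlation >= 1)
    stop("module_correlation must be in [0, 1)")
  if (heritability < 0 || heritability >= 1)
    stop("heritability must be in [0, 1)")
  if (length(rewired_modules) &&
      !all(rewired_modules %in% seq_along(module_sizes)))
    stop("rewired_modules must index into module_sizes")
  structure(list(
    n_families = n_families, family_size = family_size, n_probes = n_probes,
    module_sizes = module_sizes, module_correlation = module_correlation,
    rewired_modules = rewired_modules, heritability = heritability,
    covariate_effects = covariate_effects,
    phenotype_module = phenotype_module, phenotype_effect = phenotype_effect,
    shared_effect = shared_effect, noise_sd = noise_sd,
    loading_min = loading_min, post_fraction = post_fraction,
    n_batches = n_batches, batch_var = batch_var,
    seed = as.integer(seed)
  ), class = "cometh_config")
}

# module color aliases in descending size order; grey = unassigned
module_palette <- function(n) {
  pal <- c("pink", "blue", "brown", "yellow", "green", "red", "turquoise",
           "black", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan")
  if (n > length(pal)) pal <- c(pal, paste0("module", seq_len(n - length(pal))))
  pal[seq_len(n)]
}

#' Color aliases for a module assignment
#'
#' Maps integer module labels to color names in descending order of module
#' size; label 0 maps to "grey".
#'
#' @param modules integer vector of module labels (0 = unassigned).
#' @return character vector of colors, same length and names as `modules`.
#' @export
module_colors <- function(modules) {
  labs <- sort(setdiff(unique(modules), 0L))
  if (length(labs) == 0) return(setNames(rep("grey", length(modules)), names(modules)))
  sizes <- vapply(labs, function(l) sum(modules == l), integer(1))
  ord <- labs[order(-sizes, labs)]
  pal <- module_palette(length(ord))
  map <- setNames(c(pal, "grey"), c(ord, 0L))
  setNames(map[as.character(modules)], names(modules))
}

build_pedigree <- function(n_families, family_size) {
  stopifnot(family_size >= 2)
  rows <- lapply(seq_len(n_families), function(f) {
    fam <- sprintf("F%03d", f)
    ids <- sprintf("%s_I%02d", fam, seq_len(family_size))
    father <- c(NA, NA, rep(ids[1], family_size - 2))
    mother <- c(NA, NA, rep(ids[2], family_size - 2))
    data.frame(id = ids, father = father, mother = mother,
               family_id = fam, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a family-structured pre/post methylation study
#'
#' Latent probe values follow a one-factor-per-module model: probe i in
#' module m has latent value
#' `sqrt(h2) * g_i + sqrt(1 - h2) * (lambda_i * f_m + sqrt(1 - lambda_i^2) * eps_i)`
#' where `g_i` is a kinship-correlated genetic effect (covariance = kinship
#' matrix), `f_m` a per-sample module factor, and `lambda_i` per-probe
#' loadings spread over `sqrt(module_correlation) * [loading_min, 1]`. Covariate effects are
#' added on the latent scale and values are squashed into (0,1) by the
#' inverse-logit around a probe-specific baseline. Post-treatment betas are
#' regenerated with identical loadings for preserved modules; for rewired
#' modules each probe is moved onto its own independent factor, preserving
#' marginal moments but destroying within-module co-methylation. logTG is a
#' linear function of the module factors (strongest for `phenotype_module`),
#' the covariates, and kinship-correlated noise.
#'
#' @param config a `cometh_config` from [simulation_config()].
#' @return a `cometh_study` list: `pre_betas`, `post_betas` (probe x sample
#'   matrices), `sample_sheet`, `kinship`, `probe_annotation`,
#'   `planted_modules` (data.frame probe_id/module/color), `rewired_flags`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "cometh_config"))
  set.seed(config$seed)
  ped <- build_pedigree(config$n_families, config$family_size)
  K <- build_kinship(ped[, c("id", "father", "mother")])
  n <- nrow(ped)
  h2 <- config$heritability

  sample_sheet <- data.frame(
    sample_id = ped$id,
    family_id = ped$family_id,
    age = round(runif(n, 20, 70), 1),
    sex = rbinom(n, 1, 0.5),
    center = sample(c("A", "B", "C"), n, replace = TRUE, prob = c(0.4, 0.35, 0.25)),
    smoking = rbinom(n, 1, 0.25),
    stringsAsFactors = FALSE
  )

  p <- config$n_probes
  sizes <- config$module_sizes
  m <- length(sizes)
  modules <- integer(p)
  idx <- 1L
  for (k in seq_len(m)) {
    modules[idx:(idx + sizes[k] - 1L)] <- k
    idx <- idx + sizes[k]
  }
  probe_ids <- sprintf("cg%07d", seq_len(p))
  names(modules) <- probe_ids

  lam <- numeric(p)
  in_mod <- modules > 0L
  lam[in_mod] <- sqrt(config$module_correlation) *
    runif(sum(in_mod), config$loading_min, 1)
  if (config$module_correlation == 0) lam[] <- 0

  # kinship-correlated draws: t(chol(K)) %*% z, one column per probe
  L <- t(chol(K + diag(1e-10, n)))
  kin_draw <- function(cols) L %*% matrix(rnorm(n * cols), n, cols)

  ce <- config$covariate_effects
  cov_latent <- ce$age * (sample_sheet$age - 45) / 10 +
    ce$sex * sample_sheet$sex +
    ce$center * (match(sample_sheet$center, c("A", "B", "C")) - 2) +
    ce$smoking * sample_sheet$smoking
  baseline <- rnorm(p, 0, 1.5)

  nb <- config$n_batches %||% 0
  batch_scores <- list()
  batch_matrix <- function(label) {
    if (nb == 0) return(0)
    scores <- matrix(rnorm(n * nb), n, nb)
    batch_scores[[label]] <<- scores
    loads <- matrix(rnorm(nb * p, 0, sqrt(config$batch_var / nb)), nb, p)
    scores %*% loads                              # n x p
  }
  latent_matrix <- function(factors) {
    # factors: n x m matrix of module factor values
    g <- kin_draw(p)                              # n x p genetic effects
    eps <- matrix(rnorm(n * p), n, p)
    env <- eps
    for (k in seq_len(m)) {
      pr <- which(modules == k)
      env[, pr] <- factors[, k] %o% lam[pr] +
        eps[, pr] * rep(sqrt(1 - lam[pr]^2), each = n)
    }
    sqrt(h2) * g + sqrt(1 - h2) * env + batch_matrix("pre")   # n x p
  }
  lat_scale <- 1 / sqrt(1 + if (nb > 0) config$batch_var else 0)
  squash <- function(lat) {
    # probe x sample betas in (0,1); latent standardized so batch structure
    # does not saturate the inverse-logit
    b <- plogis(t(lat * lat_scale + cov_latent) + baseline)
    dimnames(b) <- list(probe_ids, sample_sheet$sample_id)
    b
  }

  f_pre <- matrix(rnorm(n * m), n, m)
  pre_lat <- latent_matrix(f_pre)
  pre_betas <- squash(pre_lat)

  # phenotype measured at the pre-treatment visit
  coefs <- rep(config$shared_effect, m)
  coefs[config$phenotype_module] <- config$phenotype_effect
  logTG <- as.numeric(f_pre %*% coefs) +
    0.5 * cov_latent +
    config$noise_sd * as.numeric(kin_draw(1))
  sample_sheet$logTG <- round(logTG, 6)

  # post-treatment: preserved modules keep loadings (fresh factor values);
  # rewired modules lose their shared factor entirely
  keep_n <- max(3L, ceiling(config$post_fraction * n))
  post_idx <- sort(sample.int(n, keep_n))
  f_post <- matrix(rnorm(n * m), n, m)
  g_post <- kin_draw(p)
  eps_post <- matrix(rnorm(n * p), n, p)
  env_post <- eps_post
  for (k in seq_len(m)) {
    pr <- which(modules == k)
    if (k %in% config$rewired_modules) next      # independent probes post
    env_post[, pr] <- f_post[, k] %o% lam[pr] +
      eps_post[, pr] * rep(sqrt(1 - lam[pr]^2), each = n)
  }
  post_lat <- sqrt(h2) * g_post + sqrt(1 - h2) * env_post + batch_matrix("post")
  post_betas <- squash(post_lat)[, post_idx, drop = FALSE]

  # probe -> gene map: roughly two probes per gene
  gene <- paste0("GENE", sprintf("%04d", ceiling(seq_len(p) / 2)))
  annotation <- data.frame(probe_id = probe_ids, gene = gene,
                           stringsAsFactors = FALSE)

  # size-ranked labels for the truth assignment
  ord <- order(-sizes, seq_len(m))
  relabel <- integer(m); relabel[ord] <- seq_len(m)
  truth <- ifelse(modules > 0L, relabel[modules], 0L)
  names(truth) <- probe_ids
  planted <- data.frame(probe_id = probe_ids, module = truth,
                        color = unname(module_colors(truth)),
                        stringsAsFactors = FALSE)
  rewired <- setNames(seq_len(m) %in% config$rewired_modules, seq_len(m))
  rewired_flags <- setNames(rewired[ord], seq_len(m))  # on size-ranked labels

  structure(list(
    pre_betas = pre_betas, post_betas = post_betas,
    sample_sheet = sample_sheet, kinship = K,
    probe_annotation = annotation, planted_modules = planted,
    rewired_flags = rewired_flags,
    batch_scores = if (nb > 0) batch_scores else NULL, config = config
  ), class = "cometh_study")
}
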