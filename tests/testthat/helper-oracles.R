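# independent brute-force oracles and shared fixtures

# triple-loop topological overlap (works for weighted and binary adjacency)
tom_oracle <- function(a, diag_value) {
  n <- nrow(a)
  out <- matrix(diag_value, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- num / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# double-loop GHD with off-diagonal mean centering
ghd_oracle <- function(wa, wb) {
  n <- nrow(wa)
  ma <- mean(wa[row(wa) != col(wa)]); mb <- mean(wb[row(wb) != col(wb)])
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    s <- s + ((wa[i, j] - ma) - (wb[i, j] - mb))^2
  s / (n * (n - 1))
}

# nuclear-family pedigree (2 founders + fam_size-2 full sibs per family)
family_pedigree <- function(n_families, fam_size = 4) {
  do.call(rbind, lapply(seq_len(n_families), function(f) {
    ids <- sprintf("F%02d_I%d", f, seq_len(fam_size))
    data.frame(id = ids,
               father = c(NA, NA, rep(ids[1], fam_size - 2)),
               mother = c(NA, NA, rep(ids[2], fam_size - 2)),
               stringsAsFactors = FALSE)
  }))
}

# default-world analysis (residualization with n_pcs = 0: the simulated
# world plants no batch structure), cached across test files
.world_cache <- new.env(parent = emptyenv())
world_analysis <- function(seed) {
  key <- paste0("seed", seed)
  if (!exists(key, envir = .world_cache)) {
    st <- simulate_study(simulation_config(seed = seed))
    truth <- setNames(st$planted_modules$module, st$planted_modules$probe_id)
    rp <- residualize_matrix(st$pre_betas, st$sample_sheet, st$kinship, n_pcs = 0)
    rq <- residualize_matrix(st$post_betas, st$sample_sheet, st$kinship, n_pcs = 0)
    net_pre <- build_network(rp)
    net_post <- build_network(rq, net_pre$power)
    mods <- detect_modules(topological_overlap(net_pre$adjacency), 30)
    assign(key, list(study = st, truth = truth, res_pre = rp, res_post = rq,
                     net_pre = net_pre, net_post = net_post, modules = mods),
           envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

# scale-free binary adjacency via preferential attachment
ba_adjacency <- function(n, m = 2, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_pa(n, m = m, directed = FALSE)
  unname(as.matrix(igraph::as_adjacency_matrix(g)))
}
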