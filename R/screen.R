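#' Nominal triglyceride association screen
#'
#' Per probe, fits the kinship LMM with log-triglycerides as the outcome and
#' the probe's beta values plus age, sex, field center and smoking as fixed
#' effects; retains probes whose Wald p-value for the probe coefficient is
#' below `alpha_screen`. Deliberately uncorrected for multiplicity: an
#' FDR-level screen would drop probes whose signal only emerges through
#' network structure. Set `outcome = "probe"` to flip the regression
#' direction (probe as outcome, logTG as predictor).
#'
#' @param betas probe x sample beta matrix.
#' @param sample_sheet data.frame with sample_id, age, sex, center, smoking,
#'   logTG.
#' @param K kinship matrix with dimnames covering the samples.
#' @param alpha_screen retention threshold on the nominal p-value.
#' @param n_pcs principal components of the beta matrix added to the design
#'   (same adjustment as residualization); 0 to omit.
#' @param outcome which variable is the LMM outcome.
#' @return data.frame: probe_id, coefficient, se, p_value, retained.
#' @export
tg_association_screen <- function(betas, sample_sheet, K, alpha_screen = 0.05,
                                  n_pcs = 10,
                                  outcome = c("logTG", "probe")) {
  outcome <- match.arg(outcome)
  betas <- as.matrix(betas)
  ids <- colnames(betas)
  sheet <- sample_sheet[match(ids, sample_sheet$sample_id), , drop = FALSE]
  if (sum(!is.na(sheet$logTG)) < 10) stop("need >= 10 samples with logTG")
  K <- align_kinship(K, ids)
  n_pcs <- min(n_pcs, ncol(betas) - 1L, nrow(betas))
  pcs <- NULL
  if (n_pcs > 0) {
    filled <- betas
    if (anyNA(filled)) {
      mu <- rowMeans(filled, na.rm = TRUE)
      idxna <- which(is.na(filled), arr.ind = TRUE)
      filled[idxna] <- mu[idxna[, 1]]
    }
    pcs <- compute_pcs(t(filled), n_pcs)
  }
  Xbase <- covariate_design(sheet, pcs)
  eig <- eigen(K, symmetric = TRUE)
  y_tg <- sheet$logTG

  out <- lapply(seq_len(nrow(betas)), function(i) {
    probe <- betas[i, ]
    if (is.na(sd(probe, na.rm = TRUE)) || sd(probe, na.rm = TRUE) == 0) {
      return(data.frame(probe_id = rownames(betas)[i], coefficient = NA_real_,
                        se = NA_real_, p_value = 1, retained = FALSE))
    }
    if (outcome == "logTG") {
      y <- y_tg; X <- cbind(Xbase, probe = probe)
    } else {
      y <- probe; X <- cbind(Xbase, logTG = y_tg)
    }
    use_eig <- if (anyNA(y) || anyNA(X)) NULL else eig
    miss <- is.na(y) | rowSums(is.na(X)) > 0
    y[miss] <- NA
    X[is.na(X)] <- 0  # rows with any NA already dropped via y
    fit <- fit_lmm(y, X, K, eig = use_eig)
    j <- ncol(X)
    tval <- fit$beta_hat[j] / fit$se[j]
    p <- 2 * pt(-abs(tval), df = fit$df)
    data.frame(probe_id = rownames(betas)[i],
               coefficient = unname(fit$beta_hat[j]),
               se = unname(fit$se[j]), p_value = unname(p),
               retained = unname(p < alpha_screen))
  })
  do.call(rbind, out)
}

#' Drop near-constant probes
#'
#' Removes probes whose residual variance falls below
#' `1e-10 * max(abs(residuals))` taken over the whole matrix.
#'
#' @param residuals probe x sample residual matrix.
#' @return the surviving rows, with attribute `n_removed`.
#' @export
variance_filter <- function(residuals) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) == 0) stop("empty residual matrix")
  thr <- 1e-10 * max(abs(residuals), na.rm = TRUE)
  v <- apply(residuals, 1, var, na.rm = TRUE)
  keep <- which(!is.na(v) & v >= thr)
  out <- residuals[keep, , drop = FALSE]
  attr(out, "n_removed") <- nrow(residuals) - length(keep)
  out
}

#' Drop samples with mostly missing residuals
#'
#' Removes samples with strictly more than half of their residuals missing.
#'
#' @param residuals probe x sample residual matrix.
#' @return the surviving columns, with attribute `n_removed`.
#' @export
missingness_filter <- function(residuals) {
  residuals <- as.matrix(residuals)
  frac <- colMeans(is.na(residuals))
  keep <- which(frac <= 0.5)
  out <- residuals[, keep, drop = FALSE]
  attr(out, "n_removed") <- ncol(residuals) - length(keep)
  out
}

#' Detect outlier samples by hierarchical clustering
#'
#' Average-linkage clustering of samples on Euclidean distance of their
#' residual profiles; the tree is cut at `cut_height` and every sample
#' outside the largest resulting cluster is flagged. `cut_height = "auto"`
#' cuts at mean + 4 SD of the merge heights, so homogeneous cohorts yield
#' no outliers.
#'
#' @param residuals probe x sample residual matrix (>= 3 samples).
#' @param cut_height positive cut height, or "auto".
#' @return character vector of outlier sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(residuals, cut_height = "auto") {
  residuals <- as.matrix(residuals)
  if (ncol(residuals) < 3) stop("need at least 3 samples")
  hc <- hclust(dist(t(residuals)), method = "average")
  if (identical(cut_height, "auto")) {
    # flag only merges far above the bulk; a fixed quantile would always
    # flag the top merges even on perfectly homogeneous data
    cut_height <- max(mean(hc$height) + 4 * sd(hc$height),
                      .Machine$double.eps, na.rm = TRUE)
  }
  cut_height <- as.numeric(cut_height)
  if (is.na(cut_height) || cut_height <= 0) stop("cut_height must be positive")
  cut_height <- min(cut_height, max(hc$height) + 1)  # cutree dislikes Inf
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  main <- as.integer(names(sizes)[which.max(sizes)])
  colnames(residuals)[cl != main]
}
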