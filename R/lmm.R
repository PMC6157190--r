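#' Fit a single-kinship linear mixed model by REML
#'
#' Model: `y = X b + g + e`, `g ~ N(0, sigma_g2 * K)`, `e ~ N(0, sigma_e2 * I)`.
#' K is eigendecomposed once (or a precomputed decomposition passed in); the
#' rotated model has a diagonal covariance so REML reduces to a 1-D
#' optimization over the heritability `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`,
#' solved by Brent's method to tolerance 1e-8, with the boundary h2 = 0
#' admitted. Fixed effects are GLS at the optimum; random effects are BLUPs.
#'
#' @param y numeric response (samples with NA dropped together with their
#'   design rows).
#' @param X design matrix, full column rank, including intercept.
#' @param K kinship matrix aligned to rows of X, symmetric PSD.
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)` (only valid
#'   when y has no missing values).
#' @return a `cometh_lmm` list: `beta_hat`, `sigma_g2`, `sigma_e2`, `h2`,
#'   `loglik` (REML), `blup`, `residuals` (conditional, y - Xb - blup),
#'   `marginal_residuals` (y - Xb), `se` (fixed-effect standard errors),
#'   `df` (n - p), `kept` (indices of non-missing samples).
#' @export
fit_lmm <- function(y, X, K, eig = NULL) {
  X <- as.matrix(X)
  if (length(y) != nrow(X) || nrow(X) != nrow(K))
    stop("y, X and K dimensions do not align")
  keep <- which(!is.na(y))
  if (length(keep) < ncol(X) + 2)
    stop("too few non-missing samples to fit the model")
  sub <- length(keep) < length(y)
  y0 <- y[keep]
  X0 <- X[keep, , drop = FALSE]
  if (qr(X0)$rank < ncol(X0)) stop("design matrix is singular")
  if (is.null(eig) || sub) {
    K0 <- K[keep, keep, drop = FALSE]
    check_square_symmetric(K0, tol = 1e-8, what = "kinship matrix")
    eig <- eigen(K0, symmetric = TRUE)
  }
  d <- eig$values
  if (min(d) < -1e-8) stop("kinship matrix is not PSD (min eigenvalue ", min(d), ")")
  d <- pmax(d, 0)
  U <- eig$vectors
  yr <- crossprod(U, y0)
  Xr <- crossprod(U, X0)
  n <- length(y0); p <- ncol(X0)

  profile <- function(h2) {
    w <- h2 * d + (1 - h2)
    wi <- 1 / w
    XtWX <- crossprod(Xr, Xr * wi)
    XtWy <- crossprod(Xr, yr * wi)
    ch <- chol(XtWX)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- yr - Xr %*% beta
    rss <- sum(r^2 * wi)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
                    2 * sum(log(diag(ch))) + (n - p))
    list(ll = ll, beta = beta, s2 = s2, r = r, wi = wi, ch = ch)
  }

  opt <- optimize(function(h) profile(h)$ll, c(0, 1 - 1e-6),
                  maximum = TRUE, tol = 1e-8)
  # boundary h2 = 0 is a legal optimum; keep whichever is better
  h2 <- opt$maximum
  f0 <- profile(0)
  fh <- profile(h2)
  if (f0$ll >= fh$ll) { h2 <- 0; fh <- f0 }

  sigma2 <- fh$s2
  sigma_g2 <- h2 * sigma2
  sigma_e2 <- (1 - h2) * sigma2
  beta_hat <- drop(fh$beta)
  names(beta_hat) <- colnames(X0)
  # blup on rotated scale: (sigma_g2 d / v) * rotated marginal residual
  v <- h2 * d + (1 - h2)
  blup_rot <- (h2 * d / v) * drop(fh$r)
  blup <- drop(U %*% blup_rot)
  marg <- drop(y0 - X0 %*% fh$beta)
  cond <- marg - blup
  covb <- chol2inv(fh$ch) * sigma2
  se <- sqrt(diag(covb))
  names(se) <- colnames(X0)

  full_vec <- function(x) { out <- rep(NA_real_, length(y)); out[keep] <- x; out }
  structure(list(beta_hat = beta_hat, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = h2, loglik = fh$ll, blup = full_vec(blup),
                 residuals = full_vec(cond), marginal_residuals = full_vec(marg),
                 se = se, df = n - p, kept = keep),
            class = "cometh_lmm")
}

#' Residuals from a fitted kinship LMM
#'
#' Conditional residuals `y - X b - blup` by default; family-shared genetic
#' signal is removed so correlation networks are not inflated by relatedness.
#' Marginal residuals `y - X b` are available via `type = "marginal"`.
#'
#' @param fit a `cometh_lmm` from [fit_lmm()].
#' @param type "conditional" (default) or "marginal".
#' @return numeric vector aligned to the original samples (NA where y was NA).
#' @export
lmm_residuals <- function(fit, type = c("conditional", "marginal")) {
  stopifnot(inherits(fit, "cometh_lmm"))
  type <- match.arg(type)
  if (type == "conditional") fit$residuals else fit$marginal_residuals
}

#' Principal component scores of a sample x probe matrix
#'
#' Columns are standardized (zero-variance columns dropped); the top-k left
#' singular directions give per-sample scores. Sign is fixed so each
#' component's largest-magnitude probe loading is positive.
#'
#' @param values sample x probe numeric matrix.
#' @param k number of components.
#' @return sample x k score matrix (columns PC1..PCk).
#' @export
compute_pcs <- function(values, k = 10) {
  values <- as.matrix(values)
  if (k > min(dim(values))) stop("k exceeds matrix rank bound")
  sds <- apply(values, 2, sd)
  keep <- which(sds > 0 & !is.na(sds))
  if (length(keep) == 0) stop("all columns are constant")
  Z <- scale(values[, keep, drop = FALSE])
  sv <- svd(Z, nu = k, nv = k)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(values)
  scores
}

# design matrix used by both residualization and the TG screen:
# intercept, age, sex, center dummies, smoking (+ optional PC scores)
covariate_design <- function(sample_sheet, pcs = NULL) {
  df <- data.frame(age = sample_sheet$age,
                   sex = sample_sheet$sex,
                   smoking = sample_sheet$smoking)
  terms <- c("age", "sex", "smoking")
  if (length(unique(sample_sheet$center)) > 1) {  # dummies need >= 2 levels
    df$center <- factor(sample_sheet$center)
    terms <- c(terms, "center")
  }
  X <- model.matrix(stats::reformulate(terms), df)
  if (!is.null(pcs)) X <- cbind(X, pcs)
  rownames(X) <- sample_sheet$sample_id
  X
}

#' Kinship-adjusted residual methylation matrix
#'
#' Per probe: fit [fit_lmm()] of the beta values on intercept, age, sex,
#' field-center dummies, smoking status and the first `n_pcs` principal
#' components of the (standardized) beta matrix, with the kinship matrix as
#' random-effect covariance; take conditional residuals and center them to
#' mean zero. Missing beta values propagate to missing residuals.
#'
#' @param betas probe x sample matrix of beta values.
#' @param sample_sheet data.frame with sample_id, age, sex, center, smoking.
#' @param K kinship matrix with dimnames covering the samples.
#' @param n_pcs number of principal components in the design (default 10).
#' @param type residual type passed to [lmm_residuals()].
#' @return probe x sample residual matrix (class "matrix"), centered per probe.
#' @export
residualize_matrix <- function(betas, sample_sheet, K, n_pcs = 10,
                               type = c("conditional", "marginal")) {
  type <- match.arg(type)
  betas <- as.matrix(betas)
  ids <- colnames(betas)
  if (is.null(ids)) stop("betas must have sample ids as column names")
  sheet <- sample_sheet[match(ids, sample_sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("sample sheet does not cover all samples")
  K <- align_kinship(K, ids)
  if (ncol(betas) < 10) stop("fewer than 10 samples after alignment")
  if (nrow(betas) == 0)
    return(matrix(numeric(0), 0, ncol(betas), dimnames = list(NULL, ids)))

  n_pcs <- min(n_pcs, ncol(betas) - 1L, nrow(betas))
  pcs <- NULL
  if (n_pcs > 0) {
    filled <- betas
    if (anyNA(filled)) {   # probe-mean imputation, PCA only
      mu <- rowMeans(filled, na.rm = TRUE)
      idx <- which(is.na(filled), arr.ind = TRUE)
      filled[idx] <- mu[idx[, 1]]
    }
    pcs <- compute_pcs(t(filled), n_pcs)
  }
  X <- covariate_design(sheet, pcs)
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8) stop("kinship matrix is not PSD")

  res <- matrix(NA_real_, nrow(betas), ncol(betas),
                dimnames = dimnames(betas))
  for (i in seq_len(nrow(betas))) {
    y <- betas[i, ]
    if (sd(y, na.rm = TRUE) == 0 || anyNA(y)) {
      if (all(is.na(y)) || sd(y, na.rm = TRUE) == 0) { res[i, !is.na(y)] <- 0; next }
      fit <- fit_lmm(y, X, K)
    } else {
      fit <- fit_lmm(y, X, K, eig = eig)
    }
    r <- lmm_residuals(fit, type)
    r <- r - mean(r, na.rm = TRUE)
    res[i, ] <- r
  }
  res
}
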