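#' Quality-control filter for a genotype table
#'
#' Samples with genotype missingness above `sample_miss` are removed first;
#' then SNPs with minor allele frequency below `maf` or missingness above
#' `snp_miss` are removed.  Removal counts are reported with a message.
#'
#' @param gt a `genotype_table` (list with matrix `G` of 0/1/2 dosages and
#'   `map`), e.g. from [simulate_f2_cross()].
#' @param sample_miss maximum sample missingness (default 0.10).
#' @param snp_miss maximum SNP missingness (default 0.10).
#' @param maf minimum minor allele frequency (default 0.05).
#' @return the filtered `genotype_table`.
#' @export
qc_filter <- function(gt, sample_miss = 0.10, snp_miss = 0.10, maf = 0.05) {
  G <- gt$G
  smiss <- rowMeans(is.na(G))
  keep_s <- smiss <= sample_miss
  if (!any(keep_s)) stop("all samples removed by missingness filter")
  G <- G[keep_s, , drop = FALSE]
  p <- colMeans(G, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  vmiss <- colMeans(is.na(G))
  keep_v <- !is.na(mafs) & mafs >= maf & vmiss <= snp_miss
  message("qc_filter: removed ", sum(!keep_s), " sample(s), ",
          sum(!keep_v), " SNP(s)")
  structure(list(G = G[, keep_v, drop = FALSE],
                 map = gt$map[keep_v, , drop = FALSE],
                 samples = gt$samples[keep_s]),
            class = "genotype_table")
}

#' SNP-based relatedness (kinship) matrix
#'
#' Missing genotypes are mean-imputed per SNP; zero-variance SNPs are
#' excluded; the centered (optionally standardized) genotype cross-product is
#' divided by the number of SNPs used.  The result is symmetric positive
#' semi-definite up to numerical tolerance.
#'
#' @param gt a `genotype_table` (post-QC).
#' @param standardized divide each SNP by `sqrt(2 p (1-p))` (default FALSE:
#'   centered only).
#' @return n x n kinship matrix with sample dimnames.
#' @export
kinship_matrix <- function(gt, standardized = FALSE) {
  G <- gt$G
  mu <- colMeans(G, na.rm = TRUE)
  for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  v <- apply(G, 2, stats::var)
  use <- v > 0
  X <- sweep(G[, use, drop = FALSE], 2, mu[use])
  if (standardized) {
    p <- mu[use] / 2
    X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  }
  K <- tcrossprod(X) / ncol(X)
  dimnames(K) <- list(gt$samples, gt$samples)
  K
}

# profile log-likelihood of the null LMM at variance ratio lambda, in the
# eigenbasis of K (d = eigenvalues, ys/Ws rotated response/covariates)
null_loglik <- function(log_lambda, d, ys, Ws) {
  lam <- exp(log_lambda)
  v <- lam * d + 1
  w <- 1 / v
  WtW <- crossprod(Ws * w, Ws)
  Wty <- crossprod(Ws * w, ys)
  alpha <- solve(WtW, Wty)
  r <- ys - Ws %*% alpha
  rss <- sum(w * r^2)
  n <- length(ys)
  -0.5 * (n * log(rss / n) + sum(log(v)))
}

#' Linear mixed model association scan
#'
#' Fits `y = W alpha + x beta + u + e` with `u ~ MVN(0, lambda tau^-1 K)` and
#' `e ~ MVN(0, tau^-1 I)`.  The variance ratio `lambda` is estimated once by
#' maximum likelihood on the null model (no SNP) via a log10 grid search with
#' golden-section refinement on the eigendecomposition of `K`, then held
#' fixed across SNPs (the usual scan approximation); each SNP is tested by
#' generalized least squares in the rotated space with a Wald chi-square(1)
#' test on `beta^2 / se^2`.  Missing genotypes are mean-imputed.
#'
#' @param y numeric trait vector (length n, finite).
#' @param W covariate matrix including the intercept (n x c), or `NULL` for
#'   intercept only.
#' @param X genotype matrix (n x m, 0/1/2 dosages).
#' @param K kinship matrix from [kinship_matrix()].
#' @param map optional data.frame with one row per SNP (`snp`, `contig`,
#'   `pos`) carried into the result.
#' @return data.frame with columns `snp`, `contig`, `pos` (when `map` given),
#'   `beta`, `se`, `wald`, `p`, `n`, plus attribute `lambda`.
#' @export
lmm_scan <- function(y, W = NULL, X, K, map = NULL) {
  if (any(!is.finite(y))) stop("non-finite trait values")
  n <- length(y)
  if (n < 10) stop("need at least 10 samples")
  if (is.null(W)) W <- matrix(1, n, 1)
  if (qr(W)$rank < ncol(W)) stop("singular covariate matrix")
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- as.vector(crossprod(U, y))
  Ws <- crossprod(U, W)
  Xs <- crossprod(U, X)
  # ML estimate of lambda on the null model: coarse log-grid then
  # golden-section refinement
  grid <- seq(-5, 5, by = 0.25)
  ll <- vapply(grid, null_loglik, numeric(1), d = d, ys = ys, Ws = Ws)
  i0 <- which.max(ll)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- null_loglik(x1, d, ys, Ws); f2 <- null_loglik(x2, d, ys, Ws)
  for (it in 1:40) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- null_loglik(x2, d, ys, Ws)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- null_loglik(x1, d, ys, Ws)
    }
    if (abs(b - a) < 1e-6) break
  }
  lambda <- exp((a + b) / 2)
  w <- 1 / (lambda * d + 1)
  m <- ncol(X)
  beta <- se <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    xj <- X[, j]
    if (any(is.na(xj))) xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
    xs <- as.vector(crossprod(U, xj))
    M <- cbind(Ws, xs)
    MtM <- crossprod(M * w, M)
    Mty <- crossprod(M * w, ys)
    ok <- tryCatch({ coef <- solve(MtM, Mty); TRUE }, error = function(e) FALSE)
    if (!ok) next
    r <- ys - M %*% coef
    df <- n - ncol(M)
    sigma2 <- sum(w * r^2) / df
    covb <- sigma2 * solve(MtM)
    k <- ncol(M)
    beta[j] <- coef[k]
    se[j] <- sqrt(covb[k, k])
  }
  wald <- (beta / se)^2
  p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  out <- data.frame(snp = if (!is.null(map)) map$snp else
                      sprintf("snp%05d", seq_len(m)),
                    beta = beta, se = se, wald = wald, p = p, n = n,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) { out$contig <- map$contig; out$pos <- map$pos }
  attr(out, "lambda") <- lambda
  out
}

#' Bonferroni genome-wide significance threshold
#'
#' `alpha / m`, reported to 3 significant figures (e.g. 0.05 over 647,471
#' tests gives 7.72e-8).
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests (>= 1).
#' @return the threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  signif(alpha / m, 3)
}
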