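#' Rank-based inverse normal transform of one vector
#'
#' Blom offsets: \code{qnorm((rank - 3/8) / (n + 1/4))}; ties receive
#' average ranks so tied inputs map to identical outputs.
#'
#' @param x numeric vector (NA kept as NA).
#' @param offset numerator offset (3/8 = Blom, configurable).
#' @return transformed vector, mean ~ 0 and SD ~ 1; all zeros (with a
#'   warning) when \code{x} has zero variance.
#' @export
rbint <- function(x, offset = 3 / 8) {
  ok <- !is.na(x)
  out <- rep(NA_real_, length(x))
  if (sum(ok) == 0L) return(out)
  if (var(x[ok]) == 0) {
    warning("zero-variance input: rank-based INT maps to all zeros")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - offset) / (sum(ok) + 1 - 2 * offset))
  out
}

# median-target quantile normalisation of a genes x samples matrix:
# the target distribution is the per-rank MEDIAN across samples.
.quantile_normalize_median <- function(v) {
  target <- apply(apply(v, 2, sort), 1, median)
  out <- apply(v, 2, function(x) {
    r <- rank(x, ties.method = "average")
    # average the target over tied ranks via linear interpolation
    approx(seq_along(target), target, xout = r)$y
  })
  dimnames(out) <- dimnames(v)
  out
}

# per-gene robust-regression outlier replacement: fit a Huber robust model
# (tuning 1.345) of the gene on the covariates (intercept-only when NULL),
# flag residuals beyond Q1 - 3 IQR / Q3 + 3 IQR, refit without them and
# substitute the refitted values.
.impute_outliers <- function(y, covar = NULL) {
  n <- length(y)
  Xm <- if (is.null(covar)) matrix(1, n, 1) else cbind(1, as.matrix(covar))
  fit <- tryCatch(
    MASS::rlm(Xm, y, psi = MASS::psi.huber, k = 1.345, maxit = 50),
    error = function(e) NULL)
  if (is.null(fit)) return(y)
  r <- y - drop(Xm %*% coef(fit))
  q <- quantile(r, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  out <- r < q[1] - 3 * iqr | r > q[2] + 3 * iqr
  if (!any(out) || sum(!out) <= ncol(Xm)) return(y)
  refit <- tryCatch(
    MASS::rlm(Xm[!out, , drop = FALSE], y[!out],
              psi = MASS::psi.huber, k = 1.345, maxit = 50),
    error = function(e) NULL)
  if (is.null(refit)) return(y)
  y[out] <- drop(Xm[out, , drop = FALSE] %*% coef(refit))
  y
}

#' Expression normalisation chain
#'
#' The four documented steps, applied in order:
#' \enumerate{
#'   \item \code{log2(TPM + 1)};
#'   \item quantile normalisation across samples with the per-rank
#'     \emph{median} as the target distribution (robust variant);
#'   \item per-gene robust-regression outlier replacement (residuals beyond
#'     three interquartile ranges outside the residual quartiles are
#'     replaced by refitted values);
#'   \item per-gene rank-based inverse normal transform (Blom offsets).
#' }
#'
#' @param expr an \linkS4class{ExpressionMatrix} at stage \code{"tpm"}
#'   (gene filter already applied).
#' @param covariates optional numeric matrix (samples x covariates) for the
#'   outlier-model regressors; intercept-only when NULL.
#' @param stop_at run the chain only up to this stage (for inspection).
#' @return the matrix at stage \code{"rbint"} (or \code{stop_at}); each
#'   gene then has mean ~ 0 and SD ~ 1.
#' @export
normalizeExpression <- function(expr, covariates = NULL,
                                stop_at = c("rbint", "qnorm", "log")) {
  stop_at <- match.arg(stop_at)
  stopifnot(exprStage(expr) == "tpm")
  v <- log2(exprValues(expr) + 1)
  if (stop_at == "log") return(.setStage(expr, v, "log"))
  v <- .quantile_normalize_median(v)
  if (stop_at == "qnorm") return(.setStage(expr, v, "qnorm"))
  v <- t(apply(v, 1, .impute_outliers, covar = covariates))
  v <- t(apply(v, 1, rbint))
  dimnames(v) <- dimnames(exprValues(expr))
  .setStage(expr, v, "rbint")
}

#' Hidden expression factors by covariate-residual PCA
#'
#' Projects the known covariates out of the normalised expression matrix and
#' returns the top \code{k} principal-component scores of the residuals as
#' latent factors (a PCA surrogate playing the adjustment role of
#' PEER-style factors). Factors are pairwise orthogonal with unit variance.
#'
#' @param expr an \linkS4class{ExpressionMatrix} at stage \code{"rbint"}
#'   (any numeric matrix genes x samples also accepted).
#' @param covariates numeric matrix samples x covariates (may be NULL).
#' @param k number of factors; the conventional sample-size scaling is 30
#'   factors for n ~ 180 and 15 for n ~ 100 (see [defaultHiddenFactorK()]).
#' @return samples x k matrix of factor scores.
#' @export
estimateHiddenFactors <- function(expr, covariates = NULL, k) {
  v <- if (methods::is(expr, "ExpressionMatrix")) exprValues(expr) else expr
  n <- ncol(v)
  if (k == 0L)
    return(matrix(0, n, 0, dimnames = list(colnames(v), NULL)))
  Y <- t(scale(t(v), scale = FALSE))    # centre genes
  Ys <- t(Y)                            # samples x genes
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    Q <- qr.Q(qr(cbind(1, as.matrix(covariates))))
    Ys <- Ys - Q %*% crossprod(Q, Ys)
  } else {
    Ys <- scale(Ys, scale = FALSE)
  }
  k <- min(k, n - 1L, ncol(Ys))
  s <- svd(Ys, nu = k, nv = 0)
  f <- scale(s$u[, seq_len(k), drop = FALSE] *
               rep(s$d[seq_len(k)], each = n))
  attr(f, "scaled:center") <- NULL
  attr(f, "scaled:scale") <- NULL
  dimnames(f) <- list(colnames(v), paste0("HF", seq_len(k)))
  f
}

#' Sample-size-scaled hidden factor count
#'
#' The conventional tiering: 15 factors below 150 samples, 30 from 150 to
#' 250, 45 above.
#' @param n number of samples.
#' @export
defaultHiddenFactorK <- function(n) {
  if (n < 150) 15L else if (n <= 250) 30L else 45L
}

#' Genotype principal components
#'
#' Top-\code{k} principal components of the centred, allele-frequency-scaled
#' dosage matrix (each variant centred at 2p and scaled by
#' \code{sqrt(2p(1-p))}).
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param k number of components (default 3).
#' @return samples x k matrix of PC scores.
#' @export
genotypePCs <- function(geno, k = 3L) {
  d <- dosages(geno)                 # variants x samples
  p <- rowMeans(d, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  d <- d[keep, , drop = FALSE]; p <- p[keep]
  z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  z[is.na(z)] <- 0
  k <- min(k, ncol(d) - 1L, nrow(d))
  s <- svd(t(z), nu = k, nv = 0)
  pcs <- s$u[, seq_len(k), drop = FALSE] * rep(s$d[seq_len(k)],
                                               each = ncol(d))
  dimnames(pcs) <- list(colnames(d), paste0("PC", seq_len(k)))
  pcs
}
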