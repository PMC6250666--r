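#' Select independent instruments by greedy LD pruning
#'
#' Orders the gene's eQTL results by ascending p and keeps a SNP iff its p
#' is below \code{p_max} and its r^2 with every already-kept SNP is below
#' \code{r2_max}.
#'
#' @param eqtl_results data.frame (snp, p) for one gene.
#' @param geno \linkS4class{GenotypeMatrix} (LD reference) or variants x
#'   samples dosage matrix.
#' @param r2_max LD pruning threshold (default 0.2).
#' @param p_max instrument p-value threshold (default 0.08).
#' @return character vector of instrument snp ids (>= 1, or an error).
#' @export
selectInstruments <- function(eqtl_results, geno, r2_max = 0.2,
                              p_max = 0.08) {
  d <- if (methods::is(geno, "GenotypeMatrix")) dosages(geno) else geno
  cand <- eqtl_results[eqtl_results$p < p_max, , drop = FALSE]
  cand <- cand[order(cand$p), , drop = FALSE]
  kept <- character(0)
  for (s in cand$snp) {
    if (!length(kept) ||
        all(drop(cor(d[s, ], t(d[kept, , drop = FALSE])))^2 < r2_max))
      kept <- c(kept, s)
  }
  if (!length(kept)) stop("no instruments pass the selection thresholds")
  if (length(kept) == 1L)
    warning("single instrument: only a Wald ratio estimate is possible")
  kept
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonise exposure and outcome summary rows
#'
#' Aligns the outcome beta to the exposure effect allele: allele swaps flip
#' the outcome sign; strand flips are resolved via the complement;
#' palindromic A/T and C/G SNPs are dropped by default; SNPs with
#' irreconcilable alleles are dropped with a reason.
#'
#' @param exposure data.frame (snp, effect_allele, other_allele, beta, se).
#' @param outcome data.frame with the same columns.
#' @param drop_palindromic drop A/T and C/G SNPs (default TRUE).
#' @return an \linkS4class{MrInstrumentSet}; dropped SNPs and reasons are in
#'   its \code{dropped} slot.
#' @export
harmonise <- function(exposure, outcome, drop_palindromic = TRUE) {
  m <- match(exposure$snp, outcome$snp)
  keep <- data.frame(snp = character(), effect_allele = character(),
                     beta_x = numeric(), se_x = numeric(),
                     beta_y = numeric(), se_y = numeric(),
                     stringsAsFactors = FALSE)
  dropped <- data.frame(snp = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(exposure))) {
    s <- exposure$snp[i]
    if (is.na(m[i])) {
      dropped <- rbind(dropped, data.frame(snp = s, reason = "no_outcome"))
      next
    }
    ea <- toupper(exposure$effect_allele[i])
    oa <- toupper(exposure$other_allele[i])
    if (drop_palindromic && identical(.complement[[ea]], oa)) {
      dropped <- rbind(dropped, data.frame(snp = s, reason = "palindromic"))
      next
    }
    oea <- toupper(outcome$effect_allele[m[i]])
    ooa <- toupper(outcome$other_allele[m[i]])
    flip <- if (oea == ea && ooa == oa) 1
      else if (oea == oa && ooa == ea) -1
      else if (oea == .complement[[ea]] && ooa == .complement[[oa]]) 1
      else if (oea == .complement[[oa]] && ooa == .complement[[ea]]) -1
      else NA
    if (is.na(flip)) {
      dropped <- rbind(dropped,
                       data.frame(snp = s, reason = "allele_mismatch"))
      next
    }
    keep <- rbind(keep, data.frame(
      snp = s, effect_allele = ea,
      beta_x = exposure$beta[i], se_x = exposure$se[i],
      beta_y = flip * outcome$beta[m[i]], se_y = outcome$se[m[i]],
      stringsAsFactors = FALSE))
  }
  MrInstrumentSet(keep, dropped)
}

.ins <- function(x) {
  if (methods::is(x, "MrInstrumentSet")) x@instruments
  else as.data.frame(x)
}

#' Plain inverse-variance-weighted estimate (closed form)
#'
#' \code{theta = sum(bx by / se_y^2) / sum(bx^2 / se_y^2)} — the reference
#' for the robust fit.
#'
#' @param instruments \linkS4class{MrInstrumentSet} or data.frame.
#' @return list(theta, se, p, method = "ivw").
#' @export
mrIvw <- function(instruments) {
  d <- .ins(instruments)
  w <- 1 / d$se_y^2
  theta <- sum(w * d$beta_x * d$beta_y) / sum(w * d$beta_x^2)
  se <- 1 / sqrt(sum(w * d$beta_x^2))
  list(method = "ivw", theta = theta, se = se,
       p = 2 * pnorm(-abs(theta / se)))
}

# MM-estimation (Tukey bisquare, 4.685) with inverse-variance weights,
# falling back to weighted least squares when the fit is (numerically)
# exact -- the robust scale estimate degenerates there.
.robust_wls <- function(formula, data, w) {
  data$.w <- w
  environment(formula) <- environment()
  ols <- lm(formula, data = data, weights = .w)
  scale_ref <- max(1e-8, sd(data$beta_y))
  if (sqrt(mean(resid(ols)^2)) < 1e-8 * scale_ref) {
    cf <- summary(ols)$coefficients
    cf[is.na(cf[, 2]) | !is.finite(cf[, 2]), 2] <- 0
    return(cf[, 1:2, drop = FALSE])
  }
  fit <- MASS::rlm(formula, data = data, weights = .w,
                   wt.method = "inv.var", method = "MM",
                   c = 4.685, maxit = 200)
  summary(fit)$coefficients[, 1:2, drop = FALSE]
}

.p_from <- function(est, se) if (se == 0) 0 else 2 * pnorm(-abs(est / se))

#' Robust inverse-variance-weighted MR estimate
#'
#' Slope of the zero-intercept regression of outcome on exposure betas with
#' weights 1/se_y^2, fitted by MM-estimation with Tukey's bisquare (tuning
#' 4.685) so that instruments with outlying ratio estimates are
#' down-weighted.
#'
#' @inheritParams mrIvw
#' @return list(method, theta, se, p).
#' @export
mrIvwRobust <- function(instruments) {
  d <- .ins(instruments)
  if (nrow(d) < 2L) stop("robust IVW needs at least 2 instruments")
  sm <- .robust_wls(beta_y ~ beta_x - 1, d, 1 / d$se_y^2)
  theta <- sm[1, 1]; se <- sm[1, 2]
  list(method = "ivw_robust", theta = theta, se = se,
       p = .p_from(theta, se))
}

# interpolated weighted median of x with weights w (Bowden's percentile
# construction: cumulative weight minus half the own weight, interpolate at
# 0.5)
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(x[1])
  if (0.5 >= cw[length(cw)]) return(x[length(x)])
  approx(cw, x, xout = 0.5, ties = "ordered")$y
}

#' Penalised weighted median MR estimate
#'
#' Ratio estimates \code{theta_j = beta_yj / beta_xj} carry weights
#' \code{w_j = beta_xj^2 / se_yj^2}, penalised by
#' \code{min(1, 20 * P(chi2_1 > Q_j))} where Q_j is instrument j's
#' contribution to Cochran's Q at the plain IVW estimate — heterogeneous
#' instruments are down-weighted. The estimate is the interpolated weighted
#' median; its standard error comes from a seeded parametric bootstrap.
#'
#' @inheritParams mrIvw
#' @param n_boot bootstrap resamples for the se (default 2000).
#' @param seed bootstrap seed.
#' @param penalty penalisation constant (default 20).
#' @return list(method, theta, se, p).
#' @export
mrWeightedMedianPenalised <- function(instruments, n_boot = 2000L,
                                      seed = 1L, penalty = 20) {
  d <- .ins(instruments)
  if (nrow(d) < 3L)
    stop("the weighted median needs at least 3 instruments")
  est <- function(bx, by) {
    th <- by / bx
    w <- bx^2 / d$se_y^2
    q_j <- w * (th - sum(w * th) / sum(w))^2
    wpen <- w * pmin(1, penalty * pchisq(q_j, 1, lower.tail = FALSE))
    .weighted_median(th, wpen)
  }
  theta <- est(d$beta_x, d$beta_y)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    est(rnorm(nrow(d), d$beta_x, d$se_x),
        rnorm(nrow(d), d$beta_y, d$se_y)), numeric(1))
  se <- sd(boots)
  list(method = "weighted_median_penalised", theta = theta, se = se,
       p = 2 * pnorm(-abs(theta / se)))
}

#' Robust MR-Egger regression
#'
#' Weighted regression of outcome on exposure betas WITH an intercept
#' (weights 1/se_y^2), fitted by MM-estimation with Tukey's bisquare
#' (4.685). Inputs are orientated so every beta_x >= 0 before fitting. The
#' slope is the causal estimate; the intercept measures directional
#' pleiotropy.
#'
#' @inheritParams mrIvw
#' @return list(method, theta, se, p, intercept, intercept_se,
#'   intercept_p).
#' @export
mrEggerRobust <- function(instruments) {
  d <- .ins(instruments)
  if (nrow(d) < 3L)
    stop("MR-Egger needs at least 3 instruments (slope + intercept)")
  flip <- sign(d$beta_x); flip[flip == 0] <- 1
  d$beta_x <- d$beta_x * flip
  d$beta_y <- d$beta_y * flip
  sm <- .robust_wls(beta_y ~ beta_x, d, 1 / d$se_y^2)
  theta <- sm["beta_x", 1]; se <- sm["beta_x", 2]
  a <- sm["(Intercept)", 1]; a_se <- sm["(Intercept)", 2]
  list(method = "egger_robust", theta = theta, se = se,
       p = .p_from(theta, se),
       intercept = a, intercept_se = a_se,
       intercept_p = .p_from(a, a_se))
}

#' MR sensitivity analyses
#'
#' Cochran's Q over the ratio estimates at the IVW point estimate
#' (\code{Q = sum w_j (theta_j - theta)^2}, \code{w_j = beta_x^2/se_y^2},
#' chi-square with J-1 df) and the Egger intercept test for directional
#' pleiotropy.
#'
#' @inheritParams mrIvw
#' @param theta evaluation point; defaults to the plain IVW estimate.
#' @return list(Q, Q_df, Q_p, egger_intercept, egger_intercept_p).
#' @export
mrSensitivity <- function(instruments, theta = NULL) {
  d <- .ins(instruments)
  if (is.null(theta)) theta <- mrIvw(instruments)$theta
  th <- d$beta_y / d$beta_x
  w <- d$beta_x^2 / d$se_y^2
  Q <- sum(w * (th - theta)^2)
  df <- nrow(d) - 1L
  out <- list(Q = Q, Q_df = df,
              Q_p = pchisq(Q, df, lower.tail = FALSE))
  if (nrow(d) >= 3L) {
    eg <- mrEggerRobust(instruments)
    out$egger_intercept <- eg$intercept
    out$egger_intercept_p <- eg$intercept_p
  }
  out
}

#' Causality verdict across the three robust estimators
#'
#' Causal iff at least two of the three method p-values fall below the
#' Bonferroni-corrected family level \code{alpha_family / m}.
#'
#' @param p_values numeric vector of method p-values.
#' @param m number of tests in the family (e.g. 7 genes, 11 isoforms).
#' @param alpha_family family-wise alpha (default 0.05).
#' @return list(causal, threshold, n_significant).
#' @export
mrVerdict <- function(p_values, m, alpha_family = 0.05) {
  thr <- alpha_family / m
  nsig <- sum(p_values < thr)
  list(causal = nsig >= 2L, threshold = thr, n_significant = nsig)
}

#' Run the full MR analysis for one gene
#'
#' @param instruments an \linkS4class{MrInstrumentSet}.
#' @param m Bonferroni family size for the verdict.
#' @param n_boot,seed bootstrap settings for the weighted median.
#' @return list: \code{estimates} (data.frame, one row per method),
#'   \code{sensitivity}, \code{verdict}.
#' @export
runMr <- function(instruments, m = 7L, n_boot = 2000L, seed = 1L) {
  ests <- list(mrIvwRobust(instruments),
               mrWeightedMedianPenalised(instruments, n_boot = n_boot,
                                         seed = seed),
               mrEggerRobust(instruments))
  tab <- data.frame(method = vapply(ests, `[[`, "", "method"),
                    theta = vapply(ests, `[[`, 0, "theta"),
                    se = vapply(ests, `[[`, 0, "se"),
                    p = vapply(ests, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  list(estimates = tab,
       sensitivity = mrSensitivity(instruments),
       verdict = mrVerdict(tab$p, m = m))
}
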