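# Random variance model (RVM): empirical-Bayes moderation of per-gene
# residual variances.
#
# Model: gene precisions 1/sigma_g^2 ~ Gamma(shape a, scale b), so that for a
# residual variance s^2 with m degrees of freedom, a*b*s^2 ~ F(m, 2a). The
# user-facing prior is the derived (nu0 = 2a, s0^2 = 1/(a*b)) pair: the prior
# acts as nu0 extra degrees of freedom at variance s0^2.

RVM_A_MAX <- 1e6  # finite stand-in for "complete shrinkage" (a -> Inf)

rvm_params <- function(a, b, loglik = NA_real_, n_genes_fit = NA_integer_,
                       converged = NA) {
  if (!(a > 0 && b > 0)) pt_error("a and b must be positive", "bad_rvm")
  structure(list(a = a, b = b, nu0 = 2 * a, s0_sq = 1 / (a * b),
                 fit_loglik = loglik, n_genes_fit = n_genes_fit,
                 converged = converged),
            class = "rvm_params")
}

#' @export
print.rvm_params <- function(x, ...) {
  cat(sprintf("RVM prior: a = %.4g, b = %.4g (nu0 = %.4g, s0^2 = %.4g)\n",
              x$a, x$b, x$nu0, x$s0_sq))
  if (!is.na(x$fit_loglik))
    cat(sprintf("  fitted on %d genes, loglik %.4f, converged: %s\n",
                x$n_genes_fit, x$fit_loglik, x$converged))
  invisible(x)
}

# log-likelihood of observed s^2 under a*b*s^2 ~ F(m, 2a); change of
# variables contributes the Jacobian a*b per observation
rvm_loglik <- function(a, b, s_sq, m) {
  sum(stats::df(a * b * s_sq, m, 2 * a, log = TRUE) + log(a * b))
}

# method-of-moments start: E[s^2] = 1/(b(a-1)),
# E[s^4]/E[s^2]^2 = (1 + 2/m) (a-1)/(a-2)
rvm_mom_start <- function(s_sq, m) {
  m1 <- mean(s_sq)
  ratio <- mean(s_sq^2) / m1^2
  r <- ratio / (1 + 2 / m)
  a0 <- if (r > 1 + 1e-12) (2 * r - 1) / (r - 1) else 100
  a0 <- min(max(a0, 1.1), 1e3)
  b0 <- 1 / (m1 * (a0 - 1))
  c(a0, b0)
}

#' Fit the random variance model to per-gene residual variances
#'
#' Maximum-likelihood fit of the inverse-gamma variance prior under the
#' scaled-F identity `a*b*s^2 ~ F(m, 2a)`. Optimization is quasi-Newton on
#' `(log a, log b)` from a method-of-moments start. Non-positive or
#' non-finite variances are excluded (with a message). When the observed
#' variances carry no overdispersion relative to the F(m, Inf) limit (e.g.
#' all equal), `a` is pinned at its upper bound `1e6` — complete shrinkage —
#' with a warning.
#'
#' @param residual_variances Per-gene residual variances `s^2` (positive).
#' @param m Common residual degrees of freedom of those variances.
#' @param init Optional `c(a, b)` start overriding method of moments.
#' @return An `rvm_params` object: `a`, `b`, derived `nu0 = 2a` and
#'   `s0_sq = 1/(a b)`, `fit_loglik`, `n_genes_fit`, `converged`.
#' @export
fit_rvm <- function(residual_variances, m, init = NULL) {
  ok <- is.finite(residual_variances) & residual_variances > 0
  if (any(!ok))
    message(sum(!ok), " gene(s) with non-positive or non-finite variance excluded from RVM fit")
  s_sq <- residual_variances[ok]
  if (length(s_sq) < 50L)
    pt_error("need >= 50 positive finite variances to fit the RVM", "bad_rvm")
  if (max(s_sq) / min(s_sq) < 1 + 1e-10) {
    warning("variances are (near-)identical: complete shrinkage (a at upper bound)",
            call. = FALSE)
    a <- RVM_A_MAX
    b <- 1 / (mean(s_sq) * a)  # s0_sq = 1/(ab) = mean(s^2)
    return(rvm_params(a, b, rvm_loglik(a, b, s_sq, m), length(s_sq), TRUE))
  }
  start <- if (is.null(init)) rvm_mom_start(s_sq, m) else init
  nll <- function(par) {
    a <- exp(par[1L]); b <- exp(par[2L])
    if (!is.finite(a) || !is.finite(b) || a > RVM_A_MAX) return(1e300)
    ll <- rvm_loglik(a, b, s_sq, m)
    if (!is.finite(ll)) return(1e300)
    -ll
  }
  opt <- stats::optim(log(start), nll, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-8))
  if (opt$convergence != 0L)
    pt_error(paste0("RVM optimizer failed to converge (code ", opt$convergence,
                    "): ", paste(utils::capture.output(utils::str(opt)), collapse = " ")),
             "rvm_nonconvergence")
  a <- min(exp(opt$par[1L]), RVM_A_MAX)
  b <- exp(opt$par[2L])
  rvm_params(a, b, -opt$value, length(s_sq), TRUE)
}

#' Moderate a per-gene variance toward the RVM prior
#'
#' Weighted combination `s~^2 = (m s^2 + nu0 s0^2) / (m + nu0)`; the result
#' always lies between `s^2` and `s0^2`.
#'
#' @param s_sq Per-gene residual variance(s).
#' @param m Residual degrees of freedom of `s_sq`.
#' @param params An `rvm_params` object (see [fit_rvm()]).
#' @return Moderated variance(s), same length as `s_sq`.
#' @export
moderate_variance <- function(s_sq, m, params) {
  stopifnot(inherits(params, "rvm_params"))
  (m * s_sq + params$nu0 * params$s0_sq) / (m + params$nu0)
}

#' Moderated F statistic and p-value
#'
#' `F = (ss_effect / df1) / s~^2`, referred to an F distribution with
#' `(df1, m + nu0)` degrees of freedom — the prior contributes `nu0` extra
#' denominator df. A zero moderated variance yields an infinite-F sentinel
#' with `p = 0` (warned).
#'
#' @param ss_effect Sum of squares of the tested effect.
#' @param df1 Numerator degrees of freedom (>= 1).
#' @param s_tilde_sq Moderated variance from [moderate_variance()].
#' @param m Residual degrees of freedom of the unmoderated variance.
#' @param params `rvm_params`.
#' @return List with vectors `F` and `p`.
#' @export
moderated_f <- function(ss_effect, df1, s_tilde_sq, m, params) {
  stopifnot(inherits(params, "rvm_params"), df1 >= 1)
  f <- (ss_effect / df1) / s_tilde_sq
  zero <- is.finite(ss_effect) & s_tilde_sq <= 0
  if (any(zero, na.rm = TRUE)) {
    warning("zero moderated variance: infinite F sentinel, p = 0", call. = FALSE)
    f[zero] <- Inf
  }
  p <- stats::pf(f, df1, m + params$nu0, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  list(F = f, p = p)
}
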