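#' Parameter set of a joint latent class model
#'
#' Collects every free parameter of a G-class JLCM under the
#' reference-class identifiability constraint (class G carries zero
#' logistic coefficients, so only G-1 rows are stored for `xi0`/`xi1`).
#' The random-effects covariance `B` and the residual standard deviation
#' `sigma_eps` are common to the classes; the random-effects mean is fixed
#' at zero, class-specific location being carried by the fixed effects.
#'
#' @param spec a [jlcm_spec()].
#' @param xi0 numeric vector of G-1 logistic intercepts.
#' @param xi1 (G-1) x q matrix of logistic covariate effects (q = number
#'   of logistic covariates).
#' @param gamma common longitudinal fixed effects, one per
#'   `longit_common_covariates` entry.
#' @param beta G x p matrix of class-specific longitudinal fixed effects;
#'   columns are `(Intercept)` followed by `longit_class_covariates`.
#' @param B random-effects covariance matrix (symmetric positive
#'   semi-definite, dimension = number of random effects); a scalar is
#'   accepted for a random-intercept model.
#' @param sigma_eps residual standard deviation (> 0).
#' @param zeta1,zeta2 per-class Weibull scale and shape vectors (length G,
#'   all > 0), in the spec's parameterization.
#' @param vartheta common survival covariate effects.
#' @param eta G x s matrix of class-specific survival covariate effects.
#' @return an object of class `jlcm_params`.
#' @examples
#' sp <- jlcm_spec(2)
#' jlcm_params(sp, xi0 = log(0.3 / 0.7),
#'             beta = rbind(c(170, 88), c(100, 1.2)),
#'             B = 50, sigma_eps = sqrt(60),
#'             zeta1 = c(4.5, 50), zeta2 = c(2, 1.01))
#' @export
jlcm_params <- function(spec, xi0 = numeric(spec$n_classes - 1L),
                        xi1 = NULL, gamma = NULL, beta, B, sigma_eps,
                        zeta1, zeta2, vartheta = NULL, eta = NULL) {
  stopifnot(inherits(spec, "jlcm_spec"))
  G <- spec$n_classes
  q <- length(spec$logistic_covariates)
  p <- length(longit_class_terms(spec))
  r <- n_ranef(spec)
  s1 <- length(spec$surv_common_covariates)
  s2 <- length(spec$surv_class_covariates)

  xi0 <- as.numeric(xi0)
  if (length(xi0) != G - 1L)
    stop("'xi0' must have length G-1 = ", G - 1L)
  if (is.null(xi1)) xi1 <- matrix(0, G - 1L, q)
  xi1 <- matrix(as.numeric(xi1), G - 1L, q)
  if (is.null(gamma)) gamma <- numeric(length(spec$longit_common_covariates))
  if (length(gamma) != length(spec$longit_common_covariates))
    stop("'gamma' must have one entry per common longitudinal covariate")
  beta <- matrix(as.numeric(beta), G, p, byrow = FALSE,
                 dimnames = list(NULL, longit_class_terms(spec)))
  if (length(beta) != G * p)
    stop("'beta' must be a G x ", p, " matrix")
  B <- as.matrix(B)
  if (!all(dim(B) == r))
    stop("'B' must be ", r, " x ", r)
  if (max(abs(B - t(B))) > 1e-8) stop("'B' must be symmetric")
  if (min(eigen(B, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("'B' must be positive semi-definite")
  sigma_eps <- as.numeric(sigma_eps)
  if (length(sigma_eps) != 1L || sigma_eps <= 0)
    stop("'sigma_eps' must be a single positive number")
  zeta1 <- as.numeric(zeta1); zeta2 <- as.numeric(zeta2)
  if (length(zeta1) != G || length(zeta2) != G)
    stop("'zeta1' and 'zeta2' must have length G = ", G)
  if (any(zeta1 <= 0) || any(zeta2 <= 0))
    stop("Weibull parameters must be strictly positive")
  if (is.null(vartheta)) vartheta <- numeric(s1)
  if (length(vartheta) != s1)
    stop("'vartheta' must have one entry per common survival covariate")
  if (is.null(eta)) eta <- matrix(0, G, s2)
  eta <- matrix(as.numeric(eta), G, s2)

  structure(
    list(xi0 = xi0, xi1 = xi1, gamma = as.numeric(gamma), beta = beta,
         B = (B + t(B)) / 2, sigma_eps = sigma_eps,
         zeta1 = zeta1, zeta2 = zeta2,
         vartheta = as.numeric(vartheta), eta = eta),
    class = "jlcm_params")
}

#' @export
print.jlcm_params <- function(x, ...) {
  G <- length(x$zeta1)
  cat("JLCM parameter set (", G, if (G == 1) " class)\n" else " classes)\n",
      sep = "")
  if (G > 1) cat("  xi0:", format(x$xi0, digits = 4), "\n")
  if (length(x$gamma)) cat("  gamma:", format(x$gamma, digits = 4), "\n")
  cat("  beta (class x term):\n")
  print(round(x$beta, 4))
  cat("  sd(random effects):",
      format(sqrt(diag(as.matrix(x$B))), digits = 4), "\n")
  cat("  sigma_eps:", format(x$sigma_eps, digits = 4), "\n")
  cat("  Weibull scale:", format(x$zeta1, digits = 4),
      " shape:", format(x$zeta2, digits = 4), "\n")
  if (length(x$vartheta)) cat("  vartheta:", format(x$vartheta, digits = 4), "\n")
  if (length(x$eta)) cat("  eta:\n"); if (length(x$eta)) print(round(x$eta, 4))
  invisible(x)
}

## apply a permutation of class labels to all class-indexed parameters;
## the logistic block is re-expressed against the new reference class.
permute_params <- function(params, perm) {
  G <- length(params$zeta1)
  stopifnot(length(perm) == G, sort(perm) == seq_len(G))
  out <- params
  xi0f <- c(params$xi0, 0)[perm]
  out$xi0 <- xi0f[-G] - xi0f[G]
  if (ncol(params$xi1) > 0) {
    xi1f <- rbind(params$xi1, 0)[perm, , drop = FALSE]
    out$xi1 <- sweep(xi1f[-G, , drop = FALSE], 2, xi1f[G, ])
  }
  out$beta <- params$beta[perm, , drop = FALSE]
  out$zeta1 <- params$zeta1[perm]
  out$zeta2 <- params$zeta2[perm]
  out$eta <- params$eta[perm, , drop = FALSE]
  out
}
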