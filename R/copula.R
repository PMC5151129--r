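#' Convert a Spearman correlation to the Pearson correlation of a Gaussian copula
#'
#' For bivariate normal variables with Pearson correlation \eqn{r}, the
#' population Spearman correlation is \eqn{(6/\pi)\arcsin(r/2)}. Inverting
#' gives \eqn{r = 2\sin(\pi\rho_s/6)}: sampling normal variables at this
#' Pearson correlation yields data whose rank correlation is the requested
#' Spearman value. Used to calibrate the synthetic-data generator.
#'
#' @param rho_s numeric vector of Spearman correlations in \[-1, 1\].
#' @return Pearson correlation(s) in \[-1, 1\]; an odd, strictly increasing
#'   map with fixed points at -1, 0 and 1.
#' @examples
#' spearman_to_pearson(c(-1, 0, 0.5, 1))
#' @export
spearman_to_pearson <- function(rho_s) {
  if (!is.numeric(rho_s) || anyNA(rho_s)) {
    stop("'rho_s' must be numeric with no missing values")
  }
  if (any(rho_s < -1 | rho_s > 1)) {
    stop("Spearman correlation out of range [-1, 1]: ",
         paste(format(rho_s[rho_s < -1 | rho_s > 1]), collapse = ", "))
  }
  2 * sin(pi * rho_s / 6)
}

# Repair a symmetric correlation matrix to positive definiteness by clipping
# eigenvalues at `floor` and rescaling to unit diagonal. Returns the repaired
# matrix with attribute "repaired" (logical) and "max_change" (largest absolute
# entry change). Errors if the repair perturbs any requested entry by more
# than `max_change_tol`, naming the worst offending pairs.
repair_correlation <- function(R, floor = 1e-8, max_change_tol = 0.05,
                               labels = NULL) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= floor) {
    attr(R, "repaired") <- FALSE
    attr(R, "max_change") <- 0
    return(R)
  }
  lam <- pmax(ev$values, floor)
  R2 <- ev$vectors %*% (lam * t(ev$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  delta <- abs(R2 - R)
  mc <- max(delta)
  if (mc > max_change_tol) {
    idx <- which(delta == mc, arr.ind = TRUE)[1, ]
    nm <- if (is.null(labels)) paste(idx, collapse = ",") else
      paste(labels[idx], collapse = " / ")
    stop(sprintf(paste0(
      "target correlation matrix is not positive definite and cannot be ",
      "repaired within an entry change of %.3g (worst pair: %s, change %.3g); ",
      "relax the planted correlations"), max_change_tol, nm, mc))
  }
  warning(sprintf(
    "target correlation matrix repaired to positive definite (eigenvalue floor %g, max entry change %.3g)",
    floor, mc))
  attr(R2, "repaired") <- TRUE
  attr(R2, "max_change") <- mc
  R2
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. NULL seed evaluates in the current state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
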