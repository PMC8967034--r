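## sparCC correlations for compositional count data.
##
## For components i, j the log-ratio variance t_ij = Var(log((x_i + pc) /
## (x_j + pc))) across samples decomposes as t_ij = w_i + w_j - 2 rho_ij
## sqrt(w_i w_j), where w are the basis (log) variances. Under the sparse-
## correlation assumption (sum of covariances of each component with the
## rest ~ 0) the basis variances solve a linear system in the row sums of t;
## correlations follow as rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j)).
## Strongly correlated pairs violate the assumption, so the strongest pair
## is iteratively excluded from the system and the variances re-solved.

#' sparCC correlation matrix
#'
#' @param x proteins (components) x samples count matrix; rows that are all
#'   zero are removed.
#' @param n_iterations maximum exclusion iterations (default 20).
#' @param exclusion_threshold stop excluding once the strongest remaining
#'   |rho| is below this (default 0.1).
#' @param pseudocount added to counts before logging (default 1).
#' @return M x M correlation matrix, clipped to \[-1, 1\], unit diagonal.
#'   With fewer than 4 components the sparCC system is under-determined and
#'   the function falls back to Pearson correlation of CLR-transformed
#'   counts, with a warning.
#' @export
sparcc <- function(x, n_iterations = 20L, exclusion_threshold = 0.1,
                   pseudocount = 1) {
  stopifnot(is.matrix(x), pseudocount > 0)
  x <- x[rowSums(x) > 0, , drop = FALSE]
  M <- nrow(x)
  if (ncol(x) < 3L) stop("need at least 3 samples for correlation")
  if (M < 4L) {
    warning("fewer than 4 components: falling back to CLR-Pearson")
    return(clr_pearson(x, pseudocount))
  }
  lx <- log(x + pseudocount)
  ## all pairwise log-ratio variances: Var(a - b) = Var a + Var b - 2 Cov
  cv <- stats::cov(t(lx))
  v <- diag(cv)
  t_mat <- outer(v, v, "+") - 2 * cv
  diag(t_mat) <- 0

  excluded <- matrix(FALSE, M, M)
  rho <- solve_basis(t_mat, excluded)
  for (it in seq_len(n_iterations)) {
    cand <- abs(rho)
    cand[!upper.tri(cand)] <- -Inf
    cand[excluded] <- -Inf
    mx <- max(cand)
    if (!is.finite(mx) || mx < exclusion_threshold) break
    top <- which(cand == mx, arr.ind = TRUE)[1, ]
    excluded[top[1], top[2]] <- excluded[top[2], top[1]] <- TRUE
    ## keep every component in at least one pair
    if (any(rowSums(!excluded) - 1L < 2L)) break
    rho <- solve_basis(t_mat, excluded)
  }
  dimnames(rho) <- list(rownames(x), rownames(x))
  rho
}

## solve for basis variances given the exclusion mask, return correlations
solve_basis <- function(t_mat, excluded) {
  M <- nrow(t_mat)
  incl <- !excluded
  diag(incl) <- FALSE
  A <- incl * 1
  diag(A) <- rowSums(incl)
  ti <- rowSums(t_mat * incl)
  w <- tryCatch(solve(A, ti), error = function(e) rep(NA_real_, M))
  if (anyNA(w)) w <- rep(mean(t_mat[upper.tri(t_mat)]) / 2, M)
  w <- pmax(w, 1e-12)
  rho <- (outer(w, w, "+") - t_mat) / (2 * sqrt(outer(w, w)))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

#' Pearson correlation of CLR-transformed counts
#'
#' Fallback compositional correlation for very small component sets.
#'
#' @inheritParams sparcc
#' @return M x M correlation matrix.
#' @export
clr_pearson <- function(x, pseudocount = 1) {
  lx <- log(x + pseudocount)
  clr <- sweep(lx, 2, colMeans(lx))
  r <- stats::cor(t(clr))
  dimnames(r) <- list(rownames(x), rownames(x))
  r
}
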