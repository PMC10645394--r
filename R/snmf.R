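#' Sparse non-negative matrix factorization of pseudobulk profiles
#'
#' Factorizes a non-negative genes x pseudobulks matrix `X ~ W H` with an L1
#' sparsity penalty `rho` on the coefficient matrix `H`, by multiplicative
#' updates. Columns of `W` are renormalized to unit Euclidean norm each
#' iteration (with the compensating rescale of `H`) so the penalty has a fixed
#' scale. The first restart is initialized by non-negative double SVD (NNDSVD);
#' further restarts use seeded random initializations, and the restart with the
#' lowest reconstruction error is kept. Each column's provisional cluster label
#' is the argmax of its coefficient vector (ties to the lowest component
#' index).
#'
#' @param x non-negative numeric matrix (typically the `shifted` fold matrix
#'   restricted to guide genes).
#' @param k number of components; must be `< ncol(x)`.
#' @param rho L1 sparsity weight on the coefficients (default 0.3).
#' @param n_restarts number of initializations (default 10).
#' @param max_iter,tol iteration cap and relative-objective convergence
#'   tolerance.
#' @param seed integer seed making the restarts reproducible.
#'
#' @return list with `basis` (genes x k), `coefficients` (k x columns),
#'   `labels` (integer component per column), `recon_error` (relative
#'   Frobenius), `converged`.
#' @export
snmf_factorize <- function(x, k, rho = 0.3, n_restarts = 10,
                           max_iter = 300, tol = 1e-5, seed = 1) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("input matrix must be non-negative", call. = FALSE)
  if (k >= ncol(x)) stop("'k' must be smaller than the number of columns",
                         call. = FALSE)
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  xnorm <- sqrt(sum(x^2))
  if (xnorm == 0) stop("input matrix is identically zero", call. = FALSE)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1L) .nndsvd_init(x, k) else {
      set.seed((seed + 7919L * r) %% .Machine$integer.max)
      list(W = matrix(stats::runif(nrow(x) * k, 0, max(x)), ncol = k),
           H = matrix(stats::runif(k * ncol(x), 0, 1), nrow = k))
    }
    fit <- .snmf_mu(x, init$W, init$H, rho = rho, max_iter = max_iter,
                    tol = tol)
    fit$recon_error <- sqrt(sum((x - fit$W %*% fit$H)^2)) / xnorm
    if (is.null(best) || fit$recon_error < best$recon_error) best <- fit
  }
  if (!best$converged)
    warning("sparse NMF did not converge within ", max_iter,
            " iterations; returning best iterate", call. = FALSE)

  labels <- apply(best$H, 2, which.max)   # ties: lowest component index
  dimnames(best$W) <- list(rownames(x), paste0("C", seq_len(k)))
  dimnames(best$H) <- list(paste0("C", seq_len(k)), colnames(x))
  list(basis = best$W, coefficients = best$H,
       labels = stats::setNames(as.integer(labels), colnames(x)),
       recon_error = best$recon_error, converged = best$converged)
}

# multiplicative updates for 0.5||X-WH||^2 + rho * sum(H), W >= 0, H >= 0,
# with unit-norm basis columns
.snmf_mu <- function(x, W, H, rho, max_iter, tol) {
  eps <- 1e-10
  W <- pmax(W, eps); H <- pmax(H, eps)
  nrm <- sqrt(colSums(W^2)); nrm[nrm == 0] <- 1
  W <- sweep(W, 2, nrm, "/"); H <- H * nrm
  obj_old <- Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    H <- H * crossprod(W, x) / (crossprod(W, WH) + rho + eps)
    WH <- W %*% H
    W <- W * tcrossprod(x, H) / (tcrossprod(WH, H) + eps)
    nrm <- sqrt(colSums(W^2)); nrm[nrm == 0] <- 1
    W <- sweep(W, 2, nrm, "/"); H <- H * nrm
    if (it %% 10L == 0L || it == max_iter) {
      obj <- 0.5 * sum((x - W %*% H)^2) + rho * sum(H)
      if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(obj_old, eps)) {
        converged <- TRUE
        break
      }
      obj_old <- obj
    }
  }
  list(W = W, H = H, converged = converged)
}

# non-negative double SVD initialization (positive/negative part splitting of
# the leading singular vectors; zero components fall back to the matrix mean)
.nndsvd_init <- function(x, k) {
  s <- svd(x, nu = k, nv = k)
  m <- nrow(x); n <- ncol(x)
  W <- matrix(0, m, k); H <- matrix(0, k, n)
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    n_up <- sqrt(sum(up^2)); n_un <- sqrt(sum(un^2))
    n_vp <- sqrt(sum(vp^2)); n_vn <- sqrt(sum(vn^2))
    if (n_up * n_vp >= n_un * n_vn) {
      sig <- n_up * n_vp
      if (sig > 0) {
        W[, j] <- sqrt(s$d[j] * sig) * up / n_up
        H[j, ] <- sqrt(s$d[j] * sig) * vp / n_vp
      }
    } else {
      sig <- n_un * n_vn
      if (sig > 0) {
        W[, j] <- sqrt(s$d[j] * sig) * un / n_un
        H[j, ] <- sqrt(s$d[j] * sig) * vn / n_vn
      }
    }
  }
  mn <- mean(x)
  W[W == 0] <- mn / k
  H[H == 0] <- mn / k
  list(W = W, H = H)
}
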