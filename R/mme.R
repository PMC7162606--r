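#' Mixed-model-equation solution
#'
#' @slot fixed named vector of fixed-effect solutions (per trait for the
#'   multi-trait model, names prefixed by trait).
#' @slot gebv matrix of additive solutions, animals x traits (one column for
#'   single-trait models), rownames = animal ids.
#' @slot residualNorm relative residual of the assembled normal equations.
#' @exportClass MMESolution
setClass("MMESolution",
  representation(fixed = "numeric", gebv = "matrix", residualNorm = "numeric"))

setMethod("show", "MMESolution", function(object) {
  cat(sprintf("MMESolution: %d animals x %d trait(s), residual %.2e\n",
              nrow(object@gebv), ncol(object@gebv), object@residualNorm))
})

.asKinv <- function(K) {
  if (is(K, "RelationshipMatrix")) {
    if (!K@kind %in% c("Ainv", "Hinv"))
      stop("expected an inverse relationship matrix (Ainv or Hinv)")
    list(M = K@values, labels = K@labels)
  } else {
    if (is.null(rownames(K))) stop("inverse relationship matrix needs dimnames")
    list(M = K, labels = rownames(K))
  }
}

.fixedDesign <- function(data, fixed) {
  keep <- character()
  for (v in all.vars(fixed)) {
    if (is.character(data[[v]]) || is.factor(data[[v]])) {
      data[[v]] <- droplevels(factor(data[[v]]))
      ## a factor observed at a single level is not estimable alongside the
      ## intercept; drop it rather than fail
      if (nlevels(data[[v]]) >= 2L) keep <- c(keep, v)
    } else keep <- c(keep, v)
  }
  f <- if (length(keep)) as.formula(paste("~", paste(keep, collapse = "+")))
       else ~1
  stats::model.matrix(f, data)
}

#' Solve the single-trait animal model
#'
#' Solves the mixed-model equations for y = Xb + Zu + e with u ~ N(0,
#' sigma2u * K), where K^-1 is a pedigree or single-step hybrid inverse over
#' all animals. Animals without records receive breeding values through the
#' relationships. Fixed-effect factors use drop-first-level (treatment)
#' constraints.
#'
#' @param data data.frame with columns `id`, `y`, and any fixed-effect
#'   covariates; one record per row.
#' @param Kinv a [RelationshipMatrix-class] of kind "Ainv"/"Hinv", or a
#'   matrix with dimnames covering all animals.
#' @param varcomp list or [VarianceComponents-class] providing `sigma2u` and
#'   `sigma2e`.
#' @param fixed one-sided formula of fixed effects (intercept always
#'   included), default `~ sex + population` when those columns exist.
#' @return an [MMESolution-class].
#' @export
solveSingleTrait <- function(data, Kinv, varcomp, fixed = NULL) {
  kv <- .asKinv(Kinv)
  s2u <- if (is(varcomp, "VarianceComponents")) varcomp@sigma2u else varcomp$sigma2u
  s2e <- if (is(varcomp, "VarianceComponents")) varcomp@sigma2e else varcomp$sigma2e
  nA <- length(kv$labels)
  if (is.null(fixed)) {
    cand <- intersect(c("sex", "population"), names(data))
    fixed <- if (length(cand)) as.formula(paste("~", paste(cand, collapse = "+")))
             else ~1
  }
  if (s2u <= 0) {
    ## no additive variance: only fixed effects explain the data
    X <- .fixedDesign(data, fixed)
    b <- qr.coef(qr(X), data$y)
    b[is.na(b)] <- 0
    gebv <- matrix(0, nA, 1, dimnames = list(kv$labels, "trait1"))
    return(new("MMESolution", fixed = b, gebv = gebv, residualNorm = 0))
  }
  lambda <- s2e / s2u
  X <- .fixedDesign(data, fixed)
  aidx <- match(as.character(data$id), kv$labels)
  if (anyNA(aidx)) stop("records refer to animals absent from the relationship matrix")
  n <- nrow(data)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = aidx, x = 1,
                            dims = c(n, nA))
  Xs <- as(X, "CsparseMatrix")
  C <- rbind(cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
             cbind(Matrix::crossprod(Z, Xs),
                   Matrix::crossprod(Z) + lambda * as(kv$M, "CsparseMatrix")))
  rhs <- c(as.numeric(Matrix::crossprod(Xs, data$y)),
           as.numeric(Matrix::crossprod(Z, data$y)))
  sol <- .solveMme(C, rhs)
  p <- ncol(X)
  b <- sol$theta[seq_len(p)]
  names(b) <- colnames(X)
  gebv <- matrix(sol$theta[-seq_len(p)], nA, 1,
                 dimnames = list(kv$labels, "trait1"))
  new("MMESolution", fixed = b, gebv = gebv, residualNorm = sol$res)
}

## Jacobi-preconditioned conjugate gradients (the standard iterative solver
## for animal-model MMEs), with a supernodal Cholesky fallback and a ridge
## constraint for singular (non-estimable) systems.
.solveMme <- function(C, rhs, tol = 1e-10, maxit = 10000L) {
  C <- Matrix::forceSymmetric(C)
  theta <- .pcg(C, rhs, tol = tol, maxit = maxit)
  res <- .mmeResidual(C, theta, rhs)
  if (!is.finite(res) || res > 1e-8) {
    theta <- tryCatch(
      as.numeric(Matrix::solve(Matrix::Cholesky(C, LDL = FALSE, super = TRUE),
                               rhs)),
      error = function(e) {
        message("normal equations singular; applying a small ridge constraint")
        n <- nrow(C)
        ridge <- Matrix::Diagonal(n, 1e-8 * max(Matrix::diag(C)))
        as.numeric(Matrix::solve(Matrix::Cholesky(C + ridge, LDL = FALSE,
                                                  super = TRUE), rhs))
      })
    res <- .mmeResidual(C, theta, rhs)
  }
  list(theta = theta, res = res)
}

.mmeResidual <- function(C, theta, rhs) {
  sqrt(sum((as.numeric(C %*% theta) - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
}

.pcg <- function(C, b, tol = 1e-10, maxit = 10000L) {
  d <- Matrix::diag(C)
  d[d <= 0] <- 1
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- max(sqrt(sum(b^2)), 1e-300)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(C %*% p)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0) break
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * bnorm) break
    z <- r / d
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  x
}

#' Solve the three-trait (purebred/purebred/F1) animal model
#'
#' Records from different populations enter as different traits with additive
#' covariance G0 (x) H and diagonal residual covariance (each animal is
#' measured on exactly one trait). Every animal receives a breeding value for
#' every trait; crossbred validation uses the F1-trait column.
#'
#' @param data data.frame with `id`, `y`, `trait` (factor/character; level
#'   order defines the trait order of `G0`), and fixed-effect covariates.
#' @param Kinv inverse relationship matrix over all animals (see
#'   [solveSingleTrait()]).
#' @param G0 additive (co)variance matrix between traits (bent to positive
#'   definiteness with a warning if needed).
#' @param R0 diagonal residual covariance matrix (or vector of residual
#'   variances per trait).
#' @param fixed one-sided formula applied within each trait (default
#'   `~ sex` when present).
#' @return an [MMESolution-class] with one GEBV column per trait.
#' @export
solveMultiTrait <- function(data, Kinv, G0, R0, fixed = NULL) {
  kv <- .asKinv(Kinv)
  nA <- length(kv$labels)
  ## unused factor levels are kept: a trait without records still receives
  ## breeding values through the genetic covariance
  traits <- if (is.factor(data$trait)) levels(data$trait) else unique(data$trait)
  K <- length(traits)
  if (is.vector(R0)) R0 <- diag(R0, K)
  if (!all(dim(G0) == K) || !all(dim(R0) == K))
    stop("G0/R0 dimensions must match the number of traits")
  ev <- eigen((G0 + t(G0)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 1e-10 * max(ev$values)) {
    warning("G0 not positive definite; bending by minimum-eigenvalue shift")
    lam <- pmax(ev$values, 1e-8 * max(ev$values))
    G0 <- ev$vectors %*% (lam * t(ev$vectors))
  }
  if (is.null(fixed))
    fixed <- if ("sex" %in% names(data)) ~sex else ~1
  tidx <- match(as.character(data$trait), traits)
  aidx <- match(as.character(data$id), kv$labels)
  if (anyNA(aidx)) stop("records refer to animals absent from the relationship matrix")
  rInv <- 1 / diag(R0)[tidx]
  ## per-trait fixed-effect blocks
  Xl <- vector("list", K)
  for (t in seq_len(K)) {
    dt <- data[tidx == t, , drop = FALSE]
    if (!nrow(dt)) {
      Xl[[t]] <- matrix(0, 0, 0)
      next
    }
    Xt <- .fixedDesign(dt, fixed)
    colnames(Xt) <- paste0(traits[t], ":", colnames(Xt))
    Xl[[t]] <- Xt
  }
  pOff <- c(0, cumsum(vapply(Xl, ncol, 1L)))
  p <- pOff[K + 1]
  n <- nrow(data)
  Xi <- unlist(lapply(seq_len(K), function(t) rep(which(tidx == t),
                                                  ncol(Xl[[t]]))))
  Xj <- unlist(lapply(seq_len(K), function(t) rep(pOff[t] + seq_len(ncol(Xl[[t]])),
                                                  each = sum(tidx == t))))
  Xx <- unlist(lapply(Xl, function(m) as.numeric(m)))
  X <- Matrix::sparseMatrix(i = Xi, j = Xj, x = Xx, dims = c(n, p))
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = (tidx - 1L) * nA + aidx,
                            x = 1, dims = c(n, K * nA))
  G0i <- solve(G0)
  Kpen <- Matrix::kronecker(as(G0i, "CsparseMatrix"), as(kv$M, "CsparseMatrix"))
  XtR <- Matrix::t(rInv * X)
  ZtR <- Matrix::t(rInv * Z)
  C <- rbind(cbind(XtR %*% X, XtR %*% Z),
             cbind(ZtR %*% X, ZtR %*% Z + Kpen))
  rhs <- c(as.numeric(XtR %*% data$y), as.numeric(ZtR %*% data$y))
  sol <- .solveMme(C, rhs)
  b <- sol$theta[seq_len(p)]
  names(b) <- unlist(lapply(Xl, colnames))
  gebv <- matrix(sol$theta[-seq_len(p)], nA, K,
                 dimnames = list(kv$labels, traits))
  new("MMESolution", fixed = b, gebv = gebv, residualNorm = sol$res)
}

#' Pedigree BLUP breeding values for within-line selection
#'
#' Animal-model BLUP with the pedigree relationship matrix and variance
#' components fixed at their true (simulation) values; used to rank selection
#' candidates each generation.
#'
#' @param records data.frame `id`, `y` plus fixed-effect columns.
#' @param ped pedigree covering all candidate animals.
#' @param varcomp list with `sigma2u`, `sigma2e` (the true values).
#' @param fixed fixed-effect formula, default `~ sex` when present.
#' @return named numeric vector of EBVs for every animal in `ped`.
#' @export
pedigreeBlupEbv <- function(records, ped, varcomp, fixed = NULL) {
  if (is.null(fixed))
    fixed <- if ("sex" %in% names(records)) ~sex else ~1
  Ainv <- buildAinv(ped)
  sol <- solveSingleTrait(records, Ainv, varcomp, fixed = fixed)
  ebv <- sol@gebv[, 1]
  names(ebv) <- rownames(sol@gebv)
  ebv
}
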