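#' REML variance components with the pedigree relationship matrix
#'
#' Average-information REML on the marginal covariance of the recorded
#' animals. For the single-trait model V = sigma2u * A + sigma2e * I; for the
#' multi-trait (population-as-trait) model V = G0[t(i), t(j)] * A[i, j] +
#' diag(R0[t(i)]), i.e. the additive covariance is G0 (x) A restricted to the
#' one trait each animal is recorded on, and the residual covariance is
#' diagonal because traits are measured on different animals. The
#' relationship block among recorded animals is obtained from the full
#' pedigree by sparse triangular solves ([relSubset()]), so the pedigree can
#' be much larger than the record set.
#'
#' Updates are Newton steps with the average-information matrix, with step
#' halving whenever a step leaves the parameter space or decreases the
#' restricted likelihood, and a diagonal-AI (EM-flavoured) fallback when the
#' AI matrix is singular. Variances are floored at 1e-6 times the phenotypic
#' variance; a solution pinned at the floor is flagged as a boundary estimate.
#'
#' @param data data.frame with `id`, `y`, optionally `trait` (for the
#'   multi-trait model) and fixed-effect covariates.
#' @param ped pedigree data.frame covering (at least) all recorded animals.
#' @param model "single" or "multi".
#' @param fixed one-sided fixed-effect formula. Defaults: single-trait
#'   `~ sex + population` (available columns), multi-trait `~ sex` within
#'   trait.
#' @param maxit,tol iteration cap and relative-change convergence tolerance.
#' @param init optional initial values: list(sigma2u, sigma2e) or
#'   list(G0, R0).
#' @param Arec optional precomputed relationship block among `data$id`
#'   (skips [relSubset()]).
#' @return a [VarianceComponents-class].
#' @export
remlEstimate <- function(data, ped, model = c("single", "multi"), fixed = NULL,
                         maxit = 200, tol = 1e-8, init = NULL, Arec = NULL,
                         verbose = FALSE) {
  model <- match.arg(model)
  if (is.null(Arec)) Arec <- relSubset(ped, data$id)
  n <- nrow(data)
  stopifnot(nrow(Arec) == n)
  if (model == "single") {
    if (is.null(fixed)) {
      cand <- intersect(c("sex", "population"), names(data))
      fixed <- if (length(cand)) as.formula(paste("~", paste(cand, collapse = "+")))
               else ~1
    }
    X <- .fixedDesign(data, fixed)
    tidx <- rep(1L, n)
    K <- 1L
  } else {
    if (is.null(data$trait)) stop("multi-trait REML needs a trait column")
    if (is.null(fixed)) fixed <- if ("sex" %in% names(data)) ~sex else ~1
    traits <- if (is.factor(data$trait)) levels(droplevels(data$trait)) else unique(as.character(data$trait))
    K <- length(traits)
    tidx <- match(as.character(data$trait), traits)
    Xl <- lapply(seq_len(K), function(t) {
      Xt <- matrix(0, n, 0)
      dt <- data[tidx == t, , drop = FALSE]
      Xsub <- .fixedDesign(dt, fixed)
      Xt <- matrix(0, n, ncol(Xsub))
      Xt[tidx == t, ] <- Xsub
      colnames(Xt) <- paste0(traits[t], ":", colnames(Xsub))
      Xt
    })
    X <- do.call(cbind, Xl)
  }
  y <- data$y
  vy <- vapply(seq_len(K), function(t) var(y[tidx == t]), 0)

  ## parameter vector: genetic (co)variances in row-major lower triangle of
  ## G0, then residual variances
  gpar <- which(lower.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  nG <- nrow(gpar)
  pIsVar <- c(gpar[, 1] == gpar[, 2], rep(TRUE, K))
  np <- nG + K
  theta <- numeric(np)
  if (!is.null(init)) {
    if (K == 1L) {
      theta <- c(init$sigma2u, init$sigma2e)
    } else {
      G0i <- init$G0; R0i <- init$R0
      theta[seq_len(nG)] <- G0i[gpar]
      theta[nG + seq_len(K)] <- diag(as.matrix(R0i))
    }
  } else {
    G00 <- diag(0.4 * vy, K)
    for (r in seq_len(nG)) {
      k <- gpar[r, 1]; l <- gpar[r, 2]
      if (k != l) G00[k, l] <- G00[l, k] <- 0.5 * sqrt(G00[k, k] * G00[l, l])
    }
    theta[seq_len(nG)] <- G00[gpar]
    theta[nG + seq_len(K)] <- 0.6 * vy
  }
  floorV <- 1e-6 * max(vy)

  tMask <- lapply(seq_len(K), function(t) tidx == t)
  buildV <- function(th) {
    G0 <- matrix(0, K, K)
    G0[gpar] <- th[seq_len(nG)]
    G0 <- G0 + t(G0) - diag(diag(G0), K)
    r <- th[nG + seq_len(K)]
    V <- Arec * G0[tidx, tidx]
    diag(V) <- diag(V) + r[tidx]
    list(V = V, G0 = G0, r = r)
  }
  restrictedLL <- function(th) {
    Vb <- buildV(th)
    if (K > 1L) {
      ## the additive covariance matrix must stay positive definite
      if (inherits(tryCatch(chol(Vb$G0), error = function(e) e), "error"))
        return(NULL)
    }
    ch <- tryCatch(chol(Vb$V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    XtViXi <- chol2inv(chX)
    Py <- Vi %*% y - ViX %*% (XtViXi %*% crossprod(ViX, y))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                  sum(y * Py))
    list(ll = ll, Vi = Vi, ViX = ViX, XtViXi = XtViXi, Py = as.numeric(Py))
  }
  ## project a candidate's additive covariance matrix back to positive
  ## definiteness (minimum-eigenvalue bending), so a step that overshoots a
  ## correlation bound is repaired instead of rejected wholesale
  .bendG0 <- function(th, gpar, nG, K) {
    G0 <- matrix(0, K, K)
    G0[gpar] <- th[seq_len(nG)]
    G0 <- G0 + t(G0) - diag(diag(G0), K)
    e <- eigen(G0, symmetric = TRUE)
    lo <- 1e-6 * max(abs(e$values))
    if (min(e$values) < lo) {
      G0 <- e$vectors %*% (pmax(e$values, lo) * t(e$vectors))
      th[seq_len(nG)] <- G0[gpar]
    }
    th
  }
  dVmult <- function(i, v) {
    ## dV_i %*% v without forming dV_i
    if (i <= nG) {
      k <- gpar[i, 1]; l <- gpar[i, 2]
      out <- numeric(n)
      if (k == l) {
        av <- Arec %*% (v * tMask[[k]])
        out[tMask[[k]]] <- av[tMask[[k]]]
      } else {
        ## trait masks are disjoint
        avl <- Arec %*% (v * tMask[[l]])
        avk <- Arec %*% (v * tMask[[k]])
        out[tMask[[k]]] <- avl[tMask[[k]]]
        out[tMask[[l]]] <- avk[tMask[[l]]]
      }
      out
    } else {
      k <- i - nG
      v * tMask[[k]]
    }
  }

  state <- restrictedLL(theta)
  if (is.null(state)) stop("initial variance components give a singular system")
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    Vi <- state$Vi
    P <- Vi - state$ViX %*% state$XtViXi %*% t(state$ViX)
    Py <- state$Py
    PA <- P * Arec
    score <- numeric(np)
    Fm <- matrix(0, n, np)
    for (i in seq_len(np)) {
      if (i <= nG) {
        k <- gpar[i, 1]; l <- gpar[i, 2]
        trPD <- if (k == l) sum(PA[tMask[[k]], tMask[[k]]])
                else 2 * sum(PA[tMask[[k]], tMask[[l]]])
      } else {
        k <- i - nG
        trPD <- sum(diag(P)[tMask[[k]]])
      }
      Fm[, i] <- dVmult(i, Py)
      score[i] <- -0.5 * (trPD - sum(Py * Fm[, i]))
    }
    PF <- P %*% Fm
    AI <- 0.5 * crossprod(Fm, PF)
    fullStep <- tryCatch(solve(AI, score),
                         error = function(e) score / pmax(diag(AI), 1e-12))
    ## line search: the joint AI step first; if it needs deep halving (a
    ## poorly identified coordinate can make the joint direction useless),
    ## retry with the per-parameter diagonal-AI step
    ok <- FALSE
    for (pass in 1:2) {
      stp <- if (pass == 1L) fullStep else score / pmax(diag(AI), 1e-12)
      hmax <- if (pass == 1L) 8L else 25L
      for (h in 0:hmax) {
        cand <- theta + stp / 2^h
        cand[pIsVar] <- pmax(cand[pIsVar], floorV)
        if (K > 1L) cand <- .bendG0(cand, gpar, nG, K)
        newState <- restrictedLL(cand)
        if (!is.null(newState) && newState$ll >= state$ll - 1e-10) {
          ok <- TRUE
          break
        }
      }
      if (ok) break
    }
    if (!ok) { converged <- TRUE; break }  # no improving direction: stationary
    llGain <- newState$ll - state$ll
    delta <- max(abs(cand - theta) / (abs(theta) + max(vy)))
    theta <- cand
    state <- newState
    if (verbose)
      message(sprintf("it %3d  logLik %.4f  delta %.2e  pass %d  halvings %d  theta %s",
                      it, state$ll, delta, pass, h,
                      paste(signif(theta, 3), collapse = " ")))
    if (delta < tol || (it > 3L && llGain < 1e-8)) { converged <- TRUE; break }
  }
  Vb <- buildV(theta)
  boundary <- any(theta[pIsVar] <= floorV * (1 + 1e-9))
  G0 <- Vb$G0
  r <- Vb$r
  h2 <- diag(G0) / (diag(G0) + r)
  rg <- if (K > 1) stats::cov2cor(G0) else matrix(1, 1, 1)
  R0 <- diag(r, K)
  if (model == "multi") {
    dimnames(G0) <- dimnames(rg) <- dimnames(R0) <- list(traits, traits)
    names(h2) <- traits
  }
  new("VarianceComponents",
      sigma2u = if (K == 1) G0[1, 1] else diag(G0),
      sigma2e = if (K == 1) r else r,
      G0 = G0, R0 = R0, h2 = h2, rg = rg,
      converged = converged, iterations = it,
      boundary = boundary, logLik = state$ll)
}
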