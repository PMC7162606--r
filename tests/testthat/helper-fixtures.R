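# Shared fixtures. Simulated populations are built once per test run and
# memoized; all sizes here are the micro profile used for fast structural
# and behavioural checks (the acceptance file runs the desk profile).

.fixtures <- new.env(parent = emptyenv())

microGenome <- function() buildGenome(1, 10, 100)

microParams <- function() {
  ## shortened Line2 history keeps micro-scale cohorts polymorphic enough
  ## for QC while preserving the two-line + F1 structure
  simParams(scaleFactor = 0.005, histSizes = c(100, 80), histGens = c(50, 10),
            nFounders = c(male = 20, female = 20),
            line2 = list(dams = 3200, sires = 64, gens = 12),
            f1 = list(dams = 3000, sires = 60,
                      parentGens = rbind(c(7, 8, 9, 10), c(9, 10, 11, 12))),
            qtlDensityScaling = TRUE)
}

microPop <- function(sim = "SIM5", seed = 1) {
  key <- paste0(sim, "_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulatePopulation(microGenome(), sim, microParams(),
                                           seed = seed)
  .fixtures[[key]]
}

# 5-animal toy pedigree: two founders, two full sibs, one inbred offspring
toyPed <- function() {
  data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3), dam = c(0, 0, 2, 2, 4))
}

# dense GLS solution of the animal model, used as the independent oracle for
# the mixed-model-equation solvers
glsSingleTrait <- function(y, X, Z, A, s2u, s2e) {
  V <- s2u * Z %*% A %*% t(Z) + s2e * diag(nrow(Z))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2u * A %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b = as.numeric(b), u = as.numeric(u))
}

# dense multi-trait GLS oracle; records on one trait each, u ~ N(0, G0 x A)
glsMultiTrait <- function(y, X, Z, A, tidx, G0, r0) {
  n <- length(y)
  K <- nrow(G0)
  nA <- nrow(A)
  V <- G0[tidx, tidx] * (Z %*% A %*% t(Z)) + diag(r0[tidx], n)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid <- as.numeric(y - X %*% b)
  ## u for every animal x trait: Cov(u_kt, y_i) = G0[t, tidx_i] * A[k, rec_i]
  u <- matrix(0, nA, K)
  AZt <- A %*% t(Z)
  for (t in seq_len(K)) {
    Cu <- sweep(AZt, 2L, G0[t, tidx], "*")
    u[, t] <- as.numeric(Cu %*% (Vi %*% resid))
  }
  list(b = as.numeric(b), u = u)
}
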