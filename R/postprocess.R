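# Posterior summaries: posterior-mode grouping, profile alignment, recovery
# metrics (ARI, RMSE), WAIC, dimension selection and Cramér's V diagnostics.

#' Posterior-mode item grouping
#'
#' Majority label of each item across the retained draws; ties go to the
#' smallest group index.
#'
#' @param x a [GroMFit-class] or a `T x p` matrix of grouping draws.
#' @param nGroups number of groups (needed only for a bare matrix).
#' @return integer vector of length `p`.
#' @export
groupingMode <- function(x, nGroups = NULL) {
  if (is(x, "GroMFit")) {
    nGroups <- x@G
    x <- groupDraws(x)
  }
  if (nrow(x) < 1L) stop("no grouping draws available")
  if (is.null(nGroups)) nGroups <- max(x)
  apply(x, 2L, function(col) which.max(tabulate(col, nGroups)))
}

#' Align estimated extreme profiles to a reference
#'
#' Stacks the estimated and reference tables into `(sum d_j) x K` matrices,
#' forms the inner-product matrix `t(ref) %*% est`, and takes the column
#' index of the largest entry in each row as the match for that reference
#' profile.  The row-argmax recipe can collide for finite samples; when it
#' does, the assignment is repaired to a bijection greedily in decreasing
#' inner-product order.
#'
#' @param est,ref estimated and reference tables: lists of `d_j x K`
#'   matrices, stacked matrices, or [GroMModel-class] objects.
#' @return integer permutation `perm` of `1..K`: estimated column
#'   `perm[k]` corresponds to reference profile `k`.
#' @export
alignProfiles <- function(est, ref) {
  toMat <- function(x) {
    if (is(x, "GroMModel")) return(.stackTables(itemTables(x)))
    if (is.list(x)) return(.stackTables(x))
    as.matrix(x)
  }
  E <- toMat(est); R <- toMat(ref)
  if (!identical(dim(E), dim(R)))
    stop("estimate and reference have different stacked dimensions")
  K <- ncol(E)
  M <- crossprod(R, E)  # rows: reference profiles, cols: estimated
  perm <- apply(M, 1L, which.max)
  if (anyDuplicated(perm)) {
    ord <- order(M, decreasing = TRUE)
    perm <- rep(NA_integer_, K)
    usedCol <- logical(K)
    for (idx in ord) {
      r <- (idx - 1L) %% K + 1L
      cc <- (idx - 1L) %/% K + 1L
      if (is.na(perm[r]) && !usedCol[cc]) {
        perm[r] <- cc
        usedCol[cc] <- TRUE
      }
    }
  }
  as.integer(perm)
}

#' Root mean squared recovery errors
#'
#' RMSE of the aligned table estimates (pooled over every `(j, c, k)` entry)
#' and of the aligned Dirichlet concentrations.
#'
#' @param estTables,refTables estimated and reference tables (lists of
#'   `d_j x K` matrices, stacked matrices, or [GroMModel-class] objects).
#' @param estAlpha,refAlpha estimated and reference concentration vectors.
#' @param permutation integer bijection from [alignProfiles()]; estimated
#'   column `permutation[k]` is compared against reference column `k`.
#' @return named numeric vector `c(lambda = ..., alpha = ...)`.
#' @export
parameterRMSE <- function(estTables, refTables, estAlpha, refAlpha,
                          permutation) {
  toMat <- function(x) {
    if (is(x, "GroMModel")) return(.stackTables(itemTables(x)))
    if (is.list(x)) return(.stackTables(x))
    as.matrix(x)
  }
  E <- toMat(estTables); R <- toMat(refTables)
  K <- ncol(R)
  permutation <- as.integer(permutation)
  if (length(permutation) != K || anyDuplicated(permutation) ||
      any(permutation < 1L) || any(permutation > K))
    stop("permutation must be a bijection on 1..K")
  if (!identical(dim(E), dim(R)))
    stop("estimate and reference have different stacked dimensions")
  c(lambda = sqrt(mean((E[, permutation] - R)^2)),
    alpha = sqrt(mean((estAlpha[permutation] - refAlpha)^2)))
}

#' Adjusted Rand index of two partitions
#'
#' Chance-corrected agreement between two clusterings of the same objects,
#' computed from the contingency table with the permutation-model expected
#' index.  Equals 1 exactly when the partitions coincide up to relabeling.
#'
#' @param s1,s2 label vectors of equal length.
#' @return the ARI (at most 1; can be negative).
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjustedRandIndex <- function(s1, s2) {
  if (length(s1) != length(s2)) stop("partitions must have equal length")
  tab <- table(s1, s2)
  n <- length(s1)
  sumij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  maxidx <- (sa + sb) / 2
  if (abs(maxidx - expected) < .Machine$double.eps * max(1, maxidx))
    return(1)
  (sumij - expected) / (maxidx - expected)
}

.logMeanExp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(mean(exp(x - m)))
}

#' @rdname waic
#' @export
setMethod("waic", "matrix", function(object) {
  if (nrow(object) < 2L)
    stop("WAIC needs at least 2 draws (variance undefined for T < 2)")
  lppd <- sum(apply(object, 2L, .logMeanExp))
  pwaic2 <- sum(apply(object, 2L, var))
  c(waic = -2 * (lppd - pwaic2), lppd = lppd, pWAIC2 = pwaic2)
})

#' @rdname waic
#' @export
setMethod("waic", "GroMFit", function(object) waic(object@logLik))

#' Summarize a fitted model
#'
#' Computes the posterior-mode grouping, the posterior means of the stacked
#' tables and of `alpha` (over retained draws, without per-draw relabeling —
#' alignment is applied once, post hoc), WAIC, and the empty-group flag.
#' When a reference model is supplied, the estimated profiles are aligned to
#' it and ARI / RMSE recovery measures are attached.
#'
#' @param fit a [GroMFit-class].
#' @param reference optional [GroMModel-class] ground truth.
#' @param alignDraws also align every retained draw before averaging
#'   (optional; the default averages raw draws).
#' @return a [GroMSummary-class].
#' @export
summarizeFit <- function(fit, reference = NULL, alignDraws = FALSE) {
  stopifnot(is(fit, "GroMFit"))
  sbar <- groupingMode(fit)
  lam <- lambdaDraws(fit)
  if (alignDraws && !is.null(reference)) {
    refMat <- .stackTables(itemTables(reference))
    T <- dim(lam)[3]
    acc <- matrix(0, dim(lam)[1], dim(lam)[2])
    accA <- numeric(ncol(alphaDraws(fit)))
    for (t in seq_len(T)) {
      pt <- alignProfiles(lam[, , t], refMat)
      acc <- acc + lam[, pt, t]
      accA <- accA + alphaDraws(fit)[t, pt]
    }
    lambdaMean <- acc / T
    alphaMean <- accA / T
  } else {
    lambdaMean <- apply(lam, c(1, 2), mean)
    alphaMean <- colMeans(alphaDraws(fit))
  }
  w <- waic(fit)
  empty <- any(tabulate(sbar, fit@G) == 0L)
  perm <- NA_integer_
  rmse <- c(lambda = NA_real_, alpha = NA_real_)
  ari <- NA_real_
  if (!is.null(reference)) {
    perm <- alignProfiles(lambdaMean, reference)
    rmse <- parameterRMSE(lambdaMean, reference, alphaMean,
                          dirichletAlpha(reference), perm)
    ari <- adjustedRandIndex(sbar, itemGroups(reference))
  }
  new("GroMSummary", grouping = as.integer(sbar),
      nGroups = fit@G, lambdaMean = lambdaMean,
      alphaMean = as.numeric(alphaMean), permutation = as.integer(perm),
      rmseLambda = unname(rmse["lambda"]), rmseAlpha = unname(rmse["alpha"]),
      ari = ari, waic = unname(w["waic"]), lppd = unname(w["lppd"]),
      pWAIC2 = unname(w["pWAIC2"]), emptyGroups = empty, d = fit@d)
}

#' Select the numbers of groups and profiles by WAIC
#'
#' Fits every `(G, K)` candidate, computes WAIC, flags fits whose
#' posterior-mode grouping leaves empty groups, and returns the
#' smallest-WAIC candidate among fits with no empty group (fits with empty
#' groups are excluded even when their WAIC is smallest, since unoccupied
#' groups cannot be interpreted).
#'
#' @param y response matrix (or [GroMSim-class]).
#' @param Gvalues,Kvalues candidate values.
#' @param control an [mcmcControl()] used for every candidate fit.
#' @param verbose print progress?
#' @return list with `table` (data.frame of G, K, waic, lppd, pWAIC2,
#'   emptyGroups), `G`, `K` (the selection; `NA` if every candidate was
#'   excluded).
#' @export
selectDimensions <- function(y, Gvalues, Kvalues, control = mcmcControl(),
                             verbose = FALSE) {
  if (is(y, "GroMSim")) y <- responses(y)
  grid <- expand.grid(G = Gvalues, K = Kvalues)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    fit <- fitGroM(y, grid$G[r], grid$K[r], control = control)
    w <- waic(fit)
    empty <- any(tabulate(groupingMode(fit), fit@G) == 0L)
    if (verbose)
      message(sprintf("G = %d, K = %d: WAIC %.1f%s", grid$G[r], grid$K[r],
                      w["waic"], if (empty) " (empty groups)" else ""))
    data.frame(G = grid$G[r], K = grid$K[r], waic = w["waic"],
               lppd = w["lppd"], pWAIC2 = w["pWAIC2"], emptyGroups = empty)
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  eligible <- which(!tab$emptyGroups)
  if (!length(eligible))
    return(list(table = tab, G = NA_integer_, K = NA_integer_))
  best <- eligible[which.min(tab$waic[eligible])]
  list(table = tab, G = tab$G[best], K = tab$K[best])
}

# Cramér's V from a joint probability table.
.cramersVTable <- function(P) {
  dmin <- min(nrow(P), ncol(P)) - 1L
  if (dmin < 1L) return(0)
  r <- rowSums(P); s <- colSums(P)
  E <- outer(r, s)
  ok <- E > 0
  phi2 <- sum((P[ok] - E[ok])^2 / E[ok])
  sqrt(phi2 / dmin)
}

#' Sample Cramér's V between all item pairs
#'
#' Classical association measure in `[0, 1]` from the observed pairwise
#' contingency tables: `V = sqrt(chi^2 / (n * min(d_j - 1, d_j' - 1)))`.
#' The diagonal is set to 1.  Items with a single observed category get
#' `V = 0` against every partner, with a warning.
#'
#' @param y response matrix (or [GroMSim-class]).
#' @param d optional per-item category counts.
#' @return symmetric `p x p` matrix.
#' @export
cramersVSample <- function(y, d = NULL) {
  if (is(y, "GroMSim")) y <- responses(y)
  y <- .checkResponses(y, d)
  d <- attr(y, "categories")
  p <- ncol(y)
  degenerate <- vapply(seq_len(p),
                       function(j) length(unique(y[, j])) < 2L, logical(1))
  if (any(degenerate))
    warning("items with a single observed category: ",
            paste(which(degenerate), collapse = ", "),
            " (their V is set to 0)")
  V <- diag(1, p)
  for (a in seq_len(p - 1L))
    for (b in seq(a + 1L, p)) {
      if (degenerate[a] || degenerate[b]) { V[a, b] <- V[b, a] <- 0; next }
      tab <- table(factor(y[, a], levels = seq_len(d[a])),
                   factor(y[, b], levels = seq_len(d[b])))
      V[a, b] <- V[b, a] <- .cramersVTable(tab / sum(tab))
    }
  V
}

#' Model-based Cramér's V between all item pairs
#'
#' The population version of Cramér's V, computed from the model-implied
#' pairwise joint distributions ([pairwiseMarginal()]) instead of observed
#' counts: `V = sqrt(phi^2 / min(d_j - 1, d_j' - 1))` with `phi^2` the
#' mean-square contingency of the implied table.
#'
#' @param model a [GroMModel-class].
#' @return symmetric `p x p` matrix with unit diagonal.
#' @export
cramersVModel <- function(model) {
  stopifnot(is(model, "GroMModel"))
  p <- nItems(model)
  V <- diag(1, p)
  for (a in seq_len(p - 1L))
    for (b in seq(a + 1L, p))
      V[a, b] <- V[b, a] <- .cramersVTable(pairwiseMarginal(model, a, b))
  V
}
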