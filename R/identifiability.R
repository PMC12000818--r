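# Executable identifiability checkers.
#
# Strict identifiability asks every group to hold >= 3 items whose tables
# have full column rank K; the Khatri-Rao relaxation only asks the stacked
# (Khatri-Rao) tables over a 3-way partition of each group to have rank K;
# the generic condition replaces ranks by the category-count products
# prod d_j >= K per partition part.  Ranks are numerical column ranks from
# singular values with a relative tolerance, since the theory's exact-rank
# statements have to be evaluated in floating point.

.numRank <- function(M, rankTol) {
  sv <- svd(M, nu = 0, nv = 0)$d
  if (!length(sv) || sv[1] == 0) return(0L)
  sum(sv > rankTol * sv[1])
}

# An item is informative about the grouping only if its table has at least
# two distinct columns (max column-pair infinity-distance above tolerance).
.distinctColumns <- function(tab, rankTol) {
  K <- ncol(tab)
  if (K == 1L) return(FALSE)
  for (a in seq_len(K - 1L))
    for (b in seq(a + 1L, K))
      if (max(abs(tab[, a] - tab[, b])) > rankTol) return(TRUE)
  FALSE
}

#' Strict identifiability check
#'
#' Condition (a): every group contains at least three items whose
#' conditional probability table has numerical column rank `K`; this alone
#' identifies the tables and the core tensor.  Condition (b): every item's
#' table has at least two distinct columns, which additionally identifies
#' the grouping itself.  Both flags are reported; `passed` is their
#' conjunction.
#'
#' @param model a [GroMModel-class].
#' @param rankTol relative singular-value tolerance for the numerical rank
#'   (and the distinct-column distance).
#' @return a [GroMCheck-class] report.
#' @export
checkStrict <- function(model, rankTol = 1e-8) {
  stopifnot(is(model, "GroMModel"))
  K <- nProfiles(model)
  tables <- itemTables(model)
  groups <- itemGroups(model)
  G <- model@nGroups
  fullRank <- vapply(tables, function(tab) .numRank(tab, rankTol) == K,
                     logical(1))
  perGroup <- vapply(seq_len(G),
                     function(g) sum(fullRank & groups == g), integer(1))
  condA <- all(perGroup >= 3L)
  distinct <- vapply(tables, .distinctColumns, logical(1), rankTol = rankTol)
  condB <- all(distinct)
  new("GroMCheck", passed = condA && condB, type = "strict",
      details = list(
        fullRankItemsPerGroup = perGroup,
        groupSizes = tabulate(groups, G),
        tablesIdentifiable = condA,
        groupingIdentifiable = condA && condB,
        itemsWithoutFullRank = which(!fullRank),
        itemsWithIdenticalColumns = which(!distinct)))
}

# Validate a 3-way partition plan against the grouping; plan is a list with
# one element per group, each a list of three disjoint item-index vectors
# covering that group's items.
.validatePlan <- function(plan, groups, G) {
  if (length(plan) != G) stop("plan must have one element per group")
  for (g in seq_len(G)) {
    parts <- plan[[g]]
    if (length(parts) != 3L)
      stop("plan for group ", g, " must have exactly three parts")
    items <- sort(unlist(parts))
    if (anyDuplicated(items))
      stop("plan parts for group ", g, " overlap")
    if (!identical(items, sort(which(groups == g))))
      stop("plan parts for group ", g,
           " do not cover exactly the group's items")
  }
  invisible(TRUE)
}

#' Khatri-Rao identifiability check
#'
#' For a 3-way partition of each group's items, forms the chained Khatri-Rao
#' product of the part's tables and requires each such stacked table to have
#' numerical column rank `K`; additionally every item must have at least two
#' distinct table columns.  Strictly weaker than [checkStrict()]: individual
#' tables may be rank-deficient (e.g. binary items with `K = 3`) as long as
#' their Khatri-Rao products are not.
#'
#' @inheritParams checkStrict
#' @param plan 3-way partition plan: a list with one element per group, each
#'   a list of three disjoint item-index vectors whose union is the group.
#' @return a [GroMCheck-class] report.
#' @export
checkKRP <- function(model, plan, rankTol = 1e-8) {
  stopifnot(is(model, "GroMModel"))
  K <- nProfiles(model)
  tables <- itemTables(model)
  groups <- itemGroups(model)
  G <- model@nGroups
  .validatePlan(plan, groups, G)
  ranks <- matrix(NA_integer_, G, 3L)
  for (g in seq_len(G))
    for (m in 1:3) {
      part <- plan[[g]][[m]]
      if (!length(part)) { ranks[g, m] <- 0L; next }
      krp <- Reduce(khatriRao, tables[part])
      ranks[g, m] <- .numRank(krp, rankTol)
    }
  condRank <- all(ranks == K)
  distinct <- vapply(tables, .distinctColumns, logical(1), rankTol = rankTol)
  condB <- all(distinct)
  new("GroMCheck", passed = condRank && condB, type = "krp",
      details = list(
        partRanks = ranks,
        rankTarget = K,
        failingParts = which(ranks < K, arr.ind = TRUE),
        itemsWithIdenticalColumns = which(!distinct)))
}

# Search for a 3-way partition of one group such that every part's
# category-count product reaches K.  Exhaustive over the 3^m assignments for
# small groups, greedy (largest d first onto the lightest part) otherwise.
.searchPartition <- function(items, d, K, exhaustiveLimit = 12L) {
  m <- length(items)
  target <- log(K)
  if (m >= 3L && m <= exhaustiveLimit) {
    assign <- as.matrix(expand.grid(rep(list(1:3), m)))
    logd <- log(d[items])
    prods <- sapply(1:3, function(part)
      as.vector((assign == part) %*% logd))
    # empty parts give product 1 (log 0), which only passes when K = 1
    ok <- prods[, 1] >= target - 1e-9 & prods[, 2] >= target - 1e-9 &
      prods[, 3] >= target - 1e-9
    if (!any(ok)) return(NULL)
    a <- assign[which(ok)[1], ]
    return(lapply(1:3, function(part) items[a == part]))
  }
  ord <- items[order(d[items], decreasing = TRUE)]
  logp <- c(0, 0, 0)
  parts <- list(integer(0), integer(0), integer(0))
  for (j in ord) {
    tgt <- which.min(logp)
    parts[[tgt]] <- c(parts[[tgt]], j)
    logp[tgt] <- logp[tgt] + log(d[j])
  }
  if (all(logp >= target - 1e-9)) parts else NULL
}

#' Generic identifiability check
#'
#' Requires, for a 3-way partition of each group's items, that every part's
#' category-count product `prod d_j` is at least `K`; under that dimension
#' condition the Khatri-Rao stacked tables have full column rank for generic
#' (almost all) parameter values.  When no plan is supplied one is searched
#' for: exhaustively for groups of up to 12 items, by a greedy balance of
#' `log d_j` for larger groups.
#'
#' @param d integer vector of per-item category counts.
#' @param groups integer item group labels.
#' @param K number of extreme latent profiles.
#' @param plan optional partition plan as in [checkKRP()]; found
#'   automatically when absent.
#' @param nGroups number of groups.
#' @return a [GroMCheck-class] report; `details$plan` carries the partition
#'   used (or found).
#' @export
checkGeneric <- function(d, groups, K, plan = NULL, nGroups = max(groups)) {
  d <- as.integer(d)
  groups <- as.integer(groups)
  G <- as.integer(nGroups)
  if (!is.null(plan)) .validatePlan(plan, groups, G)
  prods <- matrix(NA_real_, G, 3L)
  found <- vector("list", G)
  ok <- logical(G)
  for (g in seq_len(G)) {
    items <- which(groups == g)
    parts <- if (!is.null(plan)) plan[[g]]
             else .searchPartition(items, d, K)
    if (is.null(parts)) { ok[g] <- FALSE; next }
    found[[g]] <- parts
    prods[g, ] <- vapply(parts, function(part)
      if (length(part)) prod(d[part]) else 1, numeric(1))
    ok[g] <- all(prods[g, ] >= K)
  }
  new("GroMCheck", passed = all(ok), type = "generic",
      details = list(
        partProducts = prods,
        rankTarget = K,
        failingGroups = which(!ok),
        plan = found))
}
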