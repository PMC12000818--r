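# Accessor and show methods.

#' @rdname GroMModel-class
#' @export
setMethod("nItems", "GroMModel", function(object) length(object@groups))

#' @rdname GroMModel-class
#' @export
setMethod("nProfiles", "GroMModel", function(object) length(object@alpha))

#' @rdname GroMModel-class
#' @export
setMethod("nGroups", "GroMModel", function(object) object@nGroups)

#' @rdname GroMModel-class
#' @export
setMethod("itemGroups", "GroMModel", function(object) object@groups)

#' @rdname GroMModel-class
#' @export
setMethod("itemTables", "GroMModel", function(object) object@tables)

#' @rdname GroMModel-class
#' @export
setMethod("itemCategories", "GroMModel",
          function(object) vapply(object@tables, nrow, integer(1)))

#' @rdname GroMModel-class
#' @export
setMethod("dirichletAlpha", "GroMModel", function(object) object@alpha)

#' @rdname GroMModel-class
#' @export
setMethod("groupingMatrix", "GroMModel", function(object) {
  L <- matrix(0L, nItems(object), object@nGroups)
  L[cbind(seq_len(nItems(object)), object@groups)] <- 1L
  L
})

setMethod("show", "GroMModel", function(object) {
  cat(sprintf(
    "GroMModel: %d items in %d groups, %d extreme profiles%s\n",
    nItems(object), object@nGroups, nProfiles(object),
    if (nzchar(object@label)) sprintf(" [%s]", object@label) else ""))
  cat("  categories per item:",
      paste(unique(itemCategories(object)), collapse = "/"), "\n")
  cat("  alpha:", paste(signif(object@alpha, 4), collapse = ", "), "\n")
})

#' @rdname GroMSim-class
#' @export
setMethod("responses", "GroMSim", function(object) object@responses)

#' @rdname GroMSim-class
#' @export
setMethod("membership", "GroMSim", function(object) object@membership)

#' @rdname GroMSim-class
#' @export
setMethod("assignments", "GroMSim", function(object) object@assignments)

#' @rdname GroMSim-class
#' @export
setMethod("trueModel", "GroMSim", function(object) object@model)

setMethod("show", "GroMSim", function(object) {
  cat(sprintf("GroMSim: %d subjects x %d items (seed %s)\n",
              nrow(object@responses), ncol(object@responses),
              format(object@seed)))
  show(object@model)
})

#' @rdname GroMFit-class
#' @export
setMethod("nDraws", "GroMFit", function(object) nrow(object@draws$s))

#' @rdname GroMFit-class
#' @export
setMethod("groupDraws", "GroMFit", function(object) object@draws$s)

#' @rdname GroMFit-class
#' @export
setMethod("alphaDraws", "GroMFit", function(object) object@draws$alpha)

#' @rdname GroMFit-class
#' @export
setMethod("lambdaDraws", "GroMFit", function(object) object@draws$lambda)

#' @rdname GroMFit-class
#' @export
setMethod("logLikDraws", "GroMFit", function(object) object@logLik)

#' @rdname GroMFit-class
#' @export
setMethod("acceptanceRate", "GroMFit", function(object) {
  if (all(is.na(object@acceptance))) return(NA_real_)
  mean(object@acceptance, na.rm = TRUE)
})

#' Windowed Metropolis-Hastings acceptance trace
#'
#' Mean acceptance indicator over consecutive windows of iterations, the
#' quantity usually monitored to judge the lognormal proposal scale.
#'
#' @param fit a [GroMFit-class].
#' @param window window length in iterations.
#' @return numeric vector of per-window acceptance rates (`NA` for the
#'   augmented Gibbs sampler, which has no MH step).
#' @export
acceptanceTrace <- function(fit, window = 100L) {
  acc <- fit@acceptance
  if (all(is.na(acc))) return(NA_real_)
  idx <- ceiling(seq_along(acc) / window)
  as.numeric(tapply(acc, idx, mean, na.rm = TRUE))
}

setMethod("show", "GroMFit", function(object) {
  cat(sprintf("GroMFit: n = %d, p = %d, G = %d, K = %d\n",
              object@n, length(object@d), object@G, object@K))
  cat(sprintf("  sampler: %s, %d retained draws\n",
              object@control$sampler, nDraws(object)))
  ar <- acceptanceRate(object)
  if (!is.na(ar)) cat(sprintf("  MH acceptance rate: %.3f\n", ar))
})

setMethod("show", "GroMSummary", function(object) {
  cat("GroMSummary\n")
  cat("  posterior-mode grouping:",
      paste(object@grouping, collapse = " "), "\n")
  cat(sprintf("  WAIC: %.2f (lppd %.2f, pWAIC2 %.2f)\n",
              object@waic, object@lppd, object@pWAIC2))
  if (object@emptyGroups) cat("  note: grouping leaves empty group(s)\n")
  if (!is.na(object@rmseLambda))
    cat(sprintf("  vs reference: ARI %.3f, RMSE(Lambda) %.4f, RMSE(alpha) %.4f\n",
                object@ari, object@rmseLambda, object@rmseAlpha))
})

setMethod("show", "GroMCheck", function(object) {
  cat(sprintf("GroMCheck [%s]: %s\n", object@type,
              if (object@passed) "PASSED" else "FAILED"))
  det <- object@details
  for (nm in names(det)) {
    v <- det[[nm]]
    if (is.atomic(v) && length(v) <= 12)
      cat(sprintf("  %s: %s\n", nm, paste(format(v), collapse = " ")))
  }
})
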