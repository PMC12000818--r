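#' @rdname GroMModel-class
#' @param object,x a gromm object
#' @export
setGeneric("nItems", function(object) standardGeneric("nItems"))

#' @rdname GroMModel-class
#' @export
setGeneric("nProfiles", function(object) standardGeneric("nProfiles"))

#' @rdname GroMModel-class
#' @export
setGeneric("nGroups", function(object) standardGeneric("nGroups"))

#' @rdname GroMModel-class
#' @export
setGeneric("itemGroups", function(object) standardGeneric("itemGroups"))

#' @rdname GroMModel-class
#' @export
setGeneric("itemTables", function(object) standardGeneric("itemTables"))

#' @rdname GroMModel-class
#' @export
setGeneric("itemCategories", function(object) standardGeneric("itemCategories"))

#' @rdname GroMModel-class
#' @export
setGeneric("dirichletAlpha", function(object) standardGeneric("dirichletAlpha"))

#' @rdname GroMModel-class
#' @export
setGeneric("groupingMatrix", function(object) standardGeneric("groupingMatrix"))

#' @rdname GroMSim-class
#' @param object a gromm object
#' @export
setGeneric("responses", function(object) standardGeneric("responses"))

#' @rdname GroMSim-class
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname GroMSim-class
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname GroMSim-class
#' @export
setGeneric("trueModel", function(object) standardGeneric("trueModel"))

#' @rdname GroMFit-class
#' @param object a gromm object
#' @export
setGeneric("nDraws", function(object) standardGeneric("nDraws"))

#' @rdname GroMFit-class
#' @export
setGeneric("groupDraws", function(object) standardGeneric("groupDraws"))

#' @rdname GroMFit-class
#' @export
setGeneric("alphaDraws", function(object) standardGeneric("alphaDraws"))

#' @rdname GroMFit-class
#' @export
setGeneric("lambdaDraws", function(object) standardGeneric("lambdaDraws"))

#' @rdname GroMFit-class
#' @export
setGeneric("logLikDraws", function(object) standardGeneric("logLikDraws"))

#' @rdname GroMFit-class
#' @export
setGeneric("acceptanceRate", function(object) standardGeneric("acceptanceRate"))

#' Widely applicable information criterion
#'
#' Computes WAIC from per-draw pointwise likelihood values,
#' `WAIC = -2 (lppd - pWAIC2)`, where
#' `lppd = sum_i log mean_t p(y_i | theta_t)` (evaluated with a stabilized
#' log-mean-exp) and `pWAIC2 = sum_i var_t log p(y_i | theta_t)` with the
#' sample variance over the `T` retained draws.  Smaller is better.
#'
#' @param object a [GroMFit-class], or a `T x n` matrix of pointwise
#'   log-likelihood values.
#' @return named numeric vector with elements `waic`, `lppd`, `pWAIC2`.
#' @export
setGeneric("waic", function(object) standardGeneric("waic"))
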