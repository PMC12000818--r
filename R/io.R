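# File formats: response CSV, parameter (truth) archives and posterior
# archives.  Everything is plain text; doubles are written with 17
# significant digits so archives round-trip losslessly.

.fmt17 <- function(x) sprintf("%.17g", x)

.ARCHIVE_FORMAT <- 1L

#' Read a categorical response matrix from CSV
#'
#' Expects a header row of item names and integer cells coded `1..d_j`.
#' Missing cells are rejected (complete cases only) with the offending
#' row/column named; so are 0 or out-of-range codes.  Category counts are
#' inferred as the observed per-item maxima unless a schema is given.
#'
#' @param path CSV file.
#' @param categories optional integer vector of per-item category counts
#'   (takes precedence over the observed maxima).
#' @return integer matrix with a `categories` attribute.
#' @export
readResponses <- function(path, categories = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE)
  y <- as.matrix(dt)
  if (!is.numeric(y)) stop("responses must be integer codes")
  .checkResponses(y, categories)
}

#' Write a categorical response matrix to CSV
#'
#' @param y integer response matrix (or [GroMSim-class]).
#' @param path output CSV file.
#' @export
writeResponses <- function(y, path) {
  if (is(y, "GroMSim")) y <- responses(y)
  data.table::fwrite(as.data.frame(y), path)
  invisible(path)
}

#' Write / read a model parameter archive
#'
#' A parameter archive is a directory holding `model.json` (grouping,
#' Dirichlet concentrations, category counts, label) and `lambda.csv`, the
#' conditional probability tables in long form.  The round trip is lossless.
#'
#' @param model a [GroMModel-class].
#' @param dir archive directory (created if needed).
#' @return `writeModelArchive` the directory, invisibly;
#'   `readModelArchive` the reconstructed [GroMModel-class].
#' @export
writeModelArchive <- function(model, dir) {
  stopifnot(is(model, "GroMModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- itemCategories(model)
  meta <- list(format = .ARCHIVE_FORMAT,
               package = as.character(packageVersion("gromm")),
               groups = itemGroups(model), nGroups = model@nGroups,
               alpha = .fmt17(dirichletAlpha(model)), d = d,
               label = model@label)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  tabs <- itemTables(model)
  long <- do.call(rbind, lapply(seq_along(tabs), function(j) {
    tab <- tabs[[j]]
    data.frame(item = j,
               category = rep(seq_len(nrow(tab)), ncol(tab)),
               profile = rep(seq_len(ncol(tab)), each = nrow(tab)),
               value = .fmt17(as.vector(tab)))
  }))
  data.table::fwrite(long, file.path(dir, "lambda.csv"))
  invisible(dir)
}

#' @rdname writeModelArchive
#' @export
readModelArchive <- function(dir) {
  metaPath <- file.path(dir, "model.json")
  if (!file.exists(metaPath)) stop("not a model archive: ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (!identical(as.integer(meta$format), .ARCHIVE_FORMAT))
    stop("unsupported model archive format: ", meta$format)
  long <- data.table::fread(file.path(dir, "lambda.csv"))
  d <- as.integer(meta$d)
  tables <- lapply(seq_along(d), function(j) {
    sub <- long[long$item == j, ]
    if (nrow(sub) == 0) stop("archive is missing tables for item ", j)
    K <- max(sub$profile)
    tab <- matrix(NA_real_, d[j], K)
    tab[cbind(sub$category, sub$profile)] <- as.numeric(sub$value)
    if (anyNA(tab)) stop("incomplete table for item ", j)
    tab
  })
  GroMModel(as.integer(meta$groups), tables, as.numeric(meta$alpha),
            nGroups = as.integer(meta$nGroups),
            label = meta$label %||% "")
}

#' Write / read a posterior archive
#'
#' A posterior archive is a directory with a JSON manifest (configuration
#' echo, seed, package version, dimensions, acceptance summary) and one CSV
#' per parameter block of retained draws, including the per-draw pointwise
#' log-likelihood values.  The round trip reproduces the
#' [GroMFit-class] losslessly; a truncated or version-mismatched archive is
#' rejected.
#'
#' @param fit a [GroMFit-class].
#' @param dir archive directory.
#' @return `writePosteriorArchive` the directory, invisibly;
#'   `readPosteriorArchive` the reconstructed [GroMFit-class].
#' @export
writePosteriorArchive <- function(fit, dir) {
  stopifnot(is(fit, "GroMFit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctl <- fit@control
  manifest <- list(format = .ARCHIVE_FORMAT,
                   package = as.character(packageVersion("gromm")),
                   control = ctl, n = fit@n, G = fit@G, K = fit@K,
                   d = fit@d, itemNames = fit@itemNames,
                   draws = nDraws(fit),
                   acceptanceRate = acceptanceRate(fit))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  wr <- function(x, file) {
    df <- as.data.frame(apply(x, 2L, .fmt17, simplify = FALSE))
    data.table::fwrite(df, file.path(dir, file))
  }
  data.table::fwrite(as.data.frame(groupDraws(fit)),
                     file.path(dir, "s.csv"))
  wr(alphaDraws(fit), "alpha.csv")
  wr(fit@draws$xi, "xi.csv")
  wr(fit@logLik, "loglik.csv")
  lam <- lambdaDraws(fit)
  dims <- dim(lam)
  lamMat <- matrix(lam, dims[1] * dims[2], dims[3])
  wr(t(lamMat), "lambda.csv")
  data.table::fwrite(
    data.frame(iteration = seq_along(fit@acceptance),
               accepted = fit@acceptance),
    file.path(dir, "acceptance.csv"))
  invisible(dir)
}

#' @rdname writePosteriorArchive
#' @export
readPosteriorArchive <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath)) stop("not a posterior archive: ", dir)
  manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$format), .ARCHIVE_FORMAT))
    stop("unsupported posterior archive format: ", manifest$format)
  rd <- function(file) {
    fp <- file.path(dir, file)
    if (!file.exists(fp)) stop("archive is missing ", file)
    as.matrix(data.table::fread(fp, colClasses = "numeric"))
  }
  T <- as.integer(manifest$draws)
  d <- as.integer(manifest$d)
  K <- as.integer(manifest$K)
  sumd <- sum(d)
  s <- rd("s.csv"); storage.mode(s) <- "integer"
  alpha <- rd("alpha.csv")
  xi <- rd("xi.csv")
  loglik <- rd("loglik.csv")
  lamFlat <- rd("lambda.csv")
  if (nrow(s) != T || nrow(alpha) != T || nrow(loglik) != T ||
      nrow(lamFlat) != T || ncol(lamFlat) != sumd * K)
    stop("posterior archive is truncated or inconsistent")
  lam <- array(t(lamFlat), c(sumd, K, T))
  accTab <- data.table::fread(file.path(dir, "acceptance.csv"))
  ctl <- manifest$control
  ctl$seed <- if (is.null(ctl$seed)) NULL else as.integer(ctl$seed)
  new("GroMFit",
      draws = list(s = unname(s), alpha = unname(alpha), xi = unname(xi),
                   lambda = lam),
      logLik = unname(loglik),
      acceptance = as.numeric(accTab$accepted),
      control = ctl, d = d,
      itemNames = as.character(manifest$itemNames),
      n = as.integer(manifest$n), G = as.integer(manifest$G), K = K,
      finalState = list())
}
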