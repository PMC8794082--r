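#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file (tab or comma; sniffed from the header line
#' unless \code{delim} is given) with one row per variant and, per trait,
#' one effect-estimate column and one standard-error column. Rows with any
#' missing or non-finite beta/se, or non-positive se, are dropped with a
#' message reporting the count.
#'
#' @param path file path.
#' @param columnMap named list, one entry per trait, each a character vector
#'   with elements \code{beta} and \code{se} naming the columns, e.g.
#'   \code{list(bmi = c(beta = "bmi_beta", se = "bmi_se"))}.
#' @param idColumn name of the variant-id column (default \code{"rsid"});
#'   if absent from the file, row numbers are used.
#' @param primaryBetaColumn optional column of associations with the primary
#'   trait, kept for \code{\link{orientToPrimaryTrait}}.
#' @param delim field delimiter, \code{"\t"} or \code{","}; sniffed if NULL.
#' @return An \linkS4class{AssociationSet} with rows in file order.
#' @export
readAssociationTable <- function(path, columnMap, idColumn = "rsid",
                                 primaryBetaColumn = NULL, delim = NULL) {
  if (!file.exists(path))
    stop("input file not found: ", path)
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = delim,
                   stringsAsFactors = FALSE, check.names = FALSE)
  traits <- names(columnMap)
  if (is.null(traits) || length(traits) < 2L)
    stop("'columnMap' must name at least two traits")
  wanted <- unlist(lapply(columnMap, function(cm) cm[c("beta", "se")]))
  missing <- setdiff(wanted, names(df))
  if (length(missing))
    stop("column(s) not found in ", path, ": ",
         paste(missing, collapse = ", "))
  beta <- as.matrix(df[, vapply(columnMap, `[[`, "", "beta"), drop = FALSE])
  se <- as.matrix(df[, vapply(columnMap, `[[`, "", "se"), drop = FALSE])
  storage.mode(beta) <- storage.mode(se) <- "double"
  ids <- if (idColumn %in% names(df)) as.character(df[[idColumn]])
         else as.character(seq_len(nrow(df)))
  pb <- if (!is.null(primaryBetaColumn)) {
    if (!primaryBetaColumn %in% names(df))
      stop("column(s) not found in ", path, ": ", primaryBetaColumn)
    as.numeric(df[[primaryBetaColumn]])
  } else NULL
  ok <- apply(is.finite(beta), 1, all) & apply(is.finite(se), 1, all) &
    apply(se > 0, 1, all)
  ok[is.na(ok)] <- FALSE
  nDropped <- sum(!ok)
  if (nDropped > 0)
    message("dropped ", nDropped,
            " variant row(s) with missing or invalid beta/se")
  if (!any(ok))
    stop("no usable variant rows in ", path)
  AssociationSet(beta[ok, , drop = FALSE], se[ok, , drop = FALSE],
                 variantIds = ids[ok], traitNames = traits,
                 primaryBeta = if (is.null(pb)) NULL else pb[ok])
}

#' Read a trait-correlation matrix
#'
#' Reads an m x m trait correlation matrix from delimited text with a
#' header row and first column of trait names, and validates it
#' (symmetry, unit diagonal, entries in [-1, 1], positive semidefinite up
#' to tolerance).
#'
#' @param path file path.
#' @param delim field delimiter; sniffed between tab and comma if NULL.
#' @return validated numeric correlation matrix with dimnames.
#' @export
readTraitCorrelation <- function(path, delim = NULL) {
  if (!file.exists(path))
    stop("input file not found: ", path)
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = delim, row.names = 1,
                   check.names = FALSE)
  corr <- as.matrix(df)
  validateTraitCorrelation(corr)
  corr
}

# Invariant checks for a trait correlation matrix; stops on violation.
validateTraitCorrelation <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("trait correlation must be a square matrix")
  if (max(abs(corr - t(corr))) > 1e-10)
    stop("trait correlation must be symmetric (within 1e-10)")
  if (max(abs(diag(corr) - 1)) > 1e-10)
    stop("trait correlation must have unit diagonal")
  if (any(corr < -1 - 1e-12) || any(corr > 1 + 1e-12))
    stop("trait correlation entries must lie in [-1, 1]")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("trait correlation is not positive semidefinite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  invisible(TRUE)
}

#' Orient all effect alleles to the primary trait
#'
#' Flips the sign of every trait association for variants whose association
#' with the primary trait is negative, so that all effect alleles are the
#' primary-trait-increasing alleles. Standard errors are unchanged. The
#' operation is idempotent.
#'
#' @param assoc an \linkS4class{AssociationSet} with \code{primaryBeta} in
#'   its \code{rowData}.
#' @return the re-oriented \code{AssociationSet}.
#' @export
orientToPrimaryTrait <- function(assoc) {
  stopifnot(is(assoc, "AssociationSet"))
  pb <- SummarizedExperiment::rowData(assoc)$primaryBeta
  if (is.null(pb))
    stop("'primaryBeta' is required to orient alleles; ",
         "supply it when constructing the AssociationSet")
  flip <- pb < 0
  beta <- SummarizedExperiment::assay(assoc, "beta")
  beta[flip, ] <- -beta[flip, , drop = FALSE]
  SummarizedExperiment::assay(assoc, "beta") <- beta
  SummarizedExperiment::rowData(assoc)$primaryBeta <- abs(pb)
  validObject(assoc)
  assoc
}

#' Per-variant covariance of association estimates
#'
#' Builds \eqn{\hat\Sigma_j} with (k, l) entry
#' \eqn{se(\hat\beta_{jk}) se(\hat\beta_{jl})\,\hat{cor}(X_k, X_l)}.
#' When no trait correlation is supplied (traits independent or estimated
#' in separate samples) the diagonal matrix of squared standard errors is
#' returned.
#'
#' @param seRow length-m vector of positive standard errors.
#' @param corr optional m x m trait correlation matrix.
#' @return m x m covariance matrix.
#' @examples
#' buildCovariance(c(0.1, 0.2))  # diag(0.01, 0.04)
#' @export
buildCovariance <- function(seRow, corr = NULL) {
  if (any(!is.finite(seRow)) || any(seRow <= 0))
    stop("'seRow' must be positive and finite")
  if (is.null(corr))
    return(diag(seRow^2, nrow = length(seRow)))
  validateTraitCorrelation(corr)
  if (nrow(corr) != length(seRow))
    stop("dimension of 'corr' does not match 'seRow'")
  outer(seRow, seRow) * corr
}

# Symmetric inverse square root of a covariance matrix via
# eigendecomposition; eigenvalues below floorFrac * max are an error.
.invSqrtSym <- function(sigma, floorFrac = 1e-12, label = "covariance") {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < floorFrac * max(e$values))
    stop("singular covariance matrix for ", label,
         " (eigenvalue ratio below ", format(floorFrac), ")")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Standardise association estimates
#'
#' Returns the matrix with row j equal to
#' \eqn{\hat\Sigma_j^{-1/2} \hat\beta_{j\cdot}}, using the symmetric
#' (eigendecomposition) matrix inverse square root — the unique positive
#' semidefinite root. Elements of the standardised vector have unit
#' standard error and are independent under the model. With \code{corr}
#' absent (or the identity) this reduces to the familiar z-scores
#' \eqn{\hat\beta_{jl} / se(\hat\beta_{jl})}.
#'
#' @param assoc an \linkS4class{AssociationSet}.
#' @param corr optional m x m trait correlation matrix applied to all
#'   variants.
#' @return n x m numeric matrix of standardised estimates with the
#'   dimnames of \code{assoc}.
#' @export
standardizeAssociations <- function(assoc, corr = NULL) {
  stopifnot(is(assoc, "AssociationSet"))
  beta <- SummarizedExperiment::assay(assoc, "beta")
  se <- SummarizedExperiment::assay(assoc, "se")
  if (is.null(corr)) {
    z <- beta / se
  } else {
    validateTraitCorrelation(corr)
    if (nrow(corr) != ncol(beta))
      stop("dimension of 'corr' does not match the number of traits")
    cInvSqrt <- NULL
    z <- beta
    for (j in seq_len(nrow(beta))) {
      sigma <- outer(se[j, ], se[j, ]) * corr
      z[j, ] <- .invSqrtSym(sigma, label = rownames(beta)[j]) %*% beta[j, ]
    }
  }
  dimnames(z) <- dimnames(beta)
  z
}

#' Project row vectors onto the unit sphere
#'
#' Divides each row by its Euclidean norm, yielding the proportional
#' association vectors \eqn{x_j} with \eqn{\lVert x_j\rVert = 1} that the
#' mixture model clusters. Direction is preserved exactly; scaling a row
#' by any positive constant leaves its output unchanged.
#'
#' @param z n x m numeric matrix (e.g. standardised associations).
#' @param variantIds,traitNames optional dimnames (default taken from
#'   \code{z}).
#' @param normFloor rows with norm below this are an error (default 1e-12).
#' @return A \linkS4class{DirectionalSet}.
#' @examples
#' unitVectors(normalizeToUnit(rbind(c(3, 4))))  # (0.6, 0.8)
#' @export
normalizeToUnit <- function(z, variantIds = rownames(z),
                            traitNames = colnames(z), normFloor = 1e-12) {
  z <- as.matrix(z)
  if (is.null(variantIds)) variantIds <- paste0("v", seq_len(nrow(z)))
  if (is.null(traitNames)) traitNames <- paste0("trait", seq_len(ncol(z)))
  nrm <- sqrt(rowSums(z^2))
  bad <- !is.finite(nrm) | nrm < normFloor
  if (any(bad))
    stop("degenerate (near-zero norm) association vector for variant(s): ",
         paste(variantIds[bad], collapse = ", "))
  x <- z / nrm
  dimnames(x) <- list(variantIds, traitNames)
  new("DirectionalSet", unitVectors = x)
}

#' @describeIn DirectionalSet-class the matrix of unit row vectors.
#' @param object,x a \code{DirectionalSet}.
#' @export
unitVectors <- function(x) {
  stopifnot(is(x, "DirectionalSet"))
  x@unitVectors
}

#' Write a DirectionalSet as delimited text
#'
#' One row per variant: id plus the m unit-vector coordinates.
#'
#' @param x a \linkS4class{DirectionalSet}.
#' @param path output file path.
#' @param delim field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
writeDirectionalSet <- function(x, path, delim = "\t") {
  stopifnot(is(x, "DirectionalSet"))
  df <- data.frame(variant = rownames(x@unitVectors), x@unitVectors,
                   check.names = FALSE)
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}
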