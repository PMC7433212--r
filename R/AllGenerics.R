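#' Accessors for cohort and call objects
#'
#' \code{cancerOf} returns the per-sample cancer code; \code{tumorFlag} the
#' per-sample tumor indicator; \code{cnv}, \code{expr}, \code{clinical} and
#' \code{cohortTruth} extract the components of a \linkS4class{SyntheticCohort};
#' \code{lofGenes}, \code{gofGenes} and \code{conflictGenes} the components of
#' a \linkS4class{GeneSetCall}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cancerOf", function(x) standardGeneric("cancerOf"))
#' @rdname accessors
#' @export
setGeneric("tumorFlag", function(x) standardGeneric("tumorFlag"))
#' @rdname accessors
#' @export
setGeneric("cnv", function(x) standardGeneric("cnv"))
#' @rdname accessors
#' @export
setGeneric("expr", function(x) standardGeneric("expr"))
#' @rdname accessors
#' @export
setGeneric("clinical", function(x) standardGeneric("clinical"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setGeneric("lofGenes", function(x) standardGeneric("lofGenes"))
#' @rdname accessors
#' @export
setGeneric("gofGenes", function(x) standardGeneric("gofGenes"))
#' @rdname accessors
#' @export
setGeneric("conflictGenes", function(x) standardGeneric("conflictGenes"))

#' @rdname accessors
setMethod("cancerOf", "SummarizedExperiment",
          function(x) setNames(colData(x)$cancer, colnames(x)))
#' @rdname accessors
setMethod("tumorFlag", "ExprExperiment",
          function(x) setNames(colData(x)$tumor, colnames(x)))
#' @rdname accessors
setMethod("cnv", "SyntheticCohort", function(x) x@cnv)
#' @rdname accessors
setMethod("expr", "SyntheticCohort", function(x) x@expr)
#' @rdname accessors
setMethod("clinical", "SyntheticCohort", function(x) x@clinical)
#' @rdname accessors
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)
#' @rdname accessors
setMethod("lofGenes", "GeneSetCall", function(x) x@lofGenes)
#' @rdname accessors
setMethod("gofGenes", "GeneSetCall", function(x) x@gofGenes)
#' @rdname accessors
setMethod("conflictGenes", "GeneSetCall", function(x) x@conflicts)
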