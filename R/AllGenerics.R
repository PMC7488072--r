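#' Accessors for GeneNetwork and related objects
#'
#' Standard accessors: `geneNames()`, `nGenes()`, `lambdaPlus()`,
#' `lambdaMinus()`, `serviceRates()`, `routingPos()`, `routingNeg()`,
#' `departureProbs()` read the slots of a [GeneNetwork-class];
#' `qValues()` and `isStable()` read a [StationarySolution-class];
#' `generatorMatrix()` and `truncationLevel()` read a
#' [TruncatedGenerator-class].
#'
#' @param object a sangnet S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setGeneric("lambdaPlus", function(object) standardGeneric("lambdaPlus"))
#' @rdname accessors
#' @export
setGeneric("lambdaMinus", function(object) standardGeneric("lambdaMinus"))
#' @rdname accessors
#' @export
setGeneric("serviceRates", function(object) standardGeneric("serviceRates"))
#' @rdname accessors
#' @export
setGeneric("routingPos", function(object) standardGeneric("routingPos"))
#' @rdname accessors
#' @export
setGeneric("routingNeg", function(object) standardGeneric("routingNeg"))
#' @rdname accessors
#' @export
setGeneric("departureProbs", function(object) standardGeneric("departureProbs"))
#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("isStable", function(object) standardGeneric("isStable"))
#' @rdname accessors
#' @export
setGeneric("generatorMatrix", function(object) standardGeneric("generatorMatrix"))
#' @rdname accessors
#' @export
setGeneric("truncationLevel", function(object) standardGeneric("truncationLevel"))

#' @rdname accessors
setMethod("geneNames", "GeneNetwork", function(object) object@geneNames)
#' @rdname accessors
setMethod("nGenes", "GeneNetwork", function(object) length(object@geneNames))
#' @rdname accessors
setMethod("lambdaPlus", "GeneNetwork", function(object) object@lambdaPlus)
#' @rdname accessors
setMethod("lambdaMinus", "GeneNetwork", function(object) object@lambdaMinus)
#' @rdname accessors
setMethod("serviceRates", "GeneNetwork", function(object) object@mu)
#' @rdname accessors
setMethod("routingPos", "GeneNetwork", function(object) object@pPlus)
#' @rdname accessors
setMethod("routingNeg", "GeneNetwork", function(object) object@pMinus)
#' @rdname accessors
setMethod("departureProbs", "GeneNetwork", function(object) object@d)

#' @rdname accessors
setMethod("qValues", "StationarySolution", function(object) object@q)
#' @rdname accessors
setMethod("isStable", "StationarySolution", function(object) object@stable)

#' @rdname accessors
setMethod("generatorMatrix", "TruncatedGenerator", function(object) object@Q)
#' @rdname accessors
setMethod("truncationLevel", "TruncatedGenerator", function(object) object@K)
#' @rdname accessors
setMethod("geneNames", "TruncatedGenerator", function(object) object@geneNames)
#' @rdname accessors
setMethod("nGenes", "TruncatedGenerator", function(object) object@N)

setMethod("show", "GeneNetwork", function(object) {
  n <- nGenes(object)
  r <- sum(object@pPlus > 0) + sum(object@pMinus > 0)
  cat(sprintf("GeneNetwork with %d gene%s, %d synchronizing transition%s\n",
              n, if (n == 1) "" else "s", r, if (r == 1) "" else "s"))
  cat("  genes: ", paste(object@geneNames, collapse = ", "), "\n", sep = "")
  cat("  lambda+: ", paste(format(object@lambdaPlus), collapse = ", "), "\n", sep = "")
  cat("  lambda-: ", paste(format(object@lambdaMinus), collapse = ", "), "\n", sep = "")
  cat("  mu:      ", paste(format(object@mu), collapse = ", "), "\n", sep = "")
  invisible(object)
})

setMethod("show", "StationarySolution", function(object) {
  cat("StationarySolution (G-network traffic equations)\n")
  print(round(object@q, 6))
  cat(sprintf("  %d iterations, residual %.3g, %s\n", object@iterations,
              object@residual,
              if (object@stable) "stable (all q < 1)" else "UNSTABLE (some q >= 1)"))
  invisible(object)
})

setMethod("show", "TruncatedGenerator", function(object) {
  cat(sprintf("TruncatedGenerator: %d x %d sparse (K = %d, N = %d, %s semantics)\n",
              nrow(object@Q), ncol(object@Q), object@K, object@N,
              object@semantics))
  cat("  ", object@indexOrder, "\n", sep = "")
  invisible(object)
})

setMethod("show", "PairJointDistribution", function(object) {
  cat(sprintf("PairJointDistribution of genes (%d, %d) at t = %g\n",
              object@i, object@j, object@t))
  print(round(object@P, 4))
  invisible(object)
})
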