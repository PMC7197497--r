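#' @title Accessors for dipr result objects
#' @description Small accessor generics: `nLoci()` counts loci,
#'   `truthTable()` returns the simulated truth table, `locusTable()` the
#'   per-locus classification table, `classCounts()` the named topology-class
#'   counts, `deltaK()` the three divergence-shift statistics, `pValues()` the
#'   bootstrap p-values and `dipCall()` the categorical directionality call.
#' @param x a dipr object.
#' @return See each method.
#' @name dipr-accessors
#' @aliases nLoci truthTable locusTable classCounts deltaK pValues dipCall
NULL

#' @rdname dipr-accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname dipr-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname dipr-accessors
#' @export
setGeneric("locusTable", function(x) standardGeneric("locusTable"))
#' @rdname dipr-accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))
#' @rdname dipr-accessors
#' @export
setGeneric("deltaK", function(x) standardGeneric("deltaK"))
#' @rdname dipr-accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname dipr-accessors
#' @export
setGeneric("dipCall", function(x) standardGeneric("dipCall"))

#' @rdname dipr-accessors
#' @export
setMethod("nLoci", "LocusSet", function(x) length(x@loci))
#' @rdname dipr-accessors
#' @export
setMethod("nLoci", "ClassifiedLoci", function(x) nrow(x@loci))
#' @rdname dipr-accessors
#' @export
setMethod("truthTable", "LocusSet", function(x) x@truth)
#' @rdname dipr-accessors
#' @export
setMethod("locusTable", "ClassifiedLoci", function(x) x@loci)
#' @rdname dipr-accessors
#' @export
setMethod("classCounts", "ClassifiedLoci", function(x) {
  counts <- table(factor(x@loci$class, levels = .TOPOLOGIES))
  stats::setNames(as.integer(counts), .TOPOLOGIES)
})
#' @rdname dipr-accessors
#' @export
setMethod("deltaK", "DeltaKProfile", function(x)
  c(dk23 = x@dk23, dk12 = x@dk12, dk13 = x@dk13))
#' @rdname dipr-accessors
#' @export
setMethod("pValues", "DeltaKProfile", function(x)
  c(p23 = x@p23, p12 = x@p12, p13 = x@p13))
#' @rdname dipr-accessors
#' @export
setMethod("dipCall", "DeltaKProfile", function(x) x@call)

setMethod("show", "DipSimParams", function(object) {
  cat("DipSimParams (times in 4N-generation units)\n")
  cat(sprintf("  tInt=%g  tAlpha=%g  tBeta=%g  tGamma=%g  (scaleFactor=%g)\n",
              object@tInt, object@tAlpha, object@tBeta, object@tGamma,
              object@scaleFactor))
  cat(sprintf("  seqScale=%g subs/site/unit  locusLength=%d bp  kappa=%g\n",
              object@seqScale, object@locusLength, object@kappa))
  cat(sprintf("  baseFreqs=(%s)  pMove=%g  theta=%g\n",
              paste(format(object@baseFreqs), collapse = ", "),
              object@pMove, object@theta))
})

setMethod("show", "GeneTree", function(object) {
  cat(sprintf("GeneTree: truth=%s realizedTransfer=%s\n", object@truth,
              object@realizedTransfer))
  cat(" ", ape::write.tree(object@phy), "\n")
})

setMethod("show", "LocusAlignment", function(object) {
  cat(sprintf("LocusAlignment %s: 4 x %d bp (truth=%s)\n", object@locusId,
              ncol(object@seqs), object@truth))
})

setMethod("show", "LocusSet", function(object) {
  cat(sprintf("LocusSet of %d loci\n", length(object@loci)))
  if (nrow(object@truth)) {
    tab <- table(object@truth$history)
    cat("  histories:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n")
  }
})

setMethod("show", "ClassifiedLoci", function(object) {
  counts <- classCounts(object)
  cat(sprintf("ClassifiedLoci: %d loci (model=%s%s, %d dropped)\n",
              nrow(object@loci), object@model,
              if (object@omniscient) ", omniscient" else "",
              length(object@dropped)))
  cat("  ", paste(sprintf("%s=%d", names(counts), counts), collapse = "  "),
      "\n")
})

setMethod("show", "DeltaKProfile", function(object) {
  cat("1xDIP delta-K profile\n")
  cat(sprintf("  dK23=%.5g (p=%.4g)  dK12=%.5g (p=%.4g)  dK13=%.5g (p=%.4g)\n",
              object@dk23, object@p23, object@dk12, object@p12,
              object@dk13, object@p13))
  cat(sprintf("  call=%s (alpha=%g, nBoot=%d, dropped=%d%s)\n", object@call,
              object@alpha, object@nBoot, object@nDropped,
              if (object@unreliable) ", UNRELIABLE" else ""))
})

setMethod("show", "DoubleDipResult", function(object) {
  cat(sprintf("2xDIP: ddK=%.5g, two-sided p=%.4g (floor %.4g, nBoot=%d%s)\n",
              object@ddk, object@p, object@pFloor, object@nBoot,
              if (object@unreliable) ", UNRELIABLE" else ""))
})

setMethod("show", "TripleDipResult", function(object) {
  if (object@computable)
    cat(sprintf(
      "3xDIP: dddK=%.5g (ddK=%.5g, ddK_ALT=%.5g, nInt=%d, nAlt=%d), p=%.4g\n",
      object@dddk, object@ddk, object@ddkAlt, object@nInt, object@nAlt,
      object@p))
  else
    cat(sprintf("3xDIP not computable: %s (ddK=%.5g, nInt=%d, nAlt=%d)\n",
                object@reason, object@ddk, object@nInt, object@nAlt))
})
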