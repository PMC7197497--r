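setOldClass("phylo")
setOldClass("DNAbin")

## History labels and topology classes used throughout. Kept as plain
## character codes (validated at construction) rather than factors so they
## survive TSV round-trips unchanged.
.HISTORIES <- c("SP", "INT_P3_TO_P2", "INT_P2_TO_P3")
.TOPOLOGIES <- c("SP", "INT", "ALT", "UNRESOLVED")
.CALLS <- c("P3_TO_P2", "P2_TO_P3", "BIDIRECTIONAL", "INCONCLUSIVE")
.ROLES <- c("P1", "P2", "P3", "O")

#' Simulation parameters for the four-taxon introgression model
#'
#' Container for the node depths of the species tree, the introgression time,
#' and the sequence-evolution settings used by [drawGeneTree()],
#' [evolveSequences()], [simulateGenome()] and [simulateChromosome()].
#' Construct with [dipSimParams()], which applies the scaling factor and the
#' relative introgression time before validation.
#'
#' Times are in coalescent units of 4N generations; in this scaling each pair
#' of lineages within a population coalesces at rate 2 per unit.
#'
#' @slot tInt numeric; time of the introgression event.
#' @slot tAlpha,tBeta,tGamma numeric; speciation times (P1P2, +P3, +O).
#' @slot scaleFactor numeric; the multiplier that was applied to all four
#'   node depths (recorded for provenance; the time slots are post-scaling).
#' @slot relIntTime numeric; if not `NA`, the fraction of `tAlpha` at which
#'   introgression was placed (`tInt = relIntTime * tAlpha`).
#' @slot seqScale numeric; expected substitutions/site per coalescent unit.
#' @slot locusLength integer; locus length in bp.
#' @slot kappa numeric; HKY transition/transversion rate parameter.
#' @slot baseFreqs numeric(4); HKY stationary frequencies (A, C, G, T).
#' @slot pMove numeric in (0, 1]; probability that the recipient lineage
#'   transfers to the donor population at `tInt` for an introgression history.
#' @slot theta numeric; population mutation parameter. Carried for fidelity to
#'   the original simulation commands; it has no effect when sequences are
#'   evolved along the drawn genealogy.
#' @seealso [dipSimParams()]
#' @export
setClass("DipSimParams",
  representation(
    tInt = "numeric", tAlpha = "numeric", tBeta = "numeric", tGamma = "numeric",
    scaleFactor = "numeric", relIntTime = "numeric",
    seqScale = "numeric", locusLength = "integer",
    kappa = "numeric", baseFreqs = "numeric",
    pMove = "numeric", theta = "numeric"
  )
)

setValidity("DipSimParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!all(vapply(list(object@tInt, object@tAlpha, object@tBeta, object@tGamma,
                       object@scaleFactor, object@seqScale, object@kappa,
                       object@pMove, object@theta), one, logical(1))))
    msg <- c(msg, "all scalar parameters must be single finite numbers")
  else {
    if (!(0 < object@tInt && object@tInt < object@tAlpha &&
          object@tAlpha < object@tBeta && object@tBeta < object@tGamma))
      msg <- c(msg, "node depths must satisfy 0 < tInt < tAlpha < tBeta < tGamma (after scaling)")
    if (object@scaleFactor <= 0) msg <- c(msg, "scaleFactor must be > 0")
    if (object@seqScale <= 0) msg <- c(msg, "seqScale must be > 0")
    if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
    if (!(object@pMove > 0 && object@pMove <= 1))
      msg <- c(msg, "pMove must be in (0, 1]")
  }
  if (length(object@locusLength) != 1L || is.na(object@locusLength) ||
      object@locusLength < 1L)
    msg <- c(msg, "locusLength must be a single integer >= 1")
  if (length(object@baseFreqs) != 4L || any(object@baseFreqs <= 0) ||
      abs(sum(object@baseFreqs) - 1) > 1e-8)
    msg <- c(msg, "baseFreqs must be 4 positive frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

#' A single simulated four-tip genealogy
#'
#' Rooted four-tip coalescent tree with branch lengths in coalescent units
#' (4N generations), tips labeled by role (`P1`, `P2`, `P3`, `O`), the true
#' simulated history, and whether the recipient lineage actually transferred
#' at the introgression time.
#'
#' @slot phy an [ape::phylo] tree.
#' @slot truth one of `"SP"`, `"INT_P3_TO_P2"`, `"INT_P2_TO_P3"`.
#' @slot realizedTransfer logical; `TRUE` if the recipient lineage moved to
#'   the donor population at `tInt` (always `FALSE` for `"SP"`).
#' @export
setClass("GeneTree",
  representation(phy = "phylo", truth = "character",
                 realizedTransfer = "logical")
)

setValidity("GeneTree", function(object) {
  msg <- character()
  if (!(length(object@truth) == 1L && object@truth %in% .HISTORIES))
    msg <- c(msg, "truth must be one of SP, INT_P3_TO_P2, INT_P2_TO_P3")
  if (!setequal(object@phy$tip.label, .ROLES))
    msg <- c(msg, "tree tips must be exactly P1, P2, P3, O")
  if (length(msg)) msg else TRUE
})

#' One locus: a four-sequence alignment with roles and optional truth
#'
#' @slot locusId character scalar identifier.
#' @slot seqs a `DNAbin` matrix with rows named `P1`, `P2`, `P3`, `O`.
#' @slot truth simulated history label, or `NA` for empirical data.
#' @slot contig source sequence name (`NA` if not windowed from a chromosome).
#' @slot start,end 0-based half-open source coordinates (`NA` if simulated).
#' @export
setClass("LocusAlignment",
  representation(locusId = "character", seqs = "DNAbin", truth = "character",
                 contig = "character", start = "numeric", end = "numeric")
)

setValidity("LocusAlignment", function(object) {
  msg <- character()
  s <- object@seqs
  if (!is.matrix(s)) msg <- c(msg, "seqs must be a DNAbin matrix")
  else {
    if (nrow(s) != 4L || !setequal(rownames(s), .ROLES))
      msg <- c(msg, "seqs must have exactly the four rows P1, P2, P3, O")
    if (ncol(s) < 1L) msg <- c(msg, "alignment must have >= 1 column")
  }
  if (!(length(object@truth) == 1L &&
        (is.na(object@truth) || object@truth %in% .HISTORIES)))
    msg <- c(msg, "truth must be NA or a valid history label")
  if (length(msg)) msg else TRUE
})

#' A set of loci with its truth table
#'
#' The unit of analysis for a simulated or windowed "genome": a list of
#' [LocusAlignment-class] objects plus a per-locus truth table (empty columns
#' for empirical data).
#'
#' @slot loci list of [LocusAlignment-class].
#' @slot truth data.frame with columns `locus_id`, `history`,
#'   `realized_transfer`, `start`, `end`.
#' @slot params the [DipSimParams-class] used to simulate, or `NULL`.
#' @export
setClass("LocusSet",
  representation(loci = "list", truth = "data.frame", params = "ANY")
)

setValidity("LocusSet", function(object) {
  if (length(object@loci) &&
      !all(vapply(object@loci, is, logical(1), "LocusAlignment")))
    return("all elements of loci must be LocusAlignment objects")
  if (nrow(object@truth) != length(object@loci))
    return("truth table must have one row per locus")
  TRUE
})

#' Per-locus topology classes and pairwise divergences
#'
#' Result of [classifyLoci()]: one row per usable locus with its topology
#' class (`SP`, `INT`, `ALT`, `UNRESOLVED`) and the pairwise divergences
#' K23, K12, K13 (substitutions/site) with the number of sites used per pair.
#' Loci with any undefined distance (no usable sites, or distance-correction
#' saturation) are excluded and listed in `dropped`.
#'
#' @slot loci data.frame: `locus_id`, `class`, `K23`, `K12`, `K13`, `n23`,
#'   `n12`, `n13`, `truth`.
#' @slot model distance model used (`"K80"`, `"JC69"` or `"raw"`).
#' @slot omniscient logical; `TRUE` if truth labels replaced NJ topology.
#' @slot dropped character; ids of loci excluded for undefined distances.
#' @export
setClass("ClassifiedLoci",
  representation(loci = "data.frame", model = "character",
                 omniscient = "logical", dropped = "character")
)

setValidity("ClassifiedLoci", function(object) {
  need <- c("locus_id", "class", "K23", "K12", "K13", "n23", "n12", "n13", "truth")
  if (!all(need %in% names(object@loci)))
    return(paste("loci table must have columns:", paste(need, collapse = ", ")))
  if (!all(object@loci$class %in% .TOPOLOGIES))
    return("invalid topology class")
  TRUE
})

#' Result of the first DIP layer (delta-K profile)
#'
#' @slot dk23,dk12,dk13 the three divergence-shift statistics (subs/site).
#' @slot p23,p12,p13 one-sided bootstrap p-values (proportion of replicates
#'   with the statistic <= 0).
#' @slot call one of `"P3_TO_P2"`, `"P2_TO_P3"`, `"BIDIRECTIONAL"`,
#'   `"INCONCLUSIVE"`.
#' @slot nBoot number of bootstrap replicates requested.
#' @slot nDropped replicates dropped for an empty SP or INT class.
#' @slot unreliable `TRUE` if more than 10 percent of replicates were dropped.
#' @slot alpha significance level used for the call.
#' @export
setClass("DeltaKProfile",
  representation(dk23 = "numeric", dk12 = "numeric", dk13 = "numeric",
                 p23 = "numeric", p12 = "numeric", p13 = "numeric",
                 call = "character", nBoot = "integer", nDropped = "integer",
                 unreliable = "logical", alpha = "numeric")
)

#' Result of the second DIP layer (delta-delta-K)
#'
#' @slot ddk point estimate of the asymmetry statistic dK12 - dK13; positive
#'   values indicate predominance of P3-to-P2 introgression.
#' @slot p two-sided bootstrap p-value (doubled minority-side proportion,
#'   capped at 1).
#' @slot pFloor minimum resolvable p, `2 / (usable replicates)`.
#' @slot bootMean,bootQuantiles summary of the replicate distribution.
#' @slot nBoot,nDropped,unreliable as in [DeltaKProfile-class].
#' @export
setClass("DoubleDipResult",
  representation(ddk = "numeric", p = "numeric", pFloor = "numeric",
                 bootMean = "numeric", bootQuantiles = "numeric",
                 nBoot = "integer", nDropped = "integer",
                 unreliable = "logical")
)

#' Result of the third DIP layer (delta-delta-delta-K)
#'
#' The ILS-corrected asymmetry statistic. `computable` is `FALSE` (with a
#' `reason`) when there are no ALT-topology loci, or when the INT and ALT
#' counts coincide (zero denominator); `ddk` is still reported in that case.
#'
#' @slot ddk,ddkAlt the standard and ALT-substituted asymmetry statistics.
#' @slot nInt,nAlt counts of INT- and ALT-topology loci.
#' @slot dddk the corrected statistic `(ddk*nInt - ddkAlt*nAlt)/(nInt - nAlt)`.
#' @slot p two-sided bootstrap p-value; `pFloor` its resolution bound.
#' @slot computable logical; `reason` one of `"ok"`, `"no ALT loci"`,
#'   `"equal INT and ALT counts"`.
#' @slot nBoot,nDropped,unreliable as in [DeltaKProfile-class]; dropped here
#'   also counts replicates where the statistic was not computable.
#' @export
setClass("TripleDipResult",
  representation(ddk = "numeric", ddkAlt = "numeric",
                 nInt = "integer", nAlt = "integer", dddk = "numeric",
                 p = "numeric", pFloor = "numeric",
                 computable = "logical", reason = "character",
                 nBoot = "integer", nDropped = "integer",
                 unreliable = "logical")
)
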