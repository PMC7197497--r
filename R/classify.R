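## raw DNAbin codes for unambiguous bases (a, c, g, t)
.GOOD_RAW <- as.raw(c(0x88, 0x28, 0x48, 0x18))

## 256-entry lookup: TRUE at the raw codes above (fast ambiguity scan)
.GOOD_LUT <- { l <- logical(256); l[as.integer(.GOOD_RAW) + 1L] <- TRUE; l }

.asDnabinPair <- function(x) {
  if (is.character(x)) {
    if (length(x) == 1L) x <- strsplit(x, "")[[1]]
    x <- ape::as.DNAbin(matrix(tolower(x), nrow = 1L))
  } else if (inherits(x, "DNAbin")) {
    x <- as.matrix(x)
    if (nrow(x) != 1L) stop("expected a single sequence")
  } else stop("sequences must be character or DNAbin")
  x
}

#' Pairwise sequence divergence between two aligned sequences
#'
#' Computes the divergence of two equal-length sequences in
#' substitutions/site under the p-distance (`"raw"`), Jukes-Cantor (`"JC69"`)
#' or Kimura two-parameter (`"K80"`, the default) model via
#' [ape::dist.dna()]. Sites where either sequence carries a gap or ambiguity
#' code are excluded for the pair (pairwise deletion). An undefined distance
#' -- no usable sites, or a non-positive logarithm argument under JC69/K80
#' (saturation) -- is returned as `NA` with a `"reason"` attribute.
#'
#' @param a,b character strings (or character vectors of single bases, or
#'   one-row `DNAbin`) of equal length.
#' @param model `"K80"`, `"JC69"` or `"raw"`.
#' @return numeric divergence with attribute `nSites` (sites compared), or
#'   `NA` with attribute `reason`.
#' @examples
#' pairwiseDistance("AAAA", "AAGG", model = "raw")   # 0.5
#' pairwiseDistance("AAAA", "AAGG", model = "JC69")  # ~0.8239
#' @export
pairwiseDistance <- function(a, b, model = c("K80", "JC69", "raw")) {
  model <- match.arg(model)
  a <- .asDnabinPair(a)
  b <- .asDnabinPair(b)
  if (ncol(a) != ncol(b)) stop("sequences must have equal length")
  good <- (unclass(a)[1L, ] %in% .GOOD_RAW) & (unclass(b)[1L, ] %in% .GOOD_RAW)
  n <- sum(good)
  if (n == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "no usable sites"
    return(out)
  }
  m <- rbind(a, b)
  rownames(m) <- c("a", "b")
  d <- ape::dist.dna(m, model = model, pairwise.deletion = TRUE)[1L]
  if (!is.finite(d)) {
    out <- NA_real_
    attr(out, "reason") <- "saturation"
    attr(out, "nSites") <- n
    return(out)
  }
  attr(d, "nSites") <- n
  d
}

#' Neighbor-joining tree from a four-taxon distance matrix
#'
#' Thin wrapper around [ape::nj()] with precondition checks: the matrix must
#' be a symmetric 4x4 with zero diagonal and finite entries. Ties are broken
#' deterministically (first minimal pair in the fixed input order); exact
#' ties yield a zero-length internal branch, which downstream classification
#' treats as unresolved.
#'
#' @param d a 4x4 symmetric numeric matrix (or `dist`) with dimnames.
#' @return an unrooted `phylo` with four tips.
#' @examples
#' d <- matrix(0.6, 4, 4, dimnames = list(c("P1","P2","P3","O"),
#'                                        c("P1","P2","P3","O")))
#' d[1, 2] <- d[2, 1] <- 0.2; d[3, 4] <- d[4, 3] <- 0.2; diag(d) <- 0
#' njTree(d)
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != 4L || ncol(d) != 4L)
    stop("d must be a 4x4 matrix")
  if (any(!is.finite(d))) stop("distance matrix has undefined entries")
  if (any(abs(d - t(d)) > 1e-12) || any(abs(diag(d)) > 1e-12))
    stop("d must be symmetric with zero diagonal")
  ape::nj(stats::as.dist(d))
}

.pairKey <- function(pair) paste(sort(pair), collapse = "|")

.SPLIT_CLASS <- c("P1|P2" = "SP", "O|P3" = "SP",
                  "P2|P3" = "INT", "O|P1" = "INT",
                  "P1|P3" = "ALT", "O|P2" = "ALT")

#' Topology class of a four-taxon gene tree
#'
#' Maps the quartet split of a four-tip tree (tips labeled `P1`, `P2`, `P3`,
#' `O`) to its class: sister pair P1P2 (or equivalently P3O) is the species
#' topology `SP`; P2P3 the introgression topology `INT`; P1P3 the alternative
#' topology `ALT` (produced by ILS only). A non-positive internal branch --
#' including the star tree from exact distance ties -- is `UNRESOLVED`.
#'
#' @param phy a `phylo` with exactly the four tips `P1`, `P2`, `P3`, `O`
#'   (rooted or unrooted).
#' @return one of `"SP"`, `"INT"`, `"ALT"`, `"UNRESOLVED"`.
#' @examples
#' classifyTopology(ape::read.tree(text = "((P2:1,P3:1):1,P1:2,O:2);"))
#' @export
classifyTopology <- function(phy) {
  if (!inherits(phy, "phylo") || length(phy$tip.label) != 4L)
    stop("phy must be a four-tip phylo tree")
  if (!setequal(phy$tip.label, .ROLES))
    stop("tips must carry exactly the roles P1, P2, P3, O")
  phy <- ape::unroot(phy)
  internal <- which(phy$edge[, 2L] > 4L)
  if (length(internal) != 1L) return("UNRESOLVED")  # star multifurcation
  if (!is.null(phy$edge.length) && phy$edge.length[internal] <= 0)
    return("UNRESOLVED")
  node <- phy$edge[internal, 2L]
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  kids <- kids[kids <= 4L]
  if (length(kids) != 2L) return("UNRESOLVED")
  unname(.SPLIT_CLASS[.pairKey(phy$tip.label[kids])])
}

## distances, per-pair usable-site counts and topology class for one locus
.classifyOne <- function(locus, model) {
  s <- locus@seqs
  good <- matrix(.GOOD_LUT[as.integer(unclass(s)) + 1L], nrow = 4L)
  nPair <- function(i, j) sum(good[i, ] & good[j, ])
  n23 <- nPair(2L, 3L); n12 <- nPair(1L, 2L); n13 <- nPair(1L, 3L)
  nO <- min(nPair(1L, 4L), nPair(2L, 4L), nPair(3L, 4L))
  if (min(n23, n12, n13, nO) == 0L)
    return(list(ok = FALSE, reason = "no usable sites"))
  d <- ape::dist.dna(s, model = model, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(d)))
    return(list(ok = FALSE, reason = "saturation"))
  cls <- classifyTopology(ape::nj(stats::as.dist(d)))
  list(ok = TRUE, class = cls,
       K23 = d["P2", "P3"], K12 = d["P1", "P2"], K13 = d["P1", "P3"],
       n23 = n23, n12 = n12, n13 = n13)
}

#' Classify loci by gene-tree topology and compute pairwise divergences
#'
#' For every locus, computes the pairwise divergences K23 (P2 vs P3), K12
#' (P1 vs P2) and K13 (P1 vs P3) under the chosen model (pairwise deletion of
#' ambiguous/gap sites), builds a neighbor-joining gene tree from the full
#' 4x4 distance matrix, and assigns the topology class `SP`, `INT`, `ALT` or
#' `UNRESOLVED`. Divergences are computed for all loci regardless of class.
#' Loci with an undefined distance (no usable sites for some pair, or
#' saturation of the distance correction) are excluded and reported in the
#' `dropped` slot with a warning.
#'
#' With `omniscient = TRUE` the simulated truth labels replace the
#' topology-based classes (`SP` stays `SP`; both introgression directions
#' become `INT`), isolating the behavior of the statistics from
#' classification error.
#'
#' @param x a [LocusSet-class], or a list of [LocusAlignment-class] objects.
#' @param model distance model: `"K80"` (default), `"JC69"` or `"raw"`.
#' @param omniscient logical; substitute truth labels for topology classes.
#' @return a [ClassifiedLoci-class] object.
#' @examples
#' set.seed(1)
#' gs <- simulateGenome(20, 0.5, 1, dipSimParams(locusLength = 500))
#' classifyLoci(gs)
#' @export
classifyLoci <- function(x, model = c("K80", "JC69", "raw"),
                         omniscient = FALSE) {
  model <- match.arg(model)
  if (is(x, "LocusSet")) x <- x@loci
  if (!length(x)) stop("need at least one locus")
  stopifnot(all(vapply(x, is, logical(1), "LocusAlignment")))
  n <- length(x)
  ids <- vapply(x, function(l) l@locusId, character(1))
  truth <- vapply(x, function(l) l@truth, character(1))
  if (omniscient && anyNA(truth))
    stop("omniscient classification requires truth labels on every locus")
  res <- lapply(x, .classifyOne, model = model)
  ok <- vapply(res, function(r) r$ok, logical(1))
  if (!any(ok))
    stop("no locus yielded defined pairwise distances")
  if (any(!ok))
    warning(sprintf("%d locus/loci dropped for undefined distances", sum(!ok)))
  keep <- which(ok)
  tab <- data.frame(
    locus_id = ids[keep],
    class = vapply(res[keep], function(r) r$class, character(1)),
    K23 = vapply(res[keep], function(r) r$K23, numeric(1)),
    K12 = vapply(res[keep], function(r) r$K12, numeric(1)),
    K13 = vapply(res[keep], function(r) r$K13, numeric(1)),
    n23 = vapply(res[keep], function(r) r$n23, integer(1)),
    n12 = vapply(res[keep], function(r) r$n12, integer(1)),
    n13 = vapply(res[keep], function(r) r$n13, integer(1)),
    truth = truth[keep],
    stringsAsFactors = FALSE)
  if (omniscient)
    tab$class <- ifelse(tab$truth == "SP", "SP", "INT")
  methods::new("ClassifiedLoci", loci = tab, model = model,
               omniscient = omniscient, dropped = ids[!ok])
}

#' Re-label a classified genome with its simulated truth
#'
#' Converts a topology-classified [ClassifiedLoci-class] object to omniscient
#' mode without recomputing distances: each locus takes the class implied by
#' its truth label (`SP` stays `SP`, both introgression directions become
#' `INT`). Useful for contrasting topology-based and truth-based statistics
#' on the same simulated genome.
#'
#' @param classified a [ClassifiedLoci-class] with truth labels on all loci.
#' @return a [ClassifiedLoci-class] in omniscient mode.
#' @export
asOmniscient <- function(classified) {
  stopifnot(is(classified, "ClassifiedLoci"))
  tab <- classified@loci
  if (anyNA(tab$truth))
    stop("omniscient re-labeling requires truth labels on every locus")
  tab$class <- ifelse(tab$truth == "SP", "SP", "INT")
  methods::new("ClassifiedLoci", loci = tab, model = classified@model,
               omniscient = TRUE, dropped = classified@dropped)
}
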