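#' Construct simulation parameters
#'
#' Builds a validated [DipSimParams-class] object. `tInt`, `tAlpha`, `tBeta`
#' and `tGamma` are node depths in coalescent units of 4N generations
#' (defaults 1, 4, 8, 12). `scaleFactor` multiplies all four depths, so the
#' whole species tree can be shortened (more incomplete lineage sorting) or
#' stretched (less) with one knob. If `relIntTime` is given, the introgression
#' time is re-expressed as a fraction of the first speciation time:
#' `tInt = relIntTime * tAlpha` (after scaling).
#'
#' @param tInt introgression time (4N units).
#' @param tAlpha,tBeta,tGamma speciation times: P1/P2 split, P3 split, O split.
#' @param scaleFactor positive multiplier applied to all four node depths.
#' @param relIntTime optional fraction in (0, 1); overrides `tInt`.
#' @param seqScale expected substitutions/site per coalescent unit
#'   (default 0.01, so a branch of 1 coalescent unit carries 0.01 subs/site).
#' @param locusLength locus length in bp (default 5000).
#' @param kappa HKY transition/transversion rate parameter (default 2).
#' @param baseFreqs HKY stationary frequencies in A, C, G, T order.
#' @param pMove probability that the recipient lineage transfers to the donor
#'   population at `tInt` for an introgression history (default 1: a locus
#'   labeled introgressed really carries an introgressed genealogy; set 0.6
#'   to emulate simulators in which the sampled lineage is retained with
#'   probability 0.4).
#' @param theta population mutation parameter; carried for provenance, unused
#'   when sequences are evolved along the drawn genealogy.
#' @return a [DipSimParams-class] object.
#' @examples
#' dipSimParams()                      # the default deep-divergence regime
#' dipSimParams(scaleFactor = 0.1)     # short branches, heavy ILS
#' @export
dipSimParams <- function(tInt = 1, tAlpha = 4, tBeta = 8, tGamma = 12,
                         scaleFactor = 1, relIntTime = NA_real_,
                         seqScale = 0.01, locusLength = 5000, kappa = 2,
                         baseFreqs = rep(0.25, 4), pMove = 1, theta = 50) {
  if (!is.numeric(scaleFactor) || length(scaleFactor) != 1L ||
      !is.finite(scaleFactor) || scaleFactor <= 0)
    stop("scaleFactor must be a single positive number")
  tInt <- tInt * scaleFactor
  tAlpha <- tAlpha * scaleFactor
  tBeta <- tBeta * scaleFactor
  tGamma <- tGamma * scaleFactor
  if (!is.na(relIntTime)) {
    if (!(relIntTime > 0 && relIntTime < 1))
      stop("relIntTime must lie in (0, 1)")
    tInt <- relIntTime * tAlpha
  }
  methods::new("DipSimParams",
    tInt = tInt, tAlpha = tAlpha, tBeta = tBeta, tGamma = tGamma,
    scaleFactor = scaleFactor, relIntTime = as.numeric(relIntTime),
    seqScale = seqScale, locusLength = as.integer(locusLength),
    kappa = kappa, baseFreqs = baseFreqs, pMove = pMove, theta = theta)
}

#' Draw one four-tip genealogy under speciation plus directional introgression
#'
#' Simulates a structured coalescent for one lineage sampled from each of the
#' populations P1, P2, P3 and O. Backward in time, P2 merges into P1 at
#' `tAlpha`, P3 at `tBeta` and O at `tGamma`; within a population each pair of
#' lineages coalesces at rate 2 per coalescent unit (4N-generation scaling).
#' For an introgression history, the recipient's lineage (P2 for
#' `"INT_P3_TO_P2"`, P3 for `"INT_P2_TO_P3"`) moves to the donor population at
#' `tInt` with probability `pMove`.
#'
#' Uses R's global random number generator; call [set.seed()] for
#' reproducibility.
#'
#' @param params a [DipSimParams-class] object.
#' @param history one of `"SP"`, `"INT_P3_TO_P2"`, `"INT_P2_TO_P3"`.
#' @return a [GeneTree-class] object with branch lengths in coalescent units.
#' @examples
#' set.seed(1)
#' drawGeneTree(dipSimParams(), "INT_P3_TO_P2")
#' @export
drawGeneTree <- function(params, history = "SP") {
  stopifnot(is(params, "DipSimParams"))
  history <- match.arg(history, .HISTORIES)
  methods::validObject(params)

  ## event schedule, backward in time
  events <- list(list(time = params@tAlpha, type = "m2"),
                 list(time = params@tBeta, type = "m3"),
                 list(time = params@tGamma, type = "m4"))
  if (history != "SP")
    events <- c(list(list(time = params@tInt, type = "move")), events)

  recipTip <- if (history == "INT_P3_TO_P2") 2L else 3L
  donorPop <- if (history == "INT_P3_TO_P2") 3L else 2L

  linNode <- 1:4                       # active lineages (node ids)
  linPop <- c(1L, 2L, 3L, 4L)
  nodeTime <- numeric(7)               # tips 1-4 at 0, internals 5-7
  children <- vector("list", 3)
  curTime <- 0
  nextNode <- 5L
  evIdx <- 1L
  realized <- FALSE

  repeat {
    cnt <- tabulate(linPop, 4L)
    rate <- sum(cnt * (cnt - 1L))      # pairwise rate 2 per pair
    nextEv <- if (evIdx <= length(events)) events[[evIdx]]$time else Inf
    wait <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (curTime + wait < nextEv) {
      curTime <- curTime + wait
      w <- cnt * (cnt - 1L)
      pop <- sample.int(4L, 1L, prob = w)
      inPop <- which(linPop == pop)
      pair <- if (length(inPop) == 2L) inPop else sample(inPop, 2L)
      children[[nextNode - 4L]] <- linNode[pair]
      nodeTime[nextNode] <- curTime
      linNode <- c(linNode[-pair], nextNode)
      linPop <- c(linPop[-pair], pop)
      nextNode <- nextNode + 1L
      if (length(linNode) == 1L) break
    } else {
      curTime <- nextEv
      type <- events[[evIdx]]$type
      if (type == "move") {
        ## before tAlpha every population holds at most its own single
        ## lineage, so the recipient tip is still an active lineage
        i <- which(linNode == recipTip)
        if (stats::runif(1L) < params@pMove) {
          linPop[i] <- donorPop
          realized <- TRUE
        }
      } else if (type == "m2") linPop[linPop == 2L] <- 1L
      else if (type == "m3") linPop[linPop == 3L] <- 1L
      else linPop[linPop == 4L] <- 1L
      evIdx <- evIdx + 1L
    }
  }

  ## assemble an ape phylo; internal nodes were created in time order, the
  ## last one (our id 7) is the root and must become ape node 5; edges are
  ## emitted in preorder from the root (cladewise)
  remap <- function(id) if (id <= 4L) id else 12L - id
  childMap <- vector("list", 7L)
  timeApe <- numeric(7)
  for (u in 5:7) {
    childMap[[remap(u)]] <- vapply(children[[u - 4L]], remap, integer(1))
    timeApe[remap(u)] <- nodeTime[u]
  }
  edge <- matrix(0L, 6L, 2L)
  len <- numeric(6)
  r <- 0L
  emit <- function(node) {
    for (ch in childMap[[node]]) {
      r <<- r + 1L
      edge[r, ] <<- c(node, ch)
      len[r] <<- timeApe[node] - timeApe[ch]
      if (ch > 4L) emit(ch)
    }
  }
  emit(5L)
  phy <- structure(list(edge = edge, edge.length = len,
                        tip.label = .ROLES, Nnode = 3L),
                   class = "phylo", order = "cladewise")
  methods::new("GeneTree", phy = phy, truth = history,
               realizedTransfer = realized)
}

#' Evolve sequences along a genealogy under the HKY model
#'
#' Branch lengths of the gene tree (coalescent units) are multiplied by
#' `seqScale` to obtain expected substitutions/site, then sequences of
#' `locusLength` bp are simulated under HKY(`kappa`, `baseFreqs`) with
#' [phangorn::simSeq()]. The truth label of the tree is carried onto the
#' returned locus.
#'
#' @param tree a [GeneTree-class] object.
#' @param params a [DipSimParams-class] object.
#' @param locusId identifier for the resulting locus.
#' @return a [LocusAlignment-class] with four gap-free sequences.
#' @examples
#' set.seed(1)
#' evolveSequences(drawGeneTree(dipSimParams(locusLength = 100)),
#'                 dipSimParams(locusLength = 100))
#' @export
evolveSequences <- function(tree, params, locusId = "locus") {
  stopifnot(is(tree, "GeneTree"), is(params, "DipSimParams"))
  methods::validObject(params)
  phy <- tree@phy
  phy$edge.length <- phy$edge.length * params@seqScale
  dat <- phangorn::simSeq(phy, l = params@locusLength,
                          Q = c(1, params@kappa, 1, 1, params@kappa, 1),
                          bf = params@baseFreqs, type = "DNA")
  m <- as.matrix(ape::as.DNAbin(dat))[.ROLES, , drop = FALSE]
  methods::new("LocusAlignment", locusId = locusId, seqs = m,
               truth = tree@truth, contig = NA_character_,
               start = NA_real_, end = NA_real_)
}

#' Simulate a labeled multi-locus genome
#'
#' Generates `nLoci` independent loci of which exactly `round(nLoci * pInt)`
#' carry an introgression history; of those, `round(. * pP3toP2)` are
#' P3-to-P2 and the rest P2-to-P3. Counts are deterministic (not Bernoulli
#' draws) so simulated genomes have exactly their nominal composition; the
#' order of histories along the genome is randomized.
#'
#' @param nLoci number of loci (>= 1).
#' @param pInt fraction of loci with an introgression history, in `[0, 1]`.
#' @param pP3toP2 fraction of introgressed loci transferred P3-to-P2.
#' @param params a [DipSimParams-class] object.
#' @return a [LocusSet-class]; its [truthTable()] maps locus id to history.
#' @examples
#' set.seed(1)
#' gs <- simulateGenome(10, 0.5, 1, dipSimParams(locusLength = 200))
#' table(truthTable(gs)$history)
#' @export
simulateGenome <- function(nLoci, pInt, pP3toP2, params = dipSimParams()) {
  if (!(length(nLoci) == 1L && nLoci >= 1)) stop("nLoci must be >= 1")
  if (!(length(pInt) == 1L && pInt >= 0 && pInt <= 1))
    stop("pInt must lie in [0, 1]")
  if (!(length(pP3toP2) == 1L && pP3toP2 >= 0 && pP3toP2 <= 1))
    stop("pP3toP2 must lie in [0, 1]")
  nLoci <- as.integer(nLoci)
  nInt <- as.integer(round(nLoci * pInt))
  n32 <- as.integer(round(nInt * pP3toP2))
  histories <- c(rep("SP", nLoci - nInt), rep("INT_P3_TO_P2", n32),
                 rep("INT_P2_TO_P3", nInt - n32))
  histories <- sample(histories)
  ids <- sprintf("locus%05d", seq_len(nLoci))
  loci <- vector("list", nLoci)
  realized <- logical(nLoci)
  for (i in seq_len(nLoci)) {
    tr <- drawGeneTree(params, histories[i])
    realized[i] <- tr@realizedTransfer
    loci[[i]] <- evolveSequences(tr, params, locusId = ids[i])
  }
  truth <- data.frame(locus_id = ids, history = histories,
                      realized_transfer = realized,
                      start = NA_real_, end = NA_real_,
                      stringsAsFactors = FALSE)
  methods::new("LocusSet", loci = loci, truth = truth, params = params)
}

#' Simulate a whole chromosome as independent haplotype blocks
#'
#' The chromosome `[0, chromLength)` is tiled by haplotype blocks whose
#' breakpoints form a Poisson process with intensity `recombIntensity`
#' (expected breakpoints per bp). Each block independently draws a history
#' (P3-to-P2 introgression with probability `pIntByDir[1]`, P2-to-P3 with
#' probability `pIntByDir[2]`, otherwise speciation), then a genealogy and
#' sequences. Adjacent blocks are genealogically independent; this preserves
#' the block-size versus window-size behavior of interest while avoiding a
#' full ancestral-recombination-graph simulation.
#'
#' @param chromLength chromosome length in bp (>= 1).
#' @param recombIntensity expected recombination breakpoints per bp (>= 0;
#'   0 gives a single block spanning the chromosome).
#' @param pIntByDir numeric(2): per-block probabilities of P3-to-P2 and
#'   P2-to-P3 introgression; their sum must be <= 1.
#' @param params a [DipSimParams-class]; its `locusLength` is ignored (block
#'   lengths come from the breakpoint process).
#' @return a list with elements `alignment` (a 4-row `DNAbin` matrix with
#'   rows P1, P2, P3, O), `truth` (data.frame: `block`, `start`, `end`
#'   0-based half-open, `history`, `realized_transfer`) and `params`.
#' @examples
#' set.seed(1)
#' ch <- simulateChromosome(2000, 1 / 500, c(0.3, 0.1),
#'                          dipSimParams())
#' ch$truth
#' @export
simulateChromosome <- function(chromLength, recombIntensity,
                               pIntByDir = c(0, 0),
                               params = dipSimParams()) {
  if (!(length(chromLength) == 1L && chromLength >= 1))
    stop("chromLength must be >= 1")
  if (!(length(recombIntensity) == 1L && recombIntensity >= 0))
    stop("recombIntensity must be >= 0")
  if (length(pIntByDir) != 2L || any(pIntByDir < 0) || sum(pIntByDir) > 1)
    stop("pIntByDir must be two non-negative fractions summing to <= 1")
  chromLength <- as.integer(chromLength)
  nBreaks <- stats::rpois(1L, chromLength * recombIntensity)
  breaks <- integer(0)
  if (nBreaks > 0 && chromLength > 1)
    breaks <- sort(unique(sample.int(chromLength - 1L,
                                     min(nBreaks, chromLength - 1L))))
  bounds <- c(0L, breaks, chromLength)
  nBlocks <- length(bounds) - 1L
  blocks <- vector("list", nBlocks)
  truth <- data.frame(block = seq_len(nBlocks),
                      start = bounds[-length(bounds)], end = bounds[-1L],
                      history = NA_character_, realized_transfer = NA,
                      stringsAsFactors = FALSE)
  for (b in seq_len(nBlocks)) {
    u <- stats::runif(1L)
    hist <- if (u < pIntByDir[1]) "INT_P3_TO_P2"
            else if (u < sum(pIntByDir)) "INT_P2_TO_P3" else "SP"
    tr <- drawGeneTree(params, hist)
    bp <- methods::new("DipSimParams", tInt = params@tInt,
                       tAlpha = params@tAlpha, tBeta = params@tBeta,
                       tGamma = params@tGamma, scaleFactor = params@scaleFactor,
                       relIntTime = params@relIntTime,
                       seqScale = params@seqScale,
                       locusLength = truth$end[b] - truth$start[b],
                       kappa = params@kappa, baseFreqs = params@baseFreqs,
                       pMove = params@pMove, theta = params@theta)
    blocks[[b]] <- evolveSequences(tr, bp, locusId = sprintf("block%04d", b))@seqs
    truth$history[b] <- hist
    truth$realized_transfer[b] <- tr@realizedTransfer
  }
  ## cbind.DNAbin may reorder rows by name; restore role order explicitly
  aln <- do.call(cbind, blocks)[.ROLES, , drop = FALSE]
  list(alignment = aln, truth = truth, params = params)
}
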