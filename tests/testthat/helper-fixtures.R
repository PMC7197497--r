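## Build a ClassifiedLoci object directly from per-class divergence means
## (constant within class unless jitter > 0). Used to test the statistics
## layer on exactly known inputs.
makeClassified <- function(nSp = 0, nInt = 0, nAlt = 0,
                           mSp = c(0.17, 0.09, 0.17),
                           mInt = c(0.03, 0.17, 0.17),
                           mAlt = c(0.10, 0.15, 0.10),
                           jitter = 0, truthFromClass = TRUE) {
  cls <- c(rep("SP", nSp), rep("INT", nInt), rep("ALT", nAlt))
  n <- length(cls)
  K <- matrix(NA_real_, n, 3)
  if (nSp > 0) K[cls == "SP", ] <- matrix(mSp, nSp, 3, byrow = TRUE)
  if (nInt > 0) K[cls == "INT", ] <- matrix(mInt, nInt, 3, byrow = TRUE)
  if (nAlt > 0) K[cls == "ALT", ] <- matrix(mAlt, nAlt, 3, byrow = TRUE)
  if (jitter > 0) K <- K + matrix(runif(3 * n, -jitter, jitter), n, 3)
  tab <- data.frame(
    locus_id = sprintf("locus%05d", seq_len(n)),
    class = cls,
    K23 = K[, 1], K12 = K[, 2], K13 = K[, 3],
    n23 = 1000L, n12 = 1000L, n13 = 1000L,
    truth = if (truthFromClass) ifelse(cls == "SP", "SP", "INT_P3_TO_P2")
            else NA_character_,
    stringsAsFactors = FALSE)
  new("ClassifiedLoci", loci = tab, model = "K80", omniscient = FALSE,
      dropped = character(0))
}

## Replace the K columns of a ClassifiedLoci (e.g. to swap K12 and K13).
swapK1213 <- function(classified) {
  tab <- classified@loci
  tmp <- tab$K12
  tab$K12 <- tab$K13
  tab$K13 <- tmp
  new("ClassifiedLoci", loci = tab, model = classified@model,
      omniscient = classified@omniscient, dropped = classified@dropped)
}

## A four-tip GeneTree with prescribed splits and node depths (coalescent
## units): sisters coalesce at tPair, joined by the third tip at tMid, and
## the outgroup-most tip at tRoot.
makeGeneTree <- function(sisters = c("P1", "P2"), tPair = 1, tMid = 2,
                         tRoot = 3, truth = "SP") {
  others <- setdiff(c("P1", "P2", "P3", "O"), sisters)
  txt <- sprintf("((%s:%g,%s:%g):%g,%s:%g):%g,%s:%g",
                 sisters[1], tPair, sisters[2], tPair, tMid - tPair,
                 others[1], tMid, tRoot - tMid, others[2], tRoot)
  phy <- ape::read.tree(text = sprintf("(%s);", txt))
  new("GeneTree", phy = phy, truth = truth, realizedTransfer = truth != "SP")
}

## Canonical form of a quartet split: the sister pair containing P1.
canonSplit <- function(pair) {
  roles <- c("P1", "P2", "P3", "O")
  if ("P1" %in% pair) sort(pair) else sort(setdiff(roles, pair))
}

## Random additive four-taxon distance matrix with a known quartet split.
randomAdditiveMatrix <- function() {
  roles <- c("P1", "P2", "P3", "O")
  sisters <- sample(list(c(1, 2), c(2, 3), c(1, 3)), 1)[[1]]
  others <- setdiff(1:4, sisters)
  ext <- runif(4, 0.05, 0.5)
  int <- runif(1, 0.05, 0.3)
  d <- matrix(0, 4, 4, dimnames = list(roles, roles))
  pairSum <- function(i, j) {
    ext[i] + ext[j] +
      (if ((i %in% sisters) != (j %in% sisters)) int else 0)
  }
  for (i in 1:3) for (j in (i + 1):4) d[i, j] <- d[j, i] <- pairSum(i, j)
  list(d = d, sisters = canonSplit(roles[sisters]))
}

## Four-point-condition oracle: the quartet split is the pairing with the
## smallest sum of within-pair distances.
fourPointSplit <- function(d) {
  roles <- rownames(d)
  sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  pairing <- list(c(1, 2), c(1, 3), c(1, 4))[[which.min(sums)]]
  canonSplit(roles[pairing])
}

## Write a small FASTA file by hand (optionally line-wrapped).
writeFastaText <- function(seqs, path, wrap = NULL) {
  lines <- unlist(lapply(names(seqs), function(n) {
    s <- seqs[[n]]
    body <- if (is.null(wrap)) s
            else substring(s, seq(1, nchar(s), wrap),
                           pmin(seq(1, nchar(s), wrap) + wrap - 1, nchar(s)))
    c(paste0(">", n), body)
  }))
  writeLines(lines, path)
}

alnToStrings <- function(m) {
  apply(toupper(as.character(m)), 1, paste, collapse = "")
}
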