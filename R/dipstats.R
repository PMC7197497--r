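## Core statistic engine shared by point estimates and bootstrap replicates.
## Input: integer class codes (1=SP, 2=INT, 3=ALT, 4=UNRESOLVED) and the K
## columns; returns the full statistic vector with NA where not computable.
.dipCore <- function(clsIdx, K) {
  cnt <- tabulate(clsIdx, 4L)
  sums <- rowsum(K, clsIdx)
  lev <- as.integer(rownames(sums))
  m <- matrix(NA_real_, 4L, 3L)
  m[lev, ] <- sums / cnt[lev]
  dk23 <- dk12 <- dk13 <- ddk <- ddkAlt <- dddk <- NA_real_
  if (cnt[1L] > 0L && cnt[2L] > 0L) {
    dk23 <- m[1L, 1L] - m[2L, 1L]
    dk12 <- m[2L, 2L] - m[1L, 2L]
    dk13 <- m[1L, 3L] - m[2L, 3L]
    ddk <- dk12 - dk13
  }
  if (cnt[1L] > 0L && cnt[3L] > 0L)
    ddkAlt <- (m[3L, 2L] - m[1L, 2L]) - (m[1L, 1L] - m[3L, 1L])
  if (!is.na(ddk) && !is.na(ddkAlt) && cnt[3L] >= 1L && cnt[2L] != cnt[3L])
    dddk <- (ddk * cnt[2L] - ddkAlt * cnt[3L]) / (cnt[2L] - cnt[3L])
  c(dk23 = dk23, dk12 = dk12, dk13 = dk13, ddk = ddk, ddkAlt = ddkAlt,
    dddk = dddk, nInt = cnt[2L], nAlt = cnt[3L], nSp = cnt[1L])
}

.clsData <- function(classified) {
  stopifnot(is(classified, "ClassifiedLoci"))
  tab <- classified@loci
  list(clsIdx = match(tab$class, .TOPOLOGIES),
       K = cbind(tab$K23, tab$K12, tab$K13))
}

#' The delta-K profile: divergence shifts between topology classes
#'
#' Point estimates of the three divergence-shift statistics comparing mean
#' pairwise divergences of species-topology (SP) loci and
#' introgression-topology (INT) loci:
#' `dK23 = mean(K23 | SP) - mean(K23 | INT)`,
#' `dK12 = mean(K12 | INT) - mean(K12 | SP)`,
#' `dK13 = mean(K13 | SP) - mean(K13 | INT)`.
#' The sign alternation is deliberate: each statistic is positive when the
#' kind of introgression it detects is present (any introgression depresses
#' K23 among INT loci; P3-to-P2 transfer inflates K12; P2-to-P3 transfer
#' depresses K13). ALT and UNRESOLVED loci are excluded.
#'
#' @param classified a [ClassifiedLoci-class] object.
#' @return named numeric: `dk23`, `dk12`, `dk13`.
#' @export
deltaKProfile <- function(classified) {
  d <- .clsData(classified)
  s <- .dipCore(d$clsIdx, d$K)
  if (is.na(s[["dk23"]]))
    stop("delta-K profile not computable: empty SP or INT class")
  s[c("dk23", "dk12", "dk13")]
}

#' The ALT-substituted asymmetry statistic
#'
#' Recomputes the asymmetry statistic with ALT-topology loci (the
#' ILS-only quartet, P1P3) in place of the INT loci:
#' `ddkAlt = [mean(K12 | ALT) - mean(K12 | SP)] - [mean(K23 | SP) - mean(K23 | ALT)]`.
#' K23 stands in for K13 because in the ALT quartet P1 and P3 are sisters, so
#' K23 plays the role that K13 plays for the INT quartet. Under ILS alone,
#' both conflicting quartets are equally likely, making `ddkAlt` an estimate
#' of the spurious asymmetry signal that misclassified ILS loci contribute.
#'
#' @param classified a [ClassifiedLoci-class] object.
#' @return numeric scalar.
#' @export
deltaDeltaKAlt <- function(classified) {
  d <- .clsData(classified)
  s <- .dipCore(d$clsIdx, d$K)
  if (s[["nAlt"]] < 1L)
    stop("ddK_ALT not computable: no ALT loci")
  if (is.na(s[["ddkAlt"]]))
    stop("ddK_ALT not computable: empty SP class")
  unname(s[["ddkAlt"]])
}

#' Bootstrap replicates of the DIP statistics
#'
#' Resamples the classified loci (all classes) with replacement to the
#' original locus count, and recomputes class means, class counts and all
#' statistics for each replicate. Replicates where a statistic is not
#' computable (e.g. an empty SP or INT class, no ALT loci, or equal INT and
#' ALT counts for the corrected statistic) carry `NA` in that column.
#'
#' Resampling operates on the per-locus `(class, K23, K12, K13)` records:
#' classification is deterministic per locus, so this is exactly equivalent
#' to resampling the locus alignments themselves.
#'
#' @param classified a [ClassifiedLoci-class] object.
#' @param nBoot number of replicates (>= 1).
#' @return data.frame with `nBoot` rows and columns `dk23`, `dk12`, `dk13`,
#'   `ddk`, `ddkAlt`, `dddk`, `nInt`, `nAlt`, `nSp`.
#' @export
bootstrapStatistics <- function(classified, nBoot = 1000) {
  if (!(length(nBoot) == 1L && nBoot >= 1)) stop("nBoot must be >= 1")
  nBoot <- as.integer(nBoot)
  d <- .clsData(classified)
  n <- length(d$clsIdx)
  out <- matrix(NA_real_, nBoot, 9L)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    out[b, ] <- .dipCore(d$clsIdx[idx], d$K[idx, , drop = FALSE])
  }
  colnames(out) <- c("dk23", "dk12", "dk13", "ddk", "ddkAlt", "dddk",
                     "nInt", "nAlt", "nSp")
  as.data.frame(out)
}

## one- and two-sided bootstrap p-values with resolution clamping: a p-value
## is never reported below the bootstrap resolution (1/n one-sided, 2/n
## two-sided), so "no replicate crossed zero" reads as p = floor, i.e.
## "p < floor" at the achievable resolution.
.pOneSided <- function(reps) {
  n <- length(reps)
  max(mean(reps <= 0), 1 / n)
}

.pTwoSided <- function(reps) {
  n <- length(reps)
  ## ties at zero count toward both sides, so a point mass at zero reads
  ## as p = 1 rather than spuriously significant
  minority <- min(mean(reps <= 0), mean(reps >= 0))
  c(p = min(1, max(2 * minority, 2 / n)), pFloor = 2 / n)
}

#' First DIP layer: the delta-K profile with significance and a direction call
#'
#' Computes the three divergence-shift statistics, their one-sided bootstrap
#' p-values (proportion of replicates with the statistic <= 0), and the
#' categorical directionality call. With `sig` meaning `p < alpha`, the call
#' is `P3_TO_P2` for the pattern (sig, sig, nonsig) over (dK23, dK12, dK13),
#' `P2_TO_P3` for (sig, nonsig, sig), `BIDIRECTIONAL` for (sig, sig, sig),
#' and `INCONCLUSIVE` otherwise. "Equals zero" is operationalized as failure
#' to reject at `alpha`.
#'
#' @param classified a [ClassifiedLoci-class] object.
#' @param nBoot bootstrap replicates (default 1000).
#' @param alpha significance level for the call (default 0.05).
#' @param reps optional precomputed [bootstrapStatistics()] table, so several
#'   DIP layers can share one replicate set; `nBoot` is then taken from it.
#' @return a [DeltaKProfile-class] object.
#' @examples
#' set.seed(1)
#' gs <- simulateGenome(60, 0.5, 1, dipSimParams(locusLength = 500))
#' oneDip(classifyLoci(gs), nBoot = 200)
#' @export
oneDip <- function(classified, nBoot = 1000, alpha = 0.05, reps = NULL) {
  point <- deltaKProfile(classified)
  if (is.null(reps)) reps <- bootstrapStatistics(classified, nBoot)
  nBoot <- nrow(reps)
  ok <- !is.na(reps$dk23)
  nDropped <- sum(!ok)
  p23 <- .pOneSided(reps$dk23[ok])
  p12 <- .pOneSided(reps$dk12[ok])
  p13 <- .pOneSided(reps$dk13[ok])
  sig <- c(p23, p12, p13) < alpha
  call <- if (sig[1] && sig[2] && sig[3]) "BIDIRECTIONAL"
          else if (sig[1] && sig[2]) "P3_TO_P2"
          else if (sig[1] && sig[3]) "P2_TO_P3"
          else "INCONCLUSIVE"
  methods::new("DeltaKProfile",
    dk23 = unname(point["dk23"]), dk12 = unname(point["dk12"]),
    dk13 = unname(point["dk13"]), p23 = p23, p12 = p12, p13 = p13,
    call = call, nBoot = as.integer(nBoot), nDropped = as.integer(nDropped),
    unreliable = nDropped > 0.1 * nBoot, alpha = alpha)
}

#' Second DIP layer: the asymmetry statistic ddK
#'
#' `ddK = dK12 - dK13` contrasts the two direction-specific divergence
#' shifts: positive values indicate that P3-to-P2 introgression predominates,
#' negative values the reverse, zero symmetric exchange. Significance is a
#' two-sided bootstrap test: twice the proportion of replicates on the
#' minority side of zero, capped at 1 and clamped below at the resolution
#' bound `2/nBoot`.
#'
#' @param classified a [ClassifiedLoci-class] object.
#' @param nBoot bootstrap replicates (default 1000).
#' @param reps optional precomputed [bootstrapStatistics()] table.
#' @return a [DoubleDipResult-class] object.
#' @export
doubleDip <- function(classified, nBoot = 1000, reps = NULL) {
  point <- deltaKProfile(classified)
  if (is.null(reps)) reps <- bootstrapStatistics(classified, nBoot)
  nBoot <- nrow(reps)
  ok <- !is.na(reps$ddk)
  nDropped <- sum(!ok)
  pv <- .pTwoSided(reps$ddk[ok])
  methods::new("DoubleDipResult",
    ddk = unname(point["dk12"] - point["dk13"]),
    p = unname(pv["p"]), pFloor = unname(pv["pFloor"]),
    bootMean = mean(reps$ddk[ok]),
    bootQuantiles = stats::quantile(reps$ddk[ok],
                                    c(0.025, 0.25, 0.5, 0.75, 0.975)),
    nBoot = as.integer(nBoot), nDropped = as.integer(nDropped),
    unreliable = nDropped > 0.1 * nBoot)
}

#' Third DIP layer: the ILS-corrected asymmetry statistic dddK
#'
#' Corrects `ddK` for the spurious asymmetry contributed by ILS loci
#' misclassified as introgressed, using the ALT-topology loci as an ILS
#' proxy: `dddK = (ddK * nInt - ddkAlt * nAlt) / (nInt - nAlt)`. This treats
#' the observed `ddK` as a count-weighted average of a clean introgression
#' signal and an ILS signal estimated by `ddkAlt`/`nAlt`, and solves for the
#' clean part. Requires at least one ALT locus (some ILS) and
#' `nInt != nAlt`; otherwise the layer reports not-computable while still
#' carrying `ddK`. Counts are recomputed per bootstrap replicate.
#'
#' @param classified a [ClassifiedLoci-class] object.
#' @param nBoot bootstrap replicates (default 1000).
#' @param reps optional precomputed [bootstrapStatistics()] table.
#' @return a [TripleDipResult-class] object.
#' @export
tripleDip <- function(classified, nBoot = 1000, reps = NULL) {
  d <- .clsData(classified)
  s <- .dipCore(d$clsIdx, d$K)
  if (is.na(s[["ddk"]]))
    stop("ddK not computable: empty SP or INT class")
  nInt <- as.integer(s[["nInt"]])
  nAlt <- as.integer(s[["nAlt"]])
  reason <- if (nAlt == 0L) "no ALT loci"
            else if (nInt == nAlt) "equal INT and ALT counts"
            else "ok"
  if (reason != "ok")
    return(methods::new("TripleDipResult",
      ddk = unname(s[["ddk"]]), ddkAlt = NA_real_, nInt = nInt, nAlt = nAlt,
      dddk = NA_real_, p = NA_real_, pFloor = NA_real_, computable = FALSE,
      reason = reason, nBoot = 0L, nDropped = 0L, unreliable = FALSE))
  if (is.null(reps)) reps <- bootstrapStatistics(classified, nBoot)
  nBoot <- nrow(reps)
  ok <- !is.na(reps$dddk)
  nDropped <- sum(!ok)
  pv <- .pTwoSided(reps$dddk[ok])
  methods::new("TripleDipResult",
    ddk = unname(s[["ddk"]]), ddkAlt = unname(s[["ddkAlt"]]),
    nInt = nInt, nAlt = nAlt, dddk = unname(s[["dddk"]]),
    p = unname(pv["p"]), pFloor = unname(pv["pFloor"]),
    computable = TRUE, reason = "ok",
    nBoot = as.integer(nBoot), nDropped = as.integer(nDropped),
    unreliable = nDropped > 0.1 * nBoot)
}
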