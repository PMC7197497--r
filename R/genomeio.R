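#' Read a multiple sequence alignment from FASTA
#'
#' Parses a FASTA file, normalizes the sequences (uppercased, `U` converted
#' to `T`; IUPAC ambiguity codes and gaps are preserved and handled by
#' pairwise deletion downstream) and checks that records form an alignment:
#' non-empty, uniquely named, equal lengths.
#'
#' @param path path to a FASTA file (wrapped or single-line).
#' @return a `DNAbin` matrix with one row per record, named from the first
#'   whitespace-delimited token of each header.
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  nms <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(nms))) stop("FASTA record with empty name")
  if (anyDuplicated(nms)) stop("duplicate sequence names in ", path)
  w <- Biostrings::width(x)
  if (any(w == 0L)) stop("zero-length sequence in ", path)
  if (length(unique(w)) != 1L)
    stop("sequences have unequal lengths; not an alignment")
  chars <- strsplit(chartr("Uu", "Tt", toupper(as.character(x))), "")
  m <- ape::as.DNAbin(do.call(rbind, chars))
  rownames(m) <- nms
  m
}

#' Write a DNAbin alignment to FASTA
#'
#' @param aln a `DNAbin` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  ape::write.FASTA(aln, path)
  invisible(path)
}

#' Select and order the four analysis roles from an alignment
#'
#' Applies a taxon-sampling scheme: a role map naming which sample plays
#' P1, P2, P3 and O. The matching rows are selected, reordered P1, P2, P3, O
#' and renamed to the roles; extra samples are dropped. The original sample
#' names are kept in the `"samples"` attribute. Assigning roles is
#' idempotent (a role-named alignment accepts the identity map).
#'
#' @param aln a `DNAbin` matrix with named rows.
#' @param roleMap named character vector with names `P1`, `P2`, `P3`, `O`
#'   and values the sample names in `aln`, e.g.
#'   `c(P1 = "San", P2 = "French", P3 = "Neanderthal", O = "Chimp")`.
#' @return a 4-row `DNAbin` matrix with rows `P1`, `P2`, `P3`, `O`.
#' @export
assignRoles <- function(aln, roleMap) {
  if (!is.matrix(aln)) stop("aln must be a DNAbin matrix")
  if (is.null(names(roleMap)) || !setequal(names(roleMap), .ROLES) ||
      length(roleMap) != 4L)
    stop("roleMap must assign each of P1, P2, P3, O exactly once")
  if (anyDuplicated(roleMap))
    stop("the same sample is assigned to two roles")
  missing <- setdiff(roleMap, rownames(aln))
  if (length(missing))
    stop("sample(s) not present in the alignment: ",
         paste(missing, collapse = ", "))
  out <- aln[roleMap[.ROLES], , drop = FALSE]
  rownames(out) <- .ROLES
  attr(out, "samples") <- roleMap[.ROLES]
  out
}

#' Partition a role-ordered chromosome alignment into fixed-size windows
#'
#' Cuts the alignment into non-overlapping adjacent windows of `windowSize`
#' bp with 0-based half-open coordinates `[i*w, (i+1)*w)`. A trailing
#' remainder shorter than one window is dropped, keeping per-locus estimator
#' variance homogeneous. An alignment shorter than one window yields an
#' empty list with a warning.
#'
#' @param aln a 4-row `DNAbin` matrix with rows `P1`, `P2`, `P3`, `O`
#'   (see [assignRoles()]).
#' @param windowSize window length in bp (default 5000).
#' @param contig name recorded as the source contig of each window.
#' @return list of [LocusAlignment-class] objects carrying coordinates.
#' @export
partitionWindows <- function(aln, windowSize = 5000, contig = "chr") {
  if (!is.matrix(aln) || !setequal(rownames(aln), .ROLES))
    stop("aln must be a DNAbin matrix with rows P1, P2, P3, O (see assignRoles)")
  if (!(length(windowSize) == 1L && windowSize >= 1))
    stop("windowSize must be >= 1")
  windowSize <- as.integer(windowSize)
  L <- ncol(aln)
  nWin <- L %/% windowSize
  if (nWin == 0L) {
    warning(sprintf("alignment (%d bp) shorter than one window (%d bp)",
                    L, windowSize))
    return(list())
  }
  aln <- aln[.ROLES, , drop = FALSE]
  lapply(seq_len(nWin), function(i) {
    s <- (i - 1L) * windowSize
    methods::new("LocusAlignment",
      locusId = sprintf("%s_w%06d", contig, i),
      seqs = aln[, (s + 1L):(s + windowSize), drop = FALSE],
      truth = NA_character_, contig = contig,
      start = as.numeric(s), end = as.numeric(s + windowSize))
  })
}

#' Attach simulated truth labels to windowed loci
#'
#' For windows cut from a simulated chromosome, assigns each window the
#' history of the haplotype block that covers the majority of it (ties to
#' the earlier block). Windows falling entirely within one block get that
#' block's label exactly.
#'
#' @param loci list of [LocusAlignment-class] windows (with coordinates).
#' @param truth block truth table from [simulateChromosome()].
#' @return the list with `truth` slots filled.
#' @export
labelWindowsFromBlocks <- function(loci, truth) {
  lapply(loci, function(l) {
    ov <- pmin(truth$end, l@end) - pmax(truth$start, l@start)
    l@truth <- truth$history[which.max(ov)]
    l
  })
}

.fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

#' Write per-locus and summary result tables
#'
#' Writes `<prefix>_loci.tsv` (one row per classified locus) and
#' `<prefix>_summary.tsv` (one row with statistics, p-values, counts and the
#' directionality call, or explicit `NA`/not-computable markers) with a
#' deterministic column order, floats at 6 significant digits, and the run
#' configuration echoed in `#` header comments.
#'
#' @param classified a [ClassifiedLoci-class] object.
#' @param profile optional [DeltaKProfile-class].
#' @param ddip optional [DoubleDipResult-class].
#' @param tdip optional [TripleDipResult-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param config named list echoed into the headers (seed, model, ...).
#' @return character vector of the two paths, invisibly.
#' @export
writeResults <- function(classified, profile = NULL, ddip = NULL, tdip = NULL,
                         dir = ".", prefix = "dip", config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("# dipr results (%s)", format(Sys.time(), "%Y-%m-%d")),
           if (length(config))
             sprintf("# %s", paste(names(config), unlist(lapply(config, format)),
                                   sep = "=", collapse = " ")))
  lociPath <- file.path(dir, paste0(prefix, "_loci.tsv"))
  tab <- classified@loci
  tab$K23 <- .fmt(tab$K23); tab$K12 <- .fmt(tab$K12); tab$K13 <- .fmt(tab$K13)
  con <- file(lociPath, "w")
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  counts <- classCounts(classified)
  row <- c(list(n_loci = nrow(classified@loci),
                n_sp = counts[["SP"]], n_int = counts[["INT"]],
                n_alt = counts[["ALT"]], n_unresolved = counts[["UNRESOLVED"]],
                n_dropped = length(classified@dropped),
                model = classified@model,
                omniscient = classified@omniscient),
           if (!is.null(profile)) list(
             dk23 = .fmt(profile@dk23), dk12 = .fmt(profile@dk12),
             dk13 = .fmt(profile@dk13), p23 = .fmt(profile@p23),
             p12 = .fmt(profile@p12), p13 = .fmt(profile@p13),
             call = profile@call, alpha = profile@alpha,
             n_boot = profile@nBoot),
           if (!is.null(ddip)) list(
             ddk = .fmt(ddip@ddk), p_ddk = .fmt(ddip@p)),
           if (!is.null(tdip)) list(
             ddk_alt = .fmt(tdip@ddkAlt), dddk = .fmt(tdip@dddk),
             p_dddk = .fmt(tdip@p),
             dddk_status = if (tdip@computable) "ok"
                           else paste("not computable:", tdip@reason)))
  sumPath <- file.path(dir, paste0(prefix, "_summary.tsv"))
  con <- file(sumPath, "w")
  writeLines(hdr, con)
  utils::write.table(as.data.frame(row, stringsAsFactors = FALSE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(lociPath, sumPath))
}

#' Write a simulated locus set to disk
#'
#' One FASTA per locus (sequence ids are the roles), a truth table TSV and a
#' JSON sidecar echoing the simulation parameters and seed.
#'
#' @param locusSet a [LocusSet-class].
#' @param dir output directory.
#' @param seed the seed used, echoed into the sidecar (or `NA`).
#' @return `dir`, invisibly.
#' @export
writeLocusSet <- function(locusSet, dir, seed = NA) {
  stopifnot(is(locusSet, "LocusSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in locusSet@loci)
    ape::write.FASTA(l@seqs, file.path(dir, paste0(l@locusId, ".fasta")))
  utils::write.table(locusSet@truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p <- locusSet@params
  cfg <- list(seed = seed, n_loci = length(locusSet@loci))
  if (is(p, "DipSimParams"))
    cfg <- c(cfg, list(tInt = p@tInt, tAlpha = p@tAlpha, tBeta = p@tBeta,
                       tGamma = p@tGamma, scaleFactor = p@scaleFactor,
                       relIntTime = p@relIntTime, seqScale = p@seqScale,
                       locusLength = p@locusLength, kappa = p@kappa,
                       baseFreqs = p@baseFreqs, pMove = p@pMove,
                       theta = p@theta))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a directory of per-locus FASTA alignments
#'
#' Loads every `.fasta`/`.fa` file in a directory as one locus; sequence
#' names must either be the four roles already or be resolvable through
#' `roleMap`. If a `truth.tsv` written by [writeLocusSet()] is present (or
#' `truthFile` is given), truth labels are attached by locus id.
#'
#' @param dir directory of per-locus FASTA files.
#' @param roleMap optional role map (see [assignRoles()]).
#' @param truthFile optional path to a truth TSV (`locus_id`, `history`).
#' @return a [LocusSet-class].
#' @export
readLocusDir <- function(dir, roleMap = NULL, truthFile = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (!length(files)) stop("no FASTA files in ", dir)
  if (is.null(truthFile)) {
    cand <- file.path(dir, "truth.tsv")
    if (file.exists(cand)) truthFile <- cand
  }
  truth <- NULL
  if (!is.null(truthFile)) {
    truth <- utils::read.delim(truthFile, stringsAsFactors = FALSE)
    if (!all(c("locus_id", "history") %in% names(truth)))
      stop("truth table must have columns locus_id and history")
  }
  loci <- lapply(files, function(f) {
    id <- sub("\\.(fa|fasta)$", "", basename(f))
    m <- readAlignment(f)
    m <- if (is.null(roleMap)) {
      if (!setequal(rownames(m), .ROLES))
        stop("sequences in ", f, " are not role-named; supply roleMap")
      m[.ROLES, , drop = FALSE]
    } else assignRoles(m, roleMap)
    h <- NA_character_
    if (!is.null(truth)) {
      hit <- match(id, truth$locus_id)
      if (!is.na(hit)) h <- truth$history[hit]
    }
    methods::new("LocusAlignment", locusId = id, seqs = m, truth = h,
                 contig = NA_character_, start = NA_real_, end = NA_real_)
  })
  tt <- data.frame(
    locus_id = vapply(loci, function(l) l@locusId, character(1)),
    history = vapply(loci, function(l) l@truth, character(1)),
    realized_transfer = NA, start = NA_real_, end = NA_real_,
    stringsAsFactors = FALSE)
  methods::new("LocusSet", loci = loci, truth = tt, params = NULL)
}
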