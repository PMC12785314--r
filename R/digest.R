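#' In-silico restriction digestion
#'
#' A small digestion engine for verifying the assay's design logic on
#' amplicon sequences: the FV Leiden variant abolishes an MnlI site, the F2
#' G20210A variant (via a mutagenic primer) creates a HindIII site, and each
#' digestion-control amplicon carries a mandatory site. Only top-strand cut
#' coordinates are reported, because capillary electrophoresis sees the
#' denatured 5'-labelled single strand: the distance from the labelled 5'
#' end to the first cut is the fragment size that matters.
#'
#' @name digest
NULL

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.iupac_regex <- function(motif) {
  chars <- strsplit(motif, "")[[1]]
  paste(vapply(chars, function(ch) {
    bases <- .IUPAC[[ch]]
    if (is.null(bases)) stop("invalid IUPAC code in recognition motif: ", ch,
                             call. = FALSE)
    if (length(bases) == 1) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, character(1)), collapse = "")
}

.revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", seq),
                     "")[[1]]), collapse = "")
}

.check_seq <- function(seq) {
  if (length(seq) != 1 || !is.character(seq))
    stop("sequence must be a single character string", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop("sequence contains characters outside A/C/G/T (ambiguity codes ",
         "including N are rejected)", call. = FALSE)
  invisible(seq)
}

#' Define a restriction enzyme
#'
#' Cut offsets are 0-based inter-base coordinates relative to the start of a
#' forward-strand occurrence of the recognition motif, in top-strand
#' coordinates. `cut_offset_top` is where the enzyme cuts the strand bearing
#' the motif; `cut_offset_bottom` where it cuts the complementary strand.
#' For an occurrence of the motif on the bottom strand the roles swap, so the
#' reported top-strand cut lands at `match_start + motif_length -
#' cut_offset_bottom`.
#'
#' @param name Enzyme name.
#' @param recognition IUPAC DNA recognition motif.
#' @param cut_offset_top,cut_offset_bottom Inter-base cut offsets from the
#'   motif start (may exceed the motif length for type IIS enzymes).
#' @param bidirectional Scan both strands (default `TRUE`; palindromic
#'   motifs yield the same cut either way and duplicates are collapsed).
#' @return A `restriction_enzyme` object.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset_top,
                               cut_offset_bottom, bidirectional = TRUE) {
  if (!nzchar(recognition)) stop("empty recognition motif", call. = FALSE)
  .iupac_regex(recognition)  # validates IUPAC characters
  structure(list(name = name, recognition = toupper(recognition),
                 cut_offset_top = as.integer(cut_offset_top),
                 cut_offset_bottom = as.integer(cut_offset_bottom),
                 bidirectional = isTRUE(bidirectional)),
            class = "restriction_enzyme")
}

#' MnlI: type IIS, recognition CCTC, top-strand cut 7 nt downstream of the
#' motif (CCTC N7), bottom-strand cut at N6.
#' @return A `restriction_enzyme`.
#' @export
enzyme_mnli <- function()
  restriction_enzyme("MnlI", "CCTC", cut_offset_top = 4L + 7L,
                     cut_offset_bottom = 4L + 6L)

#' HindIII: palindromic A^AGCTT.
#' @return A `restriction_enzyme`.
#' @export
enzyme_hindiii <- function()
  restriction_enzyme("HindIII", "AAGCTT", cut_offset_top = 1L,
                     cut_offset_bottom = 5L)

#' Resolve enzymes by name
#' @param names Character vector, e.g. `c("MnlI", "HindIII")`.
#' @return List of `restriction_enzyme` objects.
#' @export
enzymes_by_name <- function(names) {
  known <- list(mnli = enzyme_mnli, hindiii = enzyme_hindiii)
  lapply(names, function(n) {
    f <- known[[tolower(n)]]
    if (is.null(f)) stop("unknown enzyme: ", n, call. = FALSE)
    f()
  })
}

# all (overlapping) 0-based match starts of an IUPAC motif
.match_starts <- function(seq, motif) {
  rx <- paste0("(?=", .iupac_regex(motif), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Find the top-strand cut positions of an enzyme in a sequence
#'
#' Scans both strands (for bidirectional enzymes), reports every cut as a
#' 0-based inter-base coordinate on the top strand, and silently drops cuts
#' whose offset falls outside the sequence (sites too close to an end).
#' Overlapping motif occurrences are all considered.
#'
#' @param seq Uppercase A/C/G/T string.
#' @param enzyme A `restriction_enzyme`.
#' @return Sorted unique integer vector of cut positions in `0 < pos < nchar`.
#' @export
find_sites <- function(seq, enzyme) {
  .check_seq(seq)
  n <- nchar(seq)
  m <- nchar(enzyme$recognition)
  cuts <- .match_starts(seq, enzyme$recognition) + enzyme$cut_offset_top
  if (enzyme$bidirectional) {
    rc <- .revcomp(enzyme$recognition)
    rev_cuts <- .match_starts(seq, rc) + m - enzyme$cut_offset_bottom
    cuts <- c(cuts, rev_cuts)
  }
  sort(unique(cuts[cuts > 0 & cuts < n]))
}

#' Digest a sequence with one or more enzymes
#'
#' @param seq Uppercase A/C/G/T string.
#' @param enzymes List of `restriction_enzyme` objects (or a single one).
#' @return A `digest_result`: `cut_positions` (ascending, 0-based inter-base)
#'   and `fragments`, a data frame of half-open `[start, end)` intervals with
#'   lengths that tile the sequence exactly.
#' @export
digest_sequence <- function(seq, enzymes) {
  .check_seq(seq)
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) find_sites(seq, e)))))
  bounds <- c(0L, cuts, nchar(seq))
  fragments <- data.frame(start = bounds[-length(bounds)],
                          end = bounds[-1])
  fragments$length <- fragments$end - fragments$start
  structure(list(sequence_length = nchar(seq),
                 cut_positions = as.integer(cuts), fragments = fragments),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("Digest of %d nt: %d cut(s), %d fragment(s)\n",
              x$sequence_length, length(x$cut_positions), nrow(x$fragments)))
  print(x$fragments, row.names = FALSE)
  invisible(x)
}

#' Read amplicon sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_amplicons <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}
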