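# CAPS (cleaved amplified polymorphic sequence) markers: IUPAC-aware
# restriction-site scanning, in-silico digestion, assay design across an
# enzyme table, and genotype calling from observed band patterns.
#
# Coordinates: cut positions are 0-based between-base indices, so a cut at
# position k splits a sequence into a k-bp and an (L - k)-bp fragment.

#' Restriction enzyme descriptor
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence, IUPAC codes allowed, length >= 4.
#' @param cut_offset Bases after the recognition start at which the top
#'   strand is cut (`SspI` = AAT^ATT has offset 3).
#' @return An object of class `enzyme`.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4) stop_bsr("recognition length must be >= 4")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", recognition))
    stop_bsr("recognition contains non-IUPAC characters")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    stop_bsr("cut_offset outside recognition sequence")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset), class = "enzyme")
}

#' Load a restriction-enzyme table
#'
#' @param path TSV with columns `name`, `recognition`, `cut_offset`;
#'   defaults to the bundled table (SspI, EcoRI, HindIII, EcoRV, DraI,
#'   BamHI, AluI).
#' @return Named list of [enzyme()] objects.
#' @export
load_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                            package = "bsrmap")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition", "cut_offset") %in% names(df)))
  out <- Map(enzyme, df$name, df$recognition, df$cut_offset)
  stats::setNames(out, df$name)
}

check_seq <- function(seq) {
  seq <- toupper(seq)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0)
    stop_bsr("non-nucleotide character '%s' at position %d",
             substr(seq, bad, bad), bad)
  seq
}

#' Scan a sequence for restriction cut sites
#'
#' Matches the recognition sequence (IUPAC-aware) on the top strand and, for
#' non-palindromic recognitions, its reverse complement too; all overlapping
#' matches are reported. Cuts at position 0 or at the sequence end do not
#' fragment the molecule and are dropped.
#'
#' @param seq Nucleotide sequence (A/C/G/T, case-insensitive).
#' @param enz An [enzyme()].
#' @return Sorted integer vector of 0-based between-base cut positions.
#' @export
scan_sites <- function(seq, enz) {
  stopifnot(inherits(enz, "enzyme"))
  seq <- check_seq(seq)
  subject <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(enz$recognition)
  rc <- Biostrings::reverseComplement(pat)
  fwd <- BiocGenerics::start(Biostrings::matchPattern(pat, subject, fixed = FALSE))
  cuts <- fwd - 1L + enz$cut_offset
  if (as.character(rc) != as.character(pat)) {
    rev_hits <- Biostrings::matchPattern(rc, subject, fixed = FALSE)
    # bottom-strand recognition: cut measured from the match end
    cuts <- c(cuts, BiocGenerics::end(rev_hits) - enz$cut_offset)
  }
  cuts <- sort(unique(cuts))
  cuts[cuts > 0 & cuts < nchar(seq)]
}

#' Digest a linear sequence with one enzyme
#'
#' @inheritParams scan_sites
#' @return List of class `digest_result` with `cut_positions` and sorted
#'   `fragment_lengths`; lengths always sum to the input length.
#' @export
digest <- function(seq, enz) {
  seq <- check_seq(seq)
  cuts <- scan_sites(seq, enz)
  frag <- diff(c(0L, cuts, nchar(seq)))
  structure(list(cut_positions = cuts,
                 fragment_lengths = sort(as.integer(frag))),
            class = "digest_result")
}

#' Reassemble the undigested amplicon length from band sizes
#'
#' @param fragments Positive fragment lengths.
#' @return Their sum: the length of the uncut amplicon.
#' @export
undigested_length <- function(fragments) {
  if (!length(fragments)) stop_bsr("empty fragment list")
  if (any(fragments <= 0)) stop_bsr("fragment lengths must be positive")
  as.integer(sum(fragments))
}

#' Design CAPS assays distinguishing two amplicon alleles
#'
#' Returns one assay per enzyme whose digestion band multiset differs
#' between the two alleles. Allele A is the dominant-parent (D) allele,
#' allele B the recessive-parent (R) allele; heterozygote bands are the
#' union of the two homozygote patterns (deduplicated by length). Assays
#' are ranked by the smallest pairwise band-length difference between the
#' two alleles' patterns (larger = easier to resolve on a gel).
#'
#' @param amplicon_A,amplicon_B Equal-length allele sequences differing at
#'   at least one position.
#' @param enzymes List of [enzyme()] objects (e.g. [load_enzymes()]).
#' @return List of `caps_assay` objects, best-resolvable first.
#' @export
design_caps <- function(amplicon_A, amplicon_B, enzymes) {
  amplicon_A <- check_seq(amplicon_A); amplicon_B <- check_seq(amplicon_B)
  if (nchar(amplicon_A) != nchar(amplicon_B))
    stop_bsr("amplicons must have equal length")
  if (amplicon_A == amplicon_B) stop_bsr("no polymorphism between amplicons")
  assays <- list()
  for (enz in enzymes) {
    bands_D <- digest(amplicon_A, enz)$fragment_lengths
    bands_R <- digest(amplicon_B, enz)$fragment_lengths
    if (identical(bands_D, bands_R)) next
    assays[[length(assays) + 1L]] <- structure(
      list(enzyme = enz,
           amplicon_allele_D = amplicon_A, amplicon_allele_R = amplicon_B,
           bands_D = bands_D, bands_R = bands_R,
           bands_H = sort(unique(c(bands_D, bands_R)))),
      class = "caps_assay")
  }
  if (!length(assays)) return(assays)
  resolvability <- vapply(assays, function(a)
    min(abs(outer(a$bands_D, a$bands_R, "-"))), 1)
  assays[order(resolvability, decreasing = TRUE)]
}

#' @export
print.caps_assay <- function(x, ...) {
  cat(sprintf("CAPS assay [%s %s^%d]\n  D: %s\n  R: %s\n  H: %s\n",
              x$enzyme$name, x$enzyme$recognition, x$enzyme$cut_offset,
              paste(x$bands_D, collapse = "+"),
              paste(x$bands_R, collapse = "+"),
              paste(x$bands_H, collapse = "+")))
  invisible(x)
}

# multiset equality within a band-size tolerance
bands_match <- function(observed, expected, tol) {
  if (length(observed) != length(expected)) return(FALSE)
  all(abs(sort(observed) - sort(expected)) <= tol)
}

#' Call a genotype from observed gel bands
#'
#' @param observed_bands Band lengths read off the gel.
#' @param assay A `caps_assay` from [design_caps()].
#' @param tolerance_bp Band-size matching tolerance (default 0 for
#'   in-silico data).
#' @return `"D"`, `"R"`, `"H"`, or `"unknown"`.
#' @export
call_genotype <- function(observed_bands, assay, tolerance_bp = 0L) {
  stopifnot(inherits(assay, "caps_assay"))
  if (any(observed_bands <= 0)) stop_bsr("band lengths must be positive")
  if (bands_match(observed_bands, assay$bands_D, tolerance_bp)) return("D")
  if (bands_match(observed_bands, assay$bands_R, tolerance_bp)) return("R")
  if (bands_match(observed_bands, assay$bands_H, tolerance_bp)) return("H")
  "unknown"
}

#' Protein length encoded by a CDS
#'
#' The stop codon is part of the coding sequence but is not translated, so
#' a CDS of length L encodes L/3 - 1 amino acids (618 bp -> 205 aa).
#'
#' @param cds_length_bp CDS length, divisible by 3, at least 6.
#' @return Number of encoded amino acids.
#' @export
cds_protein_length <- function(cds_length_bp) {
  cds_length_bp <- as.integer(cds_length_bp)
  if (cds_length_bp %% 3L != 0L) stop_bsr("CDS length not divisible by 3")
  if (cds_length_bp < 6L) stop_bsr("CDS too short for start + stop codon")
  cds_length_bp %/% 3L - 1L
}

#' Read/write FASTA helpers for amplicons
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}
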