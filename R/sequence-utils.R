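# IUPAC nucleotide alphabet: code -> set of bases it stands for
.iupac_expand <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# complement over the full IUPAC alphabet
.iupac_comp_from <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
.iupac_comp_to   <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"

#' Reverse complement of an IUPAC DNA string
#'
#' Complements every base over the 15-letter IUPAC nucleotide alphabet
#' (self-complementary codes `S`, `W` and `N` map to themselves) and reverses
#' the sequence. Case is preserved.
#'
#' @param seq Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements, same length as `seq`.
#' @examples
#' revcomp("GNAWN")  # "NWTNC"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl(sprintf("[^%s]", .iupac_comp_from), seq)
  if (any(bad)) {
    stop("non-IUPAC character in sequence: ",
         paste(utils::head(seq[bad], 3), collapse = ", "))
  }
  comp <- chartr(.iupac_comp_from, .iupac_comp_to, seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Does a concrete base match a degenerate IUPAC code?
#'
#' @param base Single upper-case base, one of A/C/G/T.
#' @param code Single IUPAC nucleotide code.
#' @return `TRUE` iff `base` lies in the expansion of `code`
#'   (e.g. `iupac_match("T", "W")` is `TRUE` because W = A or T).
#' @export
iupac_match <- function(base, code) {
  base <- toupper(base); code <- toupper(code)
  if (!base %in% c("A", "C", "G", "T")) stop("base must be one of A/C/G/T")
  if (is.null(.iupac_expand[[code]])) stop("not an IUPAC code: ", code)
  base %in% .iupac_expand[[code]]
}

#' IUPAC code for a set of bases
#'
#' Inverse of the code expansion: maps a non-empty subset of {A,C,G,T} to the
#' degenerate code denoting exactly that set; the empty set maps to `"N"`
#' (no information, any base).
#'
#' @param bases Character vector of upper-case bases (possibly empty).
#' @return Single IUPAC code character.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0) return("N")
  if (!all(bases %in% c("A", "C", "G", "T"))) stop("bases must be A/C/G/T")
  key <- paste(bases, collapse = "")
  hit <- names(.iupac_expand)[vapply(
    .iupac_expand,
    function(set) identical(paste(sort(set), collapse = ""), key),
    logical(1))]
  hit[1]
}

#' Coding-sequence length of a peptide
#'
#' Number of DNA bases encoding a peptide: three per residue. Used for
#' construct arithmetic, e.g. an N-terminal extension of 16 amino acids
#' corresponds to 48 added bases of coding sequence.
#'
#' @param peptide Single amino-acid string (standard one-letter codes).
#' @return Integer number of DNA bases.
#' @examples
#' peptide_coding_bases("MKLAQGAFVDVIRIGA")  # 48
#' @export
peptide_coding_bases <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  peptide <- toupper(peptide)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptide)) {
    stop("not a standard one-letter amino-acid string")
  }
  3L * nchar(peptide)
}

# all 1024 five-nt PAMs over ACGT, lexicographic; fixed reference ordering
# for every count table in the package
all_pams <- function(pam_len = 5L) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(bases), pam_len),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # vary the last position fastest so the vector sorts lexicographically
  do.call(paste0, rev(grid))
}

.check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) ||
      !grepl("^[ACGT]+$", x)) {
    stop(what, " must be a single DNA string over A/C/G/T")
  }
  invisible(x)
}
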