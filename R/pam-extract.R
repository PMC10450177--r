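# first/second occurrence bookkeeping for an exact target match in a read
# vector; returns start of the unique occurrence, NA if 0 or >= 2 hits
.unique_target_start <- function(reads, target) {
  first <- regexpr(target, reads, fixed = TRUE)
  has <- first > 0L
  out <- rep(NA_integer_, length(reads))
  if (!any(has)) return(out)
  # a second occurrence anywhere after the first (overlaps included)
  rest <- substr(reads[has], first[has] + 1L, nchar(reads[has]))
  again <- regexpr(target, rest, fixed = TRUE) > 0L
  out[has][!again] <- first[has][!again]
  out
}

#' Extract the PAM upstream of an exactly matched target
#'
#' Parses the `pam_len` nucleotides immediately preceding a correct (exact,
#' mismatch-free) target occurrence in each read. A read yields a PAM only if
#' the target occurs exactly once with at least `pam_len` bases upstream and
#' the extracted window contains only A/C/G/T; any other read (no target,
#' multiple target occurrences, insufficient upstream context, ambiguous
#' bases in the window) is unassigned (`NA`). With `search_revcomp = TRUE`
#' the reverse complement of a read with no forward hit is searched as well;
#' a forward hit always wins.
#'
#' @param reads Character vector of reads (IUPAC DNA strings).
#' @param target Target DNA string, at least 10 nt.
#' @param pam_len PAM length in nt (default 5).
#' @param search_revcomp Also search the reverse complement of each read.
#' @return Character vector of PAMs, `NA` where unassigned.
#' @examples
#' extract_pam("TTGCAACGTACGTACGTAGG", "ACGTACGTACGTA")  # "TTGCA"
#' @export
extract_pam <- function(reads, target, pam_len = 5L,
                        search_revcomp = FALSE) {
  .check_dna(target, "target")
  if (nchar(target) < 10L) stop("target must be at least 10 nt")
  stopifnot(is.character(reads))
  reads <- toupper(reads)
  pam_len <- as.integer(pam_len)

  start <- .unique_target_start(reads, target)
  if (search_revcomp) {
    miss <- which(regexpr(target, reads, fixed = TRUE) < 0L)
    if (length(miss)) {
      rc <- revcomp(reads[miss])
      rc_start <- .unique_target_start(rc, target)
      hit <- !is.na(rc_start)
      reads[miss][hit] <- rc[hit]
      start[miss][hit] <- rc_start[hit]
    }
  }

  ok <- !is.na(start) & start > pam_len
  pam <- rep(NA_character_, length(reads))
  pam[ok] <- substr(reads[ok], start[ok] - pam_len, start[ok] - 1L)
  # ambiguous bases in the PAM window leave the read unassigned
  pam[!is.na(pam) & !grepl("^[ACGT]+$", pam)] <- NA_character_
  pam
}
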