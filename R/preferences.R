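#' Position-wise percent depletion of each base
#'
#' Marginalizes the pooled count table: for each PAM position p (-5..-1,
#' where -1 abuts the target's 5' end) and base b, counts are pooled over the
#' 256 PAMs carrying b at p, and
#'
#' \deqn{\mathrm{percent\ depletion} = 100 \times \left(1 -
#'   \frac{\mathrm{targeting\ pool} / \mathrm{total\ targeting}}
#'        {\mathrm{control\ pool} / \mathrm{total\ control}}\right)}
#'
#' Positive cells mean the base promotes clearance at that position; negative
#' cells mean enrichment in the targeting arm (anti-targeting). The
#' depletion result's pseudocount is added to both pools so empty pools
#' propagate finitely.
#'
#' @param result A `pam_depletion` object from [depletion_scores()].
#' @return Object of class `pam_prefs`: list with `percent_depletion`
#'   (5 x 4 matrix, rows `-5`..`-1`, columns A,C,G,T) and the totals used.
#' @export
position_preferences <- function(result) {
  stopifnot(inherits(result, "pam_depletion"))
  tab <- result$table
  if (nrow(tab) != 1024L) stop("depletion result must cover all 1024 PAMs")
  pc <- result$pseudocount
  base_idx <- matrix(unlist(strsplit(tab$pam, "", fixed = TRUE)),
                     ncol = 5L, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  m <- matrix(NA_real_, 5L, 4L,
              dimnames = list(as.character(-5:-1), bases))
  for (p in 1:5) {
    for (b in bases) {
      sel <- base_idx[, p] == b
      ctrl_pool <- sum(tab$control[sel]) + pc
      trg_pool <- sum(tab$targeting[sel]) + pc
      m[p, b] <- 100 * (1 - (trg_pool / result$total_targeting) /
                              (ctrl_pool / result$total_control))
    }
  }
  structure(list(percent_depletion = m,
                 total_control = result$total_control,
                 total_targeting = result$total_targeting),
            class = "pam_prefs")
}

#' @export
print.pam_prefs <- function(x, digits = 1, ...) {
  cat("Percent depletion by PAM position (negative = anti-targeting):\n")
  print(round(x$percent_depletion, digits))
  invisible(x)
}

#' Call an IUPAC consensus PAM from position preferences
#'
#' Per position, the preferred set is the bases whose percent depletion is at
#' least `prefer_threshold`; the consensus character is the IUPAC code for
#' that set ('N' when empty, i.e. no preference). Bases at or below
#' `anti_threshold` (enriched in the targeting arm) are reported as
#' anti-targeting — these typically mirror the system's own CRISPR repeat and
#' mark self sequences protected from clearance.
#'
#' @param prefs A `pam_prefs` object from [position_preferences()].
#' @param prefer_threshold Percent-depletion cutoff for a preferred base, in
#'   (0, 100] (default 50).
#' @param anti_threshold Cutoff for an anti-targeting base, negative
#'   (default -50).
#' @return Object of class `pam_consensus`: list with `iupac` (5-character
#'   string), `preferred` and `anti_targeting` (per-position base sets), and
#'   the thresholds used.
#' @export
call_consensus <- function(prefs, prefer_threshold = 50,
                           anti_threshold = -50) {
  stopifnot(inherits(prefs, "pam_prefs"))
  if (prefer_threshold <= 0 || prefer_threshold > 100) {
    stop("prefer_threshold must lie in (0, 100]")
  }
  if (anti_threshold >= 0) stop("anti_threshold must be negative")
  m <- prefs$percent_depletion
  bases <- colnames(m)
  preferred <- apply(m, 1L, function(row) bases[row >= prefer_threshold],
                     simplify = FALSE)
  anti <- apply(m, 1L, function(row) bases[row <= anti_threshold],
                simplify = FALSE)
  iupac <- paste(vapply(preferred, iupac_code, character(1)), collapse = "")
  structure(list(iupac = iupac, preferred = preferred,
                 anti_targeting = anti,
                 prefer_threshold = prefer_threshold,
                 anti_threshold = anti_threshold),
            class = "pam_consensus")
}

#' @export
print.pam_consensus <- function(x, ...) {
  cat("Consensus PAM: 5'-", x$iupac, "-3'\n", sep = "")
  cat(sprintf("  thresholds: preferred >= %g%%, anti-targeting <= %g%%\n",
              x$prefer_threshold, x$anti_threshold))
  for (pos in names(x$preferred)) {
    pref <- x$preferred[[pos]]; anti <- x$anti_targeting[[pos]]
    if (length(pref) || length(anti)) {
      cat(sprintf("  position %s: %s%s\n", pos,
                  if (length(pref))
                    paste0("preferred ", paste(pref, collapse = "/"))
                  else "",
                  if (length(anti))
                    paste0(if (length(pref)) "; " else "",
                           "anti-targeting ", paste(anti, collapse = "/"))
                  else ""))
    }
  }
  invisible(x)
}

#' Export a depletion result as Krona importText for a PAM wheel
#'
#' One line per PAM in the tab-delimited dialect of the Krona text importer:
#' a magnitude (the depletion score) followed by the node path, one single
#' base per ring, ordered -5 to -1 so the wheel reads in PAM 5'-to-3' order
#' from the center outward.
#'
#' @param result A `pam_depletion` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' \dontrun{export_krona(res, "wheel.txt")  # then: ktImportText wheel.txt}
#' @export
export_krona <- function(result, path) {
  stopifnot(inherits(result, "pam_depletion"))
  tab <- result$table
  score_txt <- vapply(tab$score, function(s)
    format(s, trim = TRUE, scientific = FALSE, digits = 10), character(1))
  node_path <- vapply(strsplit(tab$pam, "", fixed = TRUE),
                      paste, character(1), collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(score_txt, node_path, sep = "\t"), con)
  invisible(path)
}

#' Plasmid-clearance ratio of target to non-target colony counts
#'
#' Per-replicate ratio of colony-forming units obtained after transforming a
#' targeted plasmid versus a non-target control, with mean and standard
#' deviation across replicates. Ratios near 0 indicate efficient clearance
#' of the targeted plasmid; 1 means no clearance.
#'
#' @param target,nontarget Non-negative integer CFU counts, one per
#'   replicate (recycled if `nontarget` has length 1).
#' @return Object of class `cfu_ratio`: list with `ratio` (per replicate),
#'   `mean`, `sd`, `n`.
#' @export
clearance_ratio <- function(target, nontarget) {
  if (length(nontarget) == 1L) nontarget <- rep(nontarget, length(target))
  stopifnot(length(target) == length(nontarget))
  if (any(target < 0) || any(nontarget < 0) ||
      any(target != round(target)) || any(nontarget != round(nontarget))) {
    stop("CFU counts must be non-negative integers")
  }
  if (any(nontarget == 0)) {
    stop("zero non-target CFU count: ratio undefined")
  }
  ratio <- target / nontarget
  structure(list(ratio = ratio, mean = mean(ratio),
                 sd = if (length(ratio) > 1L) stats::sd(ratio) else NA_real_,
                 n = length(ratio)),
            class = "cfu_ratio")
}

#' @export
print.cfu_ratio <- function(x, ...) {
  cat(sprintf(
    "Target/non-target CFU ratio: mean %.4g (sd %.3g, n = %d)\n",
    x$mean, x$sd, x$n))
  invisible(x)
}
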