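#' Per-PAM depletion scores from pooled targeting and control counts
#'
#' Counts are first summed across replicates within each arm; a score is then
#' computed for every PAM. The default statistic is
#'
#' \deqn{\mathrm{score} = \frac{\mathrm{total\ control\ reads}}
#'   {\mathrm{total\ targeting\ reads}} \times
#'   \frac{\mathrm{control\ PAM\ reads}}{\mathrm{targeting\ PAM\ reads}}}
#'
#' with a pseudocount added to the two per-PAM counts only (totals are raw
#' pooled sums), keeping scores finite for fully depleted PAMs. A score of 1
#' means no depletion; large scores mean the PAM licenses clearance. With
#' `proportion_ratio = TRUE` the depth-normalizing variant
#' (control proportion / targeting proportion, i.e. the reciprocal
#' total-reads factor) is used instead.
#'
#' @param x A `pam_counts` object from [count_pams()], or a 1024-row matrix
#'   with columns `control` and `targeting` of pooled counts.
#' @param pseudocount Non-negative value added to each per-PAM pooled count
#'   (default 0.5).
#' @param proportion_ratio Use the proportion-ratio form of the score.
#' @return Object of class `pam_depletion`: list with `table` (data frame:
#'   `pam`, `control`, `targeting`, `score`), `total_control`,
#'   `total_targeting`, `pseudocount`, `proportion_ratio`, and, when per-sample
#'   counts were supplied, `per_replicate_scores` for dispersion diagnostics.
#' @export
depletion_scores <- function(x, pseudocount = 0.5,
                             proportion_ratio = FALSE) {
  per_rep <- NULL
  if (inherits(x, "pam_counts")) {
    if (!any(x$samples$role == "targeting") ||
        !any(x$samples$role == "control")) {
      stop("need at least one targeting and one control sample")
    }
    pooled <- pool_counts(x)
    per_sample <- x$counts
    roles <- x$samples$role
    per_rep <- vapply(seq_len(ncol(per_sample)), function(i) {
      other <- if (roles[i] == "targeting") {
        rowSums(per_sample[, roles == "control", drop = FALSE])
      } else {
        rowSums(per_sample[, roles == "targeting", drop = FALSE])
      }
      this <- per_sample[, i]
      if (roles[i] == "targeting") {
        .depletion_formula(other, this, pseudocount, proportion_ratio)
      } else {
        .depletion_formula(this, other, pseudocount, proportion_ratio)
      }
    }, numeric(nrow(per_sample)))
    colnames(per_rep) <- colnames(per_sample)
  } else {
    pooled <- as.matrix(x)
    if (!all(c("control", "targeting") %in% colnames(pooled))) {
      stop("pooled matrix needs 'control' and 'targeting' columns")
    }
  }
  stopifnot(pseudocount >= 0)
  ctrl <- pooled[, "control"]
  trg <- pooled[, "targeting"]
  total_control <- sum(ctrl)
  total_targeting <- sum(trg)
  if (total_control <= 0 || total_targeting <= 0) {
    stop("zero total reads in the ",
         if (total_control <= 0) "control" else "targeting", " arm")
  }
  score <- .depletion_formula(ctrl, trg, pseudocount, proportion_ratio)
  pam_names <- rownames(pooled)
  if (is.null(pam_names)) pam_names <- all_pams()

  structure(
    list(table = data.frame(pam = pam_names, control = unname(ctrl),
                            targeting = unname(trg), score = unname(score),
                            stringsAsFactors = FALSE),
         total_control = total_control,
         total_targeting = total_targeting,
         pseudocount = pseudocount,
         proportion_ratio = proportion_ratio,
         per_replicate_scores = per_rep),
    class = "pam_depletion")
}

.depletion_formula <- function(ctrl, trg, pseudocount, proportion_ratio) {
  total_control <- sum(ctrl)
  total_targeting <- sum(trg)
  depth <- if (proportion_ratio) {
    total_targeting / total_control
  } else {
    total_control / total_targeting
  }
  depth * (ctrl + pseudocount) / (trg + pseudocount)
}

#' Write a depletion-score table as TSV
#'
#' Columns: PAM, pooled control count, pooled targeting count, score.
#'
#' @param x A `pam_depletion` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_depletion <- function(x, path) {
  stopifnot(inherits(x, "pam_depletion"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.pam_depletion <- function(x, ...) {
  cat("PAM depletion scores:", nrow(x$table), "PAMs\n")
  cat(sprintf("  pooled reads: control %s, targeting %s\n",
              format(x$total_control, big.mark = ","),
              format(x$total_targeting, big.mark = ",")))
  cat(sprintf("  statistic: %s, pseudocount %g\n",
              if (x$proportion_ratio) "proportion ratio"
              else "depletion score (printed form)",
              x$pseudocount))
  top <- x$table[order(-x$table$score), ][1:5, ]
  cat("  most depleted PAMs:\n")
  for (i in 1:5) {
    cat(sprintf("    %s  score %.3g\n", top$pam[i], top$score[i]))
  }
  invisible(x)
}
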