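#' Count PAMs over the 1024-PAM space for a set of samples
#'
#' Reads each sample's FASTQ (plain or gzipped), extracts the 5-nt PAM
#' anchored to the target with [extract_pam()], and tabulates counts over
#' all `4^5 = 1024` canonical PAMs. Reads without a uniquely anchored, fully
#' unambiguous PAM are tallied per sample as unassigned, so that for every
#' sample `sum(counts) + n_unassigned` equals the number of reads processed.
#'
#' @param manifest Data frame with columns `path`, `role`
#'   (`"targeting"`/`"control"`) and `replicate`; an optional `sample` column
#'   names the samples (defaults to `role_repN`). A [simulate_pam_library()]
#'   result may be passed directly.
#' @param target Target DNA string the PAMs are anchored to.
#' @param pam_len PAM length (default 5).
#' @param search_revcomp Search reverse complements of unanchored reads.
#' @return Object of class `pam_counts`: list with `counts` (1024 x n_samples
#'   integer matrix, rownames the PAMs), `samples` (metadata data frame),
#'   `n_unassigned` (per-sample), `target`, `pam_len`.
#' @export
count_pams <- function(manifest, target, pam_len = 5L,
                       search_revcomp = FALSE) {
  if (inherits(manifest, "simulated_run")) {
    if (missing(target)) target <- manifest$truth$target_sequence
    manifest <- manifest$manifest
  }
  stopifnot(is.data.frame(manifest),
            all(c("path", "role", "replicate") %in% names(manifest)))
  if (!all(manifest$role %in% c("targeting", "control"))) {
    stop("every sample must be labeled 'targeting' or 'control'")
  }
  if (is.null(manifest$sample)) {
    manifest$sample <- sprintf("%s_rep%s", manifest$role, manifest$replicate)
  }
  missing_files <- !file.exists(manifest$path)
  if (any(missing_files)) {
    stop("FASTQ not found: ",
         paste(manifest$path[missing_files], collapse = ", "))
  }

  pams <- all_pams(pam_len)
  counts <- matrix(0L, nrow = length(pams), ncol = nrow(manifest),
                   dimnames = list(pams, manifest$sample))
  n_unassigned <- integer(nrow(manifest))
  names(n_unassigned) <- manifest$sample
  n_reads <- integer(nrow(manifest))

  for (i in seq_len(nrow(manifest))) {
    reads <- as.character(
      Biostrings::readDNAStringSet(manifest$path[i], format = "fastq"))
    n_reads[i] <- length(reads)
    pam <- extract_pam(reads, target, pam_len, search_revcomp)
    tab <- table(factor(pam, levels = pams))
    counts[, i] <- as.integer(tab)
    n_unassigned[i] <- sum(is.na(pam))
  }
  manifest$n_reads_processed <- n_reads

  structure(
    list(counts = counts,
         samples = manifest[, c("sample", "path", "role", "replicate",
                                "n_reads_processed")],
         n_unassigned = n_unassigned,
         target = target, pam_len = as.integer(pam_len)),
    class = "pam_counts")
}

#' Pool counts across replicates within each arm
#'
#' @param x A `pam_counts` object.
#' @return Matrix with columns `control` and `targeting`, rows the PAMs.
#' @export
pool_counts <- function(x) {
  stopifnot(inherits(x, "pam_counts"))
  cbind(
    control = rowSums(x$counts[, x$samples$role == "control", drop = FALSE]),
    targeting = rowSums(x$counts[, x$samples$role == "targeting",
                                 drop = FALSE]))
}

#' Write the per-sample PAM count table as CSV
#'
#' One row per PAM, one column per sample, plus a trailing `unassigned` row.
#'
#' @param x A `pam_counts` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pam_counts <- function(x, path) {
  stopifnot(inherits(x, "pam_counts"))
  out <- data.frame(PAM = c(rownames(x$counts), "unassigned"),
                    rbind(x$counts, x$n_unassigned),
                    check.names = FALSE, row.names = NULL)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pam_counts <- function(x, ...) {
  cat("PAM count table:", nrow(x$counts), "PAMs x",
      ncol(x$counts), "samples\n")
  cat("  target anchor:", x$target, "\n")
  tot <- colSums(x$counts)
  for (i in seq_len(ncol(x$counts))) {
    cat(sprintf("  %-18s %9d assigned, %7d unassigned (%s)\n",
                colnames(x$counts)[i], tot[i], x$n_unassigned[i],
                x$samples$role[i]))
  }
  invisible(x)
}
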