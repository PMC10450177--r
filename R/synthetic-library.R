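#' Ground truth for a synthetic PAM-library depletion screen
#'
#' Describes the planted structure of a simulated plasmid-curing screen: an
#' amplicon layout (5' flank, 5-nt randomized PAM, fixed target, 3' flank)
#' and a per-position survival model. Survival of a plasmid carrying a given
#' PAM in the targeting arm is the product of per-(position, base)
#' multipliers, so positions act independently; a multiplier of 1 means the
#' base confers no clearance at that position, values below 1 mean plasmids
#' with that base are cleared (depleted) proportionally.
#'
#' @param position_effects 5 x 4 numeric matrix of survival multipliers in
#'   (0, 1], rows positions `-5`..`-1` (`-1` abuts the target's 5' end),
#'   columns `A`,`C`,`G`,`T`. Defaults to all 1 (no planted effect).
#'   [position_effects()] builds one from sparse assignments.
#' @param target_sequence Fixed target the reads are anchored to. The screen's
#'   real target sequence is not public, so the default is an arbitrary fixed
#'   32-nt sequence; anchoring is sequence-agnostic. At least 10 nt.
#' @param flank_5p,flank_3p Constant amplicon context on either side of
#'   PAM + target.
#' @param n_reads_per_sample Reads per FASTQ sample; the screen this emulates
#'   yielded roughly 5e5 reads per sample, the default.
#' @param n_replicates_per_arm Biological replicates per arm (default 3, i.e.
#'   three targeting plus three control samples).
#' @param error_rate Per-base substitution probability in [0, 0.1]
#'   (default 0.001, typical post-filter Illumina accuracy).
#' @param seed Integer seed; identical truths give byte-identical FASTQ.
#' @return Object of class `library_truth`.
#' @seealso [simulate_pam_library()], [pam_survival()], [gnawn_truth()]
#' @export
library_truth <- function(position_effects = NULL,
                          target_sequence = "ACGTCTGAATGGTCCATGTCTTGGTCTTACAG",
                          flank_5p = "GTCATAGCTGTTTCCTG",
                          flank_3p = "CAGGCATGCAAGCTTGG",
                          n_reads_per_sample = 5e5,
                          n_replicates_per_arm = 3L,
                          error_rate = 0.001,
                          seed = 1L) {
  if (is.null(position_effects)) position_effects <- position_effects()
  stopifnot(is.matrix(position_effects),
            identical(dim(position_effects), c(5L, 4L)))
  if (any(position_effects <= 0) || any(position_effects > 1)) {
    stop("position_effects must be survival multipliers in (0, 1]")
  }
  dimnames(position_effects) <- list(as.character(-5:-1), c("A", "C", "G", "T"))
  .check_dna(target_sequence, "target_sequence")
  if (nchar(target_sequence) < 10L) {
    stop("target_sequence shorter than 10 nt: anchoring becomes ambiguous")
  }
  .check_dna(flank_5p, "flank_5p"); .check_dna(flank_3p, "flank_3p")
  if (nchar(flank_5p) < 1L) stop("flank_5p must be non-empty")
  n_reads_per_sample <- as.integer(n_reads_per_sample)
  if (is.na(n_reads_per_sample) || n_reads_per_sample <= 0L) {
    stop("n_reads_per_sample must be a positive integer")
  }
  n_replicates_per_arm <- as.integer(n_replicates_per_arm)
  stopifnot(n_replicates_per_arm >= 1L)
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must lie in [0, 0.1]")
  }
  structure(
    list(position_effects = position_effects,
         target_sequence = target_sequence,
         flank_5p = flank_5p, flank_3p = flank_3p,
         n_reads_per_sample = n_reads_per_sample,
         n_replicates_per_arm = n_replicates_per_arm,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "library_truth")
}

#' Build a position-effects matrix from sparse assignments
#'
#' Starts from all multipliers equal to 1 and overrides named cells.
#'
#' @param ... Assignments of the form `"-5" = c(G = 0.1)` or
#'   `"-2" = c(A = 0.15, T = 0.15)`: names are PAM positions `-5`..`-1`,
#'   values named numeric vectors of per-base survival multipliers.
#' @return 5 x 4 numeric matrix, rows `-5`..`-1`, columns A,C,G,T.
#' @examples
#' position_effects("-5" = c(G = 0.1))
#' @export
position_effects <- function(...) {
  eff <- matrix(1, 5L, 4L,
                dimnames = list(as.character(-5:-1), c("A", "C", "G", "T")))
  assignments <- list(...)
  for (pos in names(assignments)) {
    if (!pos %in% rownames(eff)) stop("unknown PAM position: ", pos)
    v <- assignments[[pos]]
    if (is.null(names(v)) || !all(names(v) %in% colnames(eff))) {
      stop("effects for position ", pos, " must be named with bases A/C/G/T")
    }
    eff[pos, names(v)] <- v
  }
  eff
}

#' Canonical GNAWN-structured screen truth
#'
#' The package's reference planted structure: strong clearance for G at -5,
#' A at -3 and A/T at -2, no signal at -4 and -1, and self-mimicking
#' anti-targeting bases (C at -3, G and C at -2) left fully undepleted
#' against a mildly depleted background at -3, so that their survival exceeds
#' the position average and they surface as enriched (anti-targeting) in the
#' marginal readout. A pipeline run on this truth should recover the
#' consensus "GNAWN".
#'
#' @param ... Passed on to [library_truth()] (e.g. `seed`,
#'   `n_reads_per_sample`).
#' @return Object of class `library_truth`.
#' @export
gnawn_truth <- function(...) {
  eff <- position_effects(
    "-5" = c(G = 0.1),
    "-3" = c(A = 0.1, C = 1.0, G = 0.5, T = 0.5),
    "-2" = c(A = 0.15, T = 0.15, C = 1.0, G = 1.0))
  library_truth(position_effects = eff, ...)
}

#' Per-PAM survival weights implied by a truth object
#'
#' Survival of each of the 1024 PAMs under the planted model:
#' `s(PAM) = prod over positions of position_effects[p, base_p]`.
#'
#' @param truth A [library_truth()] object.
#' @return Named numeric vector of length 1024 over (0, 1], names the PAMs in
#'   lexicographic order.
#' @export
pam_survival <- function(truth) {
  stopifnot(inherits(truth, "library_truth"))
  pams <- all_pams()
  base_idx <- matrix(match(unlist(strsplit(pams, "", fixed = TRUE)),
                           c("A", "C", "G", "T")),
                     ncol = 5L, byrow = TRUE)
  s <- rep(1, length(pams))
  for (p in 1:5) s <- s * truth$position_effects[p, base_idx[, p]]
  names(s) <- pams
  s
}

#' Expected PAM frequencies in each arm
#'
#' Closed-form sampling distribution over the 1024-PAM space: control samples
#' draw PAMs uniformly (or from `library_bias` if supplied); targeting
#' samples draw proportionally to that distribution times per-PAM survival,
#' renormalized.
#'
#' @param truth A [library_truth()] object.
#' @param role `"targeting"` or `"control"`.
#' @param library_bias Optional non-uniform input-library distribution
#'   (length-1024 non-negative vector in PAM order); default uniform.
#' @return Named numeric probability vector of length 1024.
#' @export
expected_pam_freq <- function(truth, role = c("targeting", "control"),
                              library_bias = NULL) {
  role <- match.arg(role)
  if (is.null(library_bias)) {
    u <- rep(1 / 1024, 1024)
  } else {
    stopifnot(length(library_bias) == 1024, all(library_bias >= 0))
    u <- library_bias / sum(library_bias)
  }
  w <- if (role == "targeting") u * pam_survival(truth) else u
  p <- w / sum(w)
  names(p) <- all_pams()
  p
}

# draw n PAM strings for one sample; used by the FASTQ writer and directly
# by convergence tests
sample_pams <- function(truth, n, role, library_bias = NULL) {
  p <- expected_pam_freq(truth, role, library_bias)
  all_pams()[sample.int(1024L, n, replace = TRUE, prob = p)]
}

# apply iid per-base substitution errors to a vector of equal-length reads
add_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  len <- nchar(reads[1])
  n_err <- stats::rbinom(length(reads), len, error_rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(len, n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate a PAM-library depletion screen as FASTQ files
#'
#' Writes one FASTQ file per sample: `n_replicates_per_arm` targeting and as
#' many control samples, each of exactly `n_reads_per_sample` single-end
#' reads laid out as `flank_5p + PAM + target + flank_3p`, with iid per-base
#' substitution errors. Control samples draw PAMs uniformly over the 1024
#' 5-mers (or from `library_bias`); targeting samples draw from the same
#' distribution reweighted by per-PAM survival, so planted clearance shows up
#' as depletion. A JSON-like manifest of the truth parameters is written
#' beside the reads. Fully deterministic given `truth$seed`.
#'
#' @param truth A [library_truth()] object.
#' @param dir Output directory (created if missing).
#' @param gzip Compress FASTQ output (default `TRUE`).
#' @param library_bias Optional input-library PAM distribution; see
#'   [expected_pam_freq()].
#' @param revcomp_fraction Fraction of reads emitted as the reverse
#'   complement of the forward-strand layout (default 0), to exercise strand
#'   handling downstream.
#' @return Object of class `simulated_run`: list with `fastq_paths` (named by
#'   sample), `manifest` (data frame: sample, path, role, replicate,
#'   n_reads), and `truth`.
#' @export
simulate_pam_library <- function(truth, dir = tempfile("pamlib"),
                                 gzip = TRUE, library_bias = NULL,
                                 revcomp_fraction = 0) {
  stopifnot(inherits(truth, "library_truth"))
  stopifnot(revcomp_fraction >= 0, revcomp_fraction <= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(truth$seed)
  roles <- rep(c("targeting", "control"), each = truth$n_replicates_per_arm)
  reps <- rep(seq_len(truth$n_replicates_per_arm), times = 2L)
  samples <- sprintf("%s_rep%d", roles, reps)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- file.path(dir, paste0(samples, ext))
  names(paths) <- samples

  n <- truth$n_reads_per_sample
  for (i in seq_along(samples)) {
    pams <- sample_pams(truth, n, roles[i], library_bias)
    reads <- paste0(truth$flank_5p, pams, truth$target_sequence,
                    truth$flank_3p)
    reads <- add_read_errors(reads, truth$error_rate)
    if (revcomp_fraction > 0) {
      flip <- stats::runif(n) < revcomp_fraction
      if (any(flip)) reads[flip] <- revcomp(reads[flip])
    }
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- sprintf("%s_read%07d", samples[i], seq_len(n))
    qual <- Biostrings::BStringSet(rep(strrep("I", nchar(reads[1])), n))
    Biostrings::writeXStringSet(dna, paths[i], format = "fastq",
                                qualities = qual,
                                compress = if (gzip) "gzip" else FALSE)
  }

  manifest <- data.frame(sample = samples, path = unname(paths),
                         role = roles, replicate = reps, n_reads = n,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest[, c("sample", "path", "role", "replicate",
                                "n_reads")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  writeLines(
    c("# simulated PAM library truth",
      paste0("target_sequence: ", truth$target_sequence),
      paste0("flank_5p: ", truth$flank_5p),
      paste0("flank_3p: ", truth$flank_3p),
      paste0("n_reads_per_sample: ", truth$n_reads_per_sample),
      paste0("n_replicates_per_arm: ", truth$n_replicates_per_arm),
      paste0("error_rate: ", truth$error_rate),
      paste0("seed: ", truth$seed)),
    file.path(dir, "truth.yaml"))
  structure(list(fastq_paths = paths, manifest = manifest, truth = truth),
            class = "simulated_run")
}

#' @export
print.simulated_run <- function(x, ...) {
  cat("Simulated PAM-library run:",
      nrow(x$manifest), "samples x", x$truth$n_reads_per_sample,
      "reads\n")
  cat("  arms:", paste(sprintf(
    "%s (n=%d)", unique(x$manifest$role),
    tabulate(factor(x$manifest$role))), collapse = ", "), "\n")
  cat("  directory:", dirname(x$fastq_paths[1]), "\n")
  invisible(x)
}
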