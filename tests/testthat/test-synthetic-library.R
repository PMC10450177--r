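test_that("truth validation rejects malformed inputs", {
  expect_error(library_truth(n_reads_per_sample = 0), "positive")
  expect_error(library_truth(target_sequence = "ACGTACGT"), "10 nt")
  expect_error(library_truth(error_rate = 0.5), "0.1")
  eff <- position_effects("-5" = c(G = 0))
  expect_error(library_truth(position_effects = eff), "\\(0, 1\\]")
  expect_error(position_effects("-6" = c(A = 0.5)), "position")
})

test_that("per-PAM survival is the product of position multipliers", {
  eff <- position_effects("-5" = c(G = 0.1), "-2" = c(T = 0.5))
  truth <- library_truth(position_effects = eff)
  s <- pam_survival(truth)
  expect_length(s, 1024)
  expect_true(all(s > 0 & s <= 1))
  expect_equal(unname(s["GAATA"]), 0.1 * 0.5)
  expect_equal(unname(s["AAAAA"]), 1)        # no affected base => s = 1
  expect_equal(unname(s["GGGGG"]), 0.1)
})

test_that("with no planted effect the two arms share one distribution", {
  truth <- library_truth()   # all multipliers 1
  expect_equal(expected_pam_freq(truth, "targeting"),
               expected_pam_freq(truth, "control"))
  expect_equal(unname(expected_pam_freq(truth, "control")[1]), 1 / 1024)
})

test_that("empirical targeting frequencies match the closed form", {
  # multiplier 0.1 for G at -5: marginal weight of G-led PAMs is
  # 0.1 / (0.1 + 3) per position-independence; check each base's marginal
  # and per-PAM ratios at n = 1e6 within 3 binomial SEs
  eff <- position_effects("-5" = c(G = 0.1))
  truth <- library_truth(position_effects = eff, seed = 99)
  p_exp <- expected_pam_freq(truth, "targeting")
  g_led <- startsWith(names(p_exp), "G")
  expect_equal(sum(p_exp[g_led]), 0.1 / 3.1, tolerance = 1e-12)
  expect_equal(unname(p_exp["GAAAA"]), (0.1 / 3.1) / 256, tolerance = 1e-12)

  set.seed(truth$seed)
  pams <- pamkit:::sample_pams(truth, 1e6, "targeting")
  emp <- mean(startsWith(pams, "G"))
  p0 <- 0.1 / 3.1
  se <- sqrt(p0 * (1 - p0) / 1e6)
  expect_lt(abs(emp - p0), 3 * se)

  # frequency ratio targeting/control converges to s(PAM)/E[s]
  s <- pam_survival(truth)
  expect_equal(unname(p_exp * 1024), unname(s / mean(s)), tolerance = 1e-12)
})

test_that("a uniform control library covers nearly all 1024 PAMs at 1e6", {
  truth <- library_truth(seed = 5)
  set.seed(5)
  pams <- pamkit:::sample_pams(truth, 1e6, "control")
  expect_gte(length(unique(pams)), 1020)
})

test_that("simulated FASTQ round-trips through the counting reader", {
  run <- small_run(n_reads = 300, seed = 11)
  expect_length(run$fastq_paths, 6)
  expect_identical(nrow(run$manifest), 6L)
  for (p in run$fastq_paths) {
    reads <- Biostrings::readDNAStringSet(p, format = "fastq")
    expect_length(reads, 300)
  }
  pc <- count_pams(run)
  expect_identical(unname(colSums(pc$counts) + pc$n_unassigned),
                   rep(300, 6))
  # zero error rate, forward-only layout: every read yields a PAM
  expect_identical(unname(pc$n_unassigned), rep(0L, 6))
})

test_that("identical seeds give byte-identical FASTQ output", {
  t1 <- library_truth(n_reads_per_sample = 200, seed = 31,
                      error_rate = 0.01)
  r1 <- simulate_pam_library(t1, gzip = FALSE)
  r2 <- simulate_pam_library(t1, gzip = FALSE)
  for (s in names(r1$fastq_paths)) {
    expect_identical(readLines(r1$fastq_paths[[s]]),
                     readLines(r2$fastq_paths[[s]]))
  }
})

test_that("substitution errors appear at the requested rate", {
  t1 <- library_truth(n_reads_per_sample = 2000, seed = 8,
                      error_rate = 0.01)
  r1 <- simulate_pam_library(t1, gzip = FALSE)
  reads <- as.character(Biostrings::readDNAStringSet(
    r1$fastq_paths[[1]], format = "fastq"))
  clean <- paste0(t1$flank_5p, substr(reads, nchar(t1$flank_5p) + 1,
                                      nchar(t1$flank_5p) + 5),
                  t1$target_sequence, t1$flank_3p)
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads, clean)
  len <- nchar(reads[1])
  rate <- sum(mism) / (2000 * (len - 5))      # PAM bases excluded
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.02)
})

test_that("gzipped output reads back identically to plain output", {
  t1 <- library_truth(n_reads_per_sample = 150, seed = 12)
  gz <- simulate_pam_library(t1, gzip = TRUE)
  pl <- simulate_pam_library(t1, gzip = FALSE)
  expect_true(all(grepl("\\.gz$", gz$fastq_paths)))
  expect_identical(
    as.character(Biostrings::readDNAStringSet(gz$fastq_paths[[1]],
                                              format = "fastq")),
    as.character(Biostrings::readDNAStringSet(pl$fastq_paths[[1]],
                                              format = "fastq")))
})
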