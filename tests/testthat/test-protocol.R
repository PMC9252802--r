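test_that("trimmed-input detection uses modal length fraction and modal length", {
  expect_false(detect_trimmed(data.frame(length = 50L, count = 1000L)))
  expect_true(detect_trimmed(data.frame(length = c(20L, 21L, 22L),
                                        count = c(300L, 400L, 300L))))
  # homogeneous but short: already trimmed
  expect_true(detect_trimmed(data.frame(length = 22L, count = 1000L)))
  expect_error(detect_trimmed(data.frame(length = integer(),
                                         count = integer())), "empty")

  fx <- fixture_complement()
  sim <- simulate_reads(sim_config(seed = 41, n_reads = 2000, rand5 = 4,
                                   rand3 = 4), fx$complement)
  h <- length_histogram(collapse_reads(unname(sim$reads)))
  expect_false(detect_trimmed(h))
})

test_that("adapter probing measures read fraction and complement coverage", {
  fx <- fixture_complement(genome_len = 20000, n = 10)
  matures <- fx$complement$mature$sequences
  adapter <- adapter_spec("kit", "TGGAATTCTCGGGTGCCAAGG")
  set.seed(43)
  reads <- paste0(sample(matures, 100, replace = TRUE), adapter$adapter3)
  cr <- collapse_reads(reads)
  pr <- probe_adapter(cr, adapter, fx$complement$mature)
  expect_identical(pr$frac_reads_with_adapter, 1)
  expect_identical(pr$complement_coverage, 1)

  wrong <- adapter_spec("other", "AACTGTAGGCACCATCAAT")
  pr2 <- probe_adapter(cr, wrong, fx$complement$mature)
  expect_lt(pr2$frac_reads_with_adapter, 0.05)

  expect_error(probe_adapter(cr, adapter,
                             structure(list(sequences = character()),
                                       class = "ref_library")),
               "empty miRNA library")
})

test_that("probing a seeded junk-bearing run meets both thresholds", {
  fx <- fixture_complement()
  cfg <- sim_config(seed = 44, junk_frac = 0.3)
  sim <- simulate_reads(cfg, fx$complement)
  cr <- collapse_reads(unname(sim$reads))
  pr <- probe_adapter(cr, cfg$adapter, fx$complement$mature)
  expect_gt(pr$frac_reads_with_adapter, 0.6)
  expect_lt(pr$frac_reads_with_adapter, 0.72)
  expect_gte(pr$complement_coverage, 0.2)
})

test_that("guess-adapter recovers a non-catalogue adapter and rejects noise", {
  fx <- fixture_complement(genome_len = 20000, n = 12)
  novel <- "CTGACGTAGCATCAAGGTCC"
  set.seed(45)
  matures <- fx$complement$mature$sequences
  reads <- substr(paste0(sample(matures, 2000, replace = TRUE), novel,
                         strrep("A", 30)), 1, 51)
  g <- guess_adapter(collapse_reads(reads))
  expect_identical(g, substr(novel, 1, 12))

  noise <- replicate(500, paste(sample(c("A", "C", "G", "T"), 40,
                                       replace = TRUE), collapse = ""))
  expect_null(guess_adapter(collapse_reads(noise)))
})

test_that("flank modes recover randomized-end lengths", {
  fx <- fixture_complement(genome_len = 20000, n = 10)
  matures <- fx$complement$mature$sequences
  set.seed(46)
  lib <- fx$complement$mature
  n4 <- collapse_reads(paste0(rand_4 <- replicate(300, paste(
    sample(c("A", "C", "G", "T"), 4, replace = TRUE), collapse = "")),
    sample(matures, 300, replace = TRUE),
    replicate(300, paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                         collapse = ""))))
  rl <- infer_random_lengths(n4, lib)
  expect_identical(c(rl$rand5, rl$rand3), c(4L, 4L))
  expect_false(rl$low_support)

  exact <- collapse_reads(sample(matures, 300, replace = TRUE))
  rl0 <- infer_random_lengths(exact, lib)
  expect_identical(c(rl0$rand5, rl0$rand3), c(0L, 0L))

  expect_warning(low <- infer_random_lengths(
    collapse_reads(unname(matures[1:3])), lib), "anchored")
  expect_true(low$low_support)

  # asymmetric ends with sequencing errors, via the generator
  sim <- simulate_reads(sim_config(seed = 47, rand5 = 4, rand3 = 0,
                                   adapter = NULL, junk_frac = 0),
                        fx$complement)
  rl40 <- infer_random_lengths(collapse_reads(unname(sim$reads)), lib)
  expect_identical(c(rl40$rand5, rl40$rand3), c(4L, 0L))
})

test_that("full protocol detection recovers adapter and random lengths", {
  fx <- fixture_complement()
  catalogue <- read_adapter_catalogue()

  cfg1 <- sim_config(seed = 48)  # truseq, no random ends
  sim1 <- simulate_reads(cfg1, fx$complement)
  call1 <- detect_protocol(collapse_reads(unname(sim1$reads)),
                           catalogue, fx$complement$mature)
  expect_identical(call1$status, "detected")
  expect_identical(call1$adapter$adapter3, cfg1$adapter$adapter3)
  expect_identical(c(call1$rand5_len, call1$rand3_len), c(0L, 0L))

  cfg2 <- sim_config(seed = 49, rand5 = 4, rand3 = 4,
                     adapter = adapter_spec("qiaseq",
                                            "AACTGTAGGCACCATCAAT"))
  sim2 <- simulate_reads(cfg2, fx$complement)
  call2 <- detect_protocol(collapse_reads(unname(sim2$reads)),
                           catalogue, fx$complement$mature)
  expect_identical(call2$status, "detected")
  expect_identical(call2$adapter$adapter3, cfg2$adapter$adapter3)
  expect_identical(c(call2$rand5_len, call2$rand3_len), c(4L, 4L))
  expect_true(all(c("frac_reads_with_adapter", "pass") %in%
                    names(call2$diagnostics)))

  cfg3 <- sim_config(seed = 50, adapter = NULL, junk_frac = 0)
  sim3 <- simulate_reads(cfg3, fx$complement)
  call3 <- detect_protocol(collapse_reads(unname(sim3$reads)),
                           catalogue, fx$complement$mature)
  expect_identical(call3$status, "already_trimmed")
  expect_null(call3$adapter)
})

test_that("detection falls back to the guessed adapter", {
  fx <- fixture_complement()
  cfg <- sim_config(seed = 51,
                    adapter = adapter_spec("novel", "CTGACGTAGCATCAAGGTCC"))
  sim <- simulate_reads(cfg, fx$complement)
  call <- detect_protocol(collapse_reads(unname(sim$reads)),
                          read_adapter_catalogue(), fx$complement$mature)
  expect_identical(call$status, "guessed")
  expect_identical(call$adapter$adapter3, substr(cfg$adapter$adapter3, 1, 12))
  expect_identical(c(call$rand5_len, call$rand3_len), c(0L, 0L))
})

test_that("protocol call JSON round trip preserves the call", {
  fx <- fixture_complement()
  sim <- simulate_reads(sim_config(seed = 52), fx$complement)
  call <- detect_protocol(collapse_reads(unname(sim$reads)),
                          mirna_library = fx$complement$mature)
  p <- tempfile(fileext = ".json")
  write_protocol_call(call, p)
  back <- read_protocol_call(p)
  expect_identical(back$status, call$status)
  expect_identical(back$adapter$adapter3, call$adapter$adapter3)
  expect_identical(back$rand5_len, call$rand5_len)
  expect_equal(back$frac_reads_with_adapter, call$frac_reads_with_adapter)
})

test_that("trimming cuts adapter and random ends and tallies rejections", {
  adapter <- adapter_spec("kit", "TGGAATTCTCGGGTGCCAAGG")
  call <- srnakit:::new_protocol_call("detected", adapter, 0L, 0L, 1, 1,
                                      data.frame())
  insert <- "ACGTACGTACGTACGTACGTAC"
  cr <- collapse_reads(c(paste0(insert, adapter$adapter3),
                         "GGGTTTCCCAAAGGGTTTCCC"))  # no adapter anywhere
  tr <- trim_reads(cr, call)
  expect_identical(tr$reads$sequence, insert)
  expect_identical(tr$rejected, c(no_adapter = 1L, too_short = 0L))
  expect_identical(sum(tr$reads$count) + sum(tr$rejected), sum(cr$count))

  call44 <- srnakit:::new_protocol_call("detected", adapter, 4L, 4L, 1, 1,
                                        data.frame())
  cr44 <- collapse_reads(c(
    paste0("TTTT", insert, "AAAA", adapter$adapter3),
    paste0("TTTT", substr(insert, 1, 14), "AAAA", adapter$adapter3)))
  tr44 <- trim_reads(cr44, call44)
  expect_identical(tr44$reads$sequence, insert)
  # a 14-nt insert survives adapter search but dies after 4N stripping
  expect_identical(tr44$rejected, c(no_adapter = 0L, too_short = 1L))

  expect_error(trim_reads(cr, srnakit:::new_protocol_call(
    "failed", NULL, 0L, 0L, NA_real_, NA_real_, data.frame())), "failed")
})

test_that("trimming a simulated run recovers the planted insert multiset", {
  fx <- fixture_complement()
  cfg <- sim_config(seed = 53, n_reads = 4000, rand5 = 4, rand3 = 4,
                    junk_frac = 0, error_rate = 0)
  sim <- simulate_reads(cfg, fx$complement)
  cr <- collapse_reads(unname(sim$reads))
  call <- detect_protocol(cr, mirna_library = fx$complement$mature)
  tr <- trim_reads(cr, call)
  got <- rep(tr$reads$sequence, tr$reads$count)
  expect_identical(sort(got), sort(sim$truth$insert))
})

test_that("complexity ratio counts the dominant nucleotide", {
  expect_identical(complexity_ratio("AAAA"), 1)
  expect_identical(complexity_ratio("ACGT"), 0.25)
  expect_identical(complexity_ratio("AAAAAAAATC"), 0.8)
  expect_identical(complexity_ratio(c("NNNN", "AACC")), c(1, 0.5))
  expect_error(complexity_ratio(""), "empty")
})

test_that("low-complexity filter removes at the inclusive 0.8 boundary", {
  cr <- collapse_reads(c("AAAAAAAATC", "ACGTACGTAC"))
  fl <- filter_low_complexity(cr)
  expect_identical(fl$removed$sequence, "AAAAAAAATC")  # ratio exactly 0.8
  expect_identical(fl$kept$sequence, "ACGTACGTAC")
  # epsilon below the boundary is kept: 7 of 9 = 0.778
  just_below <- collapse_reads("AAAAAAATC")
  expect_identical(nrow(filter_low_complexity(just_below)$removed), 0L)

  set.seed(54)
  mixed <- collapse_reads(replicate(1000, paste(
    sample(c("A", "C", "G", "T"), 20, replace = TRUE,
           prob = runif(4)), collapse = "")))
  fl2 <- filter_low_complexity(mixed)
  ratio <- complexity_ratio(mixed$sequence)
  expect_setequal(fl2$removed$sequence, mixed$sequence[ratio >= 0.8])
  expect_identical(sum(fl2$kept$count) + sum(fl2$removed$count),
                   sum(mixed$count))
})
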