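test_that("hierarchy order decides the class and conserves read counts", {
  mat <- ref_library(c(m1 = "ACGTACGTACGTACGTACGT"), "mature", "mature")
  cdna <- ref_library(c(c1 = "TTACGTACGTACGTACGTACGTTT"), "cDNA", "cDNA")
  # read matching both libraries is counted only in the first
  cr <- collapse_reads(c("ACGTACGTACGTACGTACGT",
                         "GGGTTTAAACCCGGGTTTAAA"))
  prof <- hierarchical_profile(cr, list(mat, cdna), max_mismatches = 0)
  expect_identical(prof$class_counts$sense[prof$class_counts$class ==
                                             "mature"], 1L)
  expect_identical(prof$class_counts$sense[prof$class_counts$class ==
                                             "cDNA"], 0L)
  expect_identical(prof$unassigned$sequence, "GGGTTTAAACCCGGGTTTAAA")
  tot <- sum(prof$class_counts$sense + prof$class_counts$antisense) +
    sum(prof$unassigned$count)
  expect_identical(tot, sum(cr$count))

  dup <- ref_library(c(m1 = "AAAACCCCGGGGTTTTAAAA"), "dup", "dup")
  expect_error(hierarchical_profile(cr, list(mat, dup), 0), "shared")
})

test_that("multi-mapping reads count per record with a unique-mapper tally", {
  lib <- ref_library(c(a = "ACGTACGTACGTACGTACGT",
                       b = "ACGTACGTACGTACGTACGT",
                       c = "TTGGCCAATTGGCCAATTGG"), "mature", "mature")
  cr <- collapse_reads(c(rep("ACGTACGTACGTACGTACGT", 3),
                         rep("TTGGCCAATTGGCCAATTGG", 2)))
  prof <- hierarchical_profile(cr, list(lib), 0)
  rc <- prof$record_counts
  expect_identical(rc$count[match(c("a", "b", "c"), rc$ref_id)],
                   c(3L, 3L, 2L))
  expect_identical(rc$unique_count[match(c("a", "b", "c"), rc$ref_id)],
                   c(0L, 0L, 2L))
  # class count adds the read once, not per record
  expect_identical(prof$class_counts$sense, 5L)
})

test_that("simulated mixture fractions are recovered within a point", {
  fx <- fixture_complement()
  trna <- fixture_trna()
  cfg <- sim_config(seed = 61, n_reads = 20000, adapter = NULL,
                    junk_frac = 0.2)
  sim <- simulate_reads(cfg, fx$complement,
                        ncrna = list(library = trna, frac = 0.2))
  cr <- collapse_reads(unname(sim$reads))
  prof <- hierarchical_profile(cr, library_order(fx$complement$mature,
                                                 fx$complement$hairpin,
                                                 trna),
                               max_mismatches = 2)
  frac <- with(prof$class_counts,
               setNames(100 * (sense + antisense) / prof$total_input, class))
  truth <- 100 * table(sim$truth$origin) / cfg$n_reads
  expect_lt(abs(frac[["mature"]] - truth[["mirna"]]), 1)
  expect_lt(abs(frac[["tRNA"]] - truth[["ncrna"]]), 1)
  expect_lt(abs(100 * sum(prof$unassigned$count) / prof$total_input -
                  truth[["junk"]]), 1)
  # conservation of reads at every stage
  expect_identical(sum(prof$class_counts$sense +
                         prof$class_counts$antisense) +
                     sum(prof$unassigned$count), 20000L)
  s <- summarize_run(prof)
  expect_equal(sum(s$class_distribution$reads), 20000)
  agg <- tapply(s$length_dist$count, s$length_dist$class, sum)
  cc <- prof$class_counts
  expect_identical(as.vector(agg[cc$class[cc$sense + cc$antisense > 0]]),
                   as.integer((cc$sense + cc$antisense)[
                     cc$sense + cc$antisense > 0]))
})

test_that("permuting later libraries never changes the first class", {
  fx <- fixture_complement(genome_len = 20000, n = 10)
  trna <- fixture_trna(seed = 62, n = 8)
  other <- fixture_trna(seed = 63, n = 8)
  other$name <- other$rna_class <- "snoRNA"
  names(other$sequences) <- sub("tRNA", "sno", names(other$sequences))
  sim <- simulate_reads(sim_config(seed = 64, n_reads = 5000,
                                   adapter = NULL, junk_frac = 0.1),
                        fx$complement,
                        ncrna = list(library = trna, frac = 0.3))
  cr <- collapse_reads(unname(sim$reads))
  p1 <- hierarchical_profile(cr, list(fx$complement$mature, trna, other), 1)
  p2 <- hierarchical_profile(cr, list(fx$complement$mature, other, trna), 1)
  m1 <- p1$class_counts[p1$class_counts$class == "mature", ]
  m2 <- p2$class_counts[p2$class_counts$class == "mature", ]
  expect_identical(m1, m2)
  expect_identical(p1$record_counts[p1$record_counts$class == "mature", ],
                   p2$record_counts[p2$record_counts$class == "mature", ])
})

test_that("expression matrix tabulates counts and RPM per sample", {
  lib <- ref_library(c(m1 = "ACGTACGTACGTACGTACGT",
                       m2 = "TTGGCCAATTGGCCAATTGG"), "mature", "mature")
  pr1 <- hierarchical_profile(
    collapse_reads(rep("ACGTACGTACGTACGTACGT", 10)), list(lib), 0)
  mat <- mirna_expression_matrix(list(s1 = pr1))
  expect_identical(mat$counts["m1", "s1"], 10)
  expect_identical(dim(mat$counts), c(1L, 1L))
  # RPM equals raw counts when the sample has 1e6 assigned reads (identity
  # checked by construction on the formula's denominator)
  expect_equal(mat$rpm["m1", "s1"], 10 * 1e6 / 10)
  expect_error(mirna_expression_matrix(list(pr1)), "named")
  expect_error(mirna_expression_matrix(list(a = pr1, a = pr1)), "named")
})

test_that("a planted two-fold expression change appears in RPM", {
  fx <- fixture_complement(genome_len = 30000, n = 12)
  lib <- fx$complement$mature
  matures <- lib$sequences
  set.seed(65)
  base <- sample(500:2000, length(matures))
  base[1] <- 200  # doubling a minor species barely shifts the denominator
  mk <- function(mult) {
    counts <- base
    counts[1] <- counts[1] * mult
    collapse_reads(rep(unname(matures), counts))
  }
  p1 <- hierarchical_profile(mk(1), list(lib), 0)
  p2 <- hierarchical_profile(mk(2), list(lib), 0)
  m <- mirna_expression_matrix(list(a = p1, b = p2))
  ratio <- m$rpm[names(matures)[1], "b"] / m$rpm[names(matures)[1], "a"]
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
})

test_that("genome distribution separates disjoint sources", {
  ga <- make_genome(20000, seed = 66, name = "hostA")
  gb <- make_genome(20000, seed = 67, name = "hostB")
  set.seed(68)
  st <- sample(19000, 300)
  reads <- substring(ga$sequences[[1]], st, st + 21)
  cr <- collapse_reads(reads)
  gd <- genome_distribution(cr, list(ga, gb), 0)
  expect_equal(gd$fraction[gd$genome == "hostA"], 1)
  expect_lt(gd$fraction[gd$genome == "hostB"], 0.01)
  expect_lt(gd$fraction[gd$genome == "*unmapped*"], 0.01)
  expect_error(genome_distribution(collapse_reads(character()),
                                   list(ga), 0), "empty")
})

test_that("contaminant fraction is recovered by genome distribution", {
  fx <- fixture_complement()
  contam <- make_genome(30000, seed = 69, name = "bug")
  cfg <- sim_config(seed = 70, n_reads = 10000, adapter = NULL,
                    junk_frac = 0, contam_frac = 0.1)
  sim <- simulate_reads(cfg, fx$complement, contaminant = contam)
  cr <- collapse_reads(unname(sim$reads))
  gd <- genome_distribution(cr, list(contam), 2)
  expect_lt(abs(gd$fraction[gd$genome == "bug"] - 0.1), 0.01)
})

test_that("microbial attribution resolves collections, strands and residual", {
  bugA <- make_genome(20000, seed = 71, name = "phylumA")
  bugB <- make_genome(20000, seed = 72, name = "phylumB")
  set.seed(73)
  st <- sample(19000, 200)
  sense_reads <- substring(bugA$sequences[[1]], st, st + 21)
  anti_reads <- rc_chr(substring(bugA$sequences[[1]], st + 30, st + 51))
  cr <- collapse_reads(c(sense_reads, anti_reads))
  rep_ <- microbes_profile(cr, list(bugA, bugB), 0)
  sa <- rep_$summary[rep_$summary$collection == "phylumA", ]
  expect_identical(sa$sense_reads, length(sense_reads))
  expect_identical(sa$antisense_reads, length(anti_reads))
  expect_equal(sa$percent, 100)
  expect_lt(rep_$summary$percent[rep_$summary$collection == "phylumB"], 1)
  # per-record table sorted by sense count, strands disjoint per read
  recA <- rep_$records$phylumA
  expect_identical(recA$sense_count[1], max(recA$sense_count))

  empty <- microbes_profile(collapse_reads(character()),
                            list(bugA, bugB), 0)
  expect_true(all(empty$summary$percent == 0))
  expect_identical(empty$residual_unmapped_percent, 0)
})
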