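# simdata: seeded synthetic data with full ground truth
#
# Emulates desk-scale small RNA sequencing experiments: a toy genome with a
# planted miRNA complement, raw reads built as
# rand5 + insert + rand3 + 3' adapter (padded to the machine read length)
# under a per-base substitution error model, low-complexity junk reads,
# contaminant reads drawn from a second genome, and auxiliary fixtures
# (target-prediction tables, BLAST-style hit tables).  All outputs are
# fully determined by the seed.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the test suite:
#' 20,000 reads of 51 nt from a 50 kb genome with 30 mature miRNAs of
#' 20-24 nt, a fixed 3' adapter, 1% per-base substitution errors, 20%
#' low-complexity junk and log-normal expression across matures.
#'
#' @param seed integer RNG seed; all outputs are deterministic given it.
#' @param n_reads number of reads.
#' @param genome_len host genome length (nt).
#' @param n_matures number of planted mature miRNAs.
#' @param mature_len length range `c(min, max)` of matures (nt).
#' @param adapter an [adapter_spec()], or `NULL` for pre-trimmed reads
#'   (no adapter, no padding).
#' @param rand5,rand3 randomized-nucleotide lengths flanking the insert.
#' @param error_rate per-base substitution probability.
#' @param junk_frac fraction of low-complexity junk reads.
#' @param contam_frac fraction of reads drawn from the contaminant genome.
#' @param expression log-normal parameters `c(meanlog, sdlog)` of the
#'   relative expression of the matures.
#' @param read_len raw machine read length (nt).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_reads = 20000L, genome_len = 50000L,
                       n_matures = 30L, mature_len = c(20L, 24L),
                       adapter = adapter_spec("truseq",
                                              "TGGAATTCTCGGGTGCCAAGG"),
                       rand5 = 0L, rand3 = 0L, error_rate = 0.01,
                       junk_frac = 0.2, contam_frac = 0,
                       expression = c(meanlog = 2, sdlog = 1),
                       read_len = 51L) {
  stopifnot(junk_frac >= 0, contam_frac >= 0,
            junk_frac + contam_frac <= 1,
            error_rate >= 0, error_rate < 1,
            rand5 >= 0, rand3 >= 0, length(mature_len) == 2L,
            mature_len[1L] <= mature_len[2L])
  if (!is.null(adapter)) stopifnot(inherits(adapter, "adapter_spec"))
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 genome_len = as.integer(genome_len),
                 n_matures = as.integer(n_matures),
                 mature_len = as.integer(mature_len), adapter = adapter,
                 rand5 = as.integer(rand5), rand3 = as.integer(rand3),
                 error_rate = error_rate, junk_frac = junk_frac,
                 contam_frac = contam_frac, expression = expression,
                 read_len = as.integer(read_len)),
            class = "sim_config")
}

#' Generate a toy genome
#'
#' @param length genome length (nt).
#' @param seed RNG seed.
#' @param name record and library name.
#' @return a single-record [ref_library()] of class `"genome"`.
#' @export
make_genome <- function(length, seed = 1L, name = "toy_genome") {
  seq <- withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
  ref_library(setNames(seq, name), name = name, rna_class = "genome")
}

#' Plant a miRNA complement in a genome
#'
#' Picks `n` non-overlapping windows as mature miRNAs, each embedded in a
#' longer hairpin window; ground-truth coordinates are 0-based half-open.
#'
#' @param genome single-record [ref_library()] from [make_genome()].
#' @param n number of matures.
#' @param lengths mature length range `c(min, max)`.
#' @param seed RNG seed.
#' @param hairpin_flank nt added on each side of the mature to form the
#'   hairpin window.
#' @return list with `mature` and `hairpin` [ref_library()] objects and a
#'   `coords` data.frame (`id`, `start`, `end`, `hairpin_id`,
#'   `hairpin_start`, `hairpin_end`).
#' @export
make_mirna_complement <- function(genome, n, lengths = c(20L, 24L),
                                  seed = 1L, hairpin_flank = 20L) {
  stopifnot(inherits(genome, "ref_library"),
            length(genome$sequences) == 1L)
  gseq <- genome$sequences[[1L]]
  glen <- nchar(gseq)
  slot_w <- lengths[2L] + 2L * hairpin_flank + 10L
  n_slots <- glen %/% slot_w
  if (n_slots < n)
    stop("genome too short to place ", n, " non-overlapping hairpins")
  out <- withr::with_seed(seed, {
    slots <- sort(sample.int(n_slots, n))
    mlen <- sample(seq(lengths[1L], lengths[2L]), n, replace = TRUE)
    off <- vapply(mlen, function(l)
      sample.int(slot_w - l - 2L * hairpin_flank, 1L), integer(1))
    start0 <- (slots - 1L) * slot_w + hairpin_flank + off  # 0-based
    list(start0 = start0, mlen = mlen)
  })
  start0 <- out$start0
  mlen <- out$mlen
  mature <- substring(gseq, start0 + 1L, start0 + mlen)
  if (anyDuplicated(mature))
    stop("duplicate mature sequences drawn; use a longer genome or ",
         "another seed")
  hp_start0 <- pmax(0L, start0 - hairpin_flank)
  hp_end0 <- pmin(glen, start0 + mlen + hairpin_flank)
  hairpin <- substring(gseq, hp_start0 + 1L, hp_end0)
  ids <- sprintf("mir-%d", seq_len(n))
  hp_ids <- sprintf("hairpin-%d", seq_len(n))
  list(mature = ref_library(setNames(mature, ids), "mature",
                            rna_class = "mature"),
       hairpin = ref_library(setNames(hairpin, hp_ids), "hairpin",
                             rna_class = "hairpin"),
       coords = data.frame(id = ids, start = start0, end = start0 + mlen,
                           hairpin_id = hp_ids, hairpin_start = hp_start0,
                           hairpin_end = hp_end0))
}

# apply per-base substitution errors to reads; returns list(reads, n_errors)
apply_errors <- function(reads, error_rate) {
  n_err <- rbinom(length(reads), nchar(reads), error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    L <- nchar(reads[i])
    pos <- sample.int(L, min(n_err[i], L))
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  list(reads = reads, n_errors = n_err)
}

# one junk read: a mononucleotide run with <= 10% random substitutions,
# so the complexity ratio is always >= 0.8
make_junk <- function(n, len) {
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  reads <- strrep(base, len)
  k <- sample(0:(len %/% 10L), n, replace = TRUE)
  idx <- which(k > 0L)
  for (i in idx) {
    pos <- sample.int(len, k[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), base[i]), k[i],
                         replace = TRUE)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

# random full-length windows from a multi-record library; strands 50/50
sample_windows <- function(library, n, len_range) {
  seqs <- library$sequences
  w <- nchar(seqs)
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  rec <- sample(seq_along(seqs), n, replace = TRUE, prob = w / sum(w))
  lens <- pmin(lens, w[rec])
  start <- vapply(seq_len(n), function(i)
    sample.int(w[rec[i]] - lens[i] + 1L, 1L), integer(1))
  win <- substring(seqs[rec], start, start + lens - 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  win[strand == "-"] <- revcomp(win[strand == "-"])
  list(window = unname(win), strand = strand,
       record = names(seqs)[rec])
}

#' Simulate a small RNA sequencing run
#'
#' Generates reads according to the configuration: miRNA reads
#' (expression-weighted over the complement), optional contaminant reads
#' (windows of a second genome, either strand), optional additional ncRNA
#' fragment reads, and low-complexity junk.  Non-junk reads are assembled
#' as `rand5 + insert + rand3 + adapter`, padded with random bases to the
#' machine read length (or left as the bare insert when
#' `config$adapter` is `NULL`), then subjected to per-base substitution
#' errors.
#'
#' @param config a [sim_config()].
#' @param complement a [make_mirna_complement()] result.
#' @param contaminant optional contaminant genome ([ref_library()]);
#'   required when `contam_frac > 0`.
#' @param ncrna optional list `list(library = ref_library, frac = <fraction>)`
#'   of an additional small RNA source (e.g. tRNA) sampled as 20-24 nt
#'   fragments.
#' @return list with `reads` (named character vector), `expression` (the
#'   drawn per-mature relative expression weights), `truth` (data.frame
#'   `read_id`, `origin`, `mature_id`, `strand`, `insert`, `n_errors`) and
#'   `config`.
#' @export
simulate_reads <- function(config, complement, contaminant = NULL,
                           ncrna = NULL) {
  stopifnot(inherits(config, "sim_config"))
  p_junk <- config$junk_frac
  p_contam <- config$contam_frac
  p_nc <- if (is.null(ncrna)) 0 else ncrna$frac
  stopifnot(p_junk + p_contam + p_nc <= 1)
  if (p_contam > 0 && is.null(contaminant))
    stop("contam_frac > 0 requires a contaminant genome")
  n <- config$n_reads
  withr::with_seed(config$seed, {
    origin <- sample(c("mirna", "junk", "contam", "ncrna"), n,
                     replace = TRUE,
                     prob = c(1 - p_junk - p_contam - p_nc,
                              p_junk, p_contam, p_nc))
    mature_seq <- complement$mature$sequences
    weights <- rlnorm(length(mature_seq),
                      meanlog = config$expression[["meanlog"]],
                      sdlog = config$expression[["sdlog"]])
    insert <- character(n)
    strand <- rep("+", n)
    mature_id <- rep(NA_character_, n)
    i_mir <- which(origin == "mirna")
    if (length(i_mir)) {
      pick <- sample(seq_along(mature_seq), length(i_mir), replace = TRUE,
                     prob = weights / sum(weights))
      insert[i_mir] <- unname(mature_seq[pick])
      mature_id[i_mir] <- names(mature_seq)[pick]
    }
    i_con <- which(origin == "contam")
    if (length(i_con)) {
      sw <- sample_windows(contaminant, length(i_con), config$mature_len)
      insert[i_con] <- sw$window
      strand[i_con] <- sw$strand
    }
    i_nc <- which(origin == "ncrna")
    if (length(i_nc)) {
      sw <- sample_windows(ncrna$library, length(i_nc), config$mature_len)
      insert[i_nc] <- sw$window
      strand[i_nc] <- sw$strand
    }
    i_seq <- which(origin != "junk")
    reads <- character(n)
    if (length(i_seq)) {
      core <- paste0(rand_dna(length(i_seq), config$rand5),
                     insert[i_seq],
                     rand_dna(length(i_seq), config$rand3))
      if (!is.null(config$adapter)) {
        core <- paste0(core, config$adapter$adapter3)
        pad_needed <- pmax(0L, config$read_len - nchar(core))
        if (any(pad_needed > 0L)) {
          pad <- rand_dna(length(i_seq), max(pad_needed))
          core <- paste0(core, substr(pad, 1L, pad_needed))
        }
        core <- substr(core, 1L, config$read_len)
      }
      err <- apply_errors(core, config$error_rate)
      reads[i_seq] <- err$reads
      n_errors <- integer(n)
      n_errors[i_seq] <- err$n_errors
    } else {
      n_errors <- integer(n)
    }
    i_junk <- which(origin == "junk")
    if (length(i_junk)) {
      junk_len <- if (is.null(config$adapter)) {
        sample(seq(config$mature_len[1L], config$mature_len[2L]),
               length(i_junk), replace = TRUE)
      } else {
        rep(config$read_len, length(i_junk))
      }
      # junk lengths are constant within a run when an adapter is present
      reads[i_junk] <- if (is.null(config$adapter)) {
        vapply(junk_len, function(l) make_junk(1L, l), character(1))
      } else {
        make_junk(length(i_junk), config$read_len)
      }
      n_errors[i_junk] <- NA_integer_
    }
    ids <- sprintf("r%06d", seq_len(n))
    list(reads = setNames(reads, ids),
         expression = setNames(weights, names(mature_seq)),
         truth = data.frame(read_id = ids, origin = origin,
                            mature_id = mature_id, strand = strand,
                            insert = ifelse(origin == "junk",
                                            NA_character_, insert),
                            n_errors = n_errors),
         config = config)
  })
}

#' Write reads as FASTQ / sequences as FASTA
#'
#' @param reads named character vector of sequences.
#' @param path output path; `.gz` supported.  FASTQ qualities are constant
#'   (`I`, Phred 40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- open_out(path)
  on.exit(close(con))
  ids <- names(reads) %||% sprintf("r%06d", seq_along(reads))
  lines <- character(4L * length(reads))
  lines[seq(1L, length(lines), 4L)] <- paste0("@", ids)
  lines[seq(2L, length(lines), 4L)] <- unname(reads)
  lines[seq(3L, length(lines), 4L)] <- "+"
  lines[seq(4L, length(lines), 4L)] <- strrep("I", nchar(reads))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_fasta <- function(reads, path) {
  con <- open_out(path)
  on.exit(close(con))
  ids <- names(reads) %||% sprintf("s%06d", seq_along(reads))
  lines <- character(2L * length(reads))
  lines[c(TRUE, FALSE)] <- paste0(">", ids)
  lines[c(FALSE, TRUE)] <- unname(reads)
  writeLines(lines, con)
  invisible(path)
}

#' Synthetic target-prediction tables with known consensus truth
#'
#' Emits one site table per method under a chosen overlap scenario:
#' `"full"` (every pair predicted by all methods with jittered,
#' always-overlapping sites), `"disjoint"` (all methods predict the pair
#' but in non-overlapping regions), `"partial"` (half full, half
#' disjoint), `"mixed"` (1-3 random sites per method and pair; truth left
#' `NULL`, to be established by exhaustive enumeration).
#'
#' @param n_pairs number of (miRNA, transcript) pairs.
#' @param methods method labels (at least 2).
#' @param scenario overlap scenario.
#' @param seed RNG seed.
#' @param transcript_len transcript length (coordinate upper bound).
#' @return list with `tables` (named list of site data.frames), `truth`
#'   (expected positional-consensus data.frame, or `NULL` for `"mixed"`)
#'   and `scenario`.
#' @export
make_prediction_tables <- function(n_pairs = 12L,
                                   methods = c("methodA", "methodB",
                                               "methodC"),
                                   scenario = c("full", "partial",
                                                "disjoint", "mixed"),
                                   seed = 1L, transcript_len = 1500L) {
  scenario <- match.arg(scenario)
  stopifnot(length(methods) >= 2L)
  withr::with_seed(seed, {
    mirna <- sprintf("mir-%d", seq_len(n_pairs))
    transcript <- sprintf("tx-%d", sample.int(max(3L, n_pairs %/% 2L),
                                              n_pairs, replace = TRUE))
    kind <- switch(scenario,
                   full = rep("full", n_pairs),
                   disjoint = rep("disjoint", n_pairs),
                   partial = rep(c("full", "disjoint"),
                                 length.out = n_pairs),
                   mixed = rep("mixed", n_pairs))
    tables <- setNames(rep(list(NULL), length(methods)), methods)
    truth <- list()
    for (i in seq_len(n_pairs)) {
      if (kind[i] == "mixed") {
        for (m in methods) {
          ns <- sample.int(3L, 1L)
          st <- sample.int(transcript_len - 30L, ns)
          w <- sample(15:25, ns, replace = TRUE)
          tables[[m]] <- rbind(tables[[m]], data.frame(
            mirna_id = mirna[i], transcript_id = transcript[i],
            start = st, end = pmin(st + w, transcript_len),
            score = round(runif(ns), 3)))
        }
        next
      }
      anchor <- sample(50:(transcript_len - 120L), 1L)
      starts <- ends <- integer(length(methods))
      for (mi in seq_along(methods)) {
        if (kind[i] == "full") {
          st <- anchor + sample(-5:5, 1L)
          en <- st + sample(18:24, 1L)
        } else {
          st <- anchor + (mi - 1L) * 60L
          en <- st + sample(18:24, 1L)
        }
        starts[mi] <- st
        ends[mi] <- en
        tables[[methods[mi]]] <- rbind(tables[[methods[mi]]], data.frame(
          mirna_id = mirna[i], transcript_id = transcript[i],
          start = st, end = en, score = round(runif(1L), 3)))
      }
      if (kind[i] == "full") {
        truth[[length(truth) + 1L]] <- data.frame(
          mirna_id = mirna[i], transcript_id = transcript[i],
          consensus_start = max(starts), consensus_end = min(ends))
      }
    }
    truth_df <- if (scenario == "mixed") NULL
    else if (length(truth)) {
      td <- do.call(rbind, truth)
      td[order(td$mirna_id, td$transcript_id, td$consensus_start), ,
         drop = FALSE]
    } else {
      data.frame(mirna_id = character(), transcript_id = character(),
                 consensus_start = integer(), consensus_end = integer())
    }
    list(tables = tables, truth = truth_df, scenario = scenario)
  })
}

#' Synthetic BLAST tabular hit set with species map
#'
#' Random 12-column hit tables used to exercise the disambiguation rules;
#' the expected outcome is established by brute-force rule application in
#' the tests, not planted here.
#'
#' @param n_reads number of query reads.
#' @param n_species number of species.
#' @param max_hits maximum hits per read.
#' @param seed RNG seed.
#' @param frac_unmapped fraction of subject ids left out of the species
#'   map.
#' @return list with `hits` (12-column data.frame, no species) and
#'   `species_map` (data.frame `sseqid`, `species`).
#' @export
make_blast_table <- function(n_reads = 200L, n_species = 6L, max_hits = 5L,
                             seed = 1L, frac_unmapped = 0) {
  withr::with_seed(seed, {
    species <- sprintf("species_%02d", seq_len(n_species))
    subjects <- unlist(lapply(species, function(s)
      paste0(sub("species_", "seq", s), "_", 1:4)))
    smap <- data.frame(sseqid = subjects,
                       species = rep(species, each = 4L))
    rows <- list()
    for (i in seq_len(n_reads)) {
      h <- sample.int(max_hits, 1L)
      ss <- sample(subjects, h, replace = TRUE)
      alen <- sample(18:25, h, replace = TRUE)
      pid <- round(runif(h, 80, 100), 1)
      bs <- round(runif(h, 30, 55), 1)
      rows[[i]] <- data.frame(
        qseqid = sprintf("read_%04d", i), sseqid = ss, pident = pid,
        align_len = alen, mismatches = round(alen * (100 - pid) / 100),
        gap_opens = 0L, qstart = 1L, qend = alen,
        sstart = sample.int(500L, h), send = 0L,
        evalue = signif(10^runif(h, -8, -1), 3), bitscore = bs)
    }
    hits <- do.call(rbind, rows)
    hits$send <- hits$sstart + hits$align_len - 1L
    if (frac_unmapped > 0) {
      drop <- sample(subjects, ceiling(frac_unmapped * length(subjects)))
      smap <- smap[!smap$sseqid %in% drop, , drop = FALSE]
    }
    list(hits = hits, species_map = smap)
  })
}

#' Write a BLAST tabular file
#'
#' @param hits 12-column hit data.frame (as from [make_blast_table()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  write.table(hits[, blast_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
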