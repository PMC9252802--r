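# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the aligner oracle is a position-wise
# sliding-window Hamming scan, the consensus oracle enumerates
# one-site-per-method tuples exhaustively, and the BLAST oracle applies the
# disambiguation rules read by read with plain loops.

# reverse complement without Biostrings
rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all full-length ungapped hits of `queries` (named chr) on `library` with
# <= m mismatches; N never matches.  Sliding-window scan per record.
oracle_hits <- function(queries, library, m, strands = "both") {
  out <- list()
  recs <- lapply(library$sequences, function(s) strsplit(s, "")[[1L]])
  want <- switch(strands, both = c("+", "-"), sense = "+", antisense = "-")
  for (qi in seq_along(queries)) {
    for (s in want) {
      q <- if (s == "+") queries[[qi]] else rc_chr(queries[[qi]])
      qv <- strsplit(q, "")[[1L]]
      L <- length(qv)
      for (ri in seq_along(recs)) {
        g <- recs[[ri]]
        n_win <- length(g) - L + 1L
        if (n_win < 1L) next
        mm <- integer(n_win)
        for (j in seq_len(L)) {
          gj <- g[j:(j + n_win - 1L)]
          mm <- mm + ((gj != qv[j]) | gj == "N" | qv[j] == "N")
        }
        hit <- which(mm <= m)
        if (length(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            query_id = names(queries)[qi],
            ref_id = names(library$sequences)[ri],
            start = hit - 1L, strand = s, mismatches = mm[hit],
            query_len = L)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(query_id = character(), ref_id = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), query_len = integer()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$query_id, df$ref_id, df$start, df$strand), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

hit_key <- function(df) {
  sort(paste(df$query_id, df$ref_id, df$start, df$strand, df$mismatches))
}

# exhaustive positional-consensus oracle: enumerate every one-site-per-
# method tuple, collect the non-empty common intersections, and merge them
# into maximal runs of covered positions
oracle_consensus <- function(method_results, methods = names(method_results)) {
  all_pairs <- unique(do.call(rbind, lapply(method_results[methods],
    function(df) df[, c("mirna_id", "transcript_id")])))
  rows <- list()
  for (i in seq_len(nrow(all_pairs))) {
    per <- lapply(method_results[methods], function(df)
      df[df$mirna_id == all_pairs$mirna_id[i] &
           df$transcript_id == all_pairs$transcript_id[i], , drop = FALSE])
    if (any(vapply(per, nrow, integer(1)) == 0L)) next
    grid <- do.call(expand.grid, lapply(per, function(df) seq_len(nrow(df))))
    covered <- integer()
    for (r in seq_len(nrow(grid))) {
      st <- max(vapply(seq_along(per), function(k)
        per[[k]]$start[grid[r, k]], numeric(1)))
      en <- min(vapply(seq_along(per), function(k)
        per[[k]]$end[grid[r, k]], numeric(1)))
      if (st <= en) covered <- union(covered, st:en)
    }
    if (!length(covered)) next
    covered <- sort(covered)
    brk <- c(0L, which(diff(covered) > 1L), length(covered))
    for (b in seq_len(length(brk) - 1L)) {
      run <- covered[(brk[b] + 1L):brk[b + 1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = all_pairs$mirna_id[i],
        transcript_id = all_pairs$transcript_id[i],
        consensus_start = min(run), consensus_end = max(run))
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      consensus_start = integer(),
                      consensus_end = integer()))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$mirna_id, df$transcript_id, df$consensus_start), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

consensus_key <- function(df) {
  sort(paste(df$mirna_id, df$transcript_id, df$consensus_start,
             df$consensus_end))
}

# brute-force BLAST disambiguation: filter / rank / assign with plain loops
oracle_blast <- function(hits, threshold = 90, inclusive = FALSE) {
  keep <- if (inclusive) hits$pident >= threshold else hits$pident > threshold
  hits <- hits[keep, , drop = FALSE]
  kept <- do.call(rbind, lapply(split(hits, hits$qseqid), function(h) {
    h[h$bitscore == max(h$bitscore), , drop = FALSE]
  }))
  counts <- list()
  for (q in unique(kept$qseqid)) {
    for (sp in unique(kept$species[kept$qseqid == q])) {
      counts[[sp]] <- (counts[[sp]] %||% 0L) + 1L
    }
  }
  ranking <- data.frame(species = names(counts),
                        reads = unlist(counts, use.names = FALSE))
  ranking <- ranking[order(-ranking$reads, ranking$species), , drop = FALSE]
  rownames(ranking) <- NULL
  assignments <- lapply(split(kept, kept$qseqid), function(h) {
    pos <- match(h$species, ranking$species)
    h <- h[pos == min(pos), , drop = FALSE]
    h <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
    h <- h[h$pident == max(h$pident), , drop = FALSE]
    h[which.min(h$.hit_line), , drop = FALSE]
  })
  assignments <- do.call(rbind, assignments)
  rownames(assignments) <- NULL
  list(kept = kept, ranking = ranking,
       assignments = assignments[order(assignments$.hit_line), ,
                                 drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny shared fixtures ------------------------------------------------------

fixture_complement <- function(seed_genome = 101, seed_comp = 102,
                               genome_len = 50000, n = 30) {
  g <- make_genome(genome_len, seed = seed_genome)
  list(genome = g,
       complement = make_mirna_complement(g, n, seed = seed_comp))
}

fixture_trna <- function(seed = 103, n = 20) {
  src <- make_genome(80 * n, seed = seed, name = "trna_src")
  s <- src$sequences[[1L]]
  starts <- seq(1L, by = 80L, length.out = n)
  ref_library(setNames(substring(s, starts, starts + 71L),
                       sprintf("tRNA-%d", seq_len(n))),
              name = "tRNA", rna_class = "tRNA")
}

plant_genomes <- function(queries, pattern, base_seed = 501,
                          genome_len = 6000) {
  # pattern: logical matrix queries x genomes; plants each query verbatim
  n_g <- ncol(pattern)
  lapply(seq_len(n_g), function(j) {
    g <- make_genome(genome_len, seed = base_seed + j,
                     name = sprintf("genome%d", j))
    s <- g$sequences[[1]]
    pos <- 100
    for (qi in which(pattern[, j])) {
      substr(s, pos, pos + nchar(queries[qi]) - 1) <- queries[qi]
      pos <- pos + 60
    }
    ref_library(setNames(s, g$name), g$name, "genome")
  })
}
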