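# Independent brute-force oracles used to verify the optimised
# implementations. Each is written as the most literal possible rendering of
# the declared semantics and shares no code with the package internals.

# Cluster calling: sweep-line chain grouping plus a per-base coverage array
# for peak height and summit.
oracle_clusters <- function(tags) {
  out <- list()
  for (key in unique(paste(tags$stage, tags$chrom, tags$strand))) {
    parts <- strsplit(key, " ")[[1]]
    g <- tags[tags$stage == parts[1] & tags$chrom == parts[2] &
                tags$strand == parts[3], ]
    g <- g[order(g$start, g$end), ]
    # chain grouping: a tag joins the open cluster iff it shares >= 1 base
    cl_id <- integer(nrow(g))
    cur <- 0L
    cur_end <- -Inf
    for (i in seq_len(nrow(g))) {
      if (g$start[i] < cur_end) {
        cl_id[i] <- cur
        cur_end <- max(cur_end, g$end[i])
      } else {
        cur <- cur + 1L
        cl_id[i] <- cur
        cur_end <- g$end[i]
      }
    }
    for (c_i in unique(cl_id)) {
      sub <- g[cl_id == c_i, ]
      lo <- min(sub$start)
      hi <- max(sub$end)
      cov <- integer(hi - lo)
      for (j in seq_len(nrow(sub))) {
        idx <- (sub$start[j] - lo + 1):(sub$end[j] - lo)
        cov[idx] <- cov[idx] + 1L
      }
      ph <- max(cov)
      out[[length(out) + 1]] <- tibble::tibble(
        stage = parts[1], chrom = parts[2], strand = parts[3],
        start = lo, end = hi,
        tag_count = nrow(sub), peak_height = ph,
        summit = lo + which(cov == ph)[1] - 1L,
        replicate_support = length(unique(sub$replicate))
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), stage, chrom, strand, start)
}

# Seed scanner: enumerate every substring against every match string, then
# resolve dominance per 6mer-core locus. Match strings are built with
# Biostrings (independent of the package's base-R reverse complement).
oracle_match_strings <- function(mseq) {
  dna <- chartr("U", "T", toupper(mseq))
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s6 <- substr(dna, 2, 7)
  s7 <- substr(dna, 2, 8)
  c(`6mer` = rc(s6), `7mer-m8` = rc(s7),
    `7mer-A1` = paste0(rc(s6), "A"), `8mer` = paste0(rc(s7), "A"))
}

oracle_scan <- function(seq, catalog) {
  rows <- list()
  for (r in seq_len(nrow(catalog))) {
    ms <- oracle_match_strings(catalog$seq[r])
    found <- list()  # keyed by core position
    for (type in c("6mer", "7mer-A1", "7mer-m8", "8mer")) {
      pat <- ms[[type]]
      L <- nchar(pat)
      if (nchar(seq) < L) next
      for (p in 1:(nchar(seq) - L + 1)) {
        if (substr(seq, p, p + L - 1) == pat) {
          core_pos <- if (type %in% c("7mer-m8", "8mer")) p + 1L else p
          rank <- match(type, c("6mer", "7mer-A1", "7mer-m8", "8mer"))
          key <- as.character(core_pos)
          if (is.null(found[[key]]) || found[[key]]$rank < rank) {
            found[[key]] <- list(rank = rank, type = type, offset = p - 1L,
                                 match = pat)
          }
        }
      }
    }
    for (f in found) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        mirna = catalog$name[r], site_type = f$type, offset = f$offset,
        match = f$match
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(mirna = character(), site_type = character(),
                          offset = integer(), match = character()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), mirna, offset)
}

# One-sided KS statistic straight from the definition, evaluated at every
# pooled sample point.
oracle_ks_D <- function(test, background, alternative = "greater") {
  pts <- sort(c(test, background))
  d <- vapply(pts, function(t) {
    ft <- mean(test <= t)
    fb <- mean(background <= t)
    if (alternative == "greater") fb - ft else ft - fb
  }, numeric(1))
  max(c(0, d))
}

# Exact permutation p by full enumeration of binary label vectors.
oracle_ks_exact_p <- function(test, background, alternative = "greater") {
  m <- length(test)
  pooled <- c(test, background)
  N <- length(pooled)
  D_obs <- oracle_ks_D(test, background, alternative)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N)))
  grid <- grid[rowSums(grid) == m, , drop = FALSE]
  hits <- apply(grid, 1, function(lab) {
    oracle_ks_D(pooled[lab], pooled[!lab], alternative) >= D_obs - 1e-12
  })
  mean(hits)
}

# Peak stitching by repeated pairwise merging until fixpoint.
oracle_stitch <- function(peaks, stitch_distance) {
  regs <- lapply(seq_len(nrow(peaks)), function(i) {
    list(chrom = peaks$chrom[i], start = peaks$start[i], end = peaks$end[i],
         signal = peaks$score[i], n = 1L)
  })
  repeat {
    merged <- FALSE
    for (i in seq_along(regs)) {
      for (j in seq_along(regs)) {
        if (i >= j) next
        a <- regs[[i]]; b <- regs[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap <= stitch_distance) {
          regs[[i]] <- list(chrom = a$chrom,
                            start = min(a$start, b$start),
                            end = max(a$end, b$end),
                            signal = a$signal + b$signal, n = a$n + b$n)
          regs[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  dplyr::arrange(dplyr::bind_rows(lapply(regs, tibble::as_tibble)),
                 chrom, start)
}

# Sliding-window k-mer counter.
oracle_kmer_count <- function(seqs, kmer) {
  k <- nchar(kmer)
  sum(vapply(seqs, function(s) {
    if (nchar(s) < k) return(0L)
    sum(vapply(1:(nchar(s) - k + 1),
               function(p) substr(s, p, p + k - 1) == kmer, logical(1)))
  }, integer(1)))
}

dinuc_counts <- function(s) {
  chars <- strsplit(s, "")[[1]]
  if (length(chars) < 2) return(table(character(0)))
  table(paste0(chars[-length(chars)], chars[-1]))
}
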