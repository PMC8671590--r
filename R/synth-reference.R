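#' Generate a miniature reference with planted miRNA target sites
#'
#' Builds a self-contained reference bundle for simulation: a random genome,
#' non-overlapping single-exon gene models (5'UTR/CDS/3'UTR on one strand), a
#' miRNA catalog with one enriched developmental stage per miRNA, miRNA locus
#' TSS positions, and a table of planted seed-match sites whose exact match
#' string has been written into the genome on the transcript strand.
#'
#' Coordinates in the returned tibbles are 0-based half-open (BED convention);
#' [write_reference()] exports the GTF 1-based inclusive per the GTF standard.
#'
#' @param config A [synth_config()] object.
#' @return A list of class `agoclip_reference` with elements `genome`
#'   (a [Biostrings::DNAStringSet]), `genes`, `mirnas`, `sites` (the planted
#'   ground truth), `tss`, `stages` and `config`.
#' @export
#' @examples
#' ref <- generate_reference(synth_config(rng_seed = 7, n_genes = 6, n_mirnas = 3))
#' ref$sites
generate_reference <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(derive_seed(config$rng_seed, 101L), {
    chroms <- sprintf("chrS%d", seq_len(config$n_chroms))

    genome_chars <- lapply(chroms, function(ch) {
      sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE)
    })
    names(genome_chars) <- chroms

    genes <- place_genes(config, chroms)
    mirnas <- make_mirna_catalog(config, chroms)
    sites <- plant_sites(config, genes, mirnas)

    # Write each planted match string into the genome on the reference strand.
    if (nrow(sites) > 0) {
      for (i in seq_len(nrow(sites))) {
        s <- sites[i, ]
        ref_str <- if (s$strand == "+") s$match else revcomp_dna(s$match)
        genome_chars[[s$chrom]][(s$start + 1):s$end] <-
          strsplit(ref_str, "")[[1]]
      }
    }

    genome <- Biostrings::DNAStringSet(
      vapply(genome_chars, paste, character(1), collapse = "")
    )
    names(genome) <- chroms

    tss <- dplyr::bind_rows(
      if (nrow(genes) > 0) {
        tibble::tibble(
          id = genes$gene_id,
          class = "gene",
          chrom = genes$chrom,
          position = ifelse(genes$strand == "+", genes$start, genes$end - 1L),
          strand = genes$strand
        )
      },
      if (nrow(mirnas) > 0) {
        tibble::tibble(
          id = mirnas$name,
          class = "miRNA",
          chrom = mirnas$chrom,
          position = mirnas$tss,
          strand = mirnas$strand
        )
      }
    )

    structure(
      list(
        genome = genome,
        genes = genes,
        mirnas = mirnas,
        sites = sites,
        tss = tss,
        stages = config$stages,
        config = config
      ),
      class = "agoclip_reference"
    )
  })
}

# Place non-overlapping gene models along the chromosomes, round-robin, with
# random gaps. Errors if the chromosomes cannot host all genes.
place_genes <- function(config, chroms) {
  n <- config$n_genes
  if (n == 0) {
    return(tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(),
      utr5_start = integer(), utr5_end = integer(),
      cds_start = integer(), cds_end = integer(),
      utr3_start = integer(), utr3_end = integer()
    ))
  }
  u5 <- sample(100:250, n, replace = TRUE)
  cds <- sample(600:1200, n, replace = TRUE)
  u3 <- sample(300:700, n, replace = TRUE)
  span <- u5 + cds + u3
  chrom_of <- chroms[((seq_len(n) - 1L) %% length(chroms)) + 1L]
  min_gap <- 2000L

  rows <- vector("list", n)
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    if (length(idx) == 0) next
    need <- sum(span[idx]) + min_gap * (length(idx) + 1L)
    if (need > config$chrom_length) {
      rlang::abort(sprintf(
        paste0("chrom_length (%d) too small to place %d gene(s) on %s: ",
               "need at least %d bases (gene spans + %d bp minimum gaps)"),
        config$chrom_length, length(idx), ch, need, min_gap
      ))
    }
    slack <- config$chrom_length - need
    # Stick-breaking over the slack so gaps vary but layout always fits.
    cuts <- sort(runif(length(idx), 0, slack))
    extra <- diff(c(0, cuts))
    pos <- 0L
    for (j in seq_along(idx)) {
      i <- idx[j]
      gstart <- as.integer(pos + min_gap + extra[j])
      gend <- gstart + span[i]
      strand <- sample(c("+", "-"), 1)
      if (strand == "+") {
        reg <- c(utr5_start = gstart, utr5_end = gstart + u5[i],
                 cds_start = gstart + u5[i], cds_end = gstart + u5[i] + cds[i],
                 utr3_start = gstart + u5[i] + cds[i], utr3_end = gend)
      } else {
        reg <- c(utr5_start = gend - u5[i], utr5_end = gend,
                 cds_start = gend - u5[i] - cds[i], cds_end = gend - u5[i],
                 utr3_start = gstart, utr3_end = gstart + u3[i])
      }
      rows[[i]] <- tibble::tibble(
        gene_id = sprintf("gene%03d", i), chrom = ch, strand = strand,
        start = gstart, end = gend,
        utr5_start = reg[["utr5_start"]], utr5_end = reg[["utr5_end"]],
        cds_start = reg[["cds_start"]], cds_end = reg[["cds_end"]],
        utr3_start = reg[["utr3_start"]], utr3_end = reg[["utr3_end"]]
      )
      pos <- gend
    }
  }
  dplyr::bind_rows(rows)
}

make_mirna_catalog <- function(config, chroms) {
  n <- config$n_mirnas
  if (n == 0) {
    return(tibble::tibble(
      name = character(), seq = character(), enriched_stage = character(),
      chrom = character(), tss = integer(), strand = character()
    ))
  }
  lens <- sample(20:24, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
  }, character(1))
  tibble::tibble(
    name = sprintf("mir-%03d", seq_len(n)),
    seq = seqs,
    enriched_stage = config$stages[((seq_len(n) - 1L) %% length(config$stages)) + 1L],
    chrom = sample(chroms, n, replace = TRUE),
    tss = as.integer(floor(runif(n, 0, config$chrom_length - 1))),
    strand = "+"
  )
}

# Choose (gene, region) slots without replacement and a site type for each
# planted site; one site at most per gene region keeps edits disjoint.
plant_sites <- function(config, genes, mirnas) {
  empty <- tibble::tibble(
    mirna = character(), gene_id = character(), region = character(),
    site_type = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), match = character(),
    active_stages = character()
  )
  n_sites <- config$n_mirnas * config$sites_per_mirna
  if (n_sites == 0 || nrow(genes) == 0) return(empty)

  slots <- tidyr::expand_grid(
    gene_id = genes$gene_id,
    region = c("3UTR", "CDS", "5UTR")
  )
  if (n_sites > nrow(slots)) {
    rlang::abort(sprintf(
      "cannot plant %d sites: only %d (gene, region) slots available; increase n_genes",
      n_sites, nrow(slots)
    ))
  }
  w <- config$region_weights[slots$region]
  picked <- slots[sample.int(nrow(slots), n_sites, prob = w), ]
  picked$mirna <- rep(mirnas$name, each = config$sites_per_mirna)
  picked$site_type <- sample(.site_types, n_sites, replace = TRUE)

  rows <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    g <- genes[genes$gene_id == picked$gene_id[i], ]
    m <- mirnas[mirnas$name == picked$mirna[i], ]
    ms <- seed_match_strings(m$seq)
    match_str <- ms$match[ms$site_type == picked$site_type[i]]
    L <- nchar(match_str)
    reg <- switch(picked$region[i],
      "3UTR" = c(g$utr3_start, g$utr3_end),
      "CDS" = c(g$cds_start, g$cds_end),
      "5UTR" = c(g$utr5_start, g$utr5_end)
    )
    # keep a margin so the site sits strictly inside the region
    lo <- reg[1] + 10L
    hi <- reg[2] - 10L - L
    pos <- as.integer(floor(runif(1, lo, hi + 1)))
    rows[[i]] <- tibble::tibble(
      mirna = m$name, gene_id = g$gene_id, region = picked$region[i],
      site_type = picked$site_type[i], chrom = g$chrom,
      start = pos, end = pos + L, strand = g$strand, match = match_str,
      active_stages = m$enriched_stage
    )
  }
  dplyr::bind_rows(rows)
}

#' @export
print.agoclip_reference <- function(x, ...) {
  cat("<agoclip_reference>\n")
  cat(sprintf("  genome: %d chrom(s) x %d bp\n",
              length(x$genome), x$config$chrom_length))
  cat(sprintf("  %d gene(s), %d miRNA(s), %d planted site(s)\n",
              nrow(x$genes), nrow(x$mirnas), nrow(x$sites)))
  invisible(x)
}

#' Derive the transcript-feature table of a synthetic reference
#'
#' Returns the flat feature table ([annotate_clusters()] input) for the gene
#' models of a synthetic reference: one row per 5'UTR/CDS/3'UTR interval.
#'
#' @param reference An `agoclip_reference`.
#' @return Tibble with columns `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `feature`, `start`, `end` (0-based half-open).
#' @export
gene_feature_table <- function(reference) {
  stopifnot(inherits(reference, "agoclip_reference"))
  g <- reference$genes
  if (nrow(g) == 0) {
    return(tibble::tibble(
      gene_id = character(), transcript_id = character(), chrom = character(),
      strand = character(), feature = character(),
      start = integer(), end = integer()
    ))
  }
  dplyr::bind_rows(
    tibble::tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                   feature = "5UTR", start = g$utr5_start, end = g$utr5_end),
    tibble::tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                   feature = "CDS", start = g$cds_start, end = g$cds_end),
    tibble::tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                   feature = "3UTR", start = g$utr3_start, end = g$utr3_end)
  ) |>
    dplyr::mutate(transcript_id = paste0(.data$gene_id, ".t1"), .after = "gene_id") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Export a synthetic reference bundle to standard files
#'
#' Writes `genome.fa` (genome FASTA), `genes.gtf` (GTF 2.2, 1-based inclusive,
#' exon + CDS features), `mirnas.fa` (mature miRNA FASTA, U alphabet),
#' `tss.tsv` and `planted_sites.tsv` (the ground-truth table).
#'
#' @param reference An `agoclip_reference`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the paths written.
#' @export
write_reference <- function(reference, dir) {
  stopifnot(inherits(reference, "agoclip_reference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "genes.gtf"),
    mirnas = file.path(dir, "mirnas.fa"),
    tss = file.path(dir, "tss.tsv"),
    sites = file.path(dir, "planted_sites.tsv")
  )
  Biostrings::writeXStringSet(reference$genome, paths[["genome"]])

  g <- reference$genes
  feats <- gene_feature_table(reference)
  if (nrow(g) > 0) {
    exon <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
      type = "exon", gene_id = g$gene_id,
      transcript_id = paste0(g$gene_id, ".t1")
    )
    cds_rows <- feats[feats$feature == "CDS", ]
    cds <- GenomicRanges::GRanges(
      cds_rows$chrom, IRanges::IRanges(cds_rows$start + 1L, cds_rows$end),
      strand = cds_rows$strand, type = "CDS", gene_id = cds_rows$gene_id,
      transcript_id = cds_rows$transcript_id, phase = 0L
    )
    rtracklayer::export(c(exon, cds), paths[["gtf"]], format = "gtf")
  } else {
    writeLines(character(0), paths[["gtf"]])
  }

  if (nrow(reference$mirnas) > 0) {
    mi <- Biostrings::RNAStringSet(reference$mirnas$seq)
    names(mi) <- reference$mirnas$name
    Biostrings::writeXStringSet(mi, paths[["mirnas"]])
  } else {
    writeLines(character(0), paths[["mirnas"]])
  }
  readr::write_tsv(reference$tss, paths[["tss"]])
  readr::write_tsv(reference$sites, paths[["sites"]])
  invisible(paths)
}
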