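#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles each sequence while preserving its exact dinucleotide (and hence
#' mononucleotide) composition, via a random Euler path on the dinucleotide
#' transition multigraph (Altschul-Erickson construction). First and last
#' letters are invariant, as required by the construction. Draws from R's RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param seqs Character vector of (uppercase) sequences.
#' @return Character vector of shuffled sequences, same lengths and
#'   dinucleotide counts as the inputs.
#' @export
#' @examples
#' set.seed(1)
#' dinucleotide_shuffle("ACGTACGTAAGG")
dinucleotide_shuffle <- function(seqs) {
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(chars) <= 3) return(s)
    alphabet <- sort(unique(chars))
    code <- match(chars, alphabet) - 1L
    shuffled <- dinuc_shuffle_cpp(code, length(alphabet))
    paste(alphabet[shuffled + 1L], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' k-mer enrichment against dinucleotide-shuffled backgrounds
#'
#' Counts every overlapping k-mer occurrence across the input sequences, then
#' builds a per-k-mer null distribution from `n_shuffles` rounds of
#' per-sequence dinucleotide-preserving shuffles, and scores enrichment as
#' `z = (observed - background mean) / background sd`. A k-mer whose
#' background sd is zero (e.g. in shuffle-invariant sequences) gets `z = 0`:
#' it is unenrichable under this background. Rows are sorted by decreasing z,
#' ties broken lexicographically by k-mer.
#'
#' @param seqs Character vector of uppercase DNA sequences; sequences shorter
#'   than `k` are skipped with a warning.
#' @param k k-mer length, between 5 and 8 (default 7, the seed-match length).
#' @param n_shuffles Number of shuffle rounds (>= 20; default 100).
#' @param rng_seed Integer seed making the background reproducible.
#' @return Tibble with `kmer`, `observed`, `bg_mean`, `bg_sd`, `z`, covering
#'   all 4^k DNA k-mers.
#' @export
kmer_enrichment <- function(seqs, k = 7, n_shuffles = 100, rng_seed = 1) {
  assert_scalar_number(k, "k", min = 5, max = 8)
  assert_scalar_number(n_shuffles, "n_shuffles", min = 20)
  if (length(seqs) == 0) rlang::abort("no sequences supplied")
  if (any(grepl("[^ACGT]", seqs))) {
    rlang::abort("sequences must be uppercase DNA over {A,C,G,T}")
  }
  short <- nchar(seqs) < k
  if (any(short)) {
    rlang::warn(sprintf("skipping %d sequence(s) shorter than k = %d",
                        sum(short), k))
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0) {
    rlang::abort(sprintf("all sequences are shorter than k = %d", k))
  }

  count_kmers <- function(ss) {
    colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(ss), width = k
    ))
  }
  observed <- count_kmers(seqs)

  with_local_seed(rng_seed, {
    acc <- numeric(length(observed))
    acc2 <- numeric(length(observed))
    for (i in seq_len(n_shuffles)) {
      cnt <- count_kmers(dinucleotide_shuffle(seqs))
      acc <- acc + cnt
      acc2 <- acc2 + cnt^2
    }
    bg_mean <- acc / n_shuffles
    bg_var <- pmax(0, (acc2 - n_shuffles * bg_mean^2) / (n_shuffles - 1))
    bg_sd <- sqrt(bg_var)
    z <- ifelse(bg_sd > 0, (observed - bg_mean) / bg_sd, 0)
    tibble::tibble(
      kmer = names(observed),
      observed = as.numeric(observed),
      bg_mean = bg_mean, bg_sd = bg_sd, z = z
    ) |>
      dplyr::arrange(dplyr::desc(.data$z), .data$kmer)
  })
}

#' Match enriched k-mers to miRNA seed complements
#'
#' Annotates a [kmer_enrichment()] table with the expressed miRNAs whose
#' canonical seed-match strings ([seed_match_strings()]) are contained in (or
#' equal to) each k-mer.
#'
#' @param kmer_table [kmer_enrichment()] output.
#' @param catalog miRNA tibble (`name`, `seq`).
#' @param expressed Optional character vector restricting the catalog to
#'   expressed miRNAs (`NULL` keeps all).
#' @return `kmer_table` with a `matched_mirnas` column (comma-separated names;
#'   empty string when nothing matches).
#' @export
match_motifs_to_seeds <- function(kmer_table, catalog, expressed = NULL) {
  assert_cols(kmer_table, "kmer")
  assert_cols(catalog, c("name", "seq"))
  if (!is.null(expressed)) catalog <- catalog[catalog$name %in% expressed, ]
  if (nrow(catalog) == 0) {
    return(dplyr::mutate(kmer_table, matched_mirnas = ""))
  }
  per_mirna <- purrr::map2(catalog$name, catalog$seq, function(name, mseq) {
    strings <- seed_match_strings(mseq)$match
    strings <- strings[nchar(strings) <= max(nchar(kmer_table$kmer))]
    if (length(strings) == 0) return(rep(FALSE, nrow(kmer_table)))
    Reduce(`|`, lapply(strings, function(p) {
      stringr::str_detect(kmer_table$kmer, stringr::fixed(p))
    }))
  })
  hits <- do.call(cbind, per_mirna)
  matched <- apply(hits, 1, function(row) {
    paste(catalog$name[row], collapse = ",")
  })
  dplyr::mutate(kmer_table, matched_mirnas = matched)
}
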