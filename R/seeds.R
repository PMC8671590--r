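#' Canonical seed-match strings of a miRNA
#'
#' Computes the four canonical target-site match strings on the mRNA sense
#' strand (5'->3', DNA alphabet) from a mature miRNA sequence: the 6mer is the
#' reverse complement of seed positions 2-7, the 7mer-m8 the reverse
#' complement of positions 2-8, the 7mer-A1 the 6mer followed by an `A`
#' anchor, and the 8mer the 7mer-m8 followed by the `A` anchor. The `A` is
#' required in the mRNA regardless of the miRNA's position-1 identity
#' (TargetScan-style anchor).
#'
#' @param seq Mature miRNA sequence, 5'->3', RNA alphabet (`A`, `C`, `G`,
#'   `U`), length >= 8.
#' @return Tibble with `site_type` (`8mer`, `7mer-m8`, `7mer-A1`, `6mer`) and
#'   `match` (DNA string).
#' @export
#' @examples
#' seed_match_strings("UGGACCCUAGG")
seed_match_strings <- function(seq) {
  if (!is.character(seq) || length(seq) != 1) {
    rlang::abort("`seq` must be a single miRNA sequence string")
  }
  seq <- toupper(seq)
  if (nchar(seq) < 8) rlang::abort("miRNA sequence must be at least 8 nt")
  if (grepl("[^ACGU]", seq)) {
    rlang::abort("miRNA sequence must use the RNA alphabet {A,C,G,U}")
  }
  seed6 <- substr(seq, 2, 7)
  seed7 <- substr(seq, 2, 8)
  rc <- function(s) revcomp_dna(chartr("U", "T", s))
  tibble::tibble(
    site_type = .site_types,
    match = c(paste0(rc(seed7), "A"), rc(seed7), paste0(rc(seed6), "A"),
              rc(seed6))
  )
}

#' Scan a sense-strand sequence for canonical miRNA seed sites
#'
#' Finds every seed-match locus of every catalog miRNA in `seq` (given in
#' transcript, i.e. sense, orientation). Overlapping occurrences are all
#' reported, but at any one locus only the strongest satisfied site type is
#' kept (8mer > 7mer-m8 > 7mer-A1 > 6mer); a locus is identified by the
#' position of its 6mer seed-complement core. Results are in deterministic
#' left-to-right order per miRNA.
#'
#' @param seq Uppercase DNA string (may be empty).
#' @param catalog Tibble with `name` and `seq` (mature miRNA, RNA alphabet),
#'   e.g. `reference$mirnas`.
#' @return Tibble with `mirna`, `site_type`, `offset` (0-based start of the
#'   matched string within `seq`) and `match`.
#' @export
#' @examples
#' catalog <- tibble::tibble(name = "mir-x", seq = "UGGACCCUAGGCAGUGA")
#' scan_sequence("TTAGGGTCCATT", catalog)
scan_sequence <- function(seq, catalog) {
  assert_cols(catalog, c("name", "seq"))
  empty <- tibble::tibble(mirna = character(), site_type = character(),
                          offset = integer(), match = character())
  if (length(seq) != 1 || is.na(seq)) rlang::abort("`seq` must be one string")
  if (nchar(seq) < 6 || nrow(catalog) == 0) return(empty)

  seeds <- seed_cores(catalog)
  out <- purrr::map(seq_len(nrow(seeds)), function(i) {
    core <- seeds$core[i]
    m8 <- seeds$m8[i]
    # all (overlapping) core occurrences, 1-based starts
    pos <- gregexpr(paste0("(?=", core, ")"), seq, perl = TRUE)[[1]]
    if (pos[1] == -1) return(NULL)
    pos <- as.integer(pos)
    has_m8 <- pos > 1 & substring(seq, pos - 1, pos - 1) == m8
    has_a1 <- pos + 6 <= nchar(seq) & substring(seq, pos + 6, pos + 6) == "A"
    site_type <- dplyr::case_when(
      has_m8 & has_a1 ~ "8mer",
      has_m8 ~ "7mer-m8",
      has_a1 ~ "7mer-A1",
      TRUE ~ "6mer"
    )
    offset <- ifelse(site_type %in% c("8mer", "7mer-m8"), pos - 2L, pos - 1L)
    match_str <- dplyr::case_when(
      site_type == "8mer" ~ paste0(m8, core, "A"),
      site_type == "7mer-m8" ~ paste0(m8, core),
      site_type == "7mer-A1" ~ paste0(core, "A"),
      TRUE ~ core
    )
    tibble::tibble(
      mirna = seeds$name[i], site_type = site_type,
      offset = as.integer(offset), match = match_str
    )
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0) empty else dplyr::arrange(out, .data$mirna, .data$offset)
}

# Vectorised seed-core table for a catalog: the 6mer core (reverse complement
# of seed positions 2-7, DNA) and the m8 flanking base (complement of
# position 8).
seed_cores <- function(catalog) {
  seqs <- toupper(catalog$seq)
  bad <- grepl("[^ACGU]", seqs) | nchar(seqs) < 8
  if (any(bad)) {
    rlang::abort(sprintf(
      "miRNA(s) with invalid sequence (need >= 8 nt over {A,C,G,U}): %s",
      paste(head(catalog$name[bad], 5), collapse = ", ")
    ))
  }
  dna <- chartr("U", "T", seqs)
  tibble::tibble(
    name = catalog$name,
    core = revcomp_dna(substr(dna, 2, 7)),
    m8 = chartr("ACGT", "TGCA", substr(dna, 8, 8))
  )
}
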