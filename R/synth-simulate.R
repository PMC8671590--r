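#' Simulate aligned CLIP tags over a synthetic reference
#'
#' Draws strand-aware CLIP tags for every (stage, replicate) combination: each
#' planted site receives `Poisson(site_rate x stage activity)` tags per
#' replicate, each fully covering the site, plus a homogeneous Poisson
#' background along every chromosome strand. Tag lengths follow a discretised
#' Normal(`tag_len_mean`, `tag_len_sd`) clipped to \[18, 40\], so the default
#' modal tag length is 22 nt. A site's activity is 1 in its miRNA's enriched
#' stage and `off_activity` elsewhere.
#'
#' @param reference An `agoclip_reference` from [generate_reference()].
#' @param config A [synth_config()]; defaults to the one inside `reference`.
#' @return A list with `tags` (tibble: `chrom`, `start`, `end`, `name`,
#'   `strand`, `stage`, `replicate`; 0-based half-open) and `truth` (the
#'   planted-site table).
#' @export
simulate_clip_tags <- function(reference, config = reference$config) {
  stopifnot(inherits(reference, "agoclip_reference"),
            inherits(config, "synth_config"))
  sites <- reference$sites
  chrom_len <- config$chrom_length

  with_local_seed(derive_seed(config$rng_seed, 202L), {
    out <- list()
    for (stage in config$stages) {
      for (rep_i in seq_len(config$n_replicates)) {
        site_tags <- NULL
        if (nrow(sites) > 0) {
          act <- ifelse(
            vapply(strsplit(sites$active_stages, ","),
                   function(s) stage %in% s, logical(1)),
            1, config$off_activity
          )
          n_per_site <- rpois(nrow(sites), config$site_rate * act)
          idx <- rep(seq_len(nrow(sites)), n_per_site)
          if (length(idx) > 0) {
            L <- draw_tag_lengths(length(idx), config)
            # start uniform over positions where the tag fully covers the site
            lo <- sites$end[idx] - L
            hi <- sites$start[idx]
            start <- as.integer(floor(runif(length(idx), lo, hi + 1)))
            start <- pmax(0L, pmin(start, chrom_len - L))
            site_tags <- tibble::tibble(
              chrom = sites$chrom[idx], start = start, end = start + L,
              strand = sites$strand[idx]
            )
          }
        }
        bg_tags <- NULL
        if (config$background_rate > 0) {
          grid <- tidyr::expand_grid(
            chrom = names(reference$genome), strand = c("+", "-")
          )
          n_bg <- rpois(nrow(grid), config$background_rate * chrom_len / 1000)
          bidx <- rep(seq_len(nrow(grid)), n_bg)
          if (length(bidx) > 0) {
            L <- draw_tag_lengths(length(bidx), config)
            start <- as.integer(floor(runif(length(bidx), 0, chrom_len - L)))
            bg_tags <- tibble::tibble(
              chrom = grid$chrom[bidx], start = start, end = start + L,
              strand = grid$strand[bidx]
            )
          }
        }
        tags <- dplyr::bind_rows(site_tags, bg_tags)
        if (nrow(tags) > 0) {
          tags$stage <- stage
          tags$replicate <- rep_i
        }
        out[[paste(stage, rep_i, sep = "_")]] <- tags
      }
    }
    tags <- dplyr::bind_rows(out)
    if (nrow(tags) > 0) {
      tags <- tags |>
        dplyr::arrange(.data$stage, .data$replicate, .data$chrom, .data$start) |>
        dplyr::mutate(name = sprintf("tag%07d", dplyr::row_number()),
                      .after = "end")
    } else {
      tags <- tibble::tibble(
        chrom = character(), start = integer(), end = integer(),
        name = character(), strand = character(), stage = character(),
        replicate = integer()
      )
    }
    list(tags = tags, truth = sites)
  })
}

draw_tag_lengths <- function(n, config) {
  L <- as.integer(round(rnorm(n, config$tag_len_mean, config$tag_len_sd)))
  pmin(pmax(L, 18L), 40L)
}

#' Simulate Ago-bound miRNA tag counts per stage and replicate
#'
#' Each miRNA gets a baseline abundance (log-normal across the catalog) and is
#' enriched in exactly one stage; counts are Poisson draws around
#' `baseline x activity`, with activity 1 in the enriched stage and
#' `off_activity` elsewhere.
#'
#' @inheritParams simulate_clip_tags
#' @param mean_count Expected count scale for an enriched miRNA of median
#'   baseline.
#' @return Tibble with `mirna`, `stage`, `replicate`, `count`.
#' @export
simulate_mirna_counts <- function(reference, config = reference$config,
                                  mean_count = 200) {
  stopifnot(inherits(reference, "agoclip_reference"))
  mi <- reference$mirnas
  if (nrow(mi) == 0) {
    return(tibble::tibble(mirna = character(), stage = character(),
                          replicate = integer(), count = integer()))
  }
  with_local_seed(derive_seed(config$rng_seed, 303L), {
    baseline <- mean_count * exp(rnorm(nrow(mi), 0, 1))
    grid <- tidyr::expand_grid(
      i = seq_len(nrow(mi)),
      stage = config$stages,
      replicate = seq_len(config$n_replicates)
    )
    act <- ifelse(mi$enriched_stage[grid$i] == grid$stage, 1, config$off_activity)
    tibble::tibble(
      mirna = mi$name[grid$i],
      stage = grid$stage,
      replicate = grid$replicate,
      count = rpois(nrow(grid), baseline[grid$i] * act)
    )
  })
}

#' Simulate gene-level log2 fold changes as N(shift, sigma) / N(0, sigma)
#'
#' Low-level sampler behind [simulate_ko_expression()]: genes in `targets` are
#' drawn from `Normal(shift, sigma)`, all other genes from `Normal(0, sigma)`.
#'
#' @param universe Character vector of all gene ids (each appears once).
#' @param targets Character vector of true-target gene ids (subset of
#'   `universe`).
#' @param shift,sigma Planted mean log2FC for targets and common noise sd.
#' @param seed Integer RNG seed.
#' @return Tibble with `gene_id`, `log2fc`.
#' @export
simulate_log2fc <- function(universe, targets, shift, sigma, seed) {
  if (length(universe) == 0) rlang::abort("gene universe is empty")
  if (anyDuplicated(universe)) rlang::abort("`universe` has duplicated gene ids")
  unknown <- setdiff(targets, universe)
  if (length(unknown) > 0) {
    rlang::abort(sprintf(
      "target gene id(s) absent from the expression universe: %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  with_local_seed(seed, {
    is_target <- universe %in% targets
    tibble::tibble(
      gene_id = universe,
      log2fc = rnorm(length(universe), mean = ifelse(is_target, shift, 0),
                     sd = sigma)
    )
  })
}

#' Simulate a knockout expression-change table for one miRNA
#'
#' Genes carrying a planted site for `ko_mirna` (true targets) are de-repressed
#' by `ko_shift` on the log2 scale; all other genes are centred at zero.
#'
#' @inheritParams simulate_clip_tags
#' @param ko_mirna Name of the knocked-out miRNA (must be in the catalog).
#' @return Tibble with `gene_id`, `log2fc`, `is_target`.
#' @export
simulate_ko_expression <- function(reference, ko_mirna,
                                   config = reference$config) {
  stopifnot(inherits(reference, "agoclip_reference"))
  if (!ko_mirna %in% reference$mirnas$name) {
    rlang::abort(sprintf("unknown miRNA `%s` in catalog", ko_mirna))
  }
  truth <- reference$sites
  unknown <- setdiff(truth$gene_id, reference$genes$gene_id)
  if (length(unknown) > 0) {
    rlang::abort(sprintf(
      "truth table references unknown gene id(s): %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  targets <- unique(truth$gene_id[truth$mirna == ko_mirna])
  fc <- simulate_log2fc(
    reference$genes$gene_id, targets,
    shift = config$ko_shift, sigma = config$ko_sigma,
    seed = derive_seed(config$rng_seed, 404L)
  )
  fc$is_target <- fc$gene_id %in% targets
  fc
}

#' Simulate an H3K27ac peak landscape with planted super-enhancers
#'
#' Plants `n_h3k27ac_regions` well-separated constituent-peak groups: a
#' fraction `se_fraction` are super-enhancers with per-peak signal drawn from a
#' high-mean component (>= 10x the typical mean) and placed near a designated
#' miRNA TSS (within the assignment window); the rest are typical enhancers.
#' Groups are spaced so that stitching at the default 12.5 kb distance returns
#' exactly the planted regions. When `stages` is supplied, each super-enhancer
#' is "on" (high signal) only in its designated miRNA's enriched stage and
#' typical elsewhere, emulating stage-dynamic super-enhancer landscapes.
#'
#' @inheritParams simulate_clip_tags
#' @param stages Optional character vector of stage labels; `NULL` (default)
#'   produces a single pooled landscape with every planted SE active.
#' @param low_mean,high_mean Mean constituent-peak signal of the typical and
#'   super-enhancer components (`high_mean >= 10 * low_mean` enforced).
#' @return A list with `peaks` (tibble: `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, and `stage` when staged) and `truth` (planted regions:
#'   `region_id`, `chrom`, `start`, `end`, `is_SE`, `mirna`, `tss_distance`,
#'   `active_stages`).
#' @export
simulate_h3k27ac <- function(reference, config = reference$config,
                             stages = NULL, low_mean = 10, high_mean = 150) {
  stopifnot(inherits(reference, "agoclip_reference"))
  if (high_mean < 10 * low_mean) {
    rlang::abort("`high_mean` must be at least 10x `low_mean`")
  }
  n_regions <- config$n_h3k27ac_regions
  n_se <- round(config$se_fraction * n_regions)
  chroms <- names(reference$genome)
  chrom_len <- config$chrom_length

  slots_per_chrom <- max(3L, ceiling(1.2 * n_regions / length(chroms)))
  spacing <- floor(chrom_len / (slots_per_chrom + 1))
  if (spacing < 24000) {
    rlang::abort(sprintf(
      paste0("chrom_length (%d) too small for %d stitched regions: regions ",
             "need >= 24 kb spacing to stay distinct after 12.5 kb stitching"),
      chrom_len, n_regions
    ))
  }

  with_local_seed(derive_seed(config$rng_seed, 505L), {
    slots <- tidyr::expand_grid(chrom = chroms, j = seq_len(slots_per_chrom)) |>
      dplyr::mutate(center = as.integer(.data$j * spacing))

    # Designate SE miRNAs whose TSS has a free slot nearby (same chrom).
    se_rows <- NULL
    if (n_se > 0) {
      mi <- reference$mirnas[sample.int(nrow(reference$mirnas)), ]
      taken <- logical(nrow(slots))
      picks <- list()
      for (i in seq_len(nrow(mi))) {
        if (length(picks) == n_se) break
        on_chrom <- which(slots$chrom == mi$chrom[i] & !taken)
        if (length(on_chrom) == 0) next
        d <- abs(slots$center[on_chrom] - mi$tss[i])
        best <- on_chrom[which.min(d)]
        if (min(d) > 50000) next
        taken[best] <- TRUE
        picks[[length(picks) + 1]] <- tibble::tibble(
          slot = best, mirna = mi$name[i], tss = mi$tss[i],
          enriched_stage = mi$enriched_stage[i]
        )
      }
      if (length(picks) < n_se) {
        rlang::abort("could not place all planted super-enhancers near miRNA TSSs")
      }
      se_rows <- dplyr::bind_rows(picks)
      slots_free <- which(!taken)
    } else {
      slots_free <- seq_len(nrow(slots))
    }

    n_typ <- n_regions - n_se
    if (n_typ > length(slots_free)) {
      rlang::abort("not enough genomic slots for the requested regions")
    }
    typ_slots <- slots_free[sample.int(length(slots_free), n_typ)]

    stage_set <- stages %||% "all"
    peak_rows <- list()
    truth_rows <- list()
    rid <- 0L
    build_region <- function(slot_i, is_se) {
      n_pk <- if (is_se) sample(5:6, 1) else sample(1:3, 1)
      widths <- sample(500:1000, n_pk, replace = TRUE)
      gaps <- if (n_pk > 1) sample(500:900, n_pk - 1, replace = TRUE) else integer(0)
      span <- sum(widths) + sum(gaps)
      start <- as.integer(slots$center[slot_i] - span %/% 2)
      start <- max(0L, min(start, chrom_len - span))
      starts <- start + cumsum(c(0L, head(widths, -1) + gaps))
      tibble::tibble(
        chrom = slots$chrom[slot_i],
        start = as.integer(starts), end = as.integer(starts + widths)
      )
    }

    for (i in seq_len(n_se)) {
      rid <- rid + 1L
      geom <- build_region(se_rows$slot[i], TRUE)
      active <- if (is.null(stages)) "all" else se_rows$enriched_stage[i]
      for (st in stage_set) {
        on <- is.null(stages) || st %in% active
        mean_sig <- if (on) high_mean else low_mean
        peak_rows[[length(peak_rows) + 1]] <- geom |>
          dplyr::mutate(
            score = rgamma(dplyr::n(), shape = 4, scale = mean_sig / 4),
            stage = st, region_id = sprintf("reg%03d", rid)
          )
      }
      d <- if (se_rows$tss[i] >= min(geom$start) && se_rows$tss[i] < max(geom$end)) {
        0L
      } else if (se_rows$tss[i] < min(geom$start)) {
        se_rows$tss[i] - min(geom$start)
      } else {
        se_rows$tss[i] - max(geom$end) + 1L
      }
      truth_rows[[rid]] <- tibble::tibble(
        region_id = sprintf("reg%03d", rid), chrom = geom$chrom[1],
        start = min(geom$start), end = max(geom$end), is_SE = TRUE,
        mirna = se_rows$mirna[i], tss_distance = as.integer(d),
        active_stages = paste(active, collapse = ",")
      )
    }
    for (s in typ_slots) {
      rid <- rid + 1L
      geom <- build_region(s, FALSE)
      for (st in stage_set) {
        peak_rows[[length(peak_rows) + 1]] <- geom |>
          dplyr::mutate(
            score = rgamma(dplyr::n(), shape = 4, scale = low_mean / 4),
            stage = st, region_id = sprintf("reg%03d", rid)
          )
      }
      truth_rows[[rid]] <- tibble::tibble(
        region_id = sprintf("reg%03d", rid), chrom = geom$chrom[1],
        start = min(geom$start), end = max(geom$end), is_SE = FALSE,
        mirna = NA_character_, tss_distance = NA_integer_,
        active_stages = NA_character_
      )
    }

    peaks <- dplyr::bind_rows(peak_rows) |>
      dplyr::arrange(.data$stage, .data$chrom, .data$start) |>
      dplyr::mutate(name = sprintf("pk%05d", dplyr::row_number()),
                    strand = ".", .after = "end") |>
      dplyr::select("chrom", "start", "end", "name", "score", "strand",
                    "stage", "region_id")
    if (is.null(stages)) peaks$stage <- NULL

    list(peaks = peaks, truth = dplyr::bind_rows(truth_rows))
  })
}
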