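# Native UMI-based error correction for amplicon reads: UMI extraction
# (first 10 bp of read 2), primer-anchor amplicon assignment, directional
# UMI family grouping, count-based molecular consensus, the three consensus
# filters (read error > 5% dropped, base error > 10% masked, > 50% no-calls
# dropped), and the 500x mean-unique-coverage sample QC.

#' Consensus filter configuration
#'
#' Thresholds for molecular-consensus filtering and sample QC. The
#' "exceeded" thresholds are strict: a consensus read is dropped when its
#' read error rate is strictly above 5%, bases are masked when their error
#' rate is strictly above 10%, and the read is removed when more than 50%
#' of its bases are no-calls after masking. Sample QC requires a mean
#' unique (consensus) coverage of at least 500 across panel loci
#' (inclusive).
#'
#' @param max_read_error_rate Read-level disagreement ceiling (default 0.05).
#' @param max_base_error_rate Per-base disagreement ceiling (default 0.10).
#' @param max_no_call_fraction No-call ceiling after masking (default 0.50).
#' @param min_family_size Minimum reads per family for consensus (default 1).
#' @param umi_edit_distance UMIs within this Hamming distance merge under
#'   the directional count rule (default 1; 0 = exact grouping).
#' @param min_mean_unique_coverage Sample-QC floor on mean consensus
#'   coverage (default 500).
#' @return A list of class `consensus_filter_config`.
#' @export
consensus_filter_config <- function(max_read_error_rate = 0.05,
                                    max_base_error_rate = 0.10,
                                    max_no_call_fraction = 0.50,
                                    min_family_size = 1,
                                    umi_edit_distance = 1,
                                    min_mean_unique_coverage = 500) {
  check_probability(max_read_error_rate, "max_read_error_rate")
  check_probability(max_base_error_rate, "max_base_error_rate")
  check_probability(max_no_call_fraction, "max_no_call_fraction")
  structure(
    list(
      max_read_error_rate = max_read_error_rate,
      max_base_error_rate = max_base_error_rate,
      max_no_call_fraction = max_no_call_fraction,
      min_family_size = check_count(min_family_size, "min_family_size", min = 1),
      umi_edit_distance = check_count(umi_edit_distance, "umi_edit_distance", min = 0),
      min_mean_unique_coverage = min_mean_unique_coverage
    ),
    class = "consensus_filter_config"
  )
}

#' Extract UMIs from read pairs
#'
#' The unique molecular identifier of each template is the first
#' `umi_length` bases of read 2; those bases are removed from the read-2
#' template sequence. Read 1 spans the amplicon and is the sequence used
#' for consensus. Pairs whose read 2 is not longer than the UMI are
#' rejected and counted.
#'
#' @param pairs Tibble with `read_id`, `seq1`, `seq2`.
#' @param umi_length UMI length in bases (default 10).
#' @return Tibble of tagged reads (`read_id`, `umi`, `seq`,
#'   `seq2_trimmed`); the number of rejected pairs is attached as attribute
#'   `n_rejected` and reported.
#' @export
extract_umi <- function(pairs, umi_length = 10) {
  check_columns(pairs, c("read_id", "seq1", "seq2"), "Read-pair table")
  ok <- nchar(pairs$seq2) > umi_length
  if (any(!ok)) {
    inform(sprintf(
      "%d read pair(s) rejected: read 2 shorter than the %d-base UMI.",
      sum(!ok), umi_length
    ))
  }
  kept <- pairs[ok, , drop = FALSE]
  out <- tibble::tibble(
    read_id = kept$read_id,
    umi = substr(kept$seq2, 1, umi_length),
    seq = kept$seq1,
    seq2_trimmed = substr(kept$seq2, umi_length + 1, nchar(kept$seq2))
  )
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Assign tagged reads to amplicons by primer anchor
#'
#' In amplicon data every read 1 starts at its primer, so alignment reduces
#' to matching the read prefix against each amplicon's anchor subsequence.
#' A read is assigned to the unique anchor matching within
#' `max_mismatches`; reads matching no anchor, or two or more anchors
#' equally well within the tolerance, are left unassigned (`NA`) and
#' counted.
#'
#' @param tagged Tagged reads from [extract_umi()].
#' @param manifest Tibble with `amplicon_id` and `anchor` (equal-length,
#'   unique anchor sequences).
#' @param max_mismatches Hamming tolerance (default 1).
#' @return `tagged` with an `amplicon_id` column (`NA` = unassigned).
#' @export
assign_amplicon <- function(tagged, manifest, max_mismatches = 1) {
  check_columns(manifest, c("amplicon_id", "anchor"), "Amplicon manifest")
  if (anyDuplicated(manifest$anchor)) {
    abort("Manifest anchors must be unique.", class = "mrdtrace_manifest_error")
  }
  alen <- unique(nchar(manifest$anchor))
  if (length(alen) != 1) {
    abort("Manifest anchors must share one length.", class = "mrdtrace_manifest_error")
  }
  if (nrow(tagged) == 0) {
    return(dplyr::mutate(tagged, amplicon_id = character(0)))
  }

  prefixes <- substr(tagged$seq, 1, alen)
  # Mismatch count of every read prefix against every anchor, computed on
  # integer-coded base matrices (fast enough for desk-scale depth).
  pref_mat <- matrix(
    unlist(strsplit(prefixes, "", fixed = TRUE), use.names = FALSE),
    nrow = length(prefixes), ncol = alen, byrow = TRUE
  )
  dist <- vapply(manifest$anchor, function(anchor) {
    av <- strsplit(anchor, "", fixed = TRUE)[[1]]
    rowSums(pref_mat != matrix(av, nrow(pref_mat), alen, byrow = TRUE))
  }, numeric(nrow(pref_mat)))
  dist <- matrix(dist, nrow = nrow(pref_mat))

  best <- apply(dist, 1, min)
  n_best <- rowSums(dist == best)
  hit <- max.col(-dist, ties.method = "first")
  assigned <- ifelse(
    best <= max_mismatches & n_best == 1,
    manifest$amplicon_id[hit],
    NA_character_
  )
  n_un <- sum(is.na(assigned))
  if (n_un > 0) {
    inform(sprintf("%d read(s) unassigned (no unique anchor match).", n_un))
  }
  dplyr::mutate(tagged, amplicon_id = assigned)
}

# Directional-adjacency clustering of UMI count tables: an edge joins two
# N-free UMIs at Hamming distance <= max_dist when the smaller count is at
# most (larger/2 + 1); families are the connected components. UMIs
# containing N only ever group exactly. Neighbours are found by enumerating
# single-base substitutions (hash lookup), so grouping is near-linear in
# the number of distinct UMIs for the default distance of 1.
cluster_umis <- function(umis, counts, max_dist = 1) {
  n <- length(umis)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  if (max_dist > 0 && n > 1) {
    has_n <- grepl("N", umis, fixed = TRUE)
    idx <- setNames(seq_len(n), umis)
    mergeable <- function(i, j) {
      min(counts[i], counts[j]) <= max(counts[i], counts[j]) / 2 + 1
    }
    if (max_dist == 1) {
      bases <- c("A", "C", "G", "T")
      for (i in seq_len(n)) {
        if (has_n[i]) next
        u <- umis[i]
        for (p in seq_len(nchar(u))) {
          orig <- substr(u, p, p)
          for (b in bases) {
            if (b == orig) next
            v <- u
            substr(v, p, p) <- b
            j <- idx[v]
            if (!is.na(j) && !has_n[j] && mergeable(i, j)) union_(i, j)
          }
        }
      }
    } else {
      for (i in seq_len(n - 1)) {
        if (has_n[i]) next
        for (j in (i + 1):n) {
          if (has_n[j]) next
          if (hamming(umis[i], umis[j]) <= max_dist && mergeable(i, j)) union_(i, j)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  # Representative = highest-count member (ties by UMI string) of each
  # component.
  split_idx <- split(seq_len(n), comp)
  rep_of <- character(n)
  for (members in split_idx) {
    rep_umi <- umis[members][order(-counts[members], umis[members])][1]
    rep_of[members] <- rep_umi
  }
  rep_of
}

#' Group tagged reads into UMI families
#'
#' Partitions amplicon-assigned reads into read families. Within each
#' amplicon, UMIs within `umi_edit_distance` (Hamming) are merged under the
#' directional count rule — the smaller-count UMI is absorbed when its
#' count is at most half the larger count plus one — which separates true
#' co-occurring templates from PCR/sequencing-error satellites of an
#' abundant UMI. UMIs containing N never merge with anything but their
#' exact duplicates. Unassigned reads are excluded (and counted upstream),
#' never silently grouped.
#'
#' @param tagged Tagged, amplicon-assigned reads ([assign_amplicon()]).
#' @param cfg A [consensus_filter_config()].
#' @return `tagged` rows with `amplicon_id` present, plus `family_umi`
#'   (the family's representative UMI) and `family_id`.
#' @export
group_families <- function(tagged, cfg = consensus_filter_config()) {
  check_columns(tagged, c("umi", "seq", "amplicon_id"), "Tagged read table")
  assigned <- tagged[!is.na(tagged$amplicon_id), , drop = FALSE]
  if (nrow(assigned) == 0) {
    return(dplyr::mutate(assigned, family_umi = character(0), family_id = character(0)))
  }
  assigned |>
    dplyr::group_by(.data$amplicon_id) |>
    dplyr::group_modify(function(df, key) {
      tab <- table(df$umi)
      reps <- cluster_umis(names(tab), as.integer(tab), cfg$umi_edit_distance)
      dplyr::mutate(df, family_umi = unname(setNames(reps, names(tab))[.data$umi]))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(family_id = paste(.data$amplicon_id, .data$family_umi, sep = ":"))
}

# Count-based consensus of one family's equal-length sequences. Returns the
# consensus string, per-position disagreement among non-N member bases, and
# the read error rate (disagreeing bases / non-N member bases, over
# positions where a consensus base was called).
consensus_from_seqs <- function(seqs) {
  n <- length(seqs)
  len <- nchar(seqs[1])
  if (n == 1) {
    return(list(
      consensus = seqs, position_error = rep(0, len), read_error_rate = 0
    ))
  }
  mat <- matrix(
    unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = n, ncol = len, byrow = TRUE
  )
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(mat == b), numeric(len))
  counts <- matrix(counts, nrow = len)
  top <- apply(counts, 1, max)
  n_top <- rowSums(counts == top)
  call_idx <- max.col(counts, ties.method = "first")
  consensus_vec <- ifelse(top == 0 | n_top > 1, "N", bases[call_idx])
  non_n <- rowSums(counts)
  agree <- ifelse(consensus_vec == "N", 0, top)
  pos_err <- ifelse(non_n > 0 & consensus_vec != "N", (non_n - agree) / non_n, 0)
  called <- consensus_vec != "N" & non_n > 0
  rer <- if (any(called)) {
    sum(non_n[called] - agree[called]) / sum(non_n[called])
  } else {
    0
  }
  list(
    consensus = paste(consensus_vec, collapse = ""),
    position_error = pos_err,
    read_error_rate = rer
  )
}

#' Call molecular consensus reads
#'
#' Collapses each UMI family to its count-based consensus: per position the
#' consensus base is the plurality base among non-N member bases (ties and
#' all-N positions give N), the per-position error is the fraction of non-N
#' member bases disagreeing with the called consensus, and the read error
#' rate aggregates disagreements over all called positions. Families below
#' `min_family_size` are skipped.
#'
#' @param families Grouped reads from [group_families()].
#' @param cfg A [consensus_filter_config()].
#' @return Tibble with one row per family: `amplicon_id`, `family_umi`,
#'   `family_id`, `family_size`, `consensus`, `read_error_rate`, and a
#'   `position_error` list-column.
#' @export
call_consensus <- function(families, cfg = consensus_filter_config()) {
  check_columns(families, c("family_id", "amplicon_id", "family_umi", "seq"), "Family table")
  families |>
    dplyr::group_by(.data$amplicon_id, .data$family_umi, .data$family_id) |>
    dplyr::summarise(
      family_size = dplyr::n(),
      cons = list(consensus_from_seqs(.data$seq)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$family_size >= cfg$min_family_size) |>
    dplyr::mutate(
      consensus = purrr::map_chr(.data$cons, "consensus"),
      read_error_rate = purrr::map_dbl(.data$cons, "read_error_rate"),
      position_error = purrr::map(.data$cons, "position_error")
    ) |>
    dplyr::select(-"cons")
}

#' Apply the consensus filters
#'
#' Three filters, applied in this fixed order (order changes outcomes):
#' (1) a consensus read with read error rate strictly above
#' `max_read_error_rate` is dropped; (2) surviving reads have positions
#' with per-base error strictly above `max_base_error_rate` masked to N;
#' (3) a read whose no-call fraction after masking is strictly above
#' `max_no_call_fraction` is dropped.
#'
#' @param consensus Consensus table from [call_consensus()].
#' @param cfg A [consensus_filter_config()].
#' @return `consensus` with masked `consensus` sequences, a
#'   `no_call_fraction` column, and `filter_status` in
#'   `pass` / `dropped_read_error` / `dropped_no_call`.
#' @export
filter_consensus <- function(consensus, cfg = consensus_filter_config()) {
  if (nrow(consensus) == 0) {
    return(dplyr::mutate(consensus,
      no_call_fraction = numeric(0), filter_status = character(0)
    ))
  }
  masked <- purrr::map2_chr(
    consensus$consensus, consensus$position_error,
    function(seq, perr) {
      bad <- which(perr > cfg$max_base_error_rate)
      if (length(bad)) {
        v <- strsplit(seq, "", fixed = TRUE)[[1]]
        v[bad] <- "N"
        seq <- paste(v, collapse = "")
      }
      seq
    }
  )
  no_call <- stringr::str_count(masked, "N") / nchar(masked)
  status <- dplyr::case_when(
    consensus$read_error_rate > cfg$max_read_error_rate ~ "dropped_read_error",
    no_call > cfg$max_no_call_fraction ~ "dropped_no_call",
    TRUE ~ "pass"
  )
  # Reads dropped at step 1 keep their unmasked sequence (they never reach
  # base masking); their no-call fraction is reported pre-masking.
  pre_mask_no_call <- stringr::str_count(consensus$consensus, "N") / nchar(consensus$consensus)
  dropped1 <- status == "dropped_read_error"
  dplyr::mutate(
    consensus,
    consensus = ifelse(dropped1, .data$consensus, masked),
    no_call_fraction = ifelse(dropped1, pre_mask_no_call, no_call),
    filter_status = status
  )
}

#' Sample-level coverage QC
#'
#' A sample passes QC when the mean unique (passing consensus) coverage
#' across its panel loci is at least `min_mean_unique_coverage` (500 by
#' default, inclusive).
#'
#' @param consensus Filtered consensus table ([filter_consensus()]).
#' @param panel The sample's panel targets (needs `amplicon_id`).
#' @param cfg A [consensus_filter_config()].
#' @return A list with `per_locus` (coverage per amplicon),
#'   `mean_unique_coverage`, and `pass`.
#' @export
sample_coverage_qc <- function(consensus, panel, cfg = consensus_filter_config()) {
  if (nrow(panel) == 0) {
    abort("Empty panel: coverage QC is undefined.", class = "mrdtrace_qc_error")
  }
  passing <- consensus[consensus$filter_status == "pass", , drop = FALSE]
  per_locus <- tibble::tibble(
    amplicon_id = panel$amplicon_id,
    unique_coverage = vapply(
      panel$amplicon_id,
      function(a) sum(passing$amplicon_id == a), numeric(1)
    )
  )
  mean_cov <- mean(per_locus$unique_coverage)
  list(
    per_locus = per_locus,
    mean_unique_coverage = mean_cov,
    pass = mean_cov >= cfg$min_mean_unique_coverage
  )
}
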