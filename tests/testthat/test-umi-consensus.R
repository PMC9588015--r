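test_that("UMI extraction takes the first 10 bases of read 2", {
  pairs <- tibble::tibble(
    read_id = c("a", "b"),
    seq1 = c("GGGGCCCC", "TTTTAAAA"),
    seq2 = c("ACGTACGTACTTTTGGGG", "ACGTACGTAC")
  )
  expect_message(tagged <- extract_umi(pairs), "rejected")
  expect_equal(nrow(tagged), 1)
  expect_identical(tagged$umi, "ACGTACGTAC")
  expect_identical(tagged$seq2_trimmed, "TTTTGGGG")
  expect_identical(tagged$seq, "GGGGCCCC")
  expect_equal(attr(tagged, "n_rejected"), 1)
})

test_that("amplicon assignment matches a Hamming-distance oracle", {
  manifest <- tibble::tibble(
    amplicon_id = c("ampA", "ampB"),
    anchor = c("ACGTACGTAC", "TTTTCCCCGG")
  )
  set.seed(61)
  bases <- c("A", "C", "G", "T")
  for (i in 1:40) {
    anchor_idx <- sample(2, 1)
    seq <- manifest$anchor[anchor_idx]
    n_mut <- sample(0:3, 1)
    pos <- sample(10, n_mut)
    v <- strsplit(seq, "")[[1]]
    for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1)
    read_seq <- paste0(paste(v, collapse = ""), "AAAA")
    tagged <- tibble::tibble(
      read_id = "r", umi = "AAAAAAAAAA", seq = read_seq, seq2_trimmed = ""
    )
    res <- suppressMessages(assign_amplicon(tagged, manifest, max_mismatches = 1))
    d <- vapply(manifest$anchor, function(a) {
      sum(strsplit(a, "")[[1]] != strsplit(substr(read_seq, 1, 10), "")[[1]])
    }, numeric(1))
    best <- which(d == min(d) & d <= 1)
    expected <- if (length(best) == 1) manifest$amplicon_id[best] else NA_character_
    expect_identical(res$amplicon_id, expected)
  }
})

test_that("equally good anchor matches leave the read unassigned", {
  manifest <- tibble::tibble(
    amplicon_id = c("ampA", "ampB"),
    anchor = c("AAAAAAAAAC", "AAAAAAAAAG")
  )
  tagged <- tibble::tibble(
    read_id = "r", umi = "AAAAAAAAAA", seq = "AAAAAAAAATGGGG", seq2_trimmed = ""
  )
  res <- suppressMessages(assign_amplicon(tagged, manifest, max_mismatches = 1))
  expect_true(is.na(res$amplicon_id))
  expect_error(
    assign_amplicon(tagged, manifest[c(1, 1), ]),
    class = "mrdtrace_manifest_error"
  )
})

test_that("directional grouping merges error satellites but respects amplicons and N", {
  mk <- function(umis, amp = "amp1") {
    tibble::tibble(
      read_id = paste0("r", seq_along(umis)), umi = umis,
      seq = "ACGT", amplicon_id = amp
    )
  }
  # Same UMI, same amplicon: one family of two.
  f <- group_families(mk(c("AAAAAAAAAA", "AAAAAAAAAA")))
  expect_equal(length(unique(f$family_id)), 1)

  # Abundant UMI absorbs a distance-1 singleton.
  f <- group_families(mk(c(rep("AAAAAAAAAA", 100), "AAAAAAAAAT")))
  expect_equal(length(unique(f$family_id)), 1)
  expect_true(all(f$family_umi == "AAAAAAAAAA"))

  # Two similarly abundant UMIs stay separate (directional count rule).
  f <- group_families(mk(c(rep("AAAAAAAAAA", 4), rep("AAAAAAAAAT", 4))))
  expect_equal(length(unique(f$family_id)), 2)

  # Identical UMIs on different amplicons never merge.
  two_amp <- dplyr::bind_rows(mk("AAAAAAAAAA", "amp1"), mk("AAAAAAAAAA", "amp2"))
  f <- group_families(two_amp)
  expect_equal(length(unique(f$family_id)), 2)

  # N-containing UMIs only ever group exactly.
  f <- group_families(mk(c(rep("AAAAAAAAAA", 50), "AAAAAAAAAN", "AAAAAAAAAN")))
  expect_equal(length(unique(f$family_id)), 2)

  # Edit distance 0 forces exact grouping.
  f <- group_families(
    mk(c(rep("AAAAAAAAAA", 100), "AAAAAAAAAT")),
    consensus_filter_config(umi_edit_distance = 0)
  )
  expect_equal(length(unique(f$family_id)), 2)
})

test_that("grouping agrees with the brute-force clustering oracle on small UMI sets", {
  set.seed(71)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:30) {
    n_umis <- sample(2:20, 1)
    # Correlated UMIs: mutate a few seeds so distance-1 pairs are common.
    seeds <- replicate(max(1, n_umis %/% 3), paste(sample(bases, 10, TRUE), collapse = ""))
    umis <- vapply(seq_len(n_umis), function(i) {
      u <- sample(seeds, 1)
      if (runif(1) < 0.7) {
        p <- sample(10, 1)
        v <- strsplit(u, "")[[1]]
        v[p] <- sample(bases, 1)
        u <- paste(v, collapse = "")
      }
      u
    }, character(1))
    umis <- unique(umis)
    counts <- sample(1:60, length(umis), replace = TRUE)

    reads <- tibble::tibble(
      read_id = as.character(seq_len(sum(counts))),
      umi = rep(umis, counts),
      seq = "ACGT",
      amplicon_id = "amp1"
    )
    fam <- group_families(reads)
    got <- unique(fam[, c("umi", "family_umi")])
    oracle <- oracle_cluster_umis(umis, counts)
    expect_identical(
      partition_key(got$umi, got$family_umi),
      partition_key(umis, oracle)
    )
  }
})

test_that("families partition the assigned reads exactly", {
  set.seed(83)
  panel <- make_test_panel(2)
  em <- error_model(
    per_base_substitution_rate = 0.01, no_call_rate = 0.002,
    templates_per_amplicon = 150
  )
  sim <- simulate_amplicon_reads(panel, 0.3, em)
  tagged <- extract_umi(sim$reads)
  tagged <- suppressMessages(
    assign_amplicon(tagged, panel[, c("amplicon_id", "anchor")])
  )
  n_assigned <- sum(!is.na(tagged$amplicon_id))
  fam <- group_families(tagged)
  expect_equal(nrow(fam), n_assigned)
  cons <- call_consensus(fam)
  expect_equal(sum(cons$family_size), n_assigned)
  # Consensus depth per amplicon never exceeds family or read counts.
  for (amp in panel$amplicon_id) {
    expect_lte(
      sum(cons$amplicon_id == amp),
      sum(tagged$amplicon_id == amp, na.rm = TRUE)
    )
  }
})

test_that("consensus calling is a per-position plurality with tie and N handling", {
  fam <- tibble::tibble(
    read_id = c("a", "b", "c"),
    umi = "AAAAAAAAAA",
    seq = c("AACG", "AACG", "TACG"),
    amplicon_id = "amp1",
    family_umi = "AAAAAAAAAA",
    family_id = "amp1:AAAAAAAAAA"
  )
  cons <- call_consensus(fam)
  expect_identical(cons$consensus, "AACG")
  expect_equal(cons$position_error[[1]], c(1 / 3, 0, 0, 0))
  expect_equal(cons$read_error_rate, 1 / 12)

  # Three identical reads: zero error.
  fam$seq <- "AACG"
  cons <- call_consensus(fam)
  expect_equal(cons$read_error_rate, 0)

  # Single-read family: consensus is the read.
  single <- fam[1, ]
  cons <- call_consensus(single)
  expect_identical(cons$consensus, "AACG")
  expect_equal(cons$read_error_rate, 0)

  # Even split is a tie: N, and non-N members outvote Ns.
  fam2 <- fam
  fam2$seq <- c("AACG", "TACG", "NACG")
  cons <- call_consensus(fam2)
  expect_identical(substr(cons$consensus, 1, 1), "N")
})

test_that("consensus filters apply in order with strict thresholds", {
  mk_cons <- function(seq, perr, rer) {
    tibble::tibble(
      amplicon_id = "amp1", family_umi = "AAAAAAAAAA",
      family_id = "f", family_size = 5L,
      consensus = seq, read_error_rate = rer,
      position_error = list(perr)
    )
  }
  len <- 150
  seq <- strrep("A", len)

  # Read error 8% > 5%: dropped before any masking.
  res <- filter_consensus(mk_cons(seq, rep(0, len), 0.08))
  expect_identical(res$filter_status, "dropped_read_error")

  # Read error exactly 5% survives (strict "exceeded").
  res <- filter_consensus(mk_cons(seq, rep(0, len), 0.05))
  expect_identical(res$filter_status, "pass")

  # A position at error 1/3 > 10% is masked to N.
  perr <- rep(0, len)
  perr[10] <- 1 / 3
  res <- filter_consensus(mk_cons(seq, perr, 0.02))
  expect_identical(substr(res$consensus, 10, 10), "N")
  expect_identical(res$filter_status, "pass")

  # Position error exactly 10% is not masked.
  perr[10] <- 0.10
  res <- filter_consensus(mk_cons(seq, perr, 0.02))
  expect_identical(substr(res$consensus, 10, 10), "A")

  # 76 of 150 masked positions (50.7% no-calls) drops the read.
  perr <- rep(0, len)
  perr[1:76] <- 0.2
  res <- filter_consensus(mk_cons(seq, perr, 0.02))
  expect_identical(res$filter_status, "dropped_no_call")
  expect_equal(res$no_call_fraction, 76 / 150)

  # Exactly 50% no-calls passes (strict "greater than").
  perr <- rep(0, len)
  perr[1:75] <- 0.2
  res <- filter_consensus(mk_cons(seq, perr, 0.02))
  expect_identical(res$filter_status, "pass")
})

test_that("sample coverage QC uses an inclusive 500x mean over panel loci", {
  panel <- tibble::tibble(amplicon_id = c("amp1", "amp2"))
  mk <- function(n1, n2) {
    tibble::tibble(
      amplicon_id = c(rep("amp1", n1), rep("amp2", n2)),
      filter_status = "pass"
    )
  }
  expect_true(sample_coverage_qc(mk(500, 500), panel)$pass)
  expect_true(sample_coverage_qc(mk(499, 501), panel)$pass)
  qc <- sample_coverage_qc(mk(499, 500), panel)
  expect_false(qc$pass)
  expect_equal(qc$mean_unique_coverage, 499.5)
  expect_false(sample_coverage_qc(mk(0, 0), panel)$pass)
  expect_error(
    sample_coverage_qc(mk(1, 1), panel[0, ]),
    class = "mrdtrace_qc_error"
  )
})
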