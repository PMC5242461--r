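# Cysteine pairing, motif scanning, furin sites, conserved segments.

test_that("two all-C columns give one pair present in every taxon", {
  aln <- c(a = "ACWWCG", b = "ACKLCG", c = "ACRRCG")
  res <- detect_conserved_cysteines(aln)
  expect_equal(res$columns, c(2L, 5L))
  expect_length(res$pairs, 1L)
  expect_equal(res$pairs[[1]]$pair_id, "C1-C2")
  expect_true(all(res$pairs[[1]]$member_map))
  expect_length(res$unpaired, 0L)
})

test_that("clade-specific cysteine loss is confined to that clade", {
  truth <- simulate_family(simulation_config(seed = 1))
  res <- detect_conserved_cysteines(truth$alignment, min_fraction = 0.9)
  expect_length(res$pairs, 2L)
  expect_equal(res$columns, c(30L, 45L, 110L, 150L))
  # the UPK2a-like gene lost C3-C4; everyone else keeps it
  expect_setequal(names(which(!res$pairs[[2]]$member_map)), "upk2a")
  expect_true(all(res$pairs[[1]]$member_map))
})

test_that("six conserved columns produce three pairs (UPK3d-like)", {
  rows <- paste0("AC", "LC", "MC", "NC", "PC", "QC", "CW")
  # columns 2,4,6,8,10,12 all C, column 13 C too -> unpaired trailing
  aln <- c(a = rows, b = rows, c = rows)
  res <- detect_conserved_cysteines(aln)
  expect_length(res$pairs, 3L)
  expect_equal(res$unpaired, 13L)
  expect_equal(vapply(res$pairs, function(p) p$pair_id, ""),
               c("C1-C2", "C3-C4", "C5-C6"))
})

test_that("cysteine pairing is stable under row reordering and gap columns", {
  truth <- simulate_family(simulation_config(seed = 1))
  res <- detect_conserved_cysteines(truth$alignment, 0.9)
  shuffled <- truth$alignment[rev(names(truth$alignment))]
  res2 <- detect_conserved_cysteines(shuffled, 0.9)
  expect_equal(res2$columns, res$columns)
  expect_identical(res2$pairs[[2]]$member_map[names(res$pairs[[2]]$member_map)],
                   res$pairs[[2]]$member_map)
  # inserting an all-gap column shifts columns but not membership
  gapped <- vapply(truth$alignment, function(s) {
    paste0(substr(s, 1, 10), "-", substr(s, 11, nchar(s)))
  }, "")
  res3 <- detect_conserved_cysteines(gapped, 0.9)
  expect_equal(res3$columns, res$columns + 1L)
  expect_identical(res3$pairs[[1]]$member_map, res$pairs[[1]]$member_map)
})

test_that("signature motif scanning matches the worked example", {
  hits <- scan_motif(c(x = "ACWWCNGPLD"), "C-x(2,40)-C-N-G-P-L")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 9L)
  expect_equal(hits$match, "CWWCNGPL")
  # no NGPL, no hit
  expect_equal(nrow(scan_motif(c(x = "ACWWCNGAL"), "C-x(2,40)-C-N-G-P-L")), 0L)
})

test_that("motif scanning equals the brute-force matcher on random input", {
  set.seed(31)
  patterns <- c("C-x(2,40)-C-N-G-P-L", "R-x-[RK]-R", "N-G-P-L",
                "A-x(0,3)-[DE]-x-G")
  for (rep in 1:3) {
    s <- random_protein(10000)
    for (pat in patterns) {
      got <- scan_motif(c(q = s), pat)
      want <- bf_motif_hits(s, pat)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L, info = pat)
      } else {
        expect_equal(nrow(got), nrow(want), info = pat)
        expect_equal(got$start, want[, 1], info = pat)
        expect_equal(got$end, want[, 2], info = pat)
      }
    }
  }
})

test_that("malformed motif patterns report the offending token", {
  expect_error(scan_motif(c(a = "ACDE"), "C-x(2,1)-C"), "token 2")
  expect_error(scan_motif(c(a = "ACDE"), "C-q7-C"), "token 2")
})

test_that("furin sites follow the R-x-[RK]-R rule, overlaps included", {
  hits <- find_furin_sites("AARTKRAA")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$cleave_after, 6L)
  expect_equal(hits$site, "RTKR")
  expect_equal(nrow(find_furin_sites("AAAA")), 0L)
  # overlapping matches are all reported: RRKRR has sites at 1-4 and 2-5
  hits2 <- find_furin_sites("RRKRR")
  expect_equal(hits2$start, c(1L, 2L))
})

test_that("the implanted furin site lies between C2 and the TM span", {
  truth <- simulate_family(simulation_config(seed = 2))
  cfg <- truth$config
  p <- truth$proteins[["upk2b"]]
  hits <- find_furin_sites(p)
  pos <- cfg$furin_spec$position
  expect_true((pos + 3L) %in% hits$cleave_after)
  c2 <- cfg$cysteine_pairs[[1]][2]
  expect_gt(pos, c2)  # cleavage downstream of C2, as in the UPK2a prosequence
})

test_that("conserved segments: identical rows give one full-width segment", {
  aln <- c(a = "MKLVQWER", b = "MKLVQWER")
  seg <- conserved_segment_scan(aln)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start_col, 1L)
  expect_equal(seg$end_col, 8L)
})

test_that("a constructed conserved block amid noise is found exactly", {
  set.seed(17)
  n <- 8
  left <- replicate(n, random_protein(20))
  right <- replicate(n, random_protein(20))
  core <- "WNGPLY"
  aln <- stats::setNames(paste0(left, core, right),
                         sprintf("t%d", seq_len(n)))
  seg <- conserved_segment_scan(aln, min_length = 4, min_identity = 0.9)
  # brute-force check of the column flags
  m <- do.call(rbind, strsplit(aln, ""))
  good <- apply(m, 2, function(col) max(table(col)) / n >= 0.9)
  expect_true(all(seg$start_col >= 1 & seg$end_col <= 46))
  expect_true(any(seg$start_col <= 21 & seg$end_col >= 26))
  for (i in seq_len(nrow(seg))) {
    expect_true(all(good[seg$start_col[i]:seg$end_col[i]]))
  }
})

test_that("seven implanted frozen motifs are recovered as seven segments", {
  cfg <- simulation_config(
    substitution_rate = 3,
    cysteine_pairs = list(),
    furin_spec = NULL,
    motif_spec = lapply(seq_len(7), function(i) {
      list(pattern = c("WNGP", "LYDE", "KRFM", "HQVA", "DPTC", "EWIS",
                       "GFNK")[i],
           anchor = 20L + 25L * (i - 1L))
    }),
    loss_events = list(),
    seed = 21)
  truth <- simulate_family(cfg)
  seg <- conserved_segment_scan(truth$alignment)
  expect_equal(nrow(seg), 7L)
  anchors <- vapply(cfg$motif_spec, function(m) m$anchor, 0L)
  expect_true(all(seg$start_col == anchors))
  expect_true(all(seg$end_col == anchors + 3L))
})

test_that("the TM window finds an implanted hydrophobic stretch", {
  set.seed(5)
  s <- paste0(paste(sample(c("D", "E", "K", "R", "N", "Q"), 60, TRUE),
                    collapse = ""),
              paste(rep("L", 19), collapse = ""),
              paste(sample(c("D", "E", "K", "R", "N", "Q"), 60, TRUE),
                    collapse = ""))
  tm <- find_tm_helix(s)
  expect_equal(tm$start, 61L)
  expect_equal(tm$end, 79L)
})
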