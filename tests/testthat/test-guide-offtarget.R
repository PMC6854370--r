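# Guide enumeration, 5'-end truncation, mismatch-bounded off-target search
# and cross-length overlap, cross-checked against a matchPattern-based
# oracle and brute-force properties.

test_that("enumerate_guides finds PAM-adjacent spacers on both strands", {
  expect_equal(nrow(enumerate_guides(strrep("A", 22), 20, "NGG")), 0)

  s <- "ACGTACGTACGTACGTACGTAGG"   # 23 nt, one NGG at the forward end
  g <- enumerate_guides(s, 20, "NGG")
  fwd <- g[g$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_identical(fwd$spacer, "ACGTACGTACGTACGTACGT")
  expect_identical(fwd$pam, "AGG")
  expect_equal(fwd$start, 0)
  # minus strand by oracle: NGG on the reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  n_minus_expected <- sum(vapply(1:(nchar(rc) - 22), function(p)
    substr(rc, p + 21, p + 22) == "GG", logical(1)))
  expect_equal(sum(g$strand == "-"), n_minus_expected)

  # shorter spacers fit at least as many positions
  g17 <- enumerate_guides(s, 17, "NGG")
  expect_gte(nrow(g17), nrow(g))
})

test_that("truncation drops 5' bases and preserves seed and cut site", {
  g <- data.frame(id = "g", spacer = "AAAAACCCCCGGGGGTTTTT", spacer_len = 20L,
                  pam_pattern = "NGG", pam = "AGG", contig = "c",
                  start = 100L, end = 123L, strand = "+",
                  cut_site = cut_site_coord(100L, 123L, "+"),
                  stringsAsFactors = FALSE)
  t17 <- truncate_guide(g, 17)
  expect_identical(t17$spacer, "AACCCCCGGGGGTTTTT")
  # PAM-proximal 12-nt seed unchanged
  expect_identical(substr(t17$spacer, nchar(t17$spacer) - 11,
                          nchar(t17$spacer)),
                   substr(g$spacer, 9, 20))
  # genomic cut coordinate identical (measured from the PAM)
  expect_identical(cut_site_coord(t17$start, t17$end, t17$strand),
                   g$cut_site)
  expect_error(truncate_guide(g, 20), "shorter")
  expect_error(truncate_guide(g, 16), ">= 17")

  # minus strand: locus trimmed at the high-coordinate (PAM-distal) end
  gm <- g; gm$strand <- "-"; gm$cut_site <- cut_site_coord(100L, 123L, "-")
  t18 <- truncate_guide(gm, 18)
  expect_equal(t18$start, 100)
  expect_equal(t18$end, 121)
  expect_identical(cut_site_coord(t18$start, t18$end, "-"), gm$cut_site)
})

test_that("find_offtargets recovers a single planted perfect site", {
  g <- make_genome(2000, 0.5, 3)
  spacer <- "TGACGTCAGTACGTTAGCCA"
  r <- plant_site(g, spacer, "TGG", 0, 700, "+", seed = 2)
  sites <- find_offtargets(spacer, c(chr1 = as.vector(r$genome)),
                           max_mm = 0, pam_pattern = "NGG")
  planted <- sites[sites$start == 700, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$n_mismatch, 0)
  expect_identical(planted$protospacer, spacer)
})

test_that("NRG PAM admits NAG/NGG but not other second bases", {
  spacer <- "ACGTACGTACGTACGTACGT"
  flank <- "TTTTTTTTTT"
  for (pam in c("TAG", "TGG")) {
    gseq <- paste0(flank, spacer, pam, flank)
    hits <- find_offtargets(spacer, c(c1 = gseq), max_mm = 0,
                            pam_pattern = "NRG")
    expect_equal(sum(hits$strand == "+"), 1)
  }
  gseq <- paste0(flank, spacer, "TCG", flank)
  hits <- find_offtargets(spacer, c(c1 = gseq), max_mm = 0,
                          pam_pattern = "NRG")
  expect_equal(sum(hits$strand == "+"), 0)
})

test_that("off-target search agrees with the matchPattern oracle", {
  for (seed in 1:3) {
    gseq <- random_seq(8000, seed = seed, gc = 0.45)
    spacer <- substr(gseq, 4001, 4020)   # guaranteed 0-mm locus
    for (len in c(20, 18)) {
      sp <- substr(spacer, 21 - len, 20)
      for (mm in c(0, 2, 3)) {
        got <- find_offtargets(sp, c(chr = gseq), max_mm = mm,
                               pam_pattern = "NRG")
        expect_identical(site_keys(got),
                         oracle_offtargets(sp, gseq, mm, "NRG"),
                         info = sprintf("seed=%d len=%d mm=%d",
                                        seed, len, mm))
      }
    }
  }
})

test_that("ambiguous genome bases count as spacer mismatches", {
  spacer <- "ACGTACGTACGTACGTACGT"
  gseq <- paste0("TTTTT", sub("^AC", "NN", spacer), "AGG", "TTTTT")
  h1 <- find_offtargets(spacer, c(c1 = gseq), max_mm = 2,
                        pam_pattern = "NGG")
  expect_equal(sum(h1$strand == "+" & h1$start == 5), 1)
  h0 <- find_offtargets(spacer, c(c1 = gseq), max_mm = 1,
                        pam_pattern = "NGG")
  expect_equal(sum(h0$strand == "+" & h0$start == 5), 0)
  expect_error(find_offtargets("ACGTNCGTACGTACGTACGT", c(c1 = gseq)),
               "non-ACGT")
})

test_that("mismatch positions are PAM-proximal 1-based with seed annotation", {
  spacer <- "ACGTACGTACGTACGTACGT"
  # mutate spacer positions 1 and 20 (5' end and PAM-adjacent base)
  proto <- paste0("T", substr(spacer, 2, 19), "A")
  gseq <- paste0("GGGGG", proto, "AGG", "GGGGG")
  hit <- find_offtargets(spacer, c(c1 = gseq), max_mm = 2,
                         pam_pattern = "NGG")
  hit <- hit[hit$strand == "+" & hit$start == 5, ]
  # position 1 = PAM-proximal base (spacer position 20), position 20 = 5' end
  expect_identical(hit$mismatch_positions, "1,20")
  expect_equal(hit$seed_mismatches, 1)
})

test_that("strand symmetry: hits map onto the reverse-complement genome", {
  gseq <- random_seq(5000, seed = 9)
  spacer <- substr(gseq, 2001, 2020)
  fwd <- find_offtargets(spacer, c(chr = gseq), max_mm = 2,
                         pam_pattern = "NRG")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gseq)))
  rev <- find_offtargets(spacer, c(chr = rc), max_mm = 2,
                         pam_pattern = "NRG")
  L <- nchar(gseq)
  mapped <- data.frame(start = L - rev$end, strand = ifelse(rev$strand == "+",
                                                            "-", "+"),
                       n_mismatch = rev$n_mismatch)
  expect_identical(sort(paste(mapped$start, mapped$strand,
                              mapped$n_mismatch)),
                   sort(paste(fwd$start, fwd$strand, fwd$n_mismatch)))
})

test_that("truncation monotonicity: shorter spacers never gain mismatches", {
  gseq <- random_seq(20000, seed = 13)
  spacer20 <- substr(gseq, 9001, 9020)
  hits20 <- find_offtargets(spacer20, c(chr = gseq), max_mm = 3,
                            pam_pattern = "NRG")
  for (len in c(19, 18, 17)) {
    sp <- substr(spacer20, 21 - len, 20)
    hits <- find_offtargets(sp, c(chr = gseq), max_mm = 3,
                            pam_pattern = "NRG")
    # every locus hit by the 20-nt spacer is hit by the truncated one,
    # keyed by cut site, at no greater mismatch count
    k20 <- paste(hits20$cut_site, hits20$strand)
    kt <- paste(hits$cut_site, hits$strand)
    expect_true(all(k20 %in% kt))
    m <- match(k20, kt)
    expect_true(all(hits$n_mismatch[m] <= hits20$n_mismatch))
    expect_gte(nrow(hits), nrow(hits20))
  }
})

test_that("count_by_mismatch partitions the site list", {
  fx <- default_fixture()
  sites <- find_offtargets(fx$guides[1, ], fx$genome, max_mm = 5,
                           pam_pattern = "NRG")
  counts <- count_by_mismatch(sites)
  expect_equal(sum(counts), nrow(sites))
  # planted panel: 1 on-target (0 mm), three 1-3 mm true off-targets and
  # known mismatch classes from the truth table are all recovered
  truth_counts <- table(factor(fx$truth$n_mismatch, levels = 0:5))
  for (mm in 0:5) {
    expect_gte(counts[[as.character(mm)]],
               truth_counts[[as.character(mm)]])
  }
  expect_identical(unname(count_by_mismatch(sites[0, ])),
                   rep(0L, 6))
})

test_that("overlap across lengths keys sites by cut position", {
  a <- data.frame(contig = "c", cut_site = c(10, 20, 30), strand = "+",
                  stringsAsFactors = FALSE)
  b <- data.frame(contig = "c", cut_site = c(20, 30, 40, 50), strand = "+",
                  stringsAsFactors = FALSE)
  ov <- overlap_across_lengths(list(`20` = a, `17` = b))
  expect_equal(ov$n_intersection, 2)
  expect_equal(ov$n_union, 5)

  # identical sets: everything is shared
  ov2 <- overlap_across_lengths(list(`20` = a, `19` = a, `18` = a))
  expect_equal(ov2$n_intersection, nrow(a))
  expect_equal(ov2$n_union, nrow(a))

  # disjoint sets: empty intersection, additive union
  d <- data.frame(contig = "c", cut_site = c(100, 200), strand = "-",
                  stringsAsFactors = FALSE)
  ov3 <- overlap_across_lengths(list(`20` = a, `17` = d))
  expect_equal(ov3$n_intersection, 0)
  expect_equal(ov3$n_union, nrow(a) + nrow(d))
})
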