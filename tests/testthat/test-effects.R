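# dedicated annotation for context-category tests: one plus-strand gene on
# chr1 (tx 2001..2400, CDS 2051..2350) and one introned gene on chr2
locate_fixture <- local({
  fx <- NULL
  function() {
    if (!is.null(fx)) return(fx)
    rows <- rbind(
      data.frame(chrom = "chr1",
                 type = c("gene", "mRNA", "exon", "CDS",
                          "five_prime_UTR", "three_prime_UTR"),
                 start = c(2001, 2001, 2001, 2051, 2001, 2351),
                 end = c(2400, 2400, 2400, 2350, 2050, 2400),
                 strand = "+", transcript_id = "gA.1", gene_id = "gA"),
      data.frame(chrom = "chr2",
                 type = c("gene", "mRNA", "exon", "CDS", "exon", "CDS"),
                 start = c(2011, 2011, 2011, 2011, 2031, 2031),
                 end = c(2036, 2036, 2016, 2016, 2036, 2033),
                 strand = "+", transcript_id = "gB.1", gene_id = "gB"))
    fx <<- annotation_from_features(c(chr1 = 5000L, chr2 = 5000L), rows)
    fx
  }
})

test_that("locate_mutations applies the category precedence and windows", {
  ann <- locate_fixture()
  pts <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(2100, 2010, 2380, 1501, 3000, 100, 2020))
  cats <- locate_mutations(pts, ann, upstream_bp = 1000, downstream_bp = 1000)
  expect_equal(cats, c("exonic", "UTR5", "UTR3", "upstream", "downstream",
                       "intergenic", "intron"))
  # narrower windows reclassify flank positions as intergenic
  cats2 <- locate_mutations(pts[4:5, ], ann, upstream_bp = 100,
                            downstream_bp = 100)
  expect_equal(cats2, c("intergenic", "intergenic"))
  expect_error(locate_mutations(data.frame(chrom = "chrX", pos = 1), ann),
               "unknown chromosome")
})

test_that("location categories partition every mutation set", {
  fx <- shared_fixture()
  tr <- fx$planted$truth
  cats <- locate_mutations(tr, fx$annotation)
  expect_length(cats, nrow(tr))
  expect_true(all(cats %in% c("exonic", "UTR5", "UTR3", "intron",
                              "upstream", "downstream", "intergenic")))
  expect_equal(sum(table(cats)), nrow(tr))
})

test_that("coding SBS effects on the plus strand match the codon table", {
  tf <- tiny_gene_fixture()
  mP <- tf$models[["tP.1"]]
  # CDS 11..19 = ATG AAA TAA; codon 2 is AAA (Lys) at 14..16
  nonsense <- coding_effect_sbs("chr1", 14, "A", "T", mP, tf$genome)
  expect_equal(nonsense$category, "nonsense")
  expect_equal(nonsense$codon_change, "AAA>TAA")
  expect_equal(nonsense$aa_change, "K>*")
  syn <- coding_effect_sbs("chr1", 16, "A", "G", mP, tf$genome)
  expect_equal(syn$category, "synonymous")
  expect_equal(syn$codon_change, "AAA>AAG")
  mis <- coding_effect_sbs("chr1", 15, "A", "C", mP, tf$genome)
  expect_equal(mis$category, "nonsynonymous")
  # stop-loss maps to nonsynonymous (no class of its own)
  stoploss <- coding_effect_sbs("chr1", 17, "T", "C", mP, tf$genome)
  expect_equal(stoploss$category, "nonsynonymous")
  expect_error(coding_effect_sbs("chr1", 14, "C", "T", mP, tf$genome),
               "does not match")
  expect_error(coding_effect_sbs("chr1", 5, "G", "A", mP, tf$genome),
               "not in a CDS")
})

test_that("minus-strand effects equal the full-CDS retranslation oracle", {
  tf <- tiny_gene_fixture()
  mM <- tf$models[["tM.1"]]
  chrom_seq <- as.character(tf$genome[[1]])
  # every possible SBS in the minus-strand CDS, checked against the oracle
  for (pos in 41:49) {
    ref <- substr(chrom_seq, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      got <- coding_effect_sbs("chr1", pos, ref, alt, mM, tf$genome)
      expect_equal(got$category, oracle_sbs_effect(pos, alt, mM, chrom_seq),
                   info = sprintf("pos %d %s>%s", pos, ref, alt))
    }
  }
})

test_that("strand symmetry: reverse-complementing the fixture preserves effects", {
  tf <- tiny_gene_fixture()
  L <- 60L
  rc_genome <- Biostrings::reverseComplement(tf$genome)
  names(rc_genome) <- names(tf$genome)
  f <- tf$annotation$features
  f2 <- f
  f2$start <- L - f$end + 1L
  f2$end <- L - f$start + 1L
  f2$strand <- ifelse(f$strand == "+", "-", "+")
  rc_ann <- annotation_from_features(c(chr1 = L), f2)
  rc_models <- transcript_models(rc_ann)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chrom_seq <- as.character(tf$genome[[1]])
  for (pos in c(11:19, 41:49)) {
    ref <- substr(chrom_seq, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    tid <- if (pos <= 19) "tP.1" else "tM.1"
    fwd <- coding_effect_sbs("chr1", pos, ref, alt, tf$models[[tid]], tf$genome)
    rev <- coding_effect_sbs("chr1", L - pos + 1L, comp[[ref]], comp[[alt]],
                             rc_models[[tid]], rc_genome)
    expect_equal(fwd$category, rev$category, info = paste("pos", pos))
  }
})

test_that("coding InDel effects follow the coding-length mod-3 rule", {
  tf <- tiny_gene_fixture()
  mP <- tf$models[["tP.1"]]
  chrom_seq <- as.character(tf$genome[[1]])
  del2 <- coding_effect_indel("chr1", 13, substr(chrom_seq, 13, 15),
                              substr(chrom_seq, 13, 13), mP)
  expect_equal(del2$category, "frameshift")
  del3 <- coding_effect_indel("chr1", 13, substr(chrom_seq, 13, 16),
                              substr(chrom_seq, 13, 13), mP)
  expect_equal(del3$category, "inframe_indel")
  ins7 <- coding_effect_indel("chr1", 14, "A", "AGGGGGGG", mP)
  expect_equal(ins7$category, "frameshift")
  # deletion spanning the CDS end: only the coding overlap counts
  # pos 18, delete 19..24 -> 1 coding base (19) removed -> frameshift
  spill <- coding_effect_indel("chr1", 18, substr(chrom_seq, 18, 24),
                               substr(chrom_seq, 18, 18), mP)
  expect_equal(spill$category, "frameshift")
  expect_error(coding_effect_indel("chr1", 30, "GAA", "G", mP), "CDS")
})

test_that("effect_table matches both the truth table and the test oracle", {
  fx <- shared_fixture()
  tr <- fx$planted$truth
  mut <- data.frame(line_id = tr$line_id, chrom = tr$chrom, pos = tr$pos,
                    ref = tr$ref, alt = tr$alt, mclass = tr$class,
                    indel_len = tr$indel_len, stringsAsFactors = FALSE)
  eff <- effect_table(mut, fx$annotation, fx$genome)
  truth_coding <- tr[!is.na(tr$oracle_effect), ]
  expect_equal(nrow(eff$calls), nrow(truth_coding))
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  m <- match(key(eff$calls), key(truth_coding))
  expect_false(anyNA(m))
  expect_equal(eff$calls$category, truth_coding$oracle_effect[m])

  # independent oracle re-check of every coding SBS call
  models <- transcript_models(fx$annotation)
  chrom_seqs <- setNames(as.character(fx$genome), names(fx$genome))
  sbs_calls <- eff$calls[nchar(eff$calls$ref) == 1 & nchar(eff$calls$alt) == 1, ]
  for (i in seq_len(nrow(sbs_calls))) {
    cc <- sbs_calls[i, ]
    expect_equal(cc$category,
                 oracle_sbs_effect(cc$pos, cc$alt, models[[cc$transcript_id]],
                                   chrom_seqs[[cc$chrom]]),
                 info = paste(cc$chrom, cc$pos))
  }
  # intergenic-only input gives an all-zero table
  away <- mut[locate_mutations(mut, fx$annotation) == "intergenic", ][1:5, ]
  eff0 <- effect_table(away, fx$annotation, fx$genome)
  expect_equal(nrow(eff0$calls), 0)
  tot <- eff0$table[eff0$table$line_id == "Total",
                    c("synonymous", "nonsynonymous", "nonsense", "frameshift")]
  expect_true(all(tot == 0))
})

test_that("the re-encoded effect-count panel reproduces the published summary", {
  counts <- cib_effect_counts()
  s <- summarize_effect_counts(counts)
  expect_equal(unname(s$totals["synonymous"]), 2950)
  expect_equal(unname(s$totals["nonsense"]), 75)
  expect_equal(unname(s$totals["frameshift"]), 149)
  expect_equal(s$high_impact_headline, 28)    # (75 + 149) / 8 = 28
})
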