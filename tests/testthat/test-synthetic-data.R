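test_that("generate_genome honours the degenerate and deterministic contracts", {
  g0 <- generate_genome(1, 100000, 0, seed = 1)
  expect_length(g0$genome, 1)
  expect_equal(Biostrings::width(g0$genome), 100000)
  expect_equal(nrow(g0$annotation$features), 0)
  expect_true(grepl("^[ACGT]+$", as.character(g0$genome[[1]])))

  a <- generate_genome(2, 50000, 5, seed = 7)
  b <- generate_genome(2, 50000, 5, seed = 7)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation$features, b$annotation$features)

  expect_error(generate_genome(1, 5000, 0, seed = 1), "chrom_length")
  expect_error(generate_genome(1, 10000, 50, seed = 1), "pack")
})

test_that("every generated CDS translates start-to-stop with no internal stop", {
  g <- generate_genome(1, 50000, 3, seed = 7)
  chrom_seq <- as.character(g$genome[[1]])
  models <- transcript_models(g$annotation)
  expect_length(models, 3)
  for (m in models) {
    cds <- oracle_spliced_cds(m, chrom_seq)
    expect_equal(nchar(cds) %% 3, 0)
    prot <- oracle_translate(cds)
    expect_equal(substr(prot, 1, 1), "M")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
    # exon/CDS interval sanity
    expect_true(all(m$cds[, 2] >= m$cds[, 1]))
    expect_true(all(diff(as.vector(t(m$cds))) > 0))
  }
})

test_that("plant_mutations conserves counts and matches the genome", {
  fx <- shared_fixture()
  tr <- fx$planted$truth
  expect_equal(nrow(tr), 1200)
  expect_setequal(unique(tr$class), c("SBS", "INS", "DEL"))
  expect_equal(sum(table(tr$class)), 1200)
  # distinct positions and ref alleles matching the genome
  expect_false(any(duplicated(paste(tr$chrom, tr$pos))))
  for (i in sample.int(nrow(tr), 50)) {
    expect_identical(
      substr(as.character(fx$genome[[tr$chrom[i]]]), tr$pos[i],
             tr$pos[i] + nchar(tr$ref[i]) - 1L),
      tr$ref[i])
  }
  # degenerate indel fraction
  g <- generate_genome(1, 20000, 0, seed = 2)
  p <- plant_mutations(g$genome, g$annotation,
                       spectrum_params(indel_fraction = 0), NULL,
                       n_mutations = 1000, seed = 5, n_background = 0)
  expect_equal(sum(p$truth$class == "SBS"), 1000)
  # infeasible request
  expect_error(plant_mutations(g$genome, g$annotation, spectrum_params(),
                               NULL, n_mutations = 50000, seed = 1),
               "exceed")
})

test_that("planted Ti fraction is recovered within 3 binomial SE", {
  g <- generate_genome(1, 200000, 0, seed = 3)
  p <- plant_mutations(g$genome, g$annotation,
                       spectrum_params(ti_fraction = 0.565, indel_fraction = 0),
                       NULL, n_mutations = 20000, seed = 3, n_background = 0)
  ti <- sum(is_transition(p$truth$ref, p$truth$alt))
  se <- sqrt(0.565 * 0.435 / 20000)
  expect_lt(abs(ti / 20000 - 0.565), 3 * se)
})

test_that("hotspot weighting concentrates mutations as expected", {
  g <- generate_genome(1, 1000000, 0, seed = 9)
  hs <- hotspot_spec("chr1", 0, 10000, 50)
  p <- plant_mutations(g$genome, g$annotation,
                       spectrum_params(indel_fraction = 0), hs,
                       n_mutations = 5000, seed = 9, n_background = 0)
  n_in <- sum(p$truth$in_hotspot)
  # expected share 50*10k/(50*10k + 990k) ~ 0.336
  expect_gt(n_in / 5000, 0.25)
  # hotspot per-bp frequency exceeds 20x the chromosome mean
  expect_gt((n_in / 10000) / (5000 / 1e6), 20)
})

test_that("fixtures are deterministic byte for byte and GFF3-conformant", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_fixture(d1, chrom_length = 30000, gene_count = 3,
                   n_mutations = 200, seed = 21)
  simulate_fixture(d2, chrom_length = 30000, gene_count = 3,
                   n_mutations = 200, seed = 21)
  m1 <- md5_of_dir(d1); m2 <- md5_of_dir(d2)
  expect_identical(unname(m1), unname(m2))

  gff <- readLines(file.path(d1, "genes.gff3"))
  body <- gff[!startsWith(gff, "#")]
  expect_true(length(body) > 0)
  fields <- strsplit(body, "\t")
  expect_true(all(lengths(fields) == 9))
  starts <- as.integer(vapply(fields, `[[`, "", 4))
  ends <- as.integer(vapply(fields, `[[`, "", 5))
  expect_true(all(starts >= 1 & ends >= starts))
})

test_that("an empty per-line record set yields a valid header-only VCF", {
  g <- generate_genome(1, 20000, 0, seed = 4)
  p <- plant_mutations(g$genome, g$annotation, spectrum_params(), NULL,
                       n_mutations = 10, seed = 4, line_ids = "mut1",
                       n_background = 0)
  d <- file.path(tempdir(), "emptyvcf")
  unlink(d, recursive = TRUE)
  paths <- write_fixture(d, g$genome, g$annotation, p)
  wt <- read_vcf(paths$vcf[["WT"]], "WT")   # no background: header only
  expect_equal(nrow(wt), 0)
})

test_that("fixture round trip preserves the planted multiset exactly", {
  fx <- shared_fixture()
  tr <- fx$planted$truth
  for (l in c("mA", "mB")) {
    rec <- apply_hard_filters(read_vcf(fx$paths$vcf[[l]], l))
    wt <- apply_hard_filters(read_vcf(fx$paths$vcf[["WT"]], "WT"))
    ind <- derive_induced(rec, wt)
    tl <- tr[tr$line_id == l, ]
    expect_identical(
      sort(paste(ind$chrom, ind$pos, ind$ref, ind$alt)),
      sort(paste(tl$chrom, tl$pos, tl$ref, tl$alt)))
  }
})

test_that("spectrum_params validates its invariants", {
  expect_error(spectrum_params(ti_fraction = 1.5), "proportions")
  bad_w <- cibmut:::default_sub_weights(0.5)
  expect_error(spectrum_params(ti_fraction = 0.7, sub_weights = bad_w),
               "inconsistent")
  expect_error(spectrum_params(indel_len_dist = rep(1, 50)), "summing to 1")
  expect_error(hotspot_spec("chr1", c(0, 500), c(1000, 1500), c(2, 2)),
               "overlap")
  expect_error(hotspot_spec("chr1", 0, 1000, 0.5), "fold")
})
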