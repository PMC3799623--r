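test_that("coordinate conventions and feature extraction are exact", {
  rec <- plastome_record("r1", "AACGTTAA", circular = FALSE)
  f1 <- feature("g1", "gene", data.frame(start = 2, end = 6, strand = "+"))
  expect_identical(extract_feature_sequence(rec, f1), "CGTT")
  f2 <- feature("g2", "gene", data.frame(start = 2, end = 6, strand = "-"))
  expect_identical(extract_feature_sequence(rec, f2), "AACG")

  # multi-interval features concatenate in listed order (trans-spliced
  # style, mixed strands)
  f3 <- feature("g3", "CDS", data.frame(start = c(0, 4), end = c(2, 8),
                                        strand = c("+", "-")))
  expect_identical(extract_feature_sequence(rec, f3),
                   paste0("AA", revcomp("TTAA")))

  # origin-wrapping interval on a circular record
  circ <- plastome_record("r2", "AACGTTAA", circular = TRUE)
  fw <- feature("gw", "gene", data.frame(start = 6, end = 10, strand = "+"))
  expect_identical(extract_feature_sequence(circ, fw), "AAAA")
  expect_error(extract_feature_sequence(rec, fw), "non-circular")

  # extraction length always equals the interval-length sum
  set.seed(4)
  big <- plastome_record("r3", random_dna_str(300))
  for (i in 1:20) {
    s <- sample(0:290, 2)
    f <- feature("x", "gene",
                 data.frame(start = s, end = s + sample(3:9, 2),
                            strand = sample(c("+", "-"), 2, TRUE)))
    expect_identical(nchar(extract_feature_sequence(big, f)),
                     as.integer(sum(f$intervals$end - f$intervals$start)))
  }
})

test_that("sequence validation rejects non-N ambiguity codes", {
  expect_error(plastome_record("x", "ACGTR"), "outside")
  expect_silent(plastome_record("x", "ACGTN"))
  expect_error(plastome_record("", "ACGT"), "nonempty")
})

test_that("base composition fractions and AT percent", {
  expect_equal(base_composition("ATAT")$at_percent, 100.0)
  expect_equal(base_composition("ACGT")$at_percent, 50.0)
  b <- base_composition("AACGTN")
  expect_equal(sum(b$fractions), 1)
  expect_error(base_composition("NNN"), "unambiguous")
})

test_that("gene inventory identities hold", {
  rec <- plastome_record("r", random_dna_str(400))
  expect_equal(gene_inventory(rec)$unique_genes, 0L)

  feats <- list(
    feature("trnQ-UUG", "tRNA", data.frame(start = 0, end = 70, strand = "+")),
    feature("rrn16", "rRNA", data.frame(start = 100, end = 160, strand = "+")),
    feature("rrn16", "rRNA", data.frame(start = 300, end = 360, strand = "-")),
    feature("rbcL", "gene", data.frame(start = 200, end = 280, strand = "+")),
    feature("ycf1", "gene", data.frame(start = 370, end = 390, strand = "+"),
            pseudo = TRUE))
  rec <- plastome_record("r", random_dna_str(400), features = feats)
  gi <- gene_inventory(rec)
  expect_equal(gi$unique_genes, 3L)           # pseudogene excluded
  expect_equal(gi$duplicated_in_ir, 1L)
  expect_equal(gi$total_with_duplicates, 4L)
  expect_equal(gi$unique_genes, gi$trna + gi$rrna + gi$protein_coding)
})

test_that("GenBank files round-trip records exactly", {
  set.seed(9)
  g <- random_dna_str(900)
  feats <- list(
    feature("rps19", "gene", data.frame(start = 1, end = 10, strand = "+")),
    feature("minus", "gene", data.frame(start = 50, end = 80, strand = "-")),
    feature("twoexon", "CDS", data.frame(start = c(100, 200),
                                         end = c(150, 260),
                                         strand = c("+", "+"))),
    feature("minus2x", "CDS", data.frame(start = c(500, 400),
                                         end = c(560, 450),
                                         strand = c("-", "-"))),
    feature("wrapper", "gene", data.frame(start = 860, end = 930,
                                          strand = "+")),
    feature("pseu", "gene", data.frame(start = 700, end = 720,
                                       strand = "+"), pseudo = TRUE))
  rec <- plastome_record("RT01", g, taxon = "Testus exemplaris",
                         features = feats)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  back <- read_genbank(path)
  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$id, rec$id)
  expect_identical(back$taxon, rec$taxon)
  expect_true(back$circular)
  expect_equal(length(back$features), length(rec$features))
  for (i in seq_along(feats)) {
    expect_identical(back$features[[i]]$intervals, rec$features[[i]]$intervals)
    expect_identical(back$features[[i]]$name, rec$features[[i]]$name)
    expect_identical(back$features[[i]]$pseudo, rec$features[[i]]$pseudo)
  }
})

test_that("one-based GenBank locations convert to half-open intervals", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       MINI            9 bp    DNA     linear PLN 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     gene            1..9",
    '                     /gene="g"',
    "ORIGIN",
    "        1 acgtacgta",
    "//"), path)
  rec <- read_genbank(path)
  expect_equal(rec$features[[1]]$intervals$start, 0L)
  expect_equal(rec$features[[1]]$intervals$end, 9L)
  expect_identical(rec$sequence, "ACGTACGTA")
})

test_that("missing ORIGIN errors; bad locations are skipped with warning", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 9 bp DNA linear", "FEATURES", "//"), path)
  expect_error(read_genbank(path), "ORIGIN")
  writeLines(c(
    "LOCUS       X            9 bp    DNA     linear PLN",
    "FEATURES             Location/Qualifiers",
    "     gene            frobnicate(1..4)",
    '                     /gene="bad"',
    "     gene            6..9",
    '                     /gene="good"',
    "ORIGIN",
    "        1 acgtacgta",
    "//"), path)
  expect_warning(rec <- read_genbank(path), "unparseable")
  expect_equal(length(rec$features), 1L)
  expect_equal(rec$features[[1]]$name, "good")
})

test_that("FASTA round-trips and rejects duplicate ids", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(s1 = random_dna_str(150), s2 = random_dna_str(80))
  write_fasta(seqs, path)
  expect_identical(read_fasta(path), seqs)
  expect_error(write_fasta(stats::setNames(seqs, c("a", "a")), path),
               "unique")
})

test_that("Newick trees round-trip with zero Robinson-Foulds distance", {
  set.seed(21)
  path <- withr::local_tempfile(fileext = ".nwk")
  tr <- ape::rtree(50)
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
})

test_that("alignment container invariants: degap and source maps", {
  m <- msa(c(a = "AC-GT", b = "ACCGT"), region = "demo")
  expect_identical(degap(m, "a"), "ACGT")
  sm <- msa_source_map(m)
  expect_identical(sm$a, c(0L, 1L, NA, 2L, 3L))
  expect_identical(sm$b, 0:4)
  expect_error(msa(c(a = "ACG", b = "AC")), "equal length")
})
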