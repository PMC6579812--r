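test_that("load_reference reads FASTA, lowercases and maps ambiguity codes to n", {
  fa <- write_fixture_fasta(list(chr1 = "ACGT"))
  store <- load_reference(fa)
  expect_s3_class(store, "ref_store")
  expect_equal(unname(chrom_lengths(store)), 4L)
  expect_equal(unclass(store)[["chr1"]], "acgt")

  fa2 <- write_fixture_fasta(list(chr1 = "ACRGT"))
  expect_equal(unclass(load_reference(fa2))[["chr1"]], "acngt")

  fa3 <- write_fixture_fasta(list(chr1 = "ACGT", chr1 = "GGGG"))
  expect_error(load_reference(fa3), "duplicate")

  empty <- tempfile(fileext = ".fa"); file.create(empty)
  expect_error(load_reference(empty), "empty|read|parse")
})

test_that("read_variants parses TSV, skips non-SNVs and rejects REF==ALT", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t11\tA\tG\tdriver",
               "chr1\t20\tAT\tA\tpassenger",     # indel -> skipped
               "chr1\t5\tC\tC\tpassenger",       # REF==ALT -> rejected
               "chr2\t7\tT\tC\tPassenger",
               "chr2\t9\tG\tA"), tsv)            # no label -> unlabeled
  v <- read_variants(tsv, "tsv")
  expect_equal(nrow(v), 3L)
  expect_equal(v$label, c("driver", "passenger", "unlabeled"))
  expect_equal(attr(v, "skipped"), 1L)
  expect_equal(attr(v, "rejected"), 1L)
  expect_equal(v$pos[1], 11L)
  expect_equal(v$ref[1], "A"); expect_equal(v$alt[1], "G")

  bad <- tempfile(); writeLines("chr1\txx\tA\tG", bad)
  expect_error(read_variants(bad, "tsv"), "line 1")
})

test_that("read_variants parses VCF and keeps only biallelic SNVs", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##contig=<ID=chr1,length=1000>',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t11\tdriver\tA\tG\t.\tPASS\t.",
               "chr1\t30\t.\tA\tAT\t.\tPASS\t.",      # insertion -> skipped
               "chr1\t40\t.\tC\tG,T\t.\tPASS\t.",     # multiallelic -> skipped
               "chr1\t55\tpassenger\tT\tA\t.\tPASS\t."), vcf)
  v <- read_variants(vcf, "vcf")
  expect_equal(nrow(v), 2L)
  expect_equal(attr(v, "skipped"), 2L)
  expect_equal(v$label, c("driver", "passenger"))
})

test_that("extract_pair produces the stated matrix geometry", {
  # hand-traced fixture: chr1 = aaacgtaaaaa, variant at pos 5 (g->t), w=2
  store <- fixture_store(c(chr1 = "aaacgtaaaaa"))
  p <- extract_pair(store, list(chrom = "chr1", pos = 5, ref = "G", alt = "T"), 2)
  expect_equal(p$ref_row, "acgta")
  expect_equal(p$alt_row, "actta")

  # length law L = 2w+1 reproduces 21/101/201/1001/10001
  set.seed(1)
  big <- fixture_store(c(chr1 = paste(sample(c("a","c","g","t"), 30000,
                                             replace = TRUE), collapse = "")))
  ref15k <- toupper(substr(unclass(big)[["chr1"]], 15000, 15000))
  alt <- setdiff(c("A","C","G","T"), ref15k)[1]
  for (w in c(10, 50, 100, 500, 5000)) {
    p <- extract_pair(big, list(chrom = "chr1", pos = 15000,
                                ref = ref15k, alt = alt), w)
    expect_equal(nchar(p$ref_row), 2 * w + 1)
    expect_equal(nchar(p$alt_row), 2 * w + 1)
  }
})

test_that("rows differ only at the center and out-of-bounds pads with n", {
  store <- fixture_store(c(chr1 = "aaacgtaaaaa"))
  # variant at pos 1 with w=10: ten leading n symbols
  ref1 <- "A"
  p <- extract_pair(store, list(chrom = "chr1", pos = 1, ref = "A", alt = "C"), 10)
  expect_equal(substr(p$ref_row, 1, 10), strrep("n", 10))
  r0 <- strsplit(p$ref_row, "")[[1]]; r1 <- strsplit(p$alt_row, "")[[1]]
  expect_equal(which(r0 != r1), 11L)      # exactly one mismatch, at index w+1

  # property over random variants: single mismatch at the center,
  # and (pos, ref, alt) are recoverable from the pair
  set.seed(3)
  g <- fixture_store(c(c1 = paste(sample(c("a","c","g","t"), 500,
                                         replace = TRUE), collapse = "")))
  for (i in 1:25) {
    pos <- sample(500, 1); w <- sample(3:30, 1)
    ref <- toupper(substr(unclass(g)[["c1"]], pos, pos))
    alt <- sample(setdiff(c("A","C","G","T"), ref), 1)
    p <- extract_pair(g, list(chrom = "c1", pos = pos, ref = ref, alt = alt), w)
    a <- strsplit(p$ref_row, "")[[1]]; b <- strsplit(p$alt_row, "")[[1]]
    expect_equal(sum(a != b), 1L)
    expect_equal(which(a != b), w + 1L)
    expect_equal(toupper(a[w + 1L]), ref)
    expect_equal(toupper(b[w + 1L]), alt)
    # determinism
    p2 <- extract_pair(g, list(chrom = "c1", pos = pos, ref = ref, alt = alt), w)
    expect_identical(p$ref_row, p2$ref_row)
  }
})

test_that("reference-mismatch policy rejects by default and can warn", {
  store <- fixture_store(c(chr1 = "aaacgtaaaaa"))
  v <- list(chrom = "chr1", pos = 5, ref = "T", alt = "A")   # store has g
  expect_error(extract_pair(store, v, 2), "mismatch")
  expect_warning(p <- extract_pair(store, v, 2, on_ref_mismatch = "warn"),
                 "mismatch")
  expect_equal(p$ref_row, "acgta")   # store base kept
  expect_error(extract_pair(store, list(chrom = "chrX", pos = 1,
                                        ref = "A", alt = "C"), 2),
               "chromosome")
})

test_that("write_pairs emits the tab-separated pair table", {
  store <- fixture_store(c(chr1 = "aaacgtaaaaa"))
  p <- extract_pair(store, list(chrom = "chr1", pos = 5, ref = "G",
                                alt = "T", label = "driver"), 2)
  out <- tempfile(fileext = ".tsv")
  write_pairs(list(p), out)
  df <- read.delim(out, stringsAsFactors = FALSE)
  expect_equal(df$ref_row, "acgta")
  expect_equal(df$alt_row, "actta")
  expect_equal(df$label, "driver")
})
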