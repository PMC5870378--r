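# In-silico PCR, T-RF prediction and ARDRA fingerprints.

primers <- primerRegistry()
enzymes <- enzymeRegistry()
rc <- rcOracle
F799A <- "AACAGGATTAGATACCCGG"    # 799f with M -> A, K -> G
R1492 <- "GGTTACCTTGTTACGACTT"

test_that("in-silico PCR finds amplicons between degenerate primer sites", {
  tpl <- paste0(F799A, "TTTT", rc(R1492))
  amp <- inSilicoPCR(tpl, primers$`799f`, primers$`1492R`)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 0L)
  expect_equal(amp$length, 42L)
  expect_equal(amp$sequence, tpl)

  # forward site but no reverse site: nothing amplifies
  tpl2 <- paste0(F799A, "TTTTTTTTTT")
  expect_equal(nrow(inSilicoPCR(tpl2, primers$`799f`, primers$`1492R`)), 0L)

  # flanked amplicon with a different degeneracy expansion (M->C, K->T)
  set.seed(42)
  spacer <- randomDNAString(30)
  while (length(bruteStarts(primers$`799f`@sequence, spacer)) ||
         length(bruteStarts(rc(R1492), spacer)))
    spacer <- randomDNAString(30)
  tpl3 <- paste0(randomDNAString(10), "AACCGGATTAGATACCCTG", spacer,
                 rc(R1492), randomDNAString(5))
  amp3 <- inSilicoPCR(tpl3, primers$`799f`, primers$`1492R`)
  expect_equal(amp3$start, 10L)
  expect_equal(amp3$length, 68L)
  oracle <- brutePCR(tpl3, primers$`799f`@sequence, R1492)
  expect_equal(amp3$start, oracle$start)
  expect_equal(amp3$length, oracle$length)
})

test_that("in-silico PCR validates its inputs", {
  expect_error(inSilicoPCR("ACGTN", primers$`799f`, primers$`1492R`),
               "ambiguity")
  expect_error(inSilicoPCR("", primers$`799f`, primers$`1492R`))
  expect_error(inSilicoPCR("ACGT", "AC!T", "ACGT"), "IUPAC")
})

test_that("multiple forward matches each pair with the nearest downstream
           reverse site", {
  set.seed(11)
  mid <- randomDNAString(25)
  tpl <- paste0(F799A, mid, F799A, mid, rc(R1492))
  amp <- inSilicoPCR(tpl, primers$`799f`, primers$`1492R`)
  expect_equal(nrow(amp), 2L)
  expect_equal(amp$start, c(0L, 19L + 25L))
  expect_true(all(amp$end == nchar(tpl)))
})

test_that("predictTRF scans the labelled strand for the first site", {
  amp42 <- paste0(F799A, "TTTT", rc(R1492))
  res <- predictTRF(amp42, enzymes$DdeI)
  expect_false(res$cut_found)
  expect_equal(res$trf_length, 42L)

  amp43 <- paste0(F799A, "CTAAG", rc(R1492))
  res <- predictTRF(amp43, enzymes$DdeI)
  expect_true(res$cut_found)
  expect_equal(res$trf_length, 20L)

  res <- predictTRF("GGCCATTTT", enzymes$HaeIII)
  expect_equal(res$trf_length, 2L)

  # labelled reverse end: scan the reverse complement
  ampR <- rc(amp43)
  resR <- predictTRF(ampR, enzymes$DdeI, labeledEnd = "reverse")
  expect_equal(resR$trf_length, 20L)
})

test_that("ARDRA fragments partition the amplicon", {
  amp43 <- paste0(F799A, "CTAAG", rc(R1492))
  expect_equal(ardraPattern(amp43, enzymes$DdeI), c(23L, 20L))

  amp42 <- paste0(F799A, "TTTT", rc(R1492))
  expect_equal(ardraPattern(amp42, enzymes$DdeI), 42L)

  x <- rep("A", 40)
  x[6:9] <- c("G", "C", "G", "C")
  x[21:24] <- c("G", "C", "G", "C")
  expect_equal(ardraPattern(paste(x, collapse = ""), enzymes$HhaI),
               c(17L, 15L, 8L))
})

test_that("digest operations agree with the degeneracy-expansion oracle on
           random templates", {
  set.seed(101)
  for (i in 1:100) {
    tpl <- randomDNAString(sample(100:800, 1))
    # plant a primer pair in half the templates so amplification happens
    if (i %% 2 == 0) {
      f <- sample(expandDegenerate(primers$`799f`@sequence), 1)
      pos <- sample(1:40, 1)
      substr(tpl, pos, pos + 18) <- f
      pos2 <- pos + 19 + sample(50:200, 1)
      if (pos2 + 18 <= nchar(tpl))
        substr(tpl, pos2, pos2 + 18) <- rc(R1492)
    }
    amp <- inSilicoPCR(tpl, primers$`799f`, primers$`1492R`)
    oracle <- brutePCR(tpl, primers$`799f`@sequence, R1492)
    expect_equal(amp$start, oracle$start)
    expect_equal(amp$length, oracle$length)
    if (nrow(amp)) {
      a <- amp$sequence[1]
      for (ez in enzymes) {
        pred <- predictTRF(a, ez)
        bt <- bruteTRF(a, ez@site, ez@cutOffset)
        expect_equal(pred$trf_length, bt$trf)
        expect_equal(pred$cut_found, bt$found)
        frag <- ardraPattern(a, ez)
        expect_equal(sum(frag), nchar(a))
        expect_equal(frag, bruteDigest(a, ez@site, ez@cutOffset))
      }
    }
  }
})

test_that("the labelled T-RF equals the leftmost ARDRA cut", {
  set.seed(7)
  for (i in 1:50) {
    a <- randomDNAString(sample(60:500, 1))
    for (ez in enzymes) {
      pred <- predictTRF(a, ez)
      frag <- ardraPattern(a, ez)
      ordered <- bruteDigestOrdered(a, ez@site, ez@cutOffset)
      expect_equal(sort(frag, decreasing = TRUE),
                   sort(ordered, decreasing = TRUE))
      if (pred$cut_found) {
        expect_equal(pred$trf_length, ordered[1])
      } else {
        expect_equal(frag, nchar(a))
      }
    }
  }
})

test_that("digesting the reverse complement reverses blunt-cut fragment
           lists and preserves counts for overhang cutters", {
  set.seed(13)
  for (i in 1:40) {
    a <- randomDNAString(sample(80:400, 1))
    ar <- rcOracle(a)
    for (ez in enzymes) {
      f1 <- ardraPattern(a, ez)
      f2 <- ardraPattern(ar, ez)
      expect_equal(sum(f1), sum(f2))
      expect_equal(length(f1), length(f2))
      if (ez@name == "HaeIII") {
        expect_equal(sort(f1), sort(f2))  # blunt cut: exact mirror
      } else {
        # sticky ends shift boundaries by at most the overhang
        ov <- abs(nchar(ez@site) - 2L * ez@cutOffset)
        expect_true(all(abs(sort(f1) - sort(f2)) <= ov))
      }
    }
  }
})

test_that("ARDRA pattern equivalence tolerates small size differences", {
  expect_true(ardraEquivalent(c(100, 50), c(50.5, 99.8)))
  expect_false(ardraEquivalent(c(100, 50), c(100, 47)))
  expect_false(ardraEquivalent(c(100, 50), c(150)))
})

test_that("assignIdentity links bins to predicted taxa within tolerance", {
  preds <- data.frame(
    taxon = c("Curtobacterium", "Xanthomonas", "Microbacterium", "Delftia"),
    trf_length = c(506, 353, 353, 64))
  expect_equal(assignIdentity(506.0, preds, 1.0), "Curtobacterium")
  expect_equal(assignIdentity(353.2, preds, 1.0),
               c("Microbacterium", "Xanthomonas"))
  expect_equal(assignIdentity(144.0, preds, 1.0), character())
})

test_that("FASTA templates round-trip through the reader", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1 some description", "acgtACGT", "acgt",
               ">t2", "GGCCATT"), tf)
  seqs <- readTemplates(tf)
  expect_equal(names(seqs), c("t1", "t2"))
  expect_equal(as.character(seqs[["t1"]]), "ACGTACGTACGT")

  tf2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "ACGTN"), tf2)
  expect_error(readTemplates(tf2), "non-A/C/G/T")
})

test_that("registries and plain-text extension behave", {
  expect_equal(enzymes$DdeI@cutOffset, 1L)
  expect_equal(enzymes$HaeIII@cutOffset, 2L)
  expect_equal(enzymes$HhaI@cutOffset, 3L)
  expect_true(primers$`799f`@labeled)
  expect_warning(RestrictionEnzyme("EcoRI-ish", "GAATTT", 1L),
                 "palindromic")

  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# custom registry", "primer myF ACGTRY labeled",
               "enzyme MspI CCGG 1"), tf)
  reg <- readRegistryConfig(tf)
  expect_true(reg$primers$myF@labeled)
  expect_equal(reg$enzymes$MspI@site, "CCGG")
})

test_that("prediction tables carry taxon labels per enzyme", {
  set.seed(5)
  tpl <- paste0(F799A, "AA", "CTAAG", randomDNAString(40), rc(R1492))
  tab <- predictionTable(c(clone1 = tpl), taxa = "Pantoea")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$trf_length[tab$enzyme == "DdeI"], 22L)
  expect_setequal(tab$taxon, "Pantoea")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writePredictionTable(tab, tf)
  back <- read.delim(tf)
  expect_equal(back$trf_length, tab$trf_length)
})
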