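test_that("parsing builds aligned duplexes and round-trips through serialization", {
  d <- parseDuplex("UCAGPCAGU\nAGUCAGUCA")
  expect_equal(pairCount(d), 9L)
  cls <- classifyPairs(d)
  expect_equal(as.character(cls$category[5]), "PSI_A")
  expect_false(any(cls$category == "MISMATCH"))

  ## minimal one-pair duplex
  d1 <- parseDuplex("A\nU")
  expect_equal(pairCount(d1), 1L)
  expect_equal(as.character(classifyPairs(d1)$category), "WC_AU")

  ## a shorter bottom strand yields a single 5' dangling end, auto-aligned
  dd <- parseDuplex("PCAGUCAGU\nGUCAGUCA")
  cls <- classifyPairs(dd)
  expect_equal(pairCount(dd), 8L)
  expect_equal(as.character(cls$category[1]), "DANGLING_5")
  expect_equal(cls$top[1], "P")

  ## serialization round-trip on every fixture duplex
  for (d in tableFixtures()$duplex) {
    d2 <- parseDuplex(formatDuplex(d))
    expect_equal(topStrand(d2), topStrand(d))
    expect_equal(bottomStrand(d2), bottomStrand(d))
    expect_equal(classifyPairs(d2), classifyPairs(d))
  }
})

test_that("the Greek letter Psi is accepted on input and emitted as P", {
  d <- parseDuplex("5′ UCAGΨCAGU 3′\n3′ AGUCAGUCA 5′")
  expect_equal(topStrand(d), "UCAGPCAGU")
  expect_false(grepl("Ψ", formatDuplex(d)))
})

test_that("illegal input is rejected", {
  expect_error(parseDuplex("UCXGU\nAGUCA"), "illegal residue")
  ## a length difference of two on one strand is fine (one overhang per
  ## end); three is not
  expect_equal(pairCount(duplex("UCAGUC", "AGUA")), 4L)
  expect_error(duplex("UCAGUCA", "AGUA"), "irreconcilable|overhang")
  expect_error(parseDuplex("UCAGU\nAGUCA\nAGUCA"), "two strand lines")
})

test_that("reverseDuplex is an involution that preserves pair classes", {
  d <- parseDuplex("UC\nAG")
  r <- reverseDuplex(d)
  expect_equal(topStrand(r), "GA")
  expect_equal(bottomStrand(r), "CU")
  for (d in tableFixtures()$duplex) {
    rr <- reverseDuplex(reverseDuplex(d))
    expect_equal(topStrand(rr), topStrand(d))
    expect_equal(bottomStrand(rr), bottomStrand(d))
    ## rotation preserves the multiset of physical pair classes (the
    ## top/bottom orientation of a WC pair flips by construction)
    declass <- function(x) {
      x <- as.character(classifyPairs(x)$category)
      x[x %in% c("WC_AU", "WC_UA")] <- "AU"
      x[x %in% c("WC_GC", "WC_CG")] <- "GC"
      sort(x)
    }
    expect_equal(declass(reverseDuplex(d)), declass(d))
  }
})

test_that("classification identifies wobble, Psi and mismatch pairs", {
  cls <- classifyPairs(parseDuplex("UCAGPCAGU\nAGUCGGUCA"))
  expect_equal(as.character(cls$category[5]), "PSI_G")
  cls <- classifyPairs(duplex("GG", "CU"))
  expect_equal(as.character(cls$category), c("WC_GC", "WOBBLE_GU"))
  ## both orientations of G-U map to the wobble class
  expect_equal(as.character(classifyPairs(duplex("U", "G"))$category), "WOBBLE_GU")
  expect_equal(as.character(classifyPairs(duplex("G", "A"))$category), "MISMATCH")
})

test_that("reference duplexes are Watson-Crick except at the designed test site", {
  fx <- tableFixtures()
  for (i in seq_len(nrow(fx))) {
    cls <- classifyPairs(fx$duplex[[i]])
    odd <- !cls$category %in% c("WC_AU", "WC_UA", "WC_GC", "WC_CG")
    info <- paste(fx$group[i], fx$variant[i])
    if (fx$variant[i] == "core") {
      expect_equal(sum(odd), 0L, info = info)
    } else {
      ## at most the single designed site deviates from Watson-Crick;
      ## every Psi-containing duplex deviates exactly there (U analogs of
      ## the Psi-A duplexes are fully Watson-Crick)
      expect_lte(sum(odd), 1L)
      if (fx$variant[i] == "psi") {
        expect_equal(sum(odd), 1L, info = info)
        expect_match(as.character(cls$category[odd]), "^(PSI_|DANGLING)",
                     info = info)
      }
      ## a MISMATCH may only ever be the designed U-U / U-C site
      expect_true(sum(cls$category == "MISMATCH") <= sum(odd), info = info)
    }
  }
})
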