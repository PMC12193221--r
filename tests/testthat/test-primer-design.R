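cox2_f <- "TGGAACCCCTGGACGACTTA"   # forward, 20 bp
cox2_r <- "ACTGTGATTAGCTCCGCAAA"   # reverse, 20 bp

test_that("gc_content matches hand counts and rejects bad input", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content(cox2_f), 11 / 20)  # hand count: 11 G+C of 20
  expect_equal(gc_content("GCNNAT"), 0.5)    # ambiguity excluded both sides
  expect_error(gc_content(""), "value error")
  expect_error(gc_content("AC-GT"), "gapped")
})

test_that("check_primer reports all failures with machine-readable reasons", {
  expect_true(check_primer(cox2_f)$pass)
  expect_true(check_primer(cox2_r)$pass)

  v <- check_primer("AGCGGGAATAGTGGGAA")  # 17 bp literature candidate
  expect_false(v$pass)
  expect_equal(v$failures, "length")

  v <- check_primer(strrep("G", 20))
  expect_false(v$pass)
  expect_true("gc" %in% v$failures)

  # multiple simultaneous failures are all reported
  v <- check_primer(strrep("G", 24))
  expect_true(all(c("length", "gc") %in% v$failures))

  # hairpin: 5-bp stem, 4-nt loop, inside a length/GC-passing oligo
  hp <- "GCCGATTTTATCGGCAATAT"
  expect_true("hairpin" %in% check_primer(hp)$failures)

  # self-dimer: 8-bp palindrome gives an 8-bp antiparallel run
  sd8 <- "AGTGCATATGCTTGACCTAA"
  expect_true("self_dimer" %in% check_primer(sd8)$failures)

  expect_equal(check_primer("ACGTNACGTNACGTNACGT")$failures, "alphabet")
})

test_that("check_primer verdicts are case-invariant", {
  oligos <- c(cox2_f, cox2_r, "AGCGGGAATAGTGGGAA", strrep("G", 20),
              "GCCGATTTTATCGGCAATAT")
  for (o in oligos) {
    expect_identical(check_primer(tolower(o)), check_primer(o))
  }
})

test_that("enumerate_pairs finds flank-spanning pairs under constraints", {
  recs <- synth_barcodes(synth_panel_spec(6, 20, 57, 0.3, seed = 11))
  regions <- find_regions(conservation_profile(recs))
  pairs <- enumerate_pairs(recs, regions)
  expect_gt(nrow(pairs), 0)
  full <- pairs[pairs$product_len == 97, ]
  expect_gt(nrow(full), 0)  # includes full-flank 97 bp products
  expect_true(any(full$fwd_start == 0 & full$rev_end == 97))
  expect_true(all(diff(pairs$product_len) >= 0))  # sorted by product length

  # tightening product_max drops the long products
  small <- enumerate_pairs(recs, regions, primer_constraints(product_max = 50))
  expect_false(any(small$product_len > 50))

  # adjacent conserved regions with no variable core -> nothing to design
  ident <- lapply(1:3, function(i) {
    barcode_record(paste0("s", i), strrep("ACGT", 25))
  })
  reg2 <- find_regions(conservation_profile(ident))
  expect_equal(nrow(enumerate_pairs(ident, reg2)), 0L)
  # and no conserved regions at all -> empty, not an error
  div <- conservation_profile(list(barcode_record("a", strrep("A", 30)),
                                   barcode_record("b", strrep("C", 30))))
  expect_equal(nrow(enumerate_pairs(ident, find_regions(div))), 0L)
})

test_that("enumerated pairs re-pass screening and reproduce product length", {
  recs <- synth_barcodes(synth_panel_spec(6, 20, 57, 0.3, seed = 11))
  regions <- find_regions(conservation_profile(recs))
  pairs <- enumerate_pairs(recs, regions)
  consensus <- paste(vapply(seq_len(nchar(recs[[1]]$sequence)), function(j) {
    col <- substr(vapply(recs, `[[`, "", "sequence"), j, j)
    names(which.max(table(col)))
  }, ""), collapse = "")
  for (i in seq_len(min(nrow(pairs), 10L))) {
    expect_true(check_primer(pairs$fwd[i])$pass)
    expect_true(check_primer(pairs$rev[i])$pass)
    amps <- in_silico_pcr(pairs$fwd[i], pairs$rev[i], consensus)
    expect_equal(vapply(amps, `[[`, 0L, "length"), pairs$product_len[i])
  }
})

test_that("in_silico_pcr recovers constructed binding sites", {
  set.seed(42)
  core <- random_acgt(57)
  template <- paste0(cox2_f, core, oracle_revcomp(cox2_r))
  amps <- in_silico_pcr(cox2_f, cox2_r, template)
  expect_length(amps, 1L)
  expect_equal(amps[[1]]$length, 97L)
  expect_equal(amps[[1]]$sequence, template)

  # template lacking a reverse site -> no product
  expect_length(in_silico_pcr(cox2_f, cox2_r, paste0(cox2_f, core)), 0L)

  # mismatch tolerance with exact 3' anchoring
  mut <- template
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(mut, 3, 3))[1]
  expect_length(in_silico_pcr(cox2_f, cox2_r, mut, max_mismatch = 0), 0L)
  expect_length(in_silico_pcr(cox2_f, cox2_r, mut, max_mismatch = 1,
                              three_prime_exact = 5), 1L)
  # a 3'-terminal mismatch is never tolerated under the exactness rule
  mut3 <- template
  substr(mut3, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mut3, 20, 20))[1]
  expect_length(in_silico_pcr(cox2_f, cox2_r, mut3, max_mismatch = 1,
                              three_prime_exact = 5), 0L)
})

test_that("COXII primer pair amplifies 97 bp from the synthetic template", {
  # synthetic stand-in for the P. misera COXII region (no network access to
  # the real accession); exact primer footprints at the published spacing
  rec <- read_fasta(system.file("extdata", "synthetic_pmisera_coxii.fasta",
                                package = "hrmid"))[[1]]
  expect_equal(rec$gene, "COXII")
  amps <- in_silico_pcr(cox2_f, cox2_r, rec$sequence,
                        max_mismatch = 3, three_prime_exact = 5)
  expect_length(amps, 1L)
  expect_equal(amps[[1]]$length, 97L)
})

test_that("exact-match mode agrees with a naive string-search oracle", {
  set.seed(7)
  for (trial in 1:20) {
    fwd <- random_acgt(20)
    rev <- random_acgt(20)
    template <- random_acgt(1000)
    # plant 0-2 sites of each primer at random positions
    for (s in sample(c(fwd, oracle_revcomp(rev)), sample(0:2, 1),
                     replace = TRUE)) {
      pos <- sample(1000 - 20, 1)
      substr(template, pos, pos + 19) <- s
    }
    got <- sort(vapply(in_silico_pcr(fwd, rev, template), `[[`, 0L, "length"))
    expect_equal(got, oracle_pcr_products(fwd, rev, template))
  }
})
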