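test_that("codon alignment drops gapped columns and validates stops", {
  ident <- codon_align("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(ident$n_dropped, 0)
  expect_equal(ident$codons_a, ident$codons_b)
  # one extra codon in b: exactly one dropped column
  a <- "ATGGCTGCTAAACCC"
  b <- "ATGGCTGCTGGGAAACCC" # GGG inserted
  aln <- codon_align(a, b)
  expect_equal(aln$n_dropped, 1)
  expect_equal(length(aln$codons_a), 5)
  # internal stop names the codon index
  expect_error(codon_align("ATGTAAAAA", "ATGGCTAAA"), "codon index 2")
  # positional pairing requires equal lengths
  expect_error(codon_align(a, b, method = "positional"), "equal coding")
  pos <- codon_align(a, "ATGGCAGCAAAACCA", method = "positional")
  expect_equal(length(pos$codons_a), 5)
})

test_that("ng86 matches hand-enumerated single-codon cases", {
  # identical sequences: Ka = Ks = 0, omega undefined
  r0 <- ng86(codon_align("GGTGGT", "GGTGGT"))
  expect_equal(r0$Ks, 0)
  expect_equal(r0$Ka, 0)
  expect_true(r0$undefined_omega)
  expect_true(is.na(r0$omega))

  # TTT vs TTA: enumerating the 9 single-nt neighbours of each codon
  # (stop-creating changes nonsynonymous) gives S = (1/3 + 2/3)/2 = 0.5,
  # N = 2.5, one nonsynonymous difference
  r1 <- ng86(codon_align("TTT", "TTA"))
  expect_equal(r1$S, 0.5)
  expect_equal(r1$N, 2.5)
  expect_equal(r1$Sd, 0)
  expect_equal(r1$Nd, 1)
  expect_equal(r1$pN, 0.4)
  expect_equal(r1$Ka, -0.75 * log(1 - 4 * 0.4 / 3))
  expect_equal(r1$Ks, 0)

  # GGT GGT GGT vs GGC GGT GGT: S = 3, Sd = 1, Ks = -(3/4) log(5/9)
  r2 <- ng86(codon_align("GGTGGTGGT", "GGCGGTGGT"))
  expect_equal(r2$S, 3)
  expect_equal(r2$Sd, 1)
  expect_equal(r2$pS, 1 / 3)
  expect_equal(r2$Ks, -0.75 * log(5 / 9))
  expect_equal(r2$Ka, 0)
})

test_that("ng86 is symmetric and conserves sites", {
  set.seed(31)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    a <- paste(sample(sense, n, replace = TRUE), collapse = "")
    b_cods <- sample(sense, n, replace = TRUE)
    # keep divergence moderate: copy most codons from a
    keep <- runif(n) < 0.8
    b_cods[keep] <- abcsurvey:::split_codons(a)[keep]
    b <- paste(b_cods, collapse = "")
    rab <- tryCatch(ng86(codon_align(a, b, method = "positional")),
                    error = function(e) NULL)
    if (is.null(rab)) next
    rba <- ng86(codon_align(b, a, method = "positional"))
    expect_equal(rab$Ks, rba$Ks)
    expect_equal(rab$Ka, rba$Ka)
    expect_equal(rab$Sd, rba$Sd)
    # site conservation: S + N = 3 x retained columns
    expect_equal(rab$S + rab$N, 3 * rab$n_codons)
  }
})

test_that("pathway counts match the exhaustive oracle on sampled codon pairs", {
  code <- oracle_code()
  sense <- names(code)[code != "*"]
  set.seed(41)
  idx <- cbind(sample(sense, 150, replace = TRUE),
               sample(sense, 150, replace = TRUE))
  tab <- abcsurvey:::ng_pair_table()
  sites <- abcsurvey:::ng_site_table()
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]
    b <- idx[r, 2]
    want <- oracle_path_counts(a, b, code)
    expect_equal(tab$Sd[a, b], want[1], info = paste(a, b))
    expect_equal(tab$Nd[a, b], want[2], info = paste(a, b))
    expect_equal(sites$S[[a]], oracle_syn_sites(a, code), info = a)
  }
})

test_that("Jukes-Cantor distance is monotone on [0, 3/4)", {
  p <- seq(0, 0.74, 0.01)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
  # beyond-saturation proportion raises a distinct error
  # (AAA vs GGG etc. have pN < 3/4, so build one directly)
  aln <- structure(
    list(codons_a = rep("AAA", 4), codons_b = rep("CCC", 4), n_dropped = 0L),
    class = "codon_alignment"
  )
  expect_error(ng86(aln), "Jukes-Cantor")
})

test_that("divergence time follows the synonymous clock", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.013), 1.0)
  expect_equal(divergence_time(1.5665), 120.5)
  # lambda scales inversely
  expect_equal(divergence_time(0.13, lambda = 6.5e-8), 1.0)
  expect_error(divergence_time(-0.1), "non-negative")
})

test_that("kaks_table applies the saturation filter to summaries", {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  set.seed(51)
  anc <- paste(sample(sense, 200, replace = TRUE), collapse = "")
  lo <- evolve_cds_pair(anc, 0.3, 0.2, seed = 1)$descendant
  hi <- evolve_cds_pair(anc, 2.6, 0.2, seed = 2)$descendant
  cds <- c(a = anc, b = lo, c = hi)
  pairs <- data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
                      stringsAsFactors = FALSE)
  tab <- kaks_table(pairs, cds)
  expect_equal(nrow(tab), 2)
  flagged <- tab[tab$gene_b == "c", ]
  expect_true(flagged$discarded)
  summ <- attr(tab, "summary")
  expect_equal(summ$n, 1)
  expect_equal(summ$ks_max, tab$Ks[tab$gene_b == "b"])
  expect_error(kaks_table(data.frame(gene_a = "a", gene_b = "zz"), cds),
               "no CDS")
})

test_that("purifying-selection simulations yield omega below one", {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  hits <- 0
  n <- 40
  for (r in seq_len(n)) {
    set.seed(600 + r)
    anc <- paste(sample(sense, 300, replace = TRUE), collapse = "")
    d <- evolve_cds_pair(anc, 0.5, 0.2)$descendant
    res <- ng86(codon_align(anc, d, method = "positional"))
    if (!is.na(res$omega) && res$omega < 1) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})
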