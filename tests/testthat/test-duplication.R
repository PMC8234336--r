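test_that("pairwise homology reports identities, ranks and family structure", {
  base <- abcsurvey:::random_protein(200)
  fam <- withr::with_seed(3, c(
    m1 = base,
    m2 = as.character(abcsurvey:::mutate_protein(base, 0.1, protected = NULL)),
    m3 = as.character(abcsurvey:::mutate_protein(base, 0.15, protected = NULL)),
    bg1 = abcsurvey:::random_protein(200),
    bg2 = abcsurvey:::random_protein(250)
  ))
  pairs <- pairwise_homology(fam)
  # identical pair
  ident <- pairwise_homology(c(a = base, b = base))
  expect_equal(ident$identity, 100)
  expect_equal(ident$rank_a, 1L)
  # three-member family: each member appears in 2 pairs
  fam_pairs <- pairs[grepl("^m", pairs$gene_a) & grepl("^m", pairs$gene_b), ]
  expect_equal(nrow(fam_pairs), 3)
  cnt <- table(c(fam_pairs$gene_a, fam_pairs$gene_b))
  expect_true(all(cnt == 2))
  # no background cross-pairs at the default 40% identity floor
  expect_false(any(grepl("^bg", pairs$gene_a) | grepl("^bg", pairs$gene_b)))
  # symmetric canonical storage
  expect_true(all(pairs$gene_a < pairs$gene_b))
})

diag_genes <- function(n, chrom = "Chr01") {
  data.frame(
    gene_id = sprintf("%s_g%02d", chrom, seq_len(n)), chrom = chrom,
    rank = seq_len(n), stringsAsFactors = FALSE
  )
}

test_that("block chaining needs min_anchors and respects monotonicity", {
  ga <- diag_genes(10, "Chr01")
  gb <- diag_genes(10, "Chr02")
  mk_pairs <- function(idx_a, idx_b) {
    data.frame(gene_a = ga$gene_id[idx_a], gene_b = gb$gene_id[idx_b],
               stringsAsFactors = FALSE)
  }
  genes <- rbind(ga, gb)
  five <- detect_collinear_blocks(mk_pairs(1:5, 1:5), genes, min_anchors = 5)
  expect_equal(nrow(five$blocks), 1)
  expect_equal(five$blocks$n_anchors, 5)
  expect_equal(five$blocks$orientation, "same")
  four <- detect_collinear_blocks(mk_pairs(1:4, 1:4), genes, min_anchors = 5)
  expect_equal(nrow(four$blocks), 0)
  # inverted block
  inv <- detect_collinear_blocks(mk_pairs(1:5, 5:1), genes, min_anchors = 5)
  expect_equal(inv$blocks$orientation, "inverted")
  # gap constraint: a rank jump beyond max_gap breaks the chain
  gap <- detect_collinear_blocks(mk_pairs(c(1:4, 10), c(1:4, 10)),
                                 rbind(diag_genes(30, "Chr01"),
                                       diag_genes(30, "Chr02")),
                                 min_anchors = 5, max_gap = 3)
  expect_equal(nrow(gap$blocks), 0)
})

test_that("DP chaining equals the brute-force best chain on random instances", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    anchors <- data.frame(rank_a = sort(sample(1:40, n)),
                          rank_b = sample(1:40, n))
    max_gap <- sample(c(5, 10, 25), 1)
    for (dir in c(1, -1)) {
      got <- abcsurvey:::chain_dp(anchors, max_gap, dir)
      want <- oracle_best_chain_len(anchors$rank_a, anchors$rank_b,
                                    max_gap, dir)
      expect_equal(length(got), want, info = paste("rep", rep, "dir", dir))
      # returned chain is itself valid
      if (length(got) > 1) {
        da <- diff(anchors$rank_a[got])
        db <- dir * diff(anchors$rank_b[got])
        expect_true(all(da > 0 & da <= max_gap & db > 0 & db <= max_gap))
      }
    }
  }
})

test_that("duplicate classification applies the documented precedence", {
  genes <- diag_genes(30)
  pairs1 <- data.frame(gene_a = "Chr01_g05", gene_b = "Chr01_g06",
                       stringsAsFactors = FALSE)
  no_blocks <- list(blocks = data.frame(), anchors = data.frame(
    gene_a = character(), gene_b = character(), block_id = integer()
  ))
  tandem <- classify_duplicates(genes, pairs1, no_blocks)
  expect_equal(
    tandem$calls$type[tandem$calls$gene_id %in% c("Chr01_g05", "Chr01_g06")],
    c("tandem", "tandem")
  )
  # 8 ranks apart with window 10 -> proximal
  pairs2 <- data.frame(gene_a = "Chr01_g05", gene_b = "Chr01_g13",
                       stringsAsFactors = FALSE)
  prox <- classify_duplicates(genes, pairs2, no_blocks, proximal_window = 10)
  expect_equal(prox$calls$type[prox$calls$gene_id == "Chr01_g05"], "proximal")
  # beyond the window -> dispersed
  pairs3 <- data.frame(gene_a = "Chr01_g05", gene_b = "Chr01_g25",
                       stringsAsFactors = FALSE)
  disp <- classify_duplicates(genes, pairs3, no_blocks, proximal_window = 10)
  expect_equal(disp$calls$type[disp$calls$gene_id == "Chr01_g05"], "dispersed")
  # block membership outranks adjacency
  blocks <- list(blocks = data.frame(block_id = 1L), anchors = data.frame(
    gene_a = "Chr01_g05", gene_b = "Chr01_g06", block_id = 1L,
    stringsAsFactors = FALSE
  ))
  wgd <- classify_duplicates(genes, pairs1, blocks)
  expect_equal(wgd$calls$type[wgd$calls$gene_id == "Chr01_g05"],
               "wgd_segmental")
  # unclassifiable reference -> validation error
  pairs_bad <- data.frame(gene_a = "Chr01_g05", gene_b = "nope")
  expect_error(classify_duplicates(genes, pairs_bad, no_blocks), "absent")
})

test_that("types partition the gene set and are order-invariant", {
  sim <- small_sim(seed = 61)
  prot <- sim$annotation$protein
  pairs <- pairwise_homology(prot)
  blocks <- detect_collinear_blocks(pairs, sim$annotation$genes)
  dup <- classify_duplicates(sim$annotation$genes, pairs, blocks)
  expect_equal(sum(dup$counts), nrow(sim$annotation$genes))
  expect_equal(unname(table(dup$calls$type)[names(dup$counts)[dup$counts > 0]]),
               unname(dup$counts[dup$counts > 0]),
               ignore_attr = TRUE)
  # swapping a/b and shuffling row order leaves the classification intact
  pairs_sw <- pairs
  pairs_sw[, c("gene_a", "gene_b")] <- pairs_sw[, c("gene_b", "gene_a")]
  pairs_sw <- pairs_sw[sample(nrow(pairs_sw)), ]
  dup2 <- classify_duplicates(sim$annotation$genes, pairs_sw, blocks)
  expect_equal(dup2$calls[order(dup2$calls$gene_id), "type"],
               dup$calls[order(dup$calls$gene_id), "type"])
})

subset_annotation <- function(ann, keep) {
  g <- ann$genes[ann$genes$gene_id %in% keep, ]
  f <- ann$features[ann$features$gene_id %in% keep, ]
  g$start1 <- g$start0 + 1
  g$end1 <- g$end0
  f$start1 <- f$start0 + 1
  f$end1 <- f$end0
  new_genome_annotation(g, f, cds = ann$cds[g$gene_id],
                        protein = ann$protein[g$gene_id],
                        chrom_lengths = ann$chrom_lengths)
}

test_that("interspecies synteny classifies match cardinality", {
  # duplicate-free genome vs its own copy: strict one-to-one everywhere
  plain <- simulate_genome(genome_sim_config(
    n_chromosomes = 2, chrom_length = 2e6, n_background_genes = 25, seed = 81
  ))
  syn <- interspecies_synteny(plain$annotation, plain$annotation)
  expect_gt(nrow(syn$blocks), 0)
  expect_true(all(syn$family_pairs$cardinality == "one-to-one"))
  expect_setequal(syn$family_pairs$gene_a, plain$annotation$genes$gene_id)

  # shuffled gene order in B destroys collinearity
  annB <- plain$annotation
  withr::with_seed(8, {
    annB$genes$rank <- sample(annB$genes$rank)
  })
  synB <- interspecies_synteny(plain$annotation, annB)
  expect_equal(nrow(synB$blocks), 0)

  # a region duplicated in A but single in B gives many-to-one matches
  sim <- simulate_genome(genome_sim_config(
    n_chromosomes = 3, chrom_length = 3e6, n_background_genes = 30,
    seed = 91,
    events = list(planted_duplication("A", "segmental", 0.2, 0.2,
                                      block_size = 6, n_family = 1))
  ))
  ann <- sim$annotation
  ev_genes <- sim$truth$gene_id
  drop_chrom <- ann$genes$chrom[match(ev_genes[1], ann$genes$gene_id)]
  keep <- ann$genes$gene_id[
    !(ann$genes$gene_id %in% ev_genes & ann$genes$chrom == drop_chrom)
  ]
  annB2 <- subset_annotation(ann, keep)
  syn2 <- interspecies_synteny(ann, annB2)
  fam_b <- intersect(ev_genes, annB2$genes$gene_id)
  hit <- syn2$family_pairs[syn2$family_pairs$gene_b %in% fam_b &
                             syn2$family_pairs$gene_a != syn2$family_pairs$gene_b, ]
  expect_gt(nrow(hit), 0)
  expect_true(any(syn2$family_pairs$cardinality == "many-to-one"))
})
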