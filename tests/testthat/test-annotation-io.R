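make_tiny_annotation <- function() {
  new_genome_annotation(
    genes = data.frame(
      gene_id = c("gA", "gB"), chrom = c("Chr01", "Chr01"),
      strand = c("+", "-"), start1 = c(100, 1000), end1 = c(199, 1400),
      stringsAsFactors = FALSE
    ),
    features = data.frame(
      gene_id = c("gA", "gA", "gB", "gB", "gB", "gB"),
      chrom = "Chr01",
      strand = c("+", "+", "-", "-", "-", "-"),
      type = c("exon", "CDS", "exon", "CDS", "exon", "CDS"),
      start1 = c(100, 100, 1000, 1000, 1200, 1200),
      end1 = c(199, 199, 1100, 1100, 1400, 1400),
      stringsAsFactors = FALSE
    ),
    cds = c(gA = strrep("ATG", 33) %+% "TAA",
            gB = strrep("GGT", 100) %+% "TAG"),
    protein = c(gA = strrep("M", 33), gB = strrep("G", 100)),
    chrom_lengths = c(Chr01 = 10000)
  )
}
`%+%` <- function(a, b) paste0(a, b)

test_that("GFF3 coordinates convert to 0-based half-open and back losslessly", {
  ann <- make_tiny_annotation()
  # 1-based [100, 199] -> internal (99, 199), length 100
  expect_equal(ann$genes$start0[ann$genes$gene_id == "gA"], 99)
  expect_equal(ann$genes$end0[ann$genes$gene_id == "gA"], 199)
  expect_equal(with(ann$genes[1, ], end0 - start0), 100)

  d <- withr::local_tempdir()
  write_annotation(ann, gff3 = file.path(d, "a.gff3"),
                   protein_fasta = file.path(d, "p.fa"),
                   cds_fasta = file.path(d, "c.fa"))
  gff_lines <- readLines(file.path(d, "a.gff3"))
  gene_row <- strsplit(grep("\tgene\t", gff_lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(gene_row[4:5]), c(100, 199))

  ann2 <- read_annotation(file.path(d, "a.gff3"), file.path(d, "p.fa"),
                          file.path(d, "c.fa"))
  expect_equal(ann2$genes$start0, ann$genes$start0)
  expect_equal(ann2$genes$end0, ann$genes$end0)
  expect_equal(ann2$genes$strand, ann$genes$strand)
  expect_identical(unname(unlist(ann2$cds)), unname(unlist(ann$cds)))

  # second round trip reproduces the file byte for byte
  write_annotation(ann2, gff3 = file.path(d, "b.gff3"))
  expect_identical(readLines(file.path(d, "b.gff3")), gff_lines)
})

test_that("synthetic genomes round-trip through annotation I/O", {
  sim <- small_sim(seed = 21)
  d <- withr::local_tempdir()
  paths <- write_genome(sim, d)
  ann2 <- read_annotation(paths[["gff3"]], paths[["proteins"]], paths[["cds"]])
  g1 <- sim$annotation$genes
  g2 <- ann2$genes[match(g1$gene_id, ann2$genes$gene_id), ]
  expect_equal(g2$start0, g1$start0)
  expect_equal(g2$end0, g1$end0)
  expect_equal(g2$rank, g1$rank)
  expect_identical(unlist(ann2$protein[g1$gene_id]),
                   unlist(sim$annotation$protein[g1$gene_id]))
})

test_that("cross-reference and length validation errors are raised", {
  g <- data.frame(gene_id = "gA", chrom = "Chr01", strand = "+",
                  start1 = 1, end1 = 102, stringsAsFactors = FALSE)
  f <- data.frame(gene_id = "gA", chrom = "Chr01", strand = "+",
                  type = "exon", start1 = 1, end1 = 102,
                  stringsAsFactors = FALSE)
  expect_error(
    new_genome_annotation(g, f, cds = c(gA = strrep("ATG", 34)),
                          protein = c(gA = strrep("M", 10))),
    "length mismatch"
  )
  expect_error(
    new_genome_annotation(g, f, cds = c(other = strrep("ATG", 34)),
                          protein = c(gA = strrep("M", 34))),
    "cross-referenced"
  )
  # a CDS with or without the terminal stop codon both validate
  expect_no_error(new_genome_annotation(
    g, f, cds = c(gA = paste0(strrep("ATG", 33), "TAA")),
    protein = c(gA = strrep("M", 33))
  ))
  expect_no_error(new_genome_annotation(
    g, f, cds = c(gA = strrep("ATG", 33)),
    protein = c(gA = strrep("M", 33))
  ))
})

test_that("structure statistics count exons, introns and UTRs", {
  sim <- small_sim(seed = 31)
  st <- structure_stats(sim$annotation)
  expect_equal(st$per_gene$n_introns, pmax(st$per_gene$n_exons - 1, 0))
  single <- st$per_gene[st$per_gene$n_exons == 1, ]
  expect_true(all(single$n_introns == 0))
  f <- sim$annotation$features
  utr_genes <- unique(f$gene_id[grepl("UTR", f$type)])
  expect_setequal(st$per_gene$gene_id[st$per_gene$has_utr], utr_genes)

  # a 255-member family with 7 UTR-less members has UTR share 97.25%
  per <- data.frame(n_exons = rep(2, 255), has_utr = rep(TRUE, 255))
  expect_equal(round_half_up(100 * (255 - 7) / 255, 2), 97.25)

  # 40 exons imply 39 introns
  expect_equal(
    st$per_gene$n_introns[which.max(st$per_gene$n_exons)],
    max(st$per_gene$n_exons) - 1
  )
})

test_that("chromosomal distribution shares recompute and terminal calls work", {
  sim <- small_sim(seed = 41)
  cd <- chromosome_distribution(sim$annotation)
  expect_equal(sum(cd$per_chromosome$n_genes), nrow(sim$annotation$genes))
  expect_equal(
    cd$per_chromosome$share_pct,
    round_half_up(100 * cd$per_chromosome$n_genes / cd$total, 1)
  )
  # a gene at the exact midpoint of its chromosome is not terminal
  ann <- new_genome_annotation(
    genes = data.frame(gene_id = "mid", chrom = "Chr01", strand = "+",
                       start1 = 4901, end1 = 5100, stringsAsFactors = FALSE),
    features = data.frame(gene_id = "mid", chrom = "Chr01", strand = "+",
                          type = "exon", start1 = 4901, end1 = 5100,
                          stringsAsFactors = FALSE),
    cds = c(mid = strrep("ATG", 60)), protein = c(mid = strrep("M", 60)),
    chrom_lengths = c(Chr01 = 10000)
  )
  expect_equal(
    chromosome_distribution(ann, terminal_fraction = 0.25)$terminal_share_pct,
    0
  )
  expect_equal(
    chromosome_distribution(ann, terminal_fraction = 0.5)$terminal_share_pct,
    0
  )
})

test_that("the published per-chromosome tally sums to the family total", {
  counts <- c(32, 27, 6, 11, 13, 14, 14, 15, 16, 17, 18,
              rep(7, 3), rep(8, 3), rep(9, 3))
  expect_equal(sum(counts), 255)
  expect_equal(report_shares(27, 255, 1), 10.6)
})
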