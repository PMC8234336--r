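test_that("motif scanning matches its definitions and the brute-force oracle", {
  hits <- scan_motifs("GPSGSGKS")
  expect_equal(hits$motif, "walkerA")
  expect_equal(hits$start, 1)
  expect_equal(hits$match, "GPSGSGKS")

  expect_equal(nrow(scan_motifs("AAAAAAAA")), 0)
  expect_equal(nrow(scan_motifs("")), 0)

  two <- scan_motifs("GASGAGKTXXXXGASGAGKT")
  wa <- two[two$motif == "walkerA", ]
  expect_equal(wa$start, c(1, 13))

  # X never matches a wildcard position
  expect_equal(nrow(scan_motifs("GXXGXGKS")[
    scan_motifs("GXXGXGKS")$motif == "walkerA", ]), 0)

  # brute-force sliding-window oracle over random proteins
  set.seed(99)
  alpha <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "G", "K", "S", "T")
  for (rep in 1:40) {
    p <- paste(sample(alpha, 150, replace = TRUE), collapse = "")
    got <- scan_motifs(p)
    for (m in c("walkerA", "abc_signature")) {
      expect_equal(got$start[got$motif == m], oracle_scan(p, m),
                   info = paste("motif", m, "protein", rep))
    }
  }
})

test_that("hydropathy helix prediction behaves at the extremes", {
  one <- predict_tm_helices(
    paste0(strrep("D", 30), strrep("I", 25), strrep("D", 30))
  )
  expect_equal(nrow(one), 1)
  expect_equal(nrow(predict_tm_helices(strrep("D", 100))), 0)
  # alternating I/D: windowed mean (~0.5) below the 1.6 default
  alt <- paste(rep(c("I", "D"), 50), collapse = "")
  means <- as.numeric(stats::filter(
    abcsurvey:::KD_SCALE[strsplit(alt, "")[[1]]], rep(1 / 19, 19), sides = 2
  ))
  expect_true(all(means < 1.6, na.rm = TRUE))
  expect_equal(nrow(predict_tm_helices(alt)), 0)
  # protein shorter than the window
  expect_equal(nrow(predict_tm_helices("MI")), 0)
  expect_error(predict_tm_helices("MMM", window = 8))
})

make_block <- function(kind) {
  if (kind == "T") {
    paste(rep(c(strrep("I", 21), strrep("S", 15)), 5), collapse = "")
  } else {
    paste0(strrep("S", 20), "GPSGSGKST", strrep("N", 40), "LSGGQR",
           strrep("S", 30), "RLLDGHETLLL", strrep("N", 30))
  }
}

test_that("architecture calling derives topology from segment order", {
  half <- call_architecture(paste0(make_block("T"), strrep("G", 30),
                                   make_block("N")))
  expect_equal(half$topology, "half_forward")
  expect_true(half$accepted)

  sol <- call_architecture(make_block("N"))
  expect_equal(sol$topology, "soluble")
  expect_true(sol$accepted)

  rev2 <- call_architecture(paste0(make_block("N"), strrep("G", 30),
                                   make_block("T")))
  expect_equal(rev2$topology, "half_reverse")

  tmd <- call_architecture(make_block("T"))
  expect_equal(tmd$topology, "tmd_only")
  expect_false(tmd$accepted)

  # NBD requires the co-occurrence window: walker A alone is not enough
  wa_only <- call_architecture(paste0(strrep("S", 20), "GPSGSGKST",
                                      strrep("N", 100)))
  expect_false(wa_only$accepted)
})

test_that("random background proteins are rejected at >= 99% specificity", {
  set.seed(17)
  n <- 400
  rejected <- 0
  for (i in 1:n) {
    p <- abcsurvey:::random_protein(sample(150:450, 1))
    if (!call_architecture(p)$accepted) rejected <- rejected + 1
  }
  expect_gte(rejected / n, 0.99)
})

test_that("TMD-only candidates are rescued only via the reference panel", {
  tmd_prot <- make_block("T")
  panel <- simulate_reference_panel(seed = 2)
  res <- identify_members(c(x = tmd_prot), panel)
  expect_false("x" %in% res$accepted) # no TMD-only reference in this panel
  panel2 <- rbind(panel, data.frame(
    id = "refI9", subfamily = "I", sequence = tmd_prot
  ))
  res2 <- identify_members(c(x = tmd_prot), panel2)
  expect_true("x" %in% res2$accepted)
})

test_that("subfamily assignment recovers mutated panel copies exactly", {
  panel <- simulate_reference_panel(seed = 5, n_per_subfamily = 1)
  withr::with_seed(6, {
    cands <- setNames(
      vapply(seq_len(nrow(panel)), function(i) {
        as.character(abcsurvey:::mutate_protein(panel$sequence[i], 0.10,
                                                protected = NULL))
      }, character(1)),
      paste0("cand", seq_len(nrow(panel)))
    )
  })
  sf <- assign_subfamily(cands, panel, tree = FALSE)
  expect_equal(sf$assignments$subfamily, panel$subfamily)
  # identical candidate: distance exactly 0
  sf0 <- assign_subfamily(c(z = panel$sequence[3]), panel, tree = FALSE)
  expect_equal(sf0$assignments$distance, 0)
  expect_equal(sf0$assignments$subfamily, panel$subfamily[3])
  # panel must cover all subfamilies
  expect_error(assign_subfamily(cands, panel[panel$subfamily != "D", ]),
               "subfamilies")
})

test_that("neighbor joining recovers a quartet with additive distances", {
  # tree ((a:1,b:2):1.5,(c:3,d:1)) -> unique additive distance matrix
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 5.5
  d["a", "d"] <- d["d", "a"] <- 3.5
  d["b", "c"] <- d["c", "b"] <- 6.5
  d["b", "d"] <- d["d", "b"] <- 4.5
  d["c", "d"] <- d["d", "c"] <- 4
  phy <- build_nj_tree(d)
  cc <- ape::cophenetic.phylo(phy)[rownames(d), colnames(d)]
  expect_equal(cc, d, tolerance = 1e-10)
})

test_that("member naming follows chromosome position and ignores input order", {
  sim <- small_sim(seed = 51)
  ann <- sim$annotation
  fam <- sim$truth[sim$truth$is_family, ]
  assignments <- data.frame(gene_id = fam$gene_id,
                            subfamily = fam$family_label,
                            stringsAsFactors = FALSE)
  n1 <- name_members(assignments, ann)
  n2 <- name_members(assignments[sample(nrow(assignments)), ], ann)
  expect_identical(
    n1[order(n1$gene_id), c("gene_id", "name")],
    n2[order(n2$gene_id), c("gene_id", "name")]
  )
  # numbering within a subfamily is dense and position-ordered
  for (sub in unique(n1$subfamily)) {
    sel <- n1[n1$subfamily == sub, ]
    expect_equal(sel$name, paste0("fam", sub, seq_len(nrow(sel))))
    g <- ann$genes[match(sel$gene_id, ann$genes$gene_id), ]
    ord <- order(match(g$chrom, unique(ann$genes$chrom[
      abcsurvey:::natural_order(ann$genes$chrom)
    ])), g$start0)
    expect_equal(ord, seq_len(nrow(sel)))
  }
  expect_error(name_members(rbind(assignments, assignments[1, ]), ann),
               "duplicate")
})

test_that("natural chromosome order puts Chr2 before Chr10", {
  x <- c("Chr10", "Chr2", "Chr1")
  expect_equal(x[abcsurvey:::natural_order(x)], c("Chr1", "Chr2", "Chr10"))
})

test_that("molecular weight and pI match their closed forms", {
  pp <- protein_properties("GG")
  expect_equal(pp$mw, 2 * 57.0519 + 18.0153, tolerance = 1e-6)
  # no ionizable side chains: pI is the terminal pKa midpoint (8.6+3.6)/2
  expect_equal(protein_properties("GGGG")$pi, 6.10, tolerance = 0.01)
  expect_gt(protein_properties(strrep("K", 20))$pi, 9)
  expect_lt(protein_properties(strrep("D", 20))$pi, 4)
  # net charge at the returned pI is (numerically) zero
  aa <- "MKDECYHRAG"
  pi <- protein_properties(aa)$pi
  counts <- as.list(table(factor(strsplit(aa, "")[[1]],
                                 levels = names(abcsurvey:::AVG_RESIDUE_MASS))))
  expect_lt(abs(abcsurvey:::protein_net_charge(counts, pi)), 1e-4)
  # charge is monotone decreasing in pH
  phs <- seq(1, 13, 0.5)
  qs <- vapply(phs, function(p) abcsurvey:::protein_net_charge(counts, p),
               numeric(1))
  expect_true(all(diff(qs) < 0))
  expect_error(protein_properties(""), "empty")
  expect_error(protein_properties("GGB"), "non-standard")
})
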