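# Homolog-pair detection, collinear-block chaining by dynamic programming,
# and MCScanX-style duplicate-type classification with precedence
# WGD/segmental > tandem > proximal > dispersed > singleton.

# 4-mer containment prefilter: candidate pairs must share at least
# `min_containment` of the shorter protein's 4-mers. Family homologs
# (>70% identity) share ~25% of 4-mers; unrelated random proteins share
# well under 1%, so the filter removes the quadratic alignment bulk
# without losing true pairs.
kmer_candidate_pairs <- function(proteins, k = 4, min_containment = 0.05) {
  ids <- names(proteins)
  kmers <- lapply(proteins, function(p) {
    n <- nchar(p)
    if (n < k) return(character())
    unique(substring(p, 1:(n - k + 1), k:n))
  })
  index <- new.env(parent = emptyenv())
  for (i in seq_along(ids)) {
    for (km in kmers[[i]]) {
      index[[km]] <- c(index[[km]], i)
    }
  }
  counts <- new.env(parent = emptyenv())
  for (km in ls(index)) {
    v <- index[[km]]
    if (length(v) < 2) next
    for (a in seq_along(v)) {
      for (b in seq_along(v)) {
        if (v[b] > v[a]) {
          key <- paste(v[a], v[b])
          counts[[key]] <- (counts[[key]] %||% 0) + 1
        }
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    return(data.frame(i = integer(), j = integer()))
  }
  ij <- do.call(rbind, strsplit(keys, " "))
  i <- as.integer(ij[, 1])
  j <- as.integer(ij[, 2])
  shared <- vapply(keys, function(k2) counts[[k2]], numeric(1))
  denom <- pmin(lengths(kmers)[i], lengths(kmers)[j])
  keep <- denom > 0 & shared / denom >= min_containment
  data.frame(i = i[keep], j = j[keep])
}

#' Detect homologous protein pairs by global alignment
#'
#' All-vs-all homology with a k-mer prefilter: pairs passing a 4-mer
#' containment screen are aligned globally (BLOSUM62, gap open 10, extend
#' 0.5); pairs with percent identity >= `min_identity` are kept, limited
#' to each gene's `top_k` best-scoring partners.
#'
#' @param proteins named character vector (>= 2 sequences).
#' @param min_identity minimum percent identity (default 40).
#' @param top_k best partners kept per gene (default 5).
#' @param prefilter_containment 4-mer containment threshold for the
#'   screening stage (lower it toward 0 to force full all-vs-all
#'   alignment).
#' @return data.frame with `gene_a`, `gene_b` (canonical a < b), `score`,
#'   `identity`, and per-direction ranks `rank_a` (rank of b among a's
#'   partners) and `rank_b`.
#' @export
pairwise_homology <- function(proteins, min_identity = 40, top_k = 5,
                              prefilter_containment = 0.05) {
  stopifnot(length(proteins) >= 2, !is.null(names(proteins)))
  cand <- kmer_candidate_pairs(proteins,
                               min_containment = prefilter_containment)
  empty <- data.frame(
    gene_a = character(), gene_b = character(), score = numeric(),
    identity = numeric(), rank_a = integer(), rank_b = integer(),
    stringsAsFactors = FALSE
  )
  if (nrow(cand) == 0) return(empty)
  ids <- names(proteins)
  rows <- lapply(seq_len(nrow(cand)), function(r) {
    ai <- alignment_identity(proteins[[cand$i[r]]], proteins[[cand$j[r]]])
    data.frame(
      gene_a = ids[cand$i[r]], gene_b = ids[cand$j[r]],
      score = ai[["score"]], identity = ai[["identity"]],
      stringsAsFactors = FALSE
    )
  })
  pairs <- do.call(rbind, rows)
  pairs <- pairs[pairs$identity >= min_identity, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)
  # canonical storage a < b
  flip <- pairs$gene_a > pairs$gene_b
  tmp <- pairs$gene_a[flip]
  pairs$gene_a[flip] <- pairs$gene_b[flip]
  pairs$gene_b[flip] <- tmp
  pairs <- pairs[!duplicated(pairs[c("gene_a", "gene_b")]), ]
  # per-gene rank by score, then top_k cap (a pair survives if either
  # endpoint ranks it within top_k)
  rank_for <- function(gene, partner_scores) {
    ord <- order(-partner_scores)
    r <- integer(length(partner_scores))
    r[ord] <- seq_along(ord)
    r
  }
  long <- rbind(
    data.frame(gene = pairs$gene_a, row = seq_len(nrow(pairs)),
               score = pairs$score),
    data.frame(gene = pairs$gene_b, row = seq_len(nrow(pairs)),
               score = pairs$score)
  )
  long$rank <- stats::ave(-long$score, long$gene, FUN = rank)
  rank_a <- long$rank[seq_len(nrow(pairs))]
  rank_b <- long$rank[nrow(pairs) + seq_len(nrow(pairs))]
  pairs$rank_a <- as.integer(round(rank_a))
  pairs$rank_b <- as.integer(round(rank_b))
  pairs <- pairs[pairs$rank_a <= top_k | pairs$rank_b <= top_k, ]
  rownames(pairs) <- NULL
  pairs
}

# attach gene-rank coordinates to pairs -> anchor table
anchor_table <- function(pairs, genes_a, genes_b = genes_a) {
  ga <- genes_a[match(pairs$gene_a, genes_a$gene_id), ]
  gb <- genes_b[match(pairs$gene_b, genes_b$gene_id), ]
  if (anyNA(ga$gene_id) || anyNA(gb$gene_id)) {
    bad <- c(pairs$gene_a[is.na(ga$gene_id)], pairs$gene_b[is.na(gb$gene_id)])
    stop("pair references gene absent from models: ",
         paste(head(bad, 3), collapse = ", "))
  }
  data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    chrom_a = ga$chrom, chrom_b = gb$chrom,
    rank_a = ga$rank, rank_b = gb$rank,
    stringsAsFactors = FALSE
  )
}

# longest chain of anchors under a gap constraint; anchors is a data.frame
# with rank_a, rank_b sorted by rank_a. direction +1 (rank_b increasing)
# or -1 (decreasing). Returns indices of the best chain.
chain_dp <- function(anchors, max_gap, direction = 1) {
  n <- nrow(anchors)
  if (n == 0) return(integer())
  best_len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      da <- anchors$rank_a[i] - anchors$rank_a[j]
      db <- direction * (anchors$rank_b[i] - anchors$rank_b[j])
      if (da > 0 && db > 0 && da <= max_gap && db <= max_gap &&
          best_len[j] + 1L > best_len[i]) {
        best_len[i] <- best_len[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(best_len)
  chain <- integer()
  while (end != 0) {
    chain <- c(end, chain)
    end <- prev[end]
  }
  chain
}

#' Detect collinear blocks by dynamic-programming anchor chaining
#'
#' Groups homolog pairs (anchors) by chromosome pair and repeatedly
#' extracts the best chain in which both gene-rank coordinates are
#' strictly monotone (increasing, or decreasing for inverted blocks) with
#' consecutive rank gaps at most `max_gap` on both chromosomes; chains
#' with at least `min_anchors` anchors are emitted and their anchors
#' removed, so each anchor belongs to at most one block. Self-hits and
#' near-diagonal same-chromosome anchors (tandem-array redundancy) are
#' dropped before chaining.
#'
#' @param pairs homolog pairs (`gene_a`, `gene_b`), e.g. from
#'   [pairwise_homology()].
#' @param genes gene table with `gene_id`, `chrom`, `rank` (e.g.
#'   `ann$genes`), or a second genome's table via `genes_b` for
#'   cross-genome synteny.
#' @param genes_b optional second gene table (defaults to `genes`).
#' @param min_anchors minimum anchors per block (default 5).
#' @param max_gap maximum gene-rank gap between consecutive anchors
#'   (default 25).
#' @return list with `blocks` (data.frame block_id, chrom_a, chrom_b,
#'   orientation, n_anchors) and `anchors` (data.frame with block_id per
#'   anchor).
#' @export
detect_collinear_blocks <- function(pairs, genes, genes_b = NULL,
                                    min_anchors = 5, max_gap = 25) {
  same_genome <- is.null(genes_b)
  anchors <- anchor_table(pairs, genes, genes_b %||% genes)
  if (same_genome) {
    anchors <- anchors[anchors$gene_a != anchors$gene_b, ]
    near <- anchors$chrom_a == anchors$chrom_b &
      abs(anchors$rank_a - anchors$rank_b) <= 1
    anchors <- anchors[!near, ]
    # canonical orientation on the same chromosome: rank_a < rank_b
    flip <- anchors$chrom_a == anchors$chrom_b &
      anchors$rank_a > anchors$rank_b
    if (any(flip)) {
      anchors[flip, c("gene_a", "gene_b")] <- anchors[flip, c("gene_b", "gene_a")]
      anchors[flip, c("rank_a", "rank_b")] <- anchors[flip, c("rank_b", "rank_a")]
    }
  }
  blocks <- list()
  out_anchors <- list()
  if (nrow(anchors) > 0) {
    key <- paste(anchors$chrom_a, anchors$chrom_b)
    for (grp in split(anchors, key)) {
      grp <- grp[order(grp$rank_a, grp$rank_b), ]
      repeat {
        fwd <- chain_dp(grp, max_gap, 1)
        rev_ <- chain_dp(grp, max_gap, -1)
        chain <- if (length(fwd) >= length(rev_)) fwd else rev_
        orientation <- if (length(fwd) >= length(rev_)) "same" else "inverted"
        if (length(chain) < min_anchors) break
        bid <- length(blocks) + 1L
        blocks[[bid]] <- data.frame(
          block_id = bid, chrom_a = grp$chrom_a[1], chrom_b = grp$chrom_b[1],
          orientation = orientation, n_anchors = length(chain),
          stringsAsFactors = FALSE
        )
        hit <- grp[chain, ]
        hit$block_id <- bid
        out_anchors[[bid]] <- hit
        grp <- grp[-chain, ]
        if (nrow(grp) == 0) break
      }
    }
  }
  list(
    blocks = if (length(blocks)) do.call(rbind, blocks) else
      data.frame(block_id = integer(), chrom_a = character(),
                 chrom_b = character(), orientation = character(),
                 n_anchors = integer(), stringsAsFactors = FALSE),
    anchors = if (length(out_anchors)) do.call(rbind, out_anchors) else
      cbind(anchors[0, ], block_id = integer())
  )
}

#' Classify duplication types with MCScanX-style precedence
#'
#' Every gene receives exactly one type following the precedence
#' WGD/segmental > tandem > proximal > dispersed > singleton: a gene
#' appearing in any collinear-block anchor is `wgd_segmental`; otherwise a
#' homolog within `tandem_gap` gene ranks on the same chromosome makes it
#' `tandem`; within `proximal_window` ranks, `proximal`; any remaining
#' homolog, `dispersed`; no homolog at all, `singleton`.
#'
#' @param genes gene table (`gene_id`, `chrom`, `rank`) or a
#'   [genome_annotation]; must cover every gene referenced by `pairs`
#'   (a pair naming an absent gene is a validation error).
#' @param pairs homolog pairs among those genes.
#' @param blocks result of [detect_collinear_blocks()].
#' @param proximal_window gene-rank window for proximal (default 10).
#' @param tandem_gap gene-rank distance for tandem (default 1, strict
#'   adjacency).
#' @param subset optional gene-ID vector: classify only these genes
#'   (e.g. family members) while ranks and homologs still come from the
#'   full table. Default: all genes in `genes`.
#' @return list with `calls` (data.frame gene_id, type, evidence) and
#'   `counts` (named vector over all five types; sums to the number of
#'   classified genes).
#' @export
classify_duplicates <- function(genes, pairs, blocks,
                                proximal_window = 10, tandem_gap = 1,
                                subset = NULL) {
  if (inherits(genes, "genome_annotation")) genes <- genes$genes
  ids <- subset %||% genes$gene_id
  stopifnot(all(ids %in% genes$gene_id))
  anchors <- blocks$anchors
  in_block <- unique(c(anchors$gene_a, anchors$gene_b))
  block_of <- c(
    setNames(anchors$block_id, anchors$gene_a),
    setNames(anchors$block_id, anchors$gene_b)
  )
  at <- if (nrow(pairs) > 0) anchor_table(pairs, genes) else NULL
  type <- setNames(rep("singleton", length(ids)), ids)
  evidence <- setNames(rep(NA_character_, length(ids)), ids)
  for (g in ids) {
    if (g %in% in_block) {
      type[g] <- "wgd_segmental"
      evidence[g] <- paste0("block:", block_of[[g]])
      next
    }
    if (is.null(at)) next
    hit <- at[at$gene_a == g | at$gene_b == g, ]
    if (nrow(hit) == 0) next
    partner <- ifelse(hit$gene_a == g, hit$gene_b, hit$gene_a)
    same_chrom <- ifelse(hit$gene_a == g, hit$chrom_b, hit$chrom_a) ==
      ifelse(hit$gene_a == g, hit$chrom_a, hit$chrom_b)
    rank_self <- ifelse(hit$gene_a == g, hit$rank_a, hit$rank_b)
    rank_part <- ifelse(hit$gene_a == g, hit$rank_b, hit$rank_a)
    dist <- abs(rank_self - rank_part)
    if (any(same_chrom & dist <= tandem_gap & dist > 0)) {
      k <- which(same_chrom & dist <= tandem_gap & dist > 0)[1]
      type[g] <- "tandem"
      evidence[g] <- paste0("pair:", partner[k])
    } else if (any(same_chrom & dist <= proximal_window & dist > 0)) {
      k <- which(same_chrom & dist <= proximal_window & dist > 0)[1]
      type[g] <- "proximal"
      evidence[g] <- paste0("pair:", partner[k])
    } else {
      type[g] <- "dispersed"
      evidence[g] <- paste0("pair:", partner[1])
    }
  }
  lv <- c("singleton", "dispersed", "proximal", "tandem", "wgd_segmental")
  counts <- table(factor(type, levels = lv))
  list(
    calls = data.frame(
      gene_id = ids, type = unname(type[ids]),
      evidence = unname(evidence[ids]), stringsAsFactors = FALSE
    ),
    counts = setNames(as.integer(counts), lv)
  )
}

#' Interspecies synteny of family members
#'
#' Detects collinear blocks between two genomes from cross-genome
#' homology, reports the family-member pairs lying inside blocks, and
#' classifies the match cardinality of each family gene (one-to-one,
#' one-to-many, many-to-one) from its number of syntenic partners.
#'
#' @param ann_a,ann_b [genome_annotation] objects for the two genomes.
#' @param family_a,family_b gene-ID vectors of family members in each
#'   genome (default: all genes).
#' @param min_identity,top_k passed to [pairwise_homology()].
#' @param min_anchors,max_gap passed to [detect_collinear_blocks()].
#' @return list with `blocks`, `family_pairs` (data.frame gene_a, gene_b,
#'   block_id, cardinality), and `n_pairs`.
#' @export
interspecies_synteny <- function(ann_a, ann_b, family_a = NULL,
                                 family_b = NULL, min_identity = 40,
                                 top_k = 5, min_anchors = 5, max_gap = 25) {
  stopifnot(inherits(ann_a, "genome_annotation"),
            inherits(ann_b, "genome_annotation"))
  family_a <- family_a %||% ann_a$genes$gene_id
  family_b <- family_b %||% ann_b$genes$gene_id
  pa <- setNames(as.character(ann_a$protein), paste0("A|", names(ann_a$protein)))
  pb <- setNames(as.character(ann_b$protein), paste0("B|", names(ann_b$protein)))
  cand <- kmer_candidate_pairs(c(pa, pb))
  na <- length(pa)
  cross <- cand[(cand$i <= na) != (cand$j <= na), , drop = FALSE]
  all_ids <- c(names(pa), names(pb))
  prots <- c(pa, pb)
  rows <- lapply(seq_len(nrow(cross)), function(r) {
    ai <- alignment_identity(prots[[cross$i[r]]], prots[[cross$j[r]]])
    i <- min(cross$i[r], cross$j[r]) # A side first
    j <- max(cross$i[r], cross$j[r])
    data.frame(
      gene_a = sub("^A\\|", "", all_ids[i]),
      gene_b = sub("^B\\|", "", all_ids[j]),
      score = ai[["score"]], identity = ai[["identity"]],
      stringsAsFactors = FALSE
    )
  })
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(),
               score = numeric(), identity = numeric())
  pairs <- pairs[pairs$identity >= min_identity, , drop = FALSE]
  blocks <- detect_collinear_blocks(
    pairs, ann_a$genes, ann_b$genes,
    min_anchors = min_anchors, max_gap = max_gap
  )
  fam <- blocks$anchors[
    blocks$anchors$gene_a %in% family_a & blocks$anchors$gene_b %in% family_b,
    , drop = FALSE
  ]
  if (nrow(fam) > 0) {
    n_b_per_a <- table(fam$gene_a)
    n_a_per_b <- table(fam$gene_b)
    fam$cardinality <- mapply(function(a, b) {
      many_b <- n_b_per_a[[a]] > 1
      many_a <- n_a_per_b[[b]] > 1
      if (many_b && many_a) "many-to-many"
      else if (many_b) "one-to-many"
      else if (many_a) "many-to-one"
      else "one-to-one"
    }, fam$gene_a, fam$gene_b)
  } else {
    fam$cardinality <- character(0)
  }
  list(
    blocks = blocks$blocks,
    family_pairs = fam[, c("gene_a", "gene_b", "block_id", "cardinality")],
    n_pairs = nrow(fam)
  )
}
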