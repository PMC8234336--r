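# ABC-transporter candidate detection: conserved-motif scanning (Walker
# A/B, ABC signature, Q-/H-loops), Kyte-Doolittle transmembrane helix
# prediction, domain-architecture calling and topology classification,
# subfamily assignment against a labelled reference panel with a
# neighbor-joining tree, chromosome-position naming, and physicochemical
# protein properties.

# Motif patterns. Wildcards are [^X] so that the unknown residue X is
# tolerated in input but never matches. Walker A is the classical
# G..G.GK[S/T]; Walker B renders "(RK)X3GX3L(hydrophobic)3" with the
# hydrophobic set LIVMF; the ABC signature uses the canonical LSGGQ
# consensus. Q-loop and H-loop patterns are package heuristics (their
# consensus is not standardized) and play no part in the NBD acceptance
# rule.
MOTIF_PATTERNS <- c(
  walkerA = "G[^X][^X]G[^X]GK[ST]",
  walkerB = "[RK][^X]{3}G[^X]{3}[LIVMF][LIVMF][LIVMF]",
  abc_signature = "[LIVMFY]S[SG]G[^X][QRKE]",
  q_loop = "[LIVMF][LIVMF][^X]Q",
  h_loop = "[LIVMFA]H[LIVMFAY]"
)

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

#' Scan a protein for conserved ABC-transporter motifs
#'
#' Reports all non-overlapping occurrences (leftmost first, per motif) of
#' the Walker A, Walker B, ABC signature, Q-loop and H-loop patterns.
#'
#' @param protein amino-acid sequence (character or `AAString`); `X` is
#'   tolerated but never matches a wildcard.
#' @return data.frame with columns `motif`, `start`, `end` (1-based
#'   inclusive protein coordinates) and `match`.
#' @export
#' @examples
#' scan_motifs("MAAGPSGSGKSTLLA")
scan_motifs <- function(protein) {
  protein <- toupper(as.character(protein))
  out <- list()
  if (nchar(protein) > 0) {
    for (m in names(MOTIF_PATTERNS)) {
      hits <- gregexpr(MOTIF_PATTERNS[[m]], protein, perl = TRUE)[[1]]
      if (hits[1] != -1) {
        len <- attr(hits, "match.length")
        out[[m]] <- data.frame(
          motif = m, start = as.integer(hits),
          end = as.integer(hits) + len - 1L,
          match = substring(protein, hits, hits + len - 1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), match = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$motif), ]
  rownames(res) <- NULL
  res
}

#' Predict transmembrane helices by windowed Kyte-Doolittle hydropathy
#'
#' Marks maximal runs of window centres whose mean hydropathy is at least
#' `threshold`, expands each run by half a window, and trims/splits the
#' resulting segments to plausible helix lengths (15-30 residues; shorter
#' segments are dropped).
#'
#' @param protein amino-acid sequence; `X` scores 0.
#' @param window odd window width >= 7 (default 19).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @return data.frame with `start`, `end` per predicted helix (empty when
#'   the protein is shorter than the window).
#' @export
predict_tm_helices <- function(protein, window = 19, threshold = 1.6) {
  stopifnot(window >= 7, window %% 2 == 1)
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  n <- length(aa)
  empty <- data.frame(start = integer(), end = integer())
  if (n < window) return(empty)
  h <- KD_SCALE[aa]
  h[is.na(h)] <- 0
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centres <- which(!is.na(means) & means >= threshold)
  if (length(centres) == 0) return(empty)
  hw <- (window - 1) / 2
  runs <- split(centres, cumsum(c(1, diff(centres) != 1)))
  segs <- list()
  for (r in runs) {
    s <- max(1, min(r) - hw)
    e <- min(n, max(r) + hw)
    # expansion by half a window can overshoot into hydrophilic flanks;
    # trim ends whose residues are individually below the threshold while
    # the segment is longer than one helix
    while (e - s + 1 > 30 && h[s] < threshold) s <- s + 1
    while (e - s + 1 > 30 && h[e] < threshold) e <- e - 1
    len <- e - s + 1
    if (len < 15) next
    k <- ceiling(len / 30)
    bounds <- round(seq(s, e + 1, length.out = k + 1))
    for (i in seq_len(k)) {
      ss <- bounds[i]
      ee <- bounds[i + 1] - 1
      if (ee - ss + 1 >= 15) {
        segs[[length(segs) + 1]] <- data.frame(start = ss, end = ee)
      }
    }
  }
  if (length(segs) == 0) return(empty)
  do.call(rbind, segs)
}

#' Call the domain architecture of a candidate ABC protein
#'
#' A nucleotide-binding domain (NBD) is called where a Walker A hit
#' co-occurs with an ABC signature or Walker B hit within `nbd_window`
#' residues downstream; a transmembrane domain (TMD) where at least
#' `min_helices` predicted helices cluster within a span of `tmd_span`
#' residues. The ordered domain segments determine the topology class:
#' `full_forward` (TMD-NBD-TMD-NBD), `full_reverse` (NBD-TMD-NBD-TMD),
#' `half_forward` (TMD-NBD), `half_reverse` (NBD-TMD), `soluble` (NBDs
#' only) or `tmd_only`. A candidate is accepted when it has at least one
#' NBD; TMD-only proteins are accepted only via reference-panel support
#' (see [identify_members()]), mirroring ABCI members that consist of a
#' lone TMD.
#'
#' @param protein amino-acid sequence.
#' @param motifs,helices optional precomputed [scan_motifs()] /
#'   [predict_tm_helices()] results.
#' @param nbd_window co-occurrence window for Walker A + signature/Walker
#'   B (residues, default 250).
#' @param tmd_span maximal span of one helix cluster (default 350).
#' @param min_helices helices needed to call a TMD (default 4).
#' @return list of class `domain_architecture`: `segments` (data.frame
#'   type/start/end in order), `topology`, `accepted`, `n_nbd`, `n_tmd`.
#' @export
call_architecture <- function(protein, motifs = NULL, helices = NULL,
                              nbd_window = 250, tmd_span = 350,
                              min_helices = 4) {
  protein <- toupper(as.character(protein))
  if (is.null(motifs)) motifs <- scan_motifs(protein)
  if (is.null(helices)) helices <- predict_tm_helices(protein)

  # NBDs: anchor on Walker A, require signature or Walker B downstream
  wa <- motifs[motifs$motif == "walkerA", ]
  partner <- motifs[motifs$motif %in% c("abc_signature", "walkerB"), ]
  nbd <- list()
  for (i in seq_len(nrow(wa))) {
    hit <- partner[partner$start >= wa$start[i] &
                     partner$start <= wa$start[i] + nbd_window, ]
    if (nrow(hit) > 0) {
      nbd[[length(nbd) + 1]] <- data.frame(
        type = "NBD", start = wa$start[i], end = max(hit$end)
      )
    }
  }
  nbd <- if (length(nbd)) merge_segments(do.call(rbind, nbd)) else
    data.frame(type = character(), start = integer(), end = integer())

  # TMDs: greedy left-to-right clustering of predicted helices
  tmd <- list()
  if (nrow(helices) > 0) {
    helices <- helices[order(helices$start), ]
    i <- 1
    while (i <= nrow(helices)) {
      j <- i
      while (j + 1 <= nrow(helices) &&
             helices$end[j + 1] - helices$start[i] <= tmd_span) {
        j <- j + 1
      }
      if (j - i + 1 >= min_helices) {
        tmd[[length(tmd) + 1]] <- data.frame(
          type = "TMD", start = helices$start[i], end = helices$end[j]
        )
      }
      i <- j + 1
    }
  }
  tmd <- if (length(tmd)) do.call(rbind, tmd) else
    data.frame(type = character(), start = integer(), end = integer())

  segments <- rbind(nbd, tmd)
  segments <- segments[order(segments$start), ]
  rownames(segments) <- NULL
  topo <- classify_topology(segments$type)
  structure(
    list(
      segments = segments, topology = topo,
      n_nbd = sum(segments$type == "NBD"),
      n_tmd = sum(segments$type == "TMD"),
      accepted = sum(segments$type == "NBD") >= 1
    ),
    class = "domain_architecture"
  )
}

merge_segments <- function(seg) {
  seg <- seg[order(seg$start), ]
  out <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1]) {
    last <- nrow(out)
    if (seg$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], seg$end[i])
    } else {
      out <- rbind(out, seg[i, ])
    }
  }
  out
}

classify_topology <- function(types) {
  if (length(types) == 0) return("none")
  key <- paste(substr(types, 1, 1), collapse = "")
  # collapse adjacent repeats of the same domain type
  collapsed <- gsub("(.)\\1+", "\\1", key)
  switch(key,
    "TNTN" = "full_forward",
    "NTNT" = "full_reverse",
    "TN" = "half_forward",
    "NT" = "half_reverse",
    if (!grepl("T", key)) "soluble"
    else if (!grepl("N", key)) "tmd_only"
    else switch(collapsed,
      "TNTN" = "full_forward", "NTNT" = "full_reverse",
      "TN" = "half_forward", "NT" = "half_reverse",
      if (startsWith(collapsed, "TN")) "half_forward" else "half_reverse"
    )
  )
}

# canonical topology per subfamily, used for the consistency flag
CANONICAL_TOPOLOGY <- list(
  A = "full_forward", B = "full_forward", C = "full_forward",
  D = "half_forward", E = "soluble", F = "soluble",
  G = c("full_reverse", "half_reverse"), I = c("soluble", "tmd_only")
)

# global pairwise alignment distance used for panel assignment, homology
# and trees: 1 - identity/100 under BLOSUM62, gap open 10 / extend 0.5
alignment_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  c(identity = Biostrings::pid(pa, type = "PID1"),
    score = Biostrings::score(pa))
}

#' Assign subfamilies by nearest labelled reference
#'
#' Each candidate receives the subfamily of its nearest reference-panel
#' protein under global pairwise alignment distance (1 - identity/100;
#' BLOSUM62, gap open 10, extend 0.5). Ties break toward the reference
#' earlier in panel order and are flagged. A neighbor-joining tree over
#' candidates + references is built from the same distances. Assignments
#' whose called topology contradicts the subfamily's canonical topology
#' are flagged.
#'
#' @param candidates named character vector of candidate proteins.
#' @param panel reference panel data.frame (`id`, `subfamily`,
#'   `sequence`), covering all 8 subfamilies.
#' @param architectures optional named list of `domain_architecture`
#'   objects for the topology-consistency flag.
#' @param tree build the NJ tree (default TRUE; skip for speed).
#' @return list with `assignments` (data.frame gene_id, subfamily,
#'   best_ref, distance, tie, topology, topology_consistent) and `tree`
#'   (an `ape::phylo`, or NULL).
#' @export
assign_subfamily <- function(candidates, panel, architectures = NULL,
                             tree = TRUE) {
  if (is.null(panel) || nrow(panel) == 0) stop("empty reference panel")
  missing_sub <- setdiff(names(SUBFAMILY_LAYOUT), panel$subfamily)
  if (length(missing_sub)) {
    stop("panel does not cover subfamilies: ",
         paste(missing_sub, collapse = ", "))
  }
  stopifnot(!is.null(names(candidates)))
  nc <- length(candidates)
  np <- nrow(panel)
  dist_cp <- matrix(NA_real_, nc, np,
                    dimnames = list(names(candidates), panel$id))
  for (i in seq_len(nc)) {
    for (j in seq_len(np)) {
      dist_cp[i, j] <- 1 - alignment_identity(
        candidates[[i]], panel$sequence[j]
      )[["identity"]] / 100
    }
  }
  best <- apply(dist_cp, 1, which.min) # first minimum = earliest in panel
  tie <- vapply(seq_len(nc), function(i) {
    sum(abs(dist_cp[i, ] - dist_cp[i, best[i]]) < 1e-12) > 1
  }, logical(1))
  assignments <- data.frame(
    gene_id = names(candidates),
    subfamily = panel$subfamily[best],
    best_ref = panel$id[best],
    distance = dist_cp[cbind(seq_len(nc), best)],
    tie = tie,
    stringsAsFactors = FALSE
  )
  if (!is.null(architectures)) {
    topo <- vapply(assignments$gene_id, function(g) {
      a <- architectures[[g]]
      if (is.null(a)) NA_character_ else a$topology
    }, character(1))
    assignments$topology <- topo
    assignments$topology_consistent <- mapply(function(s, t) {
      if (is.na(t)) NA else t %in% CANONICAL_TOPOLOGY[[s]]
    }, assignments$subfamily, topo)
  }
  phy <- NULL
  if (tree) {
    all_seq <- c(candidates, setNames(panel$sequence, panel$id))
    n <- length(all_seq)
    d <- matrix(0, n, n, dimnames = list(names(all_seq), names(all_seq)))
    d[seq_len(nc), nc + seq_len(np)] <- dist_cp
    d[nc + seq_len(np), seq_len(nc)] <- t(dist_cp)
    fill <- function(idx) {
      for (a in idx) for (b in idx) {
        if (b > a) {
          d[a, b] <<- 1 - alignment_identity(all_seq[[a]],
                                             all_seq[[b]])[["identity"]] / 100
          d[b, a] <<- d[a, b]
        }
      }
    }
    fill(seq_len(nc))
    fill(nc + seq_len(np))
    phy <- build_nj_tree(d)
  }
  list(assignments = assignments, tree = phy)
}

#' Neighbor-joining tree from a distance matrix
#'
#' The tree builder behind [assign_subfamily()]. On an additive distance
#' matrix, neighbor joining recovers the generating unrooted topology with
#' exact branch lengths.
#'
#' @param d symmetric numeric distance matrix with labelled rows/columns
#'   (or a `dist`).
#' @return an `ape::phylo` tree.
#' @export
build_nj_tree <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  ape::nj(d)
}

#' Name family members by chromosomal position
#'
#' Within each subfamily, members are numbered 1..n following chromosome
#' order (natural sort of labels, so Chr2 precedes Chr10) and then start
#' coordinate, giving names like `famB3`. Input order does not matter.
#'
#' @param assignments data.frame with `gene_id` and `subfamily`.
#' @param ann a [genome_annotation] providing coordinates.
#' @param prefix name prefix (default "fam").
#' @return the assignments data.frame with a `name` column, sorted by
#'   (subfamily, chromosome, start).
#' @export
name_members <- function(assignments, ann, prefix = "fam") {
  stopifnot(inherits(ann, "genome_annotation"))
  if (anyDuplicated(assignments$gene_id)) {
    stop("duplicate gene IDs in assignments")
  }
  g <- ann$genes[match(assignments$gene_id, ann$genes$gene_id), ]
  if (anyNA(g$gene_id)) {
    stop("assignment for gene absent from annotation: ",
         assignments$gene_id[which(is.na(g$gene_id))[1]])
  }
  chrom_rank <- match(g$chrom, unique(ann$genes$chrom[
    natural_order(ann$genes$chrom)
  ]))
  ord <- order(assignments$subfamily, chrom_rank, g$start0)
  assignments <- assignments[ord, ]
  idx <- stats::ave(seq_len(nrow(assignments)), assignments$subfamily,
                    FUN = seq_along)
  assignments$name <- paste0(prefix, assignments$subfamily, idx)
  rownames(assignments) <- NULL
  assignments
}

# --- physicochemical properties ----------------------------------------------

# ExPASy-style average residue masses (Da); X contributes the mean mass
AVG_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# EMBOSS pKa set
PKA <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

protein_net_charge <- function(counts, ph) {
  pos <- 1 / (1 + 10^(ph - PKA$nterm))
  neg <- -1 / (1 + 10^(PKA$cterm - ph))
  for (r in names(PKA$positive)) {
    pos <- pos + counts[[r]] / (1 + 10^(ph - PKA$positive[[r]]))
  }
  for (r in names(PKA$negative)) {
    neg <- neg - counts[[r]] / (1 + 10^(PKA$negative[[r]] - ph))
  }
  pos + neg
}

#' Theoretical molecular weight and isoelectric point
#'
#' MW is the sum of average residue masses plus one water; `X` contributes
#' the mean residue mass. pI is found by bisection on the
#' Henderson-Hasselbalch net charge (EMBOSS pKa set over the termini and
#' D, E, C, Y, H, K, R side chains; `X` carries no charge) to
#' |charge| < 1e-4.
#'
#' @param proteins character vector (or `AAStringSet`) of sequences.
#' @return data.frame with `length` (residues), `mw` (Da) and `pi`.
#' @export
#' @examples
#' protein_properties("GG")  # MW 132.12
protein_properties <- function(proteins) {
  proteins <- as.character(proteins)
  if (any(nchar(proteins) == 0)) stop("empty protein sequence")
  one <- function(p) {
    aa <- strsplit(toupper(p), "")[[1]]
    known <- aa[aa %in% names(AVG_RESIDUE_MASS)]
    bad <- setdiff(aa, c(names(AVG_RESIDUE_MASS), "X"))
    if (length(bad)) stop("non-standard residue: ", bad[1])
    mw <- sum(AVG_RESIDUE_MASS[known]) +
      sum(aa == "X") * mean(AVG_RESIDUE_MASS) + WATER_MASS
    counts <- as.list(table(factor(aa, levels = names(AVG_RESIDUE_MASS))))
    lo <- 0
    hi <- 14
    repeat {
      mid <- (lo + hi) / 2
      q <- protein_net_charge(counts, mid)
      if (abs(q) < 1e-4 || hi - lo < 1e-10) break
      if (q > 0) lo <- mid else hi <- mid
    }
    c(length = length(aa), mw = mw, pi = mid)
  }
  res <- t(vapply(proteins, one, c(length = 0, mw = 0, pi = 0)))
  out <- data.frame(
    length = as.integer(res[, "length"]), mw = res[, "mw"], pi = res[, "pi"]
  )
  if (!is.null(names(proteins))) out <- cbind(gene_id = names(proteins), out)
  out
}

#' Identify ABC-transporter family members from a protein set
#'
#' Runs [scan_motifs()], [predict_tm_helices()] and [call_architecture()]
#' over every protein and accepts candidates with at least one called NBD.
#' TMD-only proteins are additionally accepted when a reference panel is
#' supplied and contains a TMD-only-topology member with alignment
#' identity >= `tmd_only_min_identity` (the lone-TMD ABCI case).
#'
#' @param proteins named character vector of protein sequences.
#' @param panel optional reference panel (see [read_reference_panel()]).
#' @param tmd_only_min_identity identity threshold for the TMD-only
#'   rescue (default 40).
#' @param ... passed to [call_architecture()].
#' @return list with `architectures` (named list), `accepted` (character
#'   vector of member IDs) and `table` (per-protein topology/acceptance
#'   data.frame).
#' @export
identify_members <- function(proteins, panel = NULL,
                             tmd_only_min_identity = 40, ...) {
  stopifnot(!is.null(names(proteins)))
  archs <- lapply(proteins, call_architecture, ...)
  accepted <- vapply(archs, `[[`, logical(1), "accepted")
  topo <- vapply(archs, `[[`, character(1), "topology")
  if (!is.null(panel)) {
    tmd_refs <- panel$sequence[
      vapply(panel$sequence,
             function(s) call_architecture(s, ...)$topology, character(1)) ==
        "tmd_only"
    ]
    if (length(tmd_refs)) {
      for (i in which(topo == "tmd_only" & !accepted)) {
        ids <- vapply(tmd_refs, function(r) {
          alignment_identity(proteins[[i]], r)[["identity"]]
        }, numeric(1))
        if (max(ids) >= tmd_only_min_identity) accepted[i] <- TRUE
      }
    }
  }
  list(
    architectures = archs,
    accepted = names(proteins)[accepted],
    table = data.frame(
      gene_id = names(proteins), topology = topo, accepted = accepted,
      n_nbd = vapply(archs, `[[`, numeric(1), "n_nbd"),
      n_tmd = vapply(archs, `[[`, numeric(1), "n_tmd"),
      stringsAsFactors = FALSE
    )
  )
}
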