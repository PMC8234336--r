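# Gene-model container, GFF3/FASTA I/O (via rtracklayer/Biostrings), and
# gene-structure / chromosomal-distribution statistics.
#
# Coordinates are 1-based inclusive in GFF3 and 0-based half-open
# internally; conversion happens only at the I/O boundary.

#' Gene-model container for one annotated genome
#'
#' Built by [read_annotation()] or [simulate_genome()]. Holds per-gene
#' coordinates (internally 0-based half-open), exon/UTR/CDS segments, the
#' CDS and protein sequences, and each gene's rank (ordinal position by
#' start coordinate among all genes on its chromosome; strand ignored).
#'
#' @param genes data.frame with gene_id, chrom, strand, start1, end1
#'   (1-based inclusive, converted on construction).
#' @param features data.frame with gene_id, type (exon / CDS /
#'   five_prime_UTR / three_prime_UTR), start1, end1.
#' @param cds,protein named character vectors keyed by gene_id.
#' @param chrom_lengths named numeric vector (optional; defaults to the
#'   maximum annotated end per chromosome).
#' @return an object of class `genome_annotation`.
#' @name genome_annotation
#' @export
new_genome_annotation <- function(genes, features, cds, protein,
                                  chrom_lengths = NULL) {
  stopifnot(
    all(c("gene_id", "chrom", "strand", "start1", "end1") %in% names(genes)),
    all(c("gene_id", "type", "start1", "end1") %in% names(features)),
    !anyDuplicated(genes$gene_id)
  )
  if (any(genes$start1 > genes$end1)) stop("gene with start > end")
  genes$start0 <- genes$start1 - 1L
  genes$end0 <- genes$end1
  features$start0 <- features$start1 - 1L
  features$end0 <- features$end1
  genes$start1 <- genes$end1 <- NULL
  features$start1 <- features$end1 <- NULL

  missing_cds <- setdiff(genes$gene_id, names(cds))
  missing_prot <- setdiff(genes$gene_id, names(protein))
  if (length(missing_cds) || length(missing_prot)) {
    stop("gene(s) without cross-referenced sequence: ",
         paste(head(c(missing_cds, missing_prot), 5), collapse = ", "))
  }
  # |CDS|/3 - 1 == |protein|, allowing a CDS without the terminal stop
  for (g in genes$gene_id) {
    nc <- nchar(cds[[g]]) / 3
    np <- nchar(protein[[g]])
    if (!(nc == np || nc == np + 1)) {
      stop("CDS/protein length mismatch for ", g,
           ": ", nchar(cds[[g]]), " nt vs ", np, " aa")
    }
  }

  # gene rank: ordinal by start within chromosome (strand-independent)
  genes <- genes[order(genes$chrom, genes$start0, genes$gene_id), ]
  genes$rank <- stats::ave(genes$start0, genes$chrom,
                           FUN = seq_along)
  rownames(genes) <- NULL

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end0, genes$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  structure(
    list(
      genes = genes, features = features,
      cds = cds[genes$gene_id], protein = protein[genes$gene_id],
      chrom_lengths = chrom_lengths
    ),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read an annotated genome from GFF3 + FASTA
#'
#' Parses a GFF3 annotation (gene/mRNA/exon/CDS/UTR features linked by
#' `ID=`/`Parent=`) together with protein and CDS FASTA files, and
#' cross-references them into a [genome_annotation] object. When a gene
#' has several mRNAs, the one with the longest CDS is kept.
#'
#' @param gff3 path to a GFF3 file (1-based inclusive coordinates).
#' @param protein_fasta,cds_fasta FASTA paths; sequence names must match
#'   the gene IDs (or their mRNA IDs).
#' @return a [genome_annotation] object.
#' @export
read_annotation <- function(gff3, protein_fasta, cds_fasta) {
  for (f in c(gff3, protein_fasta, cds_fasta)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  gr <- rtracklayer::import(gff3, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start1 = GenomicRanges::start(gr),
    end1 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    ID = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    stringsAsFactors = FALSE
  )
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else {
    rep(NA_character_, nrow(df))
  }
  df$Parent <- parent

  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type == "mRNA", ]
  parts <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ]

  if (anyNA(mrnas$Parent) || !all(mrnas$Parent %in% genes$ID)) {
    stop("mRNA with missing or unresolvable Parent gene")
  }
  if (!all(parts$Parent %in% mrnas$ID)) {
    bad <- setdiff(unique(parts$Parent), mrnas$ID)
    stop("feature parented to unknown mRNA: ", paste(head(bad, 3), collapse = ", "))
  }

  prot <- Biostrings::readAAStringSet(protein_fasta)
  cds <- Biostrings::readDNAStringSet(cds_fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))
  names(cds) <- sub("\\s.*$", "", names(cds))

  # choose the primary mRNA per gene: longest summed CDS
  cds_len <- tapply(
    ifelse(parts$type == "CDS", parts$end1 - parts$start1 + 1, 0),
    parts$Parent, sum
  )
  mrnas$cds_len <- as.numeric(cds_len[mrnas$ID])
  mrnas <- mrnas[order(mrnas$Parent, -mrnas$cds_len), ]
  primary <- mrnas[!duplicated(mrnas$Parent), ]
  part_keep <- parts[parts$Parent %in% primary$ID, ]
  part_keep$gene_id <- primary$Parent[match(part_keep$Parent, primary$ID)]

  lookup_seq <- function(set, gid, mid, what) {
    if (gid %in% names(set)) return(as.character(set[[gid]]))
    if (mid %in% names(set)) return(as.character(set[[mid]]))
    stop("no ", what, " sequence for gene ", gid)
  }
  gid <- genes$ID
  mid <- primary$ID[match(gid, primary$Parent)]
  cds_v <- setNames(mapply(function(g, m) lookup_seq(cds, g, m, "CDS"),
                           gid, mid), gid)
  prot_v <- setNames(mapply(function(g, m) lookup_seq(prot, g, m, "protein"),
                            gid, mid), gid)

  # rtracklayer does not surface ##sequence-region pragmas; read them
  # directly so chromosome lengths survive the round trip
  chrom_lengths <- NULL
  hdr <- grep("^##sequence-region", readLines(gff3, n = 500), value = TRUE)
  if (length(hdr)) {
    parts <- strsplit(trimws(hdr), "\\s+")
    chrom_lengths <- setNames(
      vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
      vapply(parts, function(p) p[2], character(1))
    )
  } else {
    sl <- GenomeInfoDb_seqlengths(gr)
    if (!is.null(sl) && !all(is.na(sl))) chrom_lengths <- sl[!is.na(sl)]
  }

  new_genome_annotation(
    genes = data.frame(
      gene_id = genes$ID, chrom = genes$chrom, strand = genes$strand,
      start1 = genes$start1, end1 = genes$end1, stringsAsFactors = FALSE
    ),
    features = data.frame(
      gene_id = part_keep$gene_id, chrom = part_keep$chrom,
      strand = part_keep$strand, type = part_keep$type,
      start1 = part_keep$start1, end1 = part_keep$end1,
      stringsAsFactors = FALSE
    ),
    cds = cds_v, protein = prot_v, chrom_lengths = chrom_lengths
  )
}

# isolate the seqlengths accessor (GenomeInfoDb is pulled in by
# GenomicRanges; called via the generic available on GRanges)
GenomeInfoDb_seqlengths <- function(gr) {
  out <- tryCatch(GenomicRanges::seqinfo(gr), error = function(e) NULL)
  if (is.null(out)) return(NULL)
  sl <- methods::slot(out, "seqlengths")
  setNames(as.numeric(sl), methods::slot(out, "seqnames"))
}

#' Write a genome annotation to GFF3 + FASTA
#'
#' Inverse of [read_annotation()]: emits a standards-compliant GFF3
#' (gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR rows with
#' `ID=`/`Parent=` attributes, `##sequence-region` pragmas) and wrapped
#' FASTA files; coordinates convert back from the internal 0-based
#' half-open representation to 1-based inclusive.
#'
#' @param ann a [genome_annotation].
#' @param gff3,protein_fasta,cds_fasta output paths (each optional).
#' @return invisible `ann`.
#' @export
write_annotation <- function(ann, gff3 = NULL, protein_fasta = NULL,
                             cds_fasta = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (!is.null(gff3)) {
    g <- ann$genes
    f <- ann$features
    rows <- list()
    push <- function(chrom, type, s0, e0, strand, id, parent, phase = ".") {
      rows[[length(rows) + 1]] <<- data.frame(
        seqid = chrom, source = "abcsurvey", type = type,
        start = s0 + 1, end = e0, score = ".", strand = strand,
        phase = phase,
        attributes = if (is.na(parent)) paste0("ID=", id)
                     else if (is.na(id)) paste0("Parent=", parent)
                     else paste0("ID=", id, ";Parent=", parent),
        stringsAsFactors = FALSE
      )
    }
    for (i in seq_len(nrow(g))) {
      gid <- g$gene_id[i]
      mid <- paste0(gid, ".t1")
      push(g$chrom[i], "gene", g$start0[i], g$end0[i], g$strand[i], gid, NA)
      push(g$chrom[i], "mRNA", g$start0[i], g$end0[i], g$strand[i], mid, gid)
      sub <- f[f$gene_id == gid, ]
      sub <- sub[order(sub$start0, sub$type), ]
      # CDS phase: bases of preceding CDS, read 5'->3' on the coding strand
      is_cds <- sub$type == "CDS"
      lens <- sub$end0 - sub$start0
      phase <- rep(".", nrow(sub))
      if (any(is_cds)) {
        cds_idx <- which(is_cds)
        ordered <- if (g$strand[i] == "-") rev(cds_idx) else cds_idx
        before <- cumsum(c(0, lens[ordered]))[seq_along(ordered)]
        phase[ordered] <- as.character((3 - before %% 3) %% 3)
      }
      for (j in seq_len(nrow(sub))) {
        push(sub$chrom[j], sub$type[j], sub$start0[j], sub$end0[j],
             sub$strand[j], NA, mid, phase[j])
      }
    }
    tab <- do.call(rbind, rows)
    con <- file(gff3, "w")
    writeLines("##gff-version 3", con)
    for (chr in names(ann$chrom_lengths)) {
      writeLines(sprintf("##sequence-region %s 1 %d", chr,
                         as.integer(ann$chrom_lengths[[chr]])), con)
    }
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  if (!is.null(protein_fasta)) {
    aa <- Biostrings::AAStringSet(unlist(ann$protein))
    Biostrings::writeXStringSet(aa, protein_fasta, width = 60)
  }
  if (!is.null(cds_fasta)) {
    nt <- Biostrings::DNAStringSet(unlist(ann$cds))
    Biostrings::writeXStringSet(nt, cds_fasta, width = 60)
  }
  invisible(ann)
}

#' Per-gene and family-level gene-structure statistics
#'
#' Exon count, intron count (exons - 1 for single-mRNA models) and UTR
#' presence per gene, plus summary statistics including the fraction of
#' genes carrying at least one UTR segment.
#'
#' @param ann a [genome_annotation].
#' @param genes optional character vector restricting the statistics to a
#'   subset of gene IDs (e.g. the identified family members).
#' @return list with `per_gene` (data.frame gene_id, n_exons, n_introns,
#'   has_utr) and `summary` (list: n_genes, exon range, n_single_exon,
#'   n_without_utr, utr_fraction_pct at 2 dp).
#' @export
structure_stats <- function(ann, genes = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  ids <- genes %||% ann$genes$gene_id
  f <- ann$features[ann$features$gene_id %in% ids, ]
  n_ex <- tapply(f$type == "exon", f$gene_id, sum)
  has_utr <- tapply(grepl("UTR", f$type), f$gene_id, any)
  per_gene <- data.frame(
    gene_id = ids,
    n_exons = as.integer(n_ex[ids]),
    has_utr = as.logical(has_utr[ids]),
    stringsAsFactors = FALSE
  )
  per_gene$n_introns <- pmax(per_gene$n_exons - 1L, 0L)
  per_gene <- per_gene[, c("gene_id", "n_exons", "n_introns", "has_utr")]
  list(
    per_gene = per_gene,
    summary = list(
      n_genes = nrow(per_gene),
      exon_min = min(per_gene$n_exons), exon_max = max(per_gene$n_exons),
      n_single_exon = sum(per_gene$n_exons == 1),
      n_without_utr = sum(!per_gene$has_utr),
      utr_fraction_pct = round_half_up(
        100 * sum(per_gene$has_utr) / nrow(per_gene), 2
      )
    )
  )
}

#' Chromosomal distribution of a gene set
#'
#' Per-chromosome counts and percentage shares, plus the share of genes
#' whose midpoint lies within `terminal_fraction` of either chromosome
#' end. The terminal window is a parameter because "chromosome ends" has
#' no standard definition.
#'
#' @param ann a [genome_annotation].
#' @param genes optional gene-ID subset.
#' @param terminal_fraction proportion of the chromosome length counted as
#'   terminal at each end (0 < f <= 0.5; default 0.25).
#' @param decimals decimal places for printed shares (half-up rounding).
#' @return list with `per_chromosome` (data.frame chrom, n_genes,
#'   share_pct), `total`, and `terminal_share_pct`.
#' @export
chromosome_distribution <- function(ann, genes = NULL,
                                    terminal_fraction = 0.25, decimals = 1) {
  stopifnot(
    inherits(ann, "genome_annotation"),
    terminal_fraction > 0, terminal_fraction <= 0.5
  )
  g <- ann$genes
  if (!is.null(genes)) g <- g[g$gene_id %in% genes, ]
  counts <- table(g$chrom)
  total <- nrow(g)
  per <- data.frame(
    chrom = names(counts), n_genes = as.integer(counts),
    stringsAsFactors = FALSE
  )
  per <- per[natural_order(per$chrom), ]
  rownames(per) <- NULL
  per$share_pct <- report_shares(per$n_genes, total, decimals)
  mid <- (g$start0 + g$end0) / 2
  len <- ann$chrom_lengths[g$chrom]
  terminal <- mid < terminal_fraction * len | mid > (1 - terminal_fraction) * len
  list(
    per_chromosome = per, total = total,
    terminal_share_pct = round_half_up(100 * sum(terminal) / max(total, 1),
                                       decimals)
  )
}
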