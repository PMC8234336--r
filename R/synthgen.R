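# Synthetic genomes, reference panels, expression matrices and qPCR tables
# with known ground truth, so that every downstream survey stage has a
# parameter-recovery test. All randomness flows from one integer seed.

HYDROPHOBIC <- c("I", "L", "V", "F", "A", "M")
HYDROPHILIC <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G", "P", "H")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# synonymous codon sets per amino acid (sense codons only)
codons_by_aa <- function() {
  if (is.null(.abc_cache$by_aa)) {
    gc <- genetic_code()
    sense <- sense_codons()
    .abc_cache$by_aa <- split(sense, gc[sense])
  }
  .abc_cache$by_aa
}

# uniform reverse translation of a protein; appends a random stop codon
reverse_translate <- function(protein) {
  by_aa <- codons_by_aa()
  aa <- strsplit(protein, "")[[1]]
  cods <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue '", a, "'")
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0(paste(cods, collapse = ""), sample(STOP_CODONS, 1))
}

random_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- CDS pair evolution ------------------------------------------------------

#' Evolve one coding sequence from an ancestor at a target divergence
#'
#' Simulates per-codon independent substitution (no rate heterogeneity)
#' under a continuous-time model: each single-nucleotide neighbour of the
#' current codon is reached at rate `target_ks/3` if the change is
#' synonymous and `target_omega * target_ks/3` if nonsynonymous; changes
#' creating a stop codon have rate 0 when `forbid_stop` is set. Run for
#' unit time this yields an expected synonymous density of `target_ks`
#' substitutions per synonymous site (the NG86 estimand) and a
#' nonsynonymous density of `target_omega * target_ks`.
#'
#' A terminal stop codon, if present, is carried over unchanged.
#'
#' @param ancestor_cds coding sequence, length divisible by 3, no internal
#'   stop codons.
#' @param target_ks target synonymous substitutions per synonymous site
#'   (>= 0). Values above 2 are allowed but flagged `saturated` (downstream
#'   Ka/Ks summaries discard such pairs).
#' @param target_omega target Ka/Ks ratio (>= 0).
#' @param seed optional integer; when given, the simulation runs under its
#'   own seeded RNG scope, otherwise it consumes the ambient RNG stream.
#' @param forbid_stop disallow substitutions creating internal stops
#'   (default TRUE).
#' @param invariant_codons integer codon indices at which nonsynonymous
#'   changes are disallowed (models site-specific purifying selection,
#'   e.g. on diagnostic Walker motifs of planted family members).
#' @return list with `descendant` (CDS string), realized substitution
#'   counts `n_syn`, `n_nonsyn`, and `saturated` flag.
#' @export
#' @examples
#' out <- evolve_cds_pair("ATGGCTAAATTTGGG", 0.5, 0.2, seed = 1)
#' out$n_syn
evolve_cds_pair <- function(ancestor_cds, target_ks, target_omega,
                            seed = NULL, forbid_stop = TRUE,
                            invariant_codons = integer()) {
  stopifnot(target_ks >= 0, target_omega >= 0)
  nb <- codon_neighbour_table()
  run <- function() {
    cods <- split_codons(ancestor_cds)
    aa <- translate_codons(cods)
    n <- length(cods)
    has_stop <- n > 0 && aa[n] == "*"
    evolve_idx <- seq_len(if (has_stop) n - 1 else n)
    if (any(aa[evolve_idx] == "*")) {
      stop("internal stop codon at codon index ", which(aa == "*")[1])
    }
    n_syn <- 0L
    n_nonsyn <- 0L
    if (target_ks > 0) {
      syn_rate <- target_ks / 3
      for (i in evolve_idx) {
        cur <- cods[i]
        nonsyn_rate <- if (i %in% invariant_codons) 0 else
          target_omega * target_ks / 3
        t <- 0
        repeat {
          e <- nb[[cur]]
          rates <- ifelse(e$syn, syn_rate,
                          ifelse(e$stop & forbid_stop, 0, nonsyn_rate))
          total <- sum(rates)
          if (total <= 0) break
          t <- t + rexp(1, total)
          if (t > 1) break
          pick <- sample.int(9, 1, prob = rates)
          if (e$syn[pick]) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
          cur <- e$to[pick]
        }
        cods[i] <- cur
      }
    }
    list(
      descendant = paste(cods, collapse = ""),
      n_syn = n_syn, n_nonsyn = n_nonsyn,
      saturated = target_ks > 2
    )
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# cached single-nucleotide neighbourhood of every sense codon: the 9
# neighbour codons plus synonymous / stop indicator flags
codon_neighbour_table <- function() {
  if (!is.null(.abc_cache$nbr_tab)) return(.abc_cache$nbr_tab)
  gc <- genetic_code()
  tab <- list()
  for (cod in sense_codons()) {
    to <- character(9)
    k <- 0
    for (pos in 1:3) {
      for (nt in setdiff(NUCS, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- nt
        k <- k + 1
        to[k] <- mut
      }
    }
    aa <- gc[[cod]]
    tab[[cod]] <- list(
      to = to,
      syn = unname(gc[to] == aa),
      stop = unname(gc[to] == "*")
    )
  }
  .abc_cache$nbr_tab <- tab
  tab
}

# --- ABC-like protein construction -------------------------------------------

# domain layout per subfamily: forward full transporters (A-C), a forward
# half transporter (D), soluble members (E, F, I) and reverse-organized G
SUBFAMILY_LAYOUT <- list(
  A = c("T", "N", "T", "N"), B = c("T", "N", "T", "N"),
  C = c("T", "N", "T", "N"), D = c("T", "N"),
  E = c("N"), F = c("N", "N"), G = c("N", "T", "N", "T"),
  I = c("N")
)

# motif islands planted in every synthetic NBD; these satisfy the package's
# scanning patterns (Walker A, Q-loop, ABC signature, Walker B, H-loop)
NBD_MOTIFS <- c(
  walkerA = "GPSGSGKST",
  q_loop = "LLSQ",
  abc_signature = "LSGGQR",
  walkerB = "RLLDGHETLLL",
  h_loop = "LHL"
)

# Build one ABC-like protein with the given domain layout. Motif islands
# are fixed; helices, loops and spacers are drawn from the ambient RNG.
# Returns the protein string with an attribute "protected" holding the
# residue ranges (matrix start,end) of motif islands and helix cores.
make_abc_protein <- function(layout) {
  parts <- character(0)
  protected <- NULL
  pos <- 0
  add <- function(s, protect = FALSE) {
    parts[[length(parts) + 1]] <<- s
    if (protect) {
      protected <<- rbind(protected, c(pos + 1, pos + nchar(s)))
    }
    pos <<- pos + nchar(s)
  }
  add(random_protein(15, HYDROPHILIC))
  for (dom in layout) {
    if (dom == "T") {
      for (h in 1:5) {
        add(random_protein(21, HYDROPHOBIC), protect = TRUE)
        if (h < 5) add(random_protein(15, HYDROPHILIC))
      }
    } else {
      add(random_protein(25))
      add(NBD_MOTIFS[["walkerA"]], protect = TRUE)
      add(random_protein(40))
      add(NBD_MOTIFS[["q_loop"]], protect = TRUE)
      add(random_protein(30))
      add(NBD_MOTIFS[["abc_signature"]], protect = TRUE)
      add(random_protein(20))
      add(NBD_MOTIFS[["walkerB"]], protect = TRUE)
      add(random_protein(15))
      add(NBD_MOTIFS[["h_loop"]], protect = TRUE)
      add(random_protein(20))
    }
    add(random_protein(25, HYDROPHILIC))
  }
  structure(paste(parts, collapse = ""), protected = protected)
}

# substitute residues outside protected ranges at the given rate
mutate_protein <- function(protein, rate, protected = attr(protein, "protected")) {
  aa <- strsplit(as.character(protein), "")[[1]]
  free <- rep(TRUE, length(aa))
  if (!is.null(protected)) {
    for (r in seq_len(nrow(protected))) {
      free[protected[r, 1]:protected[r, 2]] <- FALSE
    }
  }
  idx <- which(free & runif(length(aa)) < rate)
  for (i in idx) aa[i] <- sample(setdiff(AA20, aa[i]), 1)
  structure(paste(aa, collapse = ""), protected = protected)
}

#' Simulate a subfamily-labelled ABC reference panel
#'
#' Builds one or more ABC-like proteins per subfamily (A-G and I) with the
#' canonical domain layout of that subfamily (full forward transporters
#' for A-C, half for D, soluble for E/F/I, reverse-organized for G) and
#' light mutational divergence between panel members.
#'
#' @param seed integer seed.
#' @param n_per_subfamily panel members per subfamily (default 2).
#' @param divergence per-residue substitution rate between members of the
#'   same subfamily (motif islands protected).
#' @return data.frame with columns `id`, `subfamily`, `sequence`.
#' @export
simulate_reference_panel <- function(seed = 1, n_per_subfamily = 2,
                                     divergence = 0.05) {
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (sub in names(SUBFAMILY_LAYOUT)) {
      base <- make_abc_protein(SUBFAMILY_LAYOUT[[sub]])
      for (i in seq_len(n_per_subfamily)) {
        p <- if (i == 1) base else mutate_protein(base, divergence)
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("ref%s%d", sub, i), subfamily = sub,
          sequence = as.character(p), stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Write / read a subfamily-labelled reference panel FASTA
#'
#' Headers carry the label as `>id subfamily=X`.
#'
#' @param panel data.frame with `id`, `subfamily`, `sequence`.
#' @param path FASTA file path.
#' @return `read_reference_panel` returns the panel data.frame.
#' @export
write_reference_panel <- function(panel, path) {
  aa <- Biostrings::AAStringSet(panel$sequence)
  names(aa) <- sprintf("%s subfamily=%s", panel$id, panel$subfamily)
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' @rdname write_reference_panel
#' @export
read_reference_panel <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  id <- sub("\\s.*$", "", hdr)
  m <- regmatches(hdr, regexpr("subfamily=[A-Za-z]+", hdr))
  if (length(m) != length(hdr)) {
    stop("panel header without subfamily= tag")
  }
  data.frame(
    id = id, subfamily = sub("subfamily=", "", m),
    sequence = as.character(aa), stringsAsFactors = FALSE
  )
}

# --- genome simulation -------------------------------------------------------

#' Describe one planted duplication event
#'
#' @param family_label subfamily tag (one of A-G, I).
#' @param kind one of "tandem", "proximal", "dispersed", "segmental".
#' @param target_ks,target_omega divergence parameters passed to
#'   [evolve_cds_pair()].
#' @param intervening_genes background genes between the two copies
#'   (proximal only; must be >= 2 so the pair is not tandem; forced 0 for
#'   tandem).
#' @param block_size genes per collinear block copy (segmental only;
#'   >= 5 so default block detection recovers it).
#' @param n_family how many of the block genes are family members
#'   (segmental only).
#' @return a `planted_duplication` list.
#' @export
planted_duplication <- function(family_label, kind, target_ks = 0.3,
                                target_omega = 0.2, intervening_genes = 4,
                                block_size = 6, n_family = 1) {
  kind <- match.arg(kind, c("tandem", "proximal", "dispersed", "segmental"))
  stopifnot(
    family_label %in% names(SUBFAMILY_LAYOUT),
    target_ks >= 0, target_omega >= 0
  )
  if (kind == "tandem") intervening_genes <- 0L
  if (kind == "proximal" && intervening_genes < 2) {
    stop("proximal events need >= 2 intervening genes")
  }
  if (kind == "segmental") {
    if (block_size < 5) stop("segmental blocks need >= 5 genes")
    stopifnot(n_family >= 1, n_family <= block_size)
  }
  structure(
    list(
      family_label = family_label, kind = kind,
      target_ks = target_ks, target_omega = target_omega,
      intervening_genes = as.integer(intervening_genes),
      block_size = as.integer(block_size), n_family = as.integer(n_family)
    ),
    class = "planted_duplication"
  )
}

#' Genome simulation configuration
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bases (all chromosomes).
#' @param n_background_genes free-floating background genes (random codon
#'   composition, uniform usage); genes consumed as proximal interveners or
#'   segmental block filler are created in addition to this count.
#' @param events list of [planted_duplication()] objects.
#' @param seed integer; fully determines the output.
#' @param utr_dropout fraction of genes left without UTR segments.
#' @param bg_protein_len length range (residues) for background proteins.
#' @return a `genome_sim_config` list.
#' @export
genome_sim_config <- function(n_chromosomes = 5, chrom_length = 2e6,
                              n_background_genes = 100, events = list(),
                              seed = 1, utr_dropout = 0.03,
                              bg_protein_len = c(150, 450)) {
  stopifnot(
    n_chromosomes >= 1, chrom_length > 0, n_background_genes >= 0,
    all(vapply(events, inherits, logical(1), "planted_duplication")),
    utr_dropout >= 0, utr_dropout <= 1
  )
  if (length(events) > 0 && n_chromosomes < 2 &&
      any(vapply(events, `[[`, character(1), "kind") %in%
          c("dispersed", "segmental"))) {
    stop("dispersed/segmental events need >= 2 chromosomes")
  }
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.numeric(chrom_length),
      n_background_genes = as.integer(n_background_genes),
      events = events, seed = as.integer(seed),
      utr_dropout = utr_dropout, bg_protein_len = bg_protein_len
    ),
    class = "genome_sim_config"
  )
}

#' Simulate an annotated genome with planted duplications
#'
#' Generates background genes (random codon composition) plus the planted
#' duplication events of the configuration: tandem pairs (adjacent gene
#' ranks), proximal pairs (separated by intervening background genes),
#' dispersed pairs (different chromosomes, no collinear context), and
#' segmental blocks (a run of genes duplicated onto another chromosome in
#' order, so collinear-block detection recovers it). Each gene gets a full
#' gene model (exons, introns, UTRs, CDS, protein); the same seed always
#' yields identical output.
#'
#' The returned panel contains a lightly mutated copy of every planted
#' family ancestor (labelled with its subfamily) plus archetypes for the
#' subfamilies not used by any event, so panel-based subfamily assignment
#' has the true label in reach.
#'
#' @param config a [genome_sim_config()].
#' @return list of class `genome_sim`: `annotation` (a
#'   [genome_annotation] object), `truth` (data.frame of planted genes:
#'   event, kind, family label, partner, true Ks/omega, realized
#'   substitution counts), `panel` (reference-panel data.frame), `config`.
#' @seealso [write_genome()] to serialize to FASTA/GFF3/TSV.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  chroms <- sprintf("Chr%02d", seq_len(config$n_chromosomes))
  payloads <- list()   # per-gene payload: protein, cds, meta
  units <- list()      # placement units: gene index vectors + chromosome
  truth <- list()
  panel_rows <- list()
  gene_counter <- 0

  new_gene <- function(protein, cds, protected_codons = integer()) {
    gene_counter <<- gene_counter + 1
    payloads[[gene_counter]] <<- list(
      protein = protein, cds = cds, protected = protected_codons
    )
    gene_counter
  }

  make_background <- function() {
    plen <- sample(seq(config$bg_protein_len[1], config$bg_protein_len[2]), 1)
    cods <- sample(sense_codons(), plen, replace = TRUE)
    cds <- paste0(paste(cods, collapse = ""), sample(STOP_CODONS, 1))
    new_gene(cds_to_protein(cds), cds)
  }

  protected_codon_idx <- function(prot) {
    pr <- attr(prot, "protected")
    if (is.null(pr)) return(integer())
    unlist(lapply(seq_len(nrow(pr)), function(r) pr[r, 1]:pr[r, 2]))
  }

  # --- create event payloads -------------------------------------------------
  used_subfamilies <- character(0)
  for (e in seq_along(config$events)) {
    ev <- config$events[[e]]
    anc_prot <- make_abc_protein(SUBFAMILY_LAYOUT[[ev$family_label]])
    used_subfamilies <- c(used_subfamilies, ev$family_label)
    panel_rows[[length(panel_rows) + 1]] <- data.frame(
      id = sprintf("ref_%s_e%d", ev$family_label, e),
      subfamily = ev$family_label,
      sequence = as.character(mutate_protein(anc_prot, 0.03)),
      stringsAsFactors = FALSE
    )
    make_family_pair <- function() {
      anc_cds <- reverse_translate(as.character(anc_prot))
      inv <- protected_codon_idx(anc_prot)
      desc <- evolve_cds_pair(anc_cds, ev$target_ks, ev$target_omega,
                              invariant_codons = inv)
      g1 <- new_gene(cds_to_protein(anc_cds), anc_cds, inv)
      g2 <- new_gene(cds_to_protein(desc$descendant), desc$descendant, inv)
      list(g1 = g1, g2 = g2, desc = desc)
    }
    add_truth <- function(gidx, partner, is_family, desc) {
      truth[[length(truth) + 1]] <<- data.frame(
        event = e, kind = ev$kind, family_label = ev$family_label,
        gene_idx = gidx, partner_idx = partner, is_family = is_family,
        true_ks = ev$target_ks, true_omega = ev$target_omega,
        realized_syn = desc$n_syn, realized_nonsyn = desc$n_nonsyn,
        stringsAsFactors = FALSE
      )
    }
    if (ev$kind %in% c("tandem", "proximal", "dispersed")) {
      fp <- make_family_pair()
      add_truth(fp$g1, fp$g2, TRUE, fp$desc)
      add_truth(fp$g2, fp$g1, TRUE, fp$desc)
      if (ev$kind == "tandem") {
        units[[length(units) + 1]] <- list(genes = c(fp$g1, fp$g2))
      } else if (ev$kind == "proximal") {
        mid <- replicate(ev$intervening_genes, make_background())
        units[[length(units) + 1]] <- list(genes = c(fp$g1, mid, fp$g2))
      } else {
        units[[length(units) + 1]] <- list(genes = fp$g1, pair_with = length(units) + 2)
        units[[length(units) + 1]] <- list(genes = fp$g2, other_chrom_than = length(units))
      }
    } else { # segmental
      # family genes spread across the block, filler genes around them
      fam_slots <- unique(round(seq(1, ev$block_size,
                                    length.out = ev$n_family + 2)))[-c(1)]
      fam_slots <- head(fam_slots, ev$n_family)
      if (length(fam_slots) < ev$n_family) {
        fam_slots <- seq_len(ev$n_family)
      }
      block_a <- integer(ev$block_size)
      block_b <- integer(ev$block_size)
      for (s in seq_len(ev$block_size)) {
        if (s %in% fam_slots) {
          fp <- make_family_pair()
          block_a[s] <- fp$g1
          block_b[s] <- fp$g2
          add_truth(fp$g1, fp$g2, TRUE, fp$desc)
          add_truth(fp$g2, fp$g1, TRUE, fp$desc)
        } else {
          # filler ancestor: random protein, duplicated across the block so
          # it anchors the collinear chain
          plen <- sample(180:320, 1)
          anc_cds <- reverse_translate(random_protein(plen))
          desc <- evolve_cds_pair(anc_cds, ev$target_ks, ev$target_omega)
          block_a[s] <- new_gene(cds_to_protein(anc_cds), anc_cds)
          block_b[s] <- new_gene(cds_to_protein(desc$descendant),
                                 desc$descendant)
          add_truth(block_a[s], block_b[s], FALSE, desc)
          add_truth(block_b[s], block_a[s], FALSE, desc)
        }
      }
      units[[length(units) + 1]] <- list(genes = block_a)
      units[[length(units) + 1]] <- list(
        genes = block_b, other_chrom_than = length(units)
      )
    }
  }

  for (sub in setdiff(names(SUBFAMILY_LAYOUT), used_subfamilies)) {
    panel_rows[[length(panel_rows) + 1]] <- data.frame(
      id = sprintf("ref_%s_arch", sub), subfamily = sub,
      sequence = as.character(make_abc_protein(SUBFAMILY_LAYOUT[[sub]])),
      stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(config$n_background_genes)) {
    units[[length(units) + 1]] <- list(genes = make_background())
  }

  # --- assign units to chromosomes ------------------------------------------
  unit_chrom <- integer(length(units))
  for (u in seq_along(units)) {
    if (unit_chrom[u] > 0) next
    constraint <- units[[u]]$other_chrom_than
    if (!is.null(constraint)) {
      avoid <- unit_chrom[constraint]
      if (avoid == 0) { # partner not placed yet; place it first
        unit_chrom[constraint] <- sample.int(config$n_chromosomes, 1)
        avoid <- unit_chrom[constraint]
      }
      choices <- setdiff(seq_len(config$n_chromosomes), avoid)
      unit_chrom[u] <- choices[sample.int(length(choices), 1)]
    } else {
      unit_chrom[u] <- sample.int(config$n_chromosomes, 1)
    }
  }

  # --- lay out genes on each chromosome -------------------------------------
  no_utr <- runif(gene_counter) < config$utr_dropout
  gene_rows <- list()
  feat_rows <- list()
  for (ci in seq_len(config$n_chromosomes)) {
    members <- which(unit_chrom == ci)
    members <- members[sample.int(length(members))] # shuffle unit order
    cursor <- sample(1000:5000, 1)
    for (u in members) {
      for (g in units[[u]]$genes) {
        gm <- build_gene_model(payloads[[g]]$cds, no_utr[g])
        gene_start <- cursor
        if (gene_start + gm$span - 1 > config$chrom_length) {
          stop("chromosome ", chroms[ci], " too short for requested genes; ",
               "increase chrom_length or reduce gene count")
        }
        gid <- sprintf("gene%04d", g)
        strand <- sample(c("+", "-"), 1)
        gene_rows[[length(gene_rows) + 1]] <- data.frame(
          gene_id = gid, chrom = chroms[ci], strand = strand,
          start1 = gene_start, end1 = gene_start + gm$span - 1,
          stringsAsFactors = FALSE
        )
        feat_rows[[length(feat_rows) + 1]] <- within(gm$features, {
          start1 <- start1 + gene_start - 1
          end1 <- end1 + gene_start - 1
          gene_id <- gid
          chrom <- chroms[ci]
          strand <- strand
        })
        cursor <- gene_start + gm$span - 1 + sample(2000:8000, 1)
      }
    }
  }

  genes <- do.call(rbind, gene_rows)
  feats <- do.call(rbind, feat_rows)
  # flip UTR polarity for minus-strand genes: the leftmost flank is 3'
  minus <- feats$strand == "-" & grepl("UTR", feats$type)
  feats$type[minus] <- ifelse(
    feats$type[minus] == "five_prime_UTR", "three_prime_UTR", "five_prime_UTR"
  )

  ids <- sprintf("gene%04d", seq_len(gene_counter))
  prot <- setNames(
    vapply(payloads, function(p) as.character(p$protein), character(1)), ids
  )
  cds <- setNames(
    vapply(payloads, function(p) as.character(p$cds), character(1)), ids
  )

  ann <- new_genome_annotation(
    genes = genes, features = feats, cds = cds, protein = prot,
    chrom_lengths = setNames(rep(config$chrom_length, length(chroms)), chroms)
  )

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(
      event = integer(), kind = character(), family_label = character(),
      gene_idx = integer(), partner_idx = integer(), is_family = logical(),
      true_ks = numeric(), true_omega = numeric(),
      realized_syn = integer(), realized_nonsyn = integer()
    )
  if (nrow(truth_df)) {
    truth_df$gene_id <- sprintf("gene%04d", truth_df$gene_idx)
    truth_df$partner_id <- sprintf("gene%04d", truth_df$partner_idx)
    truth_df$gene_idx <- NULL
    truth_df$partner_idx <- NULL
  } else {
    truth_df$gene_id <- character()
    truth_df$partner_id <- character()
  }

  structure(
    list(
      annotation = ann, truth = truth_df,
      panel = do.call(rbind, panel_rows), config = config
    ),
    class = "genome_sim"
  )
}

# Build exon/intron/UTR layout for one gene (gene-local 1-based coords on
# the forward genomic axis). CDS includes the stop codon.
build_gene_model <- function(cds, drop_utr) {
  cds_len <- nchar(cds)
  n_codons <- cds_len / 3
  max_exons <- max(1, min(8, floor(n_codons / 15)))
  n_exons <- sample.int(max_exons, 1)
  # split the CDS into n_exons chunks, each >= 3 bases
  if (n_exons == 1) {
    chunk <- cds_len
  } else {
    cuts <- sort(sample(seq_len(cds_len - 1), n_exons - 1))
    chunk <- diff(c(0, cuts, cds_len))
    while (any(chunk < 3)) { # resample tiny chunks
      cuts <- sort(sample(seq_len(cds_len - 1), n_exons - 1))
      chunk <- diff(c(0, cuts, cds_len))
    }
  }
  utr5 <- if (drop_utr) 0 else sample(60:300, 1)
  utr3 <- if (drop_utr) 0 else sample(60:300, 1)
  introns <- if (n_exons > 1) sample(80:400, n_exons - 1, replace = TRUE) else integer()

  rows <- list()
  pos <- 1
  for (i in seq_len(n_exons)) {
    exon_start <- pos
    if (i == 1 && utr5 > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        type = "five_prime_UTR", start1 = pos, end1 = pos + utr5 - 1
      )
      pos <- pos + utr5
    }
    rows[[length(rows) + 1]] <- data.frame(
      type = "CDS", start1 = pos, end1 = pos + chunk[i] - 1
    )
    pos <- pos + chunk[i]
    if (i == n_exons && utr3 > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        type = "three_prime_UTR", start1 = pos, end1 = pos + utr3 - 1
      )
      pos <- pos + utr3
    }
    rows[[length(rows) + 1]] <- data.frame(
      type = "exon", start1 = exon_start, end1 = pos - 1
    )
    if (i < n_exons) pos <- pos + introns[i]
  }
  feats <- do.call(rbind, rows)
  list(features = feats, span = max(feats$end1))
}

#' Serialize a simulated genome to standard files
#'
#' Writes `proteins.fa`, `cds.fa` (FASTA, 60 columns), `genes.gff3`
#' (1-based inclusive, gene/mRNA/exon/CDS/UTR features), `truth.tsv` and
#' `panel.fa` into a directory.
#'
#' @param sim a `genome_sim` from [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "genome_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteins = file.path(dir, "proteins.fa"),
    cds = file.path(dir, "cds.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.tsv"),
    panel = file.path(dir, "panel.fa")
  )
  write_annotation(sim$annotation, gff3 = paths[["gff3"]],
                   protein_fasta = paths[["proteins"]],
                   cds_fasta = paths[["cds"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_reference_panel(sim$panel, paths[["panel"]])
  invisible(paths)
}

# --- expression matrix -------------------------------------------------------

#' Simulate a genes x tissues TPM matrix with known expression categories
#'
#' @param n_ubiquitous genes expressed (TPM > 0) in every tissue.
#' @param n_silent genes with TPM 0 everywhere.
#' @param n_specific genes expressed in exactly one tissue.
#' @param n_other genes expressed in between 2 and (n tissues - 1) tissues.
#' @param tissues character vector of tissue labels.
#' @param seed integer seed.
#' @param gene_ids optional gene identifiers (default gene0001...).
#' @return list with `tpm` (numeric matrix, genes x tissues) and `truth`
#'   (data.frame gene_id, category, specific_tissue).
#' @export
simulate_expression_matrix <- function(n_ubiquitous, n_silent, n_specific,
                                       n_other, tissues, seed = 1,
                                       gene_ids = NULL) {
  stopifnot(length(tissues) >= 1)
  n <- n_ubiquitous + n_silent + n_specific + n_other
  if (n_other > 0 && length(tissues) < 3) {
    stop("'other' genes need at least 3 tissues")
  }
  if (n_specific > 0 && length(tissues) < 2) {
    stop("tissue-specific genes need at least 2 tissues")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(n))
  stopifnot(length(gene_ids) == n)
  withr::with_seed(as.integer(seed), {
    tpm <- matrix(0, nrow = n, ncol = length(tissues),
                  dimnames = list(gene_ids, tissues))
    draw <- function(k) pmax(round(rlnorm(k, meanlog = 2, sdlog = 1), 2), 0.01)
    category <- rep(
      c("ubiquitous", "silent", "tissue_specific", "other"),
      c(n_ubiquitous, n_silent, n_specific, n_other)
    )
    specific <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (category[i] == "ubiquitous") {
        tpm[i, ] <- draw(length(tissues))
      } else if (category[i] == "tissue_specific") {
        t1 <- sample(seq_along(tissues), 1)
        tpm[i, t1] <- draw(1)
        specific[i] <- tissues[t1]
      } else if (category[i] == "other") {
        kk <- 2:(length(tissues) - 1)
        k <- kk[sample.int(length(kk), 1)]
        tpm[i, sample(seq_along(tissues), k)] <- draw(k)
      }
    }
    list(
      tpm = tpm,
      truth = data.frame(
        gene_id = gene_ids, category = category,
        specific_tissue = specific, stringsAsFactors = FALSE
      )
    )
  })
}

#' Write a TPM matrix as TSV (gene_id first column)
#' @param tpm numeric matrix with gene row names and tissue column names.
#' @param path output file.
#' @export
write_tpm <- function(tpm, path) {
  df <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- qPCR tables -------------------------------------------------------------

#' Simulate a qPCR Ct table under the 2^-ddCt model
#'
#' For every sample (condition x timepoint x replicate) a reference-gene
#' row is emitted with Ct around `ct_ref`; each target gene's Ct follows
#' `Ct = Ct_ref + dCt0(gene) - log2(fold) + noise`, where `fold` is the
#' true fold change (1 in the control condition) and noise is Gaussian
#' with SD `ct_noise_sd` on every measured Ct.
#'
#' @param fold_changes data.frame with columns `gene`, `timepoint`,
#'   `fold`: the true treatment/control fold change per gene and
#'   timepoint.
#' @param ct_noise_sd Gaussian noise SD in Ct cycles (default 0).
#' @param n_replicates replicates per sample (>= 2).
#' @param seed integer seed.
#' @param reference_gene label for the normalizer rows.
#' @param ct_ref baseline reference-gene Ct.
#' @return data.frame with columns gene, condition, timepoint, replicate,
#'   ct; reference-gene rows present for every sample.
#' @export
simulate_qpcr_table <- function(fold_changes, ct_noise_sd = 0,
                                n_replicates = 3, seed = 1,
                                reference_gene = "beta_tubulin",
                                ct_ref = 20) {
  stopifnot(
    all(c("gene", "timepoint", "fold") %in% names(fold_changes)),
    n_replicates >= 2, all(fold_changes$fold > 0)
  )
  genes <- unique(fold_changes$gene)
  timepoints <- sort(unique(fold_changes$timepoint))
  withr::with_seed(as.integer(seed), {
    dct0 <- setNames(runif(length(genes), 3, 8), genes)
    rows <- list()
    for (cond in c("control", "treatment")) {
      for (tp in timepoints) {
        for (rep_i in seq_len(n_replicates)) {
          noise <- function() if (ct_noise_sd > 0) rnorm(1, 0, ct_noise_sd) else 0
          rows[[length(rows) + 1]] <- data.frame(
            gene = reference_gene, condition = cond, timepoint = tp,
            replicate = rep_i, ct = ct_ref + noise(),
            stringsAsFactors = FALSE
          )
          for (g in genes) {
            fold <- if (cond == "control") 1 else {
              hit <- fold_changes$fold[fold_changes$gene == g &
                                         fold_changes$timepoint == tp]
              if (length(hit) == 0) 1 else hit[1]
            }
            rows[[length(rows) + 1]] <- data.frame(
              gene = g, condition = cond, timepoint = tp,
              replicate = rep_i,
              ct = ct_ref + dct0[[g]] - log2(fold) + noise(),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}
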