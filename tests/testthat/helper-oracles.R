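# Independent oracle implementations used to verify package results.
# These deliberately avoid the package's own code paths and lookup tables.

# --- brute-force motif matching ---------------------------------------------
# All package motif patterns are fixed-length; represent each as a list of
# allowed residue sets per position and slide a window position by
# position, taking non-overlapping leftmost matches.
ORACLE_MOTIF_SETS <- list(
  walkerA = list("G", setdiff(LETTERS, "X"), setdiff(LETTERS, "X"), "G",
                 setdiff(LETTERS, "X"), "G", "K", c("S", "T")),
  abc_signature = list(c("L", "I", "V", "M", "F", "Y"), "S", c("S", "G"),
                       "G", setdiff(LETTERS, "X"), c("Q", "R", "K", "E"))
)

oracle_scan <- function(protein, motif) {
  sets <- ORACLE_MOTIF_SETS[[motif]]
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  w <- length(sets)
  hits <- integer()
  i <- 1
  while (i <= n - w + 1) {
    ok <- TRUE
    for (p in seq_len(w)) {
      if (!(aa[i + p - 1] %in% sets[[p]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      hits <- c(hits, i)
      i <- i + w
    } else {
      i <- i + 1
    }
  }
  hits
}

# --- exhaustive NG86 enumeration --------------------------------------------
oracle_code <- function() {
  # independent copy of the standard genetic code
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  setNames(aas, codons)
}

oracle_syn_sites <- function(codon, code) {
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# enumerate minimal pathways recursively; returns c(sd, nd) averaged over
# stop-free pathways (all pathways if every one is blocked)
oracle_path_counts <- function(a, b, code) {
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  walk <- function(cur, remaining, sd, nd, blocked) {
    if (length(remaining) == 0) {
      return(list(c(sd, nd, blocked)))
    }
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      step_syn <- code[[cur]] == code[[nxt]]
      hit_stop <- code[[nxt]] == "*" && length(remaining) > 1
      out <- c(out, walk(nxt, setdiff(remaining, pos),
                         sd + step_syn, nd + !step_syn,
                         blocked || hit_stop))
    }
    out
  }
  if (length(diffs) == 0) return(c(0, 0))
  paths <- do.call(rbind, walk(a, diffs, 0, 0, FALSE))
  ok <- paths[, 3] == 0
  use <- if (any(ok)) paths[ok, , drop = FALSE] else paths
  c(mean(use[, 1]), mean(use[, 2]))
}

# --- brute-force chain search -----------------------------------------------
# longest monotone anchor chain under the gap constraint, by top-down
# recursion over successors (independent of the package's bottom-up DP)
oracle_best_chain_len <- function(rank_a, rank_b, max_gap, direction = 1) {
  n <- length(rank_a)
  if (n == 0) return(0L)
  memo <- rep(NA_integer_, n)
  longest_from <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    best <- 1L
    for (j in seq_len(n)) {
      da <- rank_a[j] - rank_a[i]
      db <- direction * (rank_b[j] - rank_b[i])
      if (da > 0 && db > 0 && da <= max_gap && db <= max_gap) {
        best <- max(best, 1L + longest_from(j))
      }
    }
    memo[i] <<- best
    best
  }
  max(vapply(seq_len(n), longest_from, integer(1)))
}

# --- shared fixtures ---------------------------------------------------------
small_sim <- function(seed = 7) {
  simulate_genome(genome_sim_config(
    n_chromosomes = 4, chrom_length = 3e6, n_background_genes = 40,
    seed = seed,
    events = list(
      planted_duplication("B", "tandem", 0.3, 0.2),
      planted_duplication("C", "proximal", 0.4, 0.2, intervening_genes = 4),
      planted_duplication("G", "dispersed", 0.5, 0.3),
      planted_duplication("A", "segmental", 0.3, 0.2,
                          block_size = 6, n_family = 2)
    )
  ))
}

SOY_TISSUES <- c(
  "suspensor", "cotyledon", "hypocotyls", "embryo", "endosperm",
  "seed_coat", "seedling", "root", "shoot", "leaves", "nodule", "flower",
  "pod", "seed", "callus"
)
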