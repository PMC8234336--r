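# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, codon-aware
# pairwise alignment, saturation filtering, and divergence-time estimation
# from a synonymous molecular clock.

NUCS <- c("A", "C", "G", "T")

# --- codon lookup tables -----------------------------------------------------

# For each sense codon, the fraction of the three possible single-nucleotide
# changes at each position that is synonymous, summed over positions.
# Changes creating a stop codon count as nonsynonymous (switchable).
ng_site_table <- function(stop_as_nonsyn = TRUE) {
  key <- paste0("sites_", stop_as_nonsyn)
  if (!is.null(.abc_cache[[key]])) return(.abc_cache[[key]])
  gc <- genetic_code()
  codons <- sense_codons()
  syn_sites <- setNames(numeric(length(codons)), codons)
  nonsyn_sites <- syn_sites
  for (cod in codons) {
    aa <- gc[[cod]]
    s <- 0
    n <- 0
    for (pos in 1:3) {
      alts <- setdiff(NUCS, substr(cod, pos, pos))
      n_considered <- 0
      n_syn <- 0
      for (nt in alts) {
        mut <- cod
        substr(mut, pos, pos) <- nt
        aa2 <- gc[[mut]]
        if (aa2 == "*" && !stop_as_nonsyn) next # excluded from site count
        n_considered <- n_considered + 1
        if (identical(aa2, aa)) n_syn <- n_syn + 1
      }
      # each position contributes one site, split between the synonymous
      # and nonsynonymous fractions of its admissible changes
      denom <- max(n_considered, 1)
      s <- s + n_syn / denom
      n <- n + (n_considered - n_syn) / denom
    }
    syn_sites[[cod]] <- s
    nonsyn_sites[[cod]] <- n
  }
  out <- list(S = syn_sites, N = nonsyn_sites)
  .abc_cache[[key]] <- out
  out
}

# Enumerate all minimal mutational pathways between two codons; average
# synonymous / nonsynonymous step counts over the stop-free pathways with
# equal weight. If every pathway passes through a stop codon, fall back to
# averaging over all pathways (steps into/out of a stop are nonsynonymous).
ng_path_counts <- function(codon_a, codon_b) {
  gc <- genetic_code()
  diffs <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  d <- length(diffs)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- if (d == 1) list(diffs) else {
    idx <- permutations_of(seq_len(d))
    lapply(idx, function(i) diffs[i])
  }
  paths <- lapply(perms, function(ord) {
    cur <- codon_a
    sd <- 0
    nd <- 0
    through_stop <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      aa1 <- gc[[cur]]
      aa2 <- gc[[nxt]]
      if (aa2 == "*" || aa1 == "*") through_stop <- through_stop || aa2 == "*"
      if (identical(aa1, aa2)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    # a terminal codon is sense by precondition, so through_stop marks
    # intermediate stops only
    list(sd = sd, nd = nd, stop = through_stop)
  })
  ok <- !vapply(paths, `[[`, logical(1), "stop")
  use <- if (any(ok)) paths[ok] else paths
  c(
    sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd"))
  )
}

permutations_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

# 61x61 matrices of pathway-averaged synonymous / nonsynonymous difference
# counts, built once and cached.
ng_pair_table <- function() {
  if (!is.null(.abc_cache$pair_tab)) return(.abc_cache$pair_tab)
  codons <- sense_codons()
  n <- length(codons)
  Sd <- matrix(0, n, n, dimnames = list(codons, codons))
  Nd <- Sd
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) {
        Sd[i, j] <- Sd[j, i]
        Nd[i, j] <- Nd[j, i]
      } else if (j > i) {
        cnt <- ng_path_counts(codons[i], codons[j])
        Sd[i, j] <- cnt[["sd"]]
        Nd[i, j] <- cnt[["nd"]]
      }
    }
  }
  .abc_cache$pair_tab <- list(Sd = Sd, Nd = Nd)
  .abc_cache$pair_tab
}

# --- codon alignment ---------------------------------------------------------

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Translates both CDSs (a single terminal stop codon is tolerated and
#' dropped), aligns the proteins globally (BLOSUM62, gap open 10, extend
#' 0.5), back-translates the alignment to codons, and drops every column
#' containing a gap in either sequence.
#'
#' @param cds_a,cds_b coding sequences (character or `DNAString`), length
#'   divisible by 3, no internal stop codons.
#' @param method `"protein"` (default: protein-guided alignment) or
#'   `"positional"` (pair codons by position; requires equal coding
#'   lengths; appropriate for sequences known to be indel-free, where a
#'   protein alignment at high divergence could introduce spurious gaps).
#' @return an object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (equal-length character vectors of retained codon columns)
#'   and `n_dropped` (gap-containing columns removed).
#' @export
#' @examples
#' aln <- codon_align("ATGGCTGCT", "ATGGCTGCC")
#' aln$codons_b
codon_align <- function(cds_a, cds_b, method = c("protein", "positional")) {
  method <- match.arg(method)
  cds_a <- toupper(as.character(cds_a))
  cds_b <- toupper(as.character(cds_b))
  prot_a <- cds_to_protein(cds_a)
  prot_b <- cds_to_protein(cds_b)
  cod_a <- split_codons(cds_a)[seq_len(nchar(prot_a))]
  cod_b <- split_codons(cds_b)[seq_len(nchar(prot_b))]
  if (method == "positional") {
    if (length(cod_a) != length(cod_b)) {
      stop("positional codon pairing requires equal coding lengths")
    }
    return(structure(
      list(codons_a = cod_a, codons_b = cod_b, n_dropped = 0L),
      class = "codon_alignment"
    ))
  }
  if (identical(prot_a, prot_b) && length(cod_a) == length(cod_b)) {
    aln_a <- seq_along(cod_a)
    aln_b <- seq_along(cod_b)
    n_dropped <- 0L
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global"
    )
    sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ia <- cumsum(sa != "-")
    ib <- cumsum(sb != "-")
    keep <- sa != "-" & sb != "-"
    aln_a <- ia[keep]
    aln_b <- ib[keep]
    n_dropped <- sum(!keep)
  }
  structure(
    list(
      codons_a = cod_a[aln_a],
      codons_b = cod_b[aln_b],
      n_dropped = n_dropped
    ),
    class = "codon_alignment"
  )
}

# --- NG86 --------------------------------------------------------------------

#' Nei-Gojobori (NG86) Ka/Ks for an aligned codon pair
#'
#' Fractional synonymous/nonsynonymous site counting per codon (averaged
#' between the two sequences; changes creating a stop codon count as
#' nonsynonymous), pathway-averaged difference counting over all minimal
#' mutational pathways (pathways through stop codons excluded; if every
#' pathway is blocked they are all used), and Jukes-Cantor correction
#' d = -(3/4) log(1 - (4/3) p).
#'
#' @param alignment a `codon_alignment` from [codon_align()], or a coding
#'   sequence (in which case `cds_b` must be given and the pair is aligned
#'   first).
#' @param cds_b optional second coding sequence.
#' @param stop_as_nonsyn logical; count stop-creating single-nucleotide
#'   changes as nonsynonymous in the site totals (the common NG86
#'   convention, default) or exclude them.
#' @return an object of class `kaks`: list with synonymous/nonsynonymous
#'   site counts `S`, `N`, difference counts `Sd`, `Nd`, proportions `pS`,
#'   `pN`, Jukes-Cantor distances `Ks`, `Ka`, the ratio `omega`
#'   (`NA` when Ks = 0), and flags `saturated` (Ks > 2) and
#'   `undefined_omega`.
#' @export
#' @examples
#' r <- ng86(codon_align("GGTGGTGGT", "GGCGGTGGT"))
#' r$Ks  # -(3/4) log(5/9)
ng86 <- function(alignment, cds_b = NULL, stop_as_nonsyn = TRUE) {
  if (!inherits(alignment, "codon_alignment")) {
    if (is.null(cds_b)) stop("supply a codon_alignment or two coding sequences")
    alignment <- codon_align(alignment, cds_b)
  }
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  if (length(ca) == 0) stop("no retained codon columns")
  bad <- ca %in% STOP_CODONS | cb %in% STOP_CODONS
  if (any(bad)) stop("internal stop codon at retained column ", which(bad)[1])

  sites <- ng_site_table(stop_as_nonsyn)
  S <- (sum(sites$S[ca]) + sum(sites$S[cb])) / 2
  N <- (sum(sites$N[ca]) + sum(sites$N[cb])) / 2

  tab <- ng_pair_table()
  idx <- cbind(match(ca, rownames(tab$Sd)), match(cb, colnames(tab$Sd)))
  Sd <- sum(tab$Sd[idx])
  Nd <- sum(tab$Nd[idx])

  pS <- Sd / S
  pN <- Nd / N
  if (pS >= 0.75 || pN >= 0.75) {
    stop("substitution proportion at or beyond 3/4 (pS = ",
         signif(pS, 4), ", pN = ", signif(pN, 4),
         "); Jukes-Cantor correction undefined")
  }
  jc <- function(p) if (p == 0) 0 else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS)
  Ka <- jc(pN)
  structure(
    list(
      S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
      Ks = Ks, Ka = Ka,
      omega = if (Ks > 0) Ka / Ks else NA_real_,
      saturated = Ks > 2,
      undefined_omega = Ks == 0,
      n_codons = length(ca), n_dropped = alignment$n_dropped
    ),
    class = "kaks"
  )
}

#' @export
print.kaks <- function(x, ...) {
  cat("NG86 Ka/Ks over", x$n_codons, "codon columns\n")
  cat(sprintf("  S = %.3f  N = %.3f  Sd = %.3f  Nd = %.3f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ks = %.4f  Ka = %.4f  Ka/Ks = %s%s\n",
              x$Ks, x$Ka,
              if (is.na(x$omega)) "undefined (Ks = 0)" else sprintf("%.4f", x$omega),
              if (x$saturated) "  [saturated: Ks > 2]" else ""))
  invisible(x)
}

# --- divergence time ---------------------------------------------------------

#' Divergence time from synonymous divergence
#'
#' Converts a synonymous distance Ks to a divergence time in million years
#' using a synonymous molecular clock: T (years) = Ks / (2 lambda), then
#' scaled to MYA. The default clock rate lambda = 6.5e-9 synonymous
#' substitutions per site per year is the standard legume rate.
#'
#' @param ks synonymous substitutions per synonymous site (>= 0).
#' @param lambda clock rate, substitutions/synonymous site/year.
#' @return numeric vector of times in million years (MYA).
#' @export
#' @examples
#' divergence_time(0.013)  # ~1 MYA
divergence_time <- function(ks, lambda = 6.5e-9) {
  if (any(ks < 0, na.rm = TRUE)) stop("ks must be non-negative")
  stopifnot(lambda > 0)
  ks / (2 * lambda) / 1e6
}

# --- batch table -------------------------------------------------------------

#' Ka/Ks and divergence-time table for a list of gene pairs
#'
#' Runs [codon_align()] + [ng86()] + [divergence_time()] for each pair and
#' applies the saturation filter: rows with Ks > `ks_max` are kept in the
#' table but flagged `discarded` and excluded from the summary statistics.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (and optionally
#'   `type`, carried through and used to group the summary).
#' @param cds named character vector or `DNAStringSet` of coding sequences.
#' @param lambda clock rate passed to [divergence_time()].
#' @param ks_max saturation cutoff; pairs with Ks above it are discarded
#'   from summaries (default 2).
#' @return data.frame (one row per pair) with S, N, Sd, Nd, Ka, Ks, omega,
#'   T_mya, `saturated`, `discarded`; a `summary` attribute holds
#'   min/max/mean of Ks, omega and T_mya over retained rows (per `type`
#'   when present).
#' @export
kaks_table <- function(pairs, cds, lambda = 6.5e-9, ks_max = 2) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  cds <- setNames(as.character(cds), names(cds))
  missing_ids <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(missing_ids)) {
    stop("no CDS for gene(s): ", paste(head(missing_ids, 5), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- tryCatch(
      ng86(codon_align(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])),
      error = function(e) {
        if (!grepl("Jukes-Cantor correction undefined", conditionMessage(e))) {
          stop(e)
        }
        # beyond-saturation pair: p >= 3/4, distance undefined; keep the
        # row but mark it saturated so the Ks filter discards it
        list(S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
             Ka = NA_real_, Ks = Inf, omega = NA_real_, saturated = TRUE)
      }
    )
    data.frame(
      gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
      S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
      Ka = r$Ka, Ks = r$Ks, omega = r$omega,
      T_mya = if (is.finite(r$Ks)) divergence_time(r$Ks, lambda) else NA_real_,
      saturated = r$saturated,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if ("type" %in% names(pairs)) out$type <- pairs$type
  out$discarded <- out$Ks > ks_max
  keep <- out[!out$discarded, , drop = FALSE]
  summarize <- function(d) {
    data.frame(
      n = nrow(d),
      ks_min = min(d$Ks), ks_max = max(d$Ks), ks_mean = mean(d$Ks),
      omega_mean = mean(d$omega, na.rm = TRUE),
      t_min_mya = min(d$T_mya), t_max_mya = max(d$T_mya),
      t_mean_mya = mean(d$T_mya)
    )
  }
  summ <- if (nrow(keep) == 0) {
    NULL
  } else if ("type" %in% names(keep)) {
    do.call(rbind, lapply(split(keep, keep$type), summarize))
  } else {
    summarize(keep)
  }
  attr(out, "summary") <- summ
  out
}
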