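# Survey orchestration: identify -> structure -> distribution ->
# duplication -> Ka/Ks -> expression (-> qPCR), with a machine-readable
# report whose tally arithmetic is internally audited.

#' Percentage shares from counts
#'
#' share = 100 * count / total, rounded half-up to `decimals` places (the
#' convention that reproduces printed survey tallies such as 69.41% for
#' 177 of 255).
#'
#' @param counts non-negative integer vector.
#' @param total positive total; every count must be <= total.
#' @param decimals decimal places (default 2).
#' @return numeric vector of shares, named like `counts`.
#' @export
#' @examples
#' report_shares(c(177, 20), 255)
report_shares <- function(counts, total, decimals = 2) {
  stopifnot(total > 0, all(counts >= 0))
  if (any(counts > total)) stop("count exceeds total")
  round_half_up(100 * counts / total, decimals)
}

#' Survey configuration
#'
#' Accepts either a YAML file path or a list. Recognized fields: input
#' paths (`gff3`, `protein_fasta`, `cds_fasta`, `panel_fasta`,
#' `tpm_tsv`, `ct_tsv`) and parameters (`lambda`, `ks_max`,
#' `min_identity`, `top_k`, `min_anchors`, `max_gap`,
#' `proximal_window`, `tandem_gap`, `terminal_fraction`, `tau`,
#' `reference_gene`, `alpha`, `name_prefix`, `total_annotated_genes`).
#' Unset parameters take the package defaults.
#'
#' @param config list or YAML path.
#' @return normalized config list.
#' @export
survey_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    lambda = 6.5e-9, ks_max = 2, min_identity = 40, top_k = 5,
    min_anchors = 5, max_gap = 25, proximal_window = 10, tandem_gap = 1,
    terminal_fraction = 0.25, tau = 0, reference_gene = "beta_tubulin",
    alpha = 0.05, name_prefix = "fam", total_annotated_genes = NULL,
    build_tree = TRUE
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

#' Run the full gene-family survey
#'
#' Stages, in dependency order: read the annotation; identify family
#' members by domain architecture (with TMD-only rescue against the
#' panel); assign subfamilies and position-based names; compute protein
#' properties, gene-structure statistics and chromosomal distribution;
#' detect homolog pairs and collinear blocks and classify duplication
#' types; compute NG86 Ka/Ks and divergence times for duplicate pairs
#' (Ks > ks_max discarded from summaries); classify tissue-expression
#' patterns (when a TPM matrix is given) and analyze a qPCR time course
#' (when a Ct table is given). The returned report's shares and sums are
#' re-audited on construction.
#'
#' @param config a [survey_config()] list or YAML path. Alternatively
#'   pass a `genome_sim` object from [simulate_genome()] (its annotation
#'   and panel are used directly).
#' @param out_dir optional directory; when given, report.json, stage TSVs
#'   and the Newick tree are written there.
#' @return an object of class `abc_survey`: list with `report` (tallies
#'   and shares), `members`, `structure`, `distribution`, `duplication`,
#'   `kaks`, `expression`, `qpcr`, `tree`, `config`.
#' @export
run_survey <- function(config, out_dir = NULL) {
  sim <- NULL
  if (inherits(config, "genome_sim")) {
    sim <- config
    config <- survey_config(list())
  } else {
    config <- survey_config(config)
  }

  stage <- "annotation"
  result <- tryCatch({
    if (!is.null(sim)) {
      ann <- sim$annotation
      panel <- sim$panel
    } else {
      ann <- read_annotation(config$gff3, config$protein_fasta,
                             config$cds_fasta)
      panel <- if (!is.null(config$panel_fasta)) {
        read_reference_panel(config$panel_fasta)
      } else {
        NULL
      }
    }
    proteins <- setNames(as.character(ann$protein), names(ann$protein))

    stage <- "identify"
    idres <- identify_members(proteins, panel)
    members <- idres$accepted
    if (length(members) == 0) stop("no family members identified")

    stage <- "subfamily"
    assign <- NULL
    tree <- NULL
    named <- data.frame(gene_id = members, stringsAsFactors = FALSE)
    if (!is.null(panel)) {
      sf <- assign_subfamily(proteins[members], panel,
                             architectures = idres$architectures,
                             tree = isTRUE(config$build_tree))
      assign <- sf$assignments
      tree <- sf$tree
      named <- name_members(assign, ann, prefix = config$name_prefix)
    }
    props <- protein_properties(proteins[members])

    stage <- "structure"
    struct <- structure_stats(ann, genes = members)
    stage <- "distribution"
    dist <- chromosome_distribution(ann, genes = members,
                                    terminal_fraction = config$terminal_fraction)

    stage <- "duplication"
    pairs <- pairwise_homology(proteins, min_identity = config$min_identity,
                               top_k = config$top_k)
    blocks <- detect_collinear_blocks(pairs, ann$genes,
                                      min_anchors = config$min_anchors,
                                      max_gap = config$max_gap)
    dup <- classify_duplicates(ann$genes, pairs, blocks,
                               proximal_window = config$proximal_window,
                               tandem_gap = config$tandem_gap,
                               subset = members)

    stage <- "kaks"
    member_pairs <- pairs[pairs$gene_a %in% members & pairs$gene_b %in% members,
                          , drop = FALSE]
    kk <- NULL
    if (nrow(member_pairs) > 0) {
      type_a <- dup$calls$type[match(member_pairs$gene_a, dup$calls$gene_id)]
      member_pairs$type <- type_a
      kk <- kaks_table(member_pairs, ann$cds, lambda = config$lambda,
                       ks_max = config$ks_max)
    }

    stage <- "expression"
    expr <- NULL
    if (!is.null(config$tpm_tsv)) {
      tpm <- load_tpm(config$tpm_tsv)
      expr <- classify_expression(tpm, tau = config$tau)
      expr$membership <- tissue_membership_counts(tpm, tau = config$tau)
    }

    stage <- "qpcr"
    qp <- NULL
    if (!is.null(config$ct_tsv)) {
      qp <- qpcr_analysis(read_ct_table(config$ct_tsv),
                          config$reference_gene, alpha = config$alpha)
    }

    stage <- "report"
    n_members <- length(members)
    subfamily_counts <- if (!is.null(assign)) {
      tab <- table(factor(assign$subfamily, levels = names(SUBFAMILY_LAYOUT)))
      setNames(as.integer(tab), names(tab))
    } else {
      NULL
    }
    report <- list(
      n_members = n_members,
      n_genes_total = nrow(ann$genes),
      subfamily_counts = subfamily_counts,
      subfamily_shares_pct = if (!is.null(subfamily_counts)) {
        report_shares(subfamily_counts, n_members, 1)
      },
      chromosome_counts = setNames(dist$per_chromosome$n_genes,
                                   dist$per_chromosome$chrom),
      chromosome_shares_pct = setNames(dist$per_chromosome$share_pct,
                                       dist$per_chromosome$chrom),
      terminal_share_pct = dist$terminal_share_pct,
      duplication_counts = dup$counts,
      duplication_shares_pct = report_shares(dup$counts, n_members, 2),
      utr_fraction_pct = struct$summary$utr_fraction_pct,
      n_without_utr = struct$summary$n_without_utr,
      exon_range = c(struct$summary$exon_min, struct$summary$exon_max),
      kaks_summary = if (!is.null(kk)) attr(kk, "summary"),
      expression_counts = if (!is.null(expr)) expr$counts,
      family_fraction_pct = if (!is.null(config$total_annotated_genes)) {
        report_shares(n_members, config$total_annotated_genes, 3)
      },
      parameters = config[c("lambda", "ks_max", "min_identity", "top_k",
                            "min_anchors", "max_gap", "proximal_window",
                            "tandem_gap", "terminal_fraction", "tau",
                            "alpha")]
    )
    audit_report(report)

    structure(
      list(
        report = report, members = named, properties = props,
        identify = idres$table, structure = struct, distribution = dist,
        duplication = dup, pairs = pairs, blocks = blocks, kaks = kk,
        expression = expr, qpcr = qp, tree = tree, config = config
      ),
      class = "abc_survey"
    )
  }, error = function(e) {
    stop("survey stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_survey(result, out_dir)
  result
}

# internal audit: every share recomputes from its counts; count groups
# sum to the member total
audit_report <- function(report) {
  n <- report$n_members
  check_shares <- function(counts, shares, decimals, total = n) {
    if (is.null(counts)) return(invisible())
    stopifnot(all(shares == report_shares(counts, total, decimals)))
  }
  check_shares(report$subfamily_counts, report$subfamily_shares_pct, 1)
  check_shares(report$duplication_counts, report$duplication_shares_pct, 2)
  check_shares(report$chromosome_counts, report$chromosome_shares_pct, 1)
  if (!is.null(report$subfamily_counts)) {
    stopifnot(sum(report$subfamily_counts) == n)
  }
  stopifnot(sum(report$duplication_counts) == n)
  stopifnot(sum(report$chromosome_counts) == n)
  invisible(report)
}

write_survey <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(x$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wt <- function(d, f) {
    if (!is.null(d) && nrow(d) > 0) {
      write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  wt(x$members, "members.tsv")
  wt(x$properties, "protein_properties.tsv")
  wt(x$structure$per_gene, "structure_stats.tsv")
  wt(x$distribution$per_chromosome, "chromosome_distribution.tsv")
  wt(x$duplication$calls, "duplicates.tsv")
  wt(x$blocks$blocks, "blocks.tsv")
  wt(x$kaks, "kaks.tsv")
  if (!is.null(x$expression)) wt(x$expression$profiles, "expression.tsv")
  if (!is.null(x$qpcr)) wt(x$qpcr, "foldchanges.tsv")
  if (!is.null(x$tree)) ape::write.tree(x$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}

#' @export
print.abc_survey <- function(x, ...) {
  r <- x$report
  cat("ABC-transporter family survey\n")
  cat("  members:", r$n_members, "of", r$n_genes_total, "genes\n")
  if (!is.null(r$subfamily_counts)) {
    cat("  subfamilies:",
        paste(sprintf("%s=%d", names(r$subfamily_counts), r$subfamily_counts),
              collapse = " "), "\n")
  }
  cat("  duplication types:",
      paste(sprintf("%s=%d", names(r$duplication_counts), r$duplication_counts),
            collapse = " "), "\n")
  if (!is.null(r$expression_counts)) {
    cat("  expression:",
        paste(sprintf("%s=%d", names(r$expression_counts), r$expression_counts),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.abc_survey <- function(object, ...) {
  print(object)
  r <- object$report
  cat("  UTR fraction:", r$utr_fraction_pct, "%\n")
  cat("  terminal-region share:", r$terminal_share_pct, "%\n")
  if (!is.null(r$kaks_summary)) {
    cat("  Ka/Ks summary (Ks <=", object$config$ks_max, "):\n")
    print(r$kaks_summary)
  }
  invisible(object)
}
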