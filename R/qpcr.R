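# Relative qPCR expression: 2^-ddCt fold changes against a reference gene
# and a same-timepoint control, replicate statistics, and compact-letter
# significance groups from one-way ANOVA + Tukey HSD.

#' Read a qPCR Ct table
#'
#' TSV with columns gene, condition (control/treatment), timepoint,
#' replicate, ct. Validates positivity of Ct and presence of >= 2
#' replicates per sample group.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ct_records(df)
  df
}

validate_ct_records <- function(records) {
  need <- c("gene", "condition", "timepoint", "replicate", "ct")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!records$condition %in% c("control", "treatment"))) {
    stop("condition must be 'control' or 'treatment'")
  }
  if (any(records$ct <= 0 | is.na(records$ct))) stop("Ct values must be positive")
  n_rep <- aggregate(replicate ~ gene + condition + timepoint, records,
                     function(x) length(unique(x)))
  if (any(n_rep$replicate < 2)) {
    bad <- n_rep[n_rep$replicate < 2, ][1, ]
    stop("fewer than 2 replicates for ", bad$gene, "/", bad$condition,
         "/t", bad$timepoint)
  }
  invisible(records)
}

#' 2^-ddCt relative expression
#'
#' Per replicate, dCt = Ct(target) - Ct(reference gene, same sample);
#' ddCt = dCt(treatment) - mean dCt(control at the same timepoint)
#' (switchable to a time-zero treatment baseline); fold = 2^-ddCt.
#' Per-replicate folds are summarized as mean and SD.
#'
#' @param records Ct data.frame (see [read_ct_table()]).
#' @param reference_gene normalizer gene present in every sample group.
#' @param baseline "matched_control" (default: control series at the same
#'   timepoint) or "time_zero" (treatment series at the earliest
#'   timepoint).
#' @return data.frame with gene, timepoint, mean_fold, sd_fold and an
#'   attribute `replicate_folds` (long data.frame gene, timepoint,
#'   replicate, fold).
#' @export
delta_delta_ct <- function(records, reference_gene,
                           baseline = c("matched_control", "time_zero")) {
  baseline <- match.arg(baseline)
  validate_ct_records(records)
  if (!reference_gene %in% records$gene) {
    stop("reference gene '", reference_gene, "' absent from the table")
  }
  ref <- records[records$gene == reference_gene, ]
  tgt <- records[records$gene != reference_gene, ]
  key <- function(d) paste(d$condition, d$timepoint, d$replicate)
  ref_ct <- setNames(ref$ct, key(ref))
  miss <- setdiff(unique(key(tgt)), names(ref_ct))
  if (length(miss)) {
    stop("missing reference-gene record for sample ", miss[1])
  }
  tgt$dct <- tgt$ct - ref_ct[key(tgt)]

  out <- list()
  folds_long <- list()
  for (g in unique(tgt$gene)) {
    dg <- tgt[tgt$gene == g, ]
    for (tp in sort(unique(dg$timepoint))) {
      treat <- dg[dg$condition == "treatment" & dg$timepoint == tp, ]
      base_dct <- if (baseline == "matched_control") {
        ctrl <- dg[dg$condition == "control" & dg$timepoint == tp, ]
        if (nrow(ctrl) == 0) stop("no control samples for ", g, " at t", tp)
        mean(ctrl$dct)
      } else {
        t0 <- dg[dg$condition == "treatment" &
                   dg$timepoint == min(dg$timepoint), ]
        mean(t0$dct)
      }
      if (nrow(treat) == 0) next
      fold <- 2^(-(treat$dct - base_dct))
      out[[length(out) + 1]] <- data.frame(
        gene = g, timepoint = tp,
        mean_fold = mean(fold), sd_fold = sd(fold),
        stringsAsFactors = FALSE
      )
      folds_long[[length(folds_long) + 1]] <- data.frame(
        gene = g, timepoint = tp, replicate = treat$replicate, fold = fold,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  attr(res, "replicate_folds") <- do.call(rbind, folds_long)
  res
}

#' Compact-letter significance groups from Tukey HSD
#'
#' One-way ANOVA across groups followed by pairwise Tukey HSD at `alpha`;
#' letters are assigned by insert-and-absorb so that two groups share at
#' least one letter exactly when they are not significantly different.
#' When every group has zero within-group variance the letters fall back
#' to exact equality of means.
#'
#' @param values named list of numeric replicate vectors (>= 2 groups,
#'   >= 2 replicates each) or a data.frame with columns `group`,
#'   `value`.
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter groups (in input group
#'   order).
#' @export
#' @examples
#' letter_groups(list(a = c(1, 1.1), b = c(1, 1.05), c = c(9, 9.1)))
letter_groups <- function(values, alpha = 0.05) {
  if (is.data.frame(values)) {
    values <- split(values$value, values$group)
  }
  stopifnot(length(values) >= 2, all(lengths(values) >= 2))
  groups <- names(values)
  k <- length(groups)
  means <- vapply(values, mean, numeric(1))
  within_var <- vapply(values, function(v) stats::var(v), numeric(1))

  # "not significantly different" matrix
  nsd <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  if (all(within_var == 0)) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      nsd[i, j] <- means[i] == means[j]
    }
  } else {
    df <- data.frame(
      value = unlist(values, use.names = FALSE),
      group = factor(rep(groups, lengths(values)), levels = groups)
    )
    tk <- TukeyHSD(aov(value ~ group, data = df),
                   conf.level = 1 - alpha)$group
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    for (r in seq_len(nrow(tk))) {
      different <- tk[r, "p adj"] < alpha
      nsd[cmp[r, 1], cmp[r, 2]] <- !different
      nsd[cmp[r, 2], cmp[r, 1]] <- !different
    }
  }
  insert_absorb(nsd)
}

# insert-and-absorb compact letter display over a symmetric
# "not significantly different" indicator matrix
insert_absorb <- function(nsd) {
  groups <- rownames(nsd)
  k <- length(groups)
  # letter classes as sets of groups; start with one class of all groups
  classes <- list(seq_len(k))
  # insert: for each significantly different pair found inside a class,
  # split the class into two, each dropping one member of the pair
  repeat {
    split_done <- FALSE
    for (ci in seq_along(classes)) {
      cl <- classes[[ci]]
      viol <- NULL
      for (a in cl) for (b in cl) {
        if (b > a && !nsd[a, b]) {
          viol <- c(a, b)
          break
        }
      }
      if (!is.null(viol)) {
        classes[[ci]] <- setdiff(cl, viol[1])
        classes[[length(classes) + 1]] <- setdiff(cl, viol[2])
        split_done <- TRUE
        break
      }
    }
    if (!split_done) break
  }
  # absorb: drop classes contained in another
  keep <- rep(TRUE, length(classes))
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      if (i != j && keep[j] &&
          all(classes[[i]] %in% classes[[j]]) &&
          (length(classes[[i]]) < length(classes[[j]]) || i > j)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  classes <- unique(classes[keep])
  # deterministic letter order: classes sorted by their smallest member
  classes <- classes[order(vapply(classes, min, numeric(1)))]
  letters_out <- rep("", k)
  for (ci in seq_along(classes)) {
    for (g in classes[[ci]]) {
      letters_out[g] <- paste0(letters_out[g], letters[ci])
    }
  }
  setNames(letters_out, groups)
}

#' Full qPCR stress-course analysis
#'
#' Computes 2^-ddCt fold changes per gene and timepoint, then assigns
#' compact significance letters across timepoints within each gene
#' (replicate folds, one-way ANOVA + Tukey HSD) and a Welch t-test
#' p-value of treatment vs control dCt per timepoint (both comparisons
#' are reported because bar-plot letters can refer to either).
#'
#' @param records Ct data.frame.
#' @param reference_gene normalizer gene.
#' @param alpha significance level for the letters.
#' @param baseline passed to [delta_delta_ct()].
#' @return data.frame gene, timepoint, mean_fold, sd_fold, letter,
#'   p_vs_control.
#' @export
qpcr_analysis <- function(records, reference_gene, alpha = 0.05,
                          baseline = "matched_control") {
  res <- delta_delta_ct(records, reference_gene, baseline)
  folds <- attr(res, "replicate_folds")
  res$letter <- NA_character_
  for (g in unique(res$gene)) {
    fg <- folds[folds$gene == g, ]
    by_tp <- split(fg$fold, fg$timepoint)
    if (length(by_tp) >= 2 && all(lengths(by_tp) >= 2)) {
      lt <- letter_groups(by_tp, alpha)
      sel <- res$gene == g
      res$letter[sel] <- lt[as.character(res$timepoint[sel])]
    }
  }
  # treatment vs control per timepoint (Welch t on dCt)
  ref <- records[records$gene == reference_gene, ]
  tgt <- records[records$gene != reference_gene, ]
  key <- function(d) paste(d$condition, d$timepoint, d$replicate)
  ref_ct <- setNames(ref$ct, key(ref))
  tgt$dct <- tgt$ct - ref_ct[key(tgt)]
  res$p_vs_control <- NA_real_
  for (r in seq_len(nrow(res))) {
    dg <- tgt[tgt$gene == res$gene[r] & tgt$timepoint == res$timepoint[r], ]
    a <- dg$dct[dg$condition == "treatment"]
    b <- dg$dct[dg$condition == "control"]
    if (length(a) >= 2 && length(b) >= 2 && (sd(a) > 0 || sd(b) > 0)) {
      res$p_vs_control[r] <- stats::t.test(a, b)$p.value
    }
  }
  res
}
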