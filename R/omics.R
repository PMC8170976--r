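# Omics module: nCounter-style miRNA workflow (housekeeping normalization,
# expression filter, differential expression, volcano table) and proteomics
# downstream analysis (overlap counts, proportions, counter-regulation pairs).

#' Construct a count matrix with group labels
#'
#' @param counts non-negative feature x sample matrix with dimnames.
#' @param groups character vector (one per sample) of `"WT"`/`"case"` labels,
#'   each group with >= 2 samples.
#' @param housekeeping ids of the stable reference features (must be rows of
#'   `counts` for miRNA-count matrices).
#' @param kind `"miRNA_counts"` or `"protein_intensity"`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups,
                         housekeeping = character(0),
                         kind = c("miRNA_counts", "protein_intensity")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            length(groups) == ncol(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(table(groups) < 2) || length(unique(groups)) != 2) {
    stop("need exactly two groups with >= 2 samples each")
  }
  if (kind == "miRNA_counts" && length(housekeeping) &&
      !all(housekeeping %in% rownames(counts))) {
    stop("housekeeping features missing from the matrix")
  }
  structure(list(counts = counts, groups = groups,
                 housekeeping = housekeeping, kind = kind),
            class = "count_matrix")
}

#' Housekeeping normalization of a count matrix
#'
#' Scales each sample so that the geometric mean (default; arithmetic behind a
#' flag) of its housekeeping features equals the across-sample average of those
#' per-sample means. Applying the normalizer twice is a no-op, and a sample
#' whose counts were globally rescaled is restored exactly.
#'
#' @param cm a [count_matrix()] with housekeeping features.
#' @param method `"geometric"` (platform standard) or `"arithmetic"`.
#' @return the normalized [count_matrix()], with attribute `scale_factors`
#'   (the per-sample divisors).
#' @export
normalize_counts <- function(cm, method = c("geometric", "arithmetic")) {
  stopifnot(inherits(cm, "count_matrix"))
  method <- match.arg(method)
  if (!length(cm$housekeeping)) stop("no housekeeping features defined")
  hk <- cm$counts[cm$housekeeping, , drop = FALSE]
  zero <- which(hk <= 0, arr.ind = TRUE)
  if (nrow(zero)) {
    stop(sprintf("housekeeping feature '%s' has a non-positive count in sample '%s'",
                 rownames(hk)[zero[1, 1]], colnames(hk)[zero[1, 2]]))
  }
  per_sample <- apply(hk, 2, if (method == "geometric") geometric_mean else mean)
  sf <- per_sample / mean(per_sample)
  out <- sweep(cm$counts, 2, sf, "/")
  res <- count_matrix(out, cm$groups, cm$housekeeping, cm$kind)
  attr(res, "scale_factors") <- sf
  res
}

#' Expression filter
#'
#' Flags a feature as robustly expressed iff its mean normalized count across
#' all samples is at least `min_count` (boundary inclusive).
#'
#' @param cm a (normalized) [count_matrix()].
#' @param min_count minimum mean count (default 100).
#' @return named logical vector, one flag per feature.
#' @export
expression_filter <- function(cm, min_count = 100) {
  stopifnot(inherits(cm, "count_matrix"))
  rowMeans(cm$counts) >= min_count
}

#' Differential expression between case and control
#'
#' For every robustly expressed feature, a two-sided equal-variance Student's
#' t-test on `log2(normalized count + 1)`; fold changes on the linear scale
#' (case/WT). Significance for the volcano-matching flag uses the unadjusted
#' p-value at `alpha`; a Benjamini-Hochberg FDR column is reported alongside
#' but not used for that flag. Features with zero within-group variance in
#' both groups and unequal means get a missing p-value and are flagged.
#'
#' @param cm a normalized [count_matrix()].
#' @param alpha unadjusted significance threshold (default 0.05).
#' @param min_count expression-filter threshold passed to
#'   [expression_filter()].
#' @return data.frame of class `de_table`: feature, mean_WT, mean_case,
#'   fold_change, log2fc, p_value, padj_bh, expressed, significant, direction,
#'   flag_zero_var.
#' @export
differential_expression <- function(cm, alpha = 0.05, min_count = 100) {
  stopifnot(inherits(cm, "count_matrix"))
  is_wt <- cm$groups == "WT"
  if (sum(is_wt) < 2 || sum(!is_wt) < 2) stop("need >= 2 samples per group")
  expressed <- expression_filter(cm, min_count)
  x <- cm$counts
  lg <- log2(x + 1)
  res <- data.frame(
    feature = rownames(x),
    mean_WT = rowMeans(x[, is_wt, drop = FALSE]),
    mean_case = rowMeans(x[, !is_wt, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  res$fold_change <- (res$mean_case + 1e-12) / (res$mean_WT + 1e-12)
  res$log2fc <- log2(res$fold_change)
  res$p_value <- NA_real_
  res$flag_zero_var <- FALSE
  for (j in which(expressed)) {
    a <- lg[j, !is_wt]; b <- lg[j, is_wt]   # case vs WT
    tol <- 1e-9 * max(1, abs(mean(a)), abs(mean(b)))
    if (stats::sd(a) < tol && stats::sd(b) < tol) {
      if (abs(mean(a) - mean(b)) < tol) {
        res$p_value[j] <- 1
      } else {
        res$flag_zero_var[j] <- TRUE        # p undefined, reported missing
      }
    } else {
      res$p_value[j] <- stats::t.test(a, b, var.equal = TRUE)$p.value
    }
  }
  res$padj_bh <- NA_real_
  res$padj_bh[expressed] <- stats::p.adjust(res$p_value[expressed],
                                            method = "BH")
  res$expressed <- expressed
  res$significant <- expressed & !is.na(res$p_value) & res$p_value <= alpha
  res$direction <- ifelse(res$log2fc > 0, "up", "down")
  attr(res, "alpha") <- alpha
  attr(res, "min_count") <- min_count
  attr(res, "filter_rule") <- "mean normalized count across all samples >= min_count"
  class(res) <- c("de_table", "data.frame")
  res
}

#' Overlap partition of two significant-feature sets
#'
#' @param sig_a,sig_b character vectors of feature ids.
#' @return named integer vector `c(a_only, b_only, both)` (order-independent
#'   exact partition counts).
#' @export
set_overlap <- function(sig_a, sig_b) {
  sig_a <- unique(sig_a); sig_b <- unique(sig_b)
  both <- length(intersect(sig_a, sig_b))
  c(a_only = length(sig_a) - both, b_only = length(sig_b) - both, both = both)
}

#' Percentage of significant features, integer-rounded
#'
#' @param n_sig number of significant features (0 <= n_sig <= n_total).
#' @param n_total total features tested (> 0).
#' @return `round(100 * n_sig / n_total)` as an integer percent.
#' @export
proportion_significant <- function(n_sig, n_total) {
  check_scalar(n_total, "n_total", lower = 1)
  check_scalar(n_sig, "n_sig", lower = 0, upper = n_total)
  round(100 * n_sig / n_total)
}

#' Counter-regulation miRNA/protein pairs
#'
#' Pairs every significantly up-regulated miRNA with every significantly
#' down-regulated protein it is annotated to target in the supplied map
#' (counter-rotated expression). Target prediction itself is out of scope: the
#' map is user-supplied.
#'
#' @param mirna_de,protein_de `de_table`s from [differential_expression()] (or
#'   any data.frame with feature, significant, direction columns).
#' @param target_map data.frame with columns `mirna` and `protein`.
#' @return list of class `pairing_result`: `pairs` (data.frame mirna, protein),
#'   `n_interactions`, `n_mirnas`, `n_proteins`.
#' @export
counter_regulation_pairs <- function(mirna_de, protein_de, target_map) {
  stopifnot(all(c("mirna", "protein") %in% names(target_map)))
  if (!nrow(target_map)) {
    warning("empty target map: no pairs can be formed")
    pairs <- data.frame(mirna = character(0), protein = character(0))
  } else {
    up <- mirna_de$feature[mirna_de$significant & mirna_de$direction == "up"]
    down <- protein_de$feature[protein_de$significant &
                                 protein_de$direction == "down"]
    keep <- target_map$mirna %in% up & target_map$protein %in% down
    pairs <- unique(target_map[keep, c("mirna", "protein")])
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs,
                 n_interactions = nrow(pairs),
                 n_mirnas = length(unique(pairs$mirna)),
                 n_proteins = length(unique(pairs$protein))),
            class = "pairing_result")
}

#' Volcano table (and optional plot)
#'
#' Plot-ready coordinates for a differential-expression table: `log2fc` on x,
#' `-log10(p)` on y, with the significance flag. Features with missing
#' p-values are omitted (and counted in attribute `n_omitted`). When `path` is
#' given, a PNG is written with a horizontal guide line at `p = alpha`.
#'
#' @param de a `de_table`.
#' @param alpha guide-line p-value (defaults to the DE table's alpha).
#' @param path optional PNG output path.
#' @return data.frame: feature, log2fc, neglog10_p, significant.
#' @export
volcano_table <- function(de, alpha = NULL, path = NULL) {
  stopifnot(inherits(de, "data.frame"))
  if (is.null(alpha)) alpha <- attr(de, "alpha") %||% 0.05
  keep <- de$expressed & !is.na(de$p_value)
  tab <- data.frame(feature = de$feature[keep],
                    log2fc = de$log2fc[keep],
                    neglog10_p = -log10(de$p_value[keep]),
                    significant = de$significant[keep],
                    stringsAsFactors = FALSE)
  attr(tab, "n_omitted") <- sum(de$expressed & is.na(de$p_value))
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(tab$log2fc, tab$neglog10_p,
         col = ifelse(tab$significant, "purple", "black"), pch = 19,
         xlab = expression(log[2] ~ "fold change (case/WT)"),
         ylab = expression(-log[10] ~ italic(p)),
         main = "Differential expression")
    graphics::abline(h = -log10(alpha), lty = 2)
  }
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read count matrices, group maps and target maps as TSV
#'
#' Count matrices are written features-in-rows with a header row of sample
#' ids; the group map is a separate two-column TSV (sample, group); target
#' maps are two-column TSVs (mirna, protein).
#'
#' @param cm a [count_matrix()].
#' @param path TSV path for the matrix; the group map goes to
#'   `<path>.groups.tsv`.
#' @return `path` invisibly (write) or the parsed object (read).
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(feature = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(cm$counts), group = cm$groups),
    paste0(path, ".groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @param housekeeping,kind passed to [count_matrix()] on read.
#' @export
read_count_matrix <- function(path, housekeeping = character(0),
                              kind = "miRNA_counts") {
  df <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  gr <- utils::read.delim(paste0(path, ".groups.tsv"))
  count_matrix(counts, groups = gr$group[match(colnames(counts), gr$sample)],
               housekeeping = housekeeping, kind = kind)
}

#' @rdname write_count_matrix
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path)
  names(df)[1:2] <- c("mirna", "protein")
  df
}
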