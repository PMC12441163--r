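#' Counts-per-million normalization
#'
#' Scales each sample to counts per million of its library size. A
#' pseudocount is *not* added here; downstream log transforms and ratios add
#' their own (see [fold_change()] and [test_deg()]).
#'
#' @param counts Non-negative matrix, genes x samples.
#' @param lib_size Library size per sample; defaults to column sums.
#' @return CPM matrix of the same shape.
#' @export
cpm_normalize <- function(counts, lib_size = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (any(lib_size <= 0)) stop("zero or negative library size")
  sweep(counts, 2, lib_size, "/") * 1e6
}

#' Per-gene fold change between two lines
#'
#' Ratio of pseudocounted mean normalized expression, `line_a` over
#' `line_b`.
#'
#' @param normalized CPM matrix (see [cpm_normalize()]).
#' @param design Line label per sample (column).
#' @param line_a,line_b Lines to compare (numerator / denominator).
#' @param pseudocount Added to each mean on the CPM scale.
#' @return Named numeric vector of per-gene ratios.
#' @export
fold_change <- function(normalized, design, line_a, line_b, pseudocount = 1) {
  design <- as.character(design)
  for (l in c(line_a, line_b))
    if (!l %in% design) stop("line label not present in design: ", l)
  ma <- rowMeans(normalized[, design == line_a, drop = FALSE])
  mb <- rowMeans(normalized[, design == line_b, drop = FALSE])
  (ma + pseudocount) / (mb + pseudocount)
}

# vectorized per-gene one-way ANOVA on the rows of a matrix
.row_anova_p <- function(logm, design) {
  design <- factor(design)
  k <- nlevels(design); n <- ncol(logm)
  gm <- rowMeans(logm)
  ssb <- 0; ssw <- 0
  for (lv in levels(design)) {
    xl <- logm[, design == lv, drop = FALSE]
    ml <- rowMeans(xl)
    ssb <- ssb + ncol(xl) * (ml - gm)^2
    ssw <- ssw + rowSums((xl - ml)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0] <- ifelse(ssb[ssw == 0] == 0, NA_real_, 0)
  p
}

#' Differential expression between lines
#'
#' Tests each gene on log2 pseudocounted CPM across lines and applies
#' Benjamini-Hochberg FDR control. The default `"moderated"` method fits the
#' limma linear model with empirical-Bayes variance moderation — the
#' standard choice at the 2-3 replicates typical of these designs, where
#' per-gene variance estimates alone are too unstable to reach
#' genome-wide significance. `"anova"` is the plain per-gene one-way ANOVA
#' (with two lines, exactly the pooled two-sample t test). A gene is flagged
#' significant when its q-value is below `alpha` *and* its fold change
#' passes `fold_threshold`. Genes constant across all samples are not
#' testable and are reported with `p = NA`, `q = 1`, not significant.
#'
#' @param normalized CPM matrix.
#' @param design Line label per sample; >= 2 replicates per line.
#' @param line_a,line_b Lines whose ratio defines the reported fold change;
#'   default: first and second line in order of appearance (mutant over
#'   control when the design lists the mutant first).
#' @param alpha FDR threshold.
#' @param fold_threshold Minimum fold change (on either side of 1).
#' @param method `"moderated"` (limma) or `"anova"`.
#' @param pseudocount Added on the CPM scale before logs and ratios.
#' @return data.frame `gene`, `fold_change`, `log2_fold`, `p_value`,
#'   `q_value`, `significant`, `tested`.
#' @export
test_deg <- function(normalized, design, line_a = NULL, line_b = NULL,
                     alpha = 0.05, fold_threshold = 2,
                     method = c("moderated", "anova"), pseudocount = 1) {
  method <- match.arg(method)
  design <- as.character(design)
  tb <- table(design)
  if (length(tb) < 2L) stop("need at least two lines")
  if (any(tb < 2L)) stop("each line needs >= 2 replicates")
  lines_seen <- unique(design)
  if (is.null(line_a)) line_a <- lines_seen[1]
  if (is.null(line_b)) line_b <- lines_seen[2]
  logm <- log2(normalized + pseudocount)
  v <- rowSums((logm - rowMeans(logm))^2)
  constant <- v < 1e-12
  p <- rep(NA_real_, nrow(logm))
  if (any(!constant)) {
    sub <- logm[!constant, , drop = FALSE]
    if (method == "moderated") {
      mm <- stats::model.matrix(~ factor(design, levels = lines_seen))
      # trend=TRUE fits the log-CPM mean-variance trend (limma-trend);
      # a constant prior variance over-calls low-count genes
      fit <- limma::eBayes(limma::lmFit(sub, mm), trend = TRUE)
      p[!constant] <- if (length(lines_seen) == 2L) fit$p.value[, 2]
      else fit$F.p.value
    } else {
      p[!constant] <- .row_anova_p(sub, design)
    }
  }
  q <- rep(1, length(p))
  q[!constant] <- stats::p.adjust(p[!constant], method = "BH")
  fc <- fold_change(normalized, design, line_a, line_b, pseudocount)
  sig <- !constant & !is.na(q) & q < alpha &
    abs(log2(fc)) >= log2(fold_threshold)
  data.frame(gene = rownames(normalized) %||% seq_len(nrow(normalized)),
             fold_change = unname(fc), log2_fold = unname(log2(fc)),
             p_value = p, q_value = q,
             significant = sig, tested = !constant)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize significant genes per pathway
#'
#' @param results Output of [test_deg()].
#' @param pathway_map data.frame `gene`, `pathway` (genes may be absent from
#'   the map; mapped pathways cover a subset of genes).
#' @return data.frame `pathway`, `n_up`, `n_down`, `median_fold` over the
#'   pathway's tested genes.
#' @export
summarize_pathway <- function(results, pathway_map) {
  if (nrow(pathway_map) == 0L)
    return(data.frame(pathway = character(0), n_up = integer(0),
                      n_down = integer(0), median_fold = numeric(0)))
  m <- merge(results, pathway_map, by = "gene")
  out <- do.call(rbind, lapply(split(m, m$pathway), function(d) {
    data.frame(pathway = d$pathway[1],
               n_up = sum(d$significant & d$fold_change > 1),
               n_down = sum(d$significant & d$fold_change < 1),
               median_fold = stats::median(d$fold_change))
  }))
  rownames(out) <- NULL
  out[order(out$pathway), , drop = FALSE]
}
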