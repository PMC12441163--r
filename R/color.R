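#' CIE76 color difference
#'
#' Euclidean distance between two CIELab triples:
#' `sqrt((L2-L1)^2 + (a2-a1)^2 + (b2-b1)^2)`. Differences below about 1 are
#' imperceptible to the human eye; values above ~5 read as clearly different
#' colors.
#'
#' @param c1,c2 Numeric (L, a, b) triples.
#' @return Non-negative scalar.
#' @examples
#' delta_e(c(96.49, 0.64, 10.25), c(67.75, 11.58, 30.33))  # parental lines
#' @export
delta_e <- function(c1, c2) {
  c1 <- as.numeric(c1); c2 <- as.numeric(c2)
  if (length(c1) != 3L || length(c2) != 3L)
    stop("delta_e expects two (L, a, b) triples")
  if (any(!is.finite(c(c1, c2))))
    stop("delta_e inputs must be finite")
  sqrt(sum((c2 - c1)^2))
}

# row-wise Delta-E of a matrix of (L, a, b) rows against one reference
.delta_e_rows <- function(m, ref) {
  sqrt((m[, 1] - ref[1])^2 + (m[, 2] - ref[2])^2 + (m[, 3] - ref[3])^2)
}

#' Average technical replicates channel-wise
#'
#' @param ph data.frame with columns `id`, `L`, `a`, `b` (one row per
#'   replicate).
#' @return data.frame with one averaged (L, a, b) row per `id`.
#' @export
average_replicates <- function(ph) {
  stopifnot(is.data.frame(ph), all(c("id", "L", "a", "b") %in% names(ph)))
  if (nrow(ph) == 0L) stop("no measurements to average")
  out <- stats::aggregate(ph[c("L", "a", "b")], list(id = ph$id), mean)
  out[order(out$id), , drop = FALSE]
}

#' Classify fiber colors against parental references
#'
#' A sample is brown when its Delta-E to the brown reference is smaller than
#' its Delta-E to the white reference by more than `cream_band`, white in the
#' mirrored case, and cream otherwise. Deterministic and order-invariant.
#'
#' @param colors data.frame with columns `id`, `L`, `a`, `b` (replicate
#'   averages).
#' @param brown_ref,white_ref (L, a, b) reference triples.
#' @param cream_band Half-width of the intermediate band, in Delta-E units.
#' @return `colors` with added columns `de_brown`, `de_white`, `group`
#'   (factor brown/cream/white).
#' @export
classify_colors <- function(colors, brown_ref, white_ref, cream_band = 5) {
  stopifnot(all(c("id", "L", "a", "b") %in% names(colors)), cream_band >= 0)
  if (delta_e(brown_ref, white_ref) <= 2 * cream_band)
    stop("reference colors closer than twice the cream band")
  m <- as.matrix(colors[c("L", "a", "b")])
  db <- .delta_e_rows(m, as.numeric(brown_ref))
  dw <- .delta_e_rows(m, as.numeric(white_ref))
  grp <- ifelse(db < dw - cream_band, "brown",
                ifelse(dw < db - cream_band, "white", "cream"))
  out <- colors
  out$de_brown <- db
  out$de_white <- dw
  out$group <- factor(grp, levels = c("brown", "cream", "white"))
  out
}

#' Multi-group trait comparison (one-way ANOVA + Tukey HSD)
#'
#' The generic comparison used for both color channels and flame-retardancy
#' traits: overall one-way ANOVA F test plus all pairwise contrasts adjusted
#' with Tukey's honest significant difference (Tukey-Kramer for unbalanced
#' groups).
#'
#' @param values Numeric trait values.
#' @param groups Group labels, same length.
#' @param trait Trait name carried into the result.
#' @return Object of class `group_comparison` with elements `trait`, `means`,
#'   `f`, `p_value` and a `pairwise` data.frame.
#' @export
compare_groups <- function(values, groups, trait = "trait") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("need >= 2 values per group")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  structure(list(trait = trait,
                 means = tapply(values, groups, mean),
                 f = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 pairwise = data.frame(pair = rownames(tk),
                                       diff = tk[, "diff"],
                                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                                       p_adj = tk[, "p adj"],
                                       row.names = NULL)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA on '%s': F = %.3f, p = %.3g\n",
              x$trait, x$f, x$p_value))
  cat("Group means:\n")
  print(round(x$means, 3))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}
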