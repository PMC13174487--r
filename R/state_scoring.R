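## Per-cell signature scoring (bin-matched control genes), the continuous
## stem-to-exhausted transition score, and discrete state assignment.

#' Construct a gene signature
#'
#' @param name Signature label.
#' @param genes Character vector of gene symbols.
#' @param direction Per-gene sign (+1/-1), recycled; default all +1.
#' @return A `gene_signature` list.
#' @export
gene_signature <- function(name, genes, direction = 1) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("signature must be non-empty", call. = FALSE)
  direction <- rep_len(direction, length(genes))
  if (!all(direction %in% c(-1, 1))) {
    stop("direction must be +1 or -1 per gene", call. = FALSE)
  }
  structure(list(name = name, genes = genes, direction = direction),
            class = "gene_signature")
}

#' Score a gene signature against expression-bin-matched controls
#'
#' For each signature gene, `n_ctrl` control genes are drawn (without
#' replacement, fixed seed) from the same average-expression bin; the cell's
#' score is the mean over signature genes of the gene's expression minus the
#' mean expression of its control genes. Adding a constant to every gene of
#' every cell therefore leaves scores unchanged. Expression should already
#' be normalized (see [lognorm()]).
#'
#' @param expr Normalized expression matrix, genes x cells.
#' @param sig A [gene_signature()] (or character vector of genes).
#' @param n_bins Number of equal-count average-expression bins (>= 2 unless
#'   1 is given explicitly for a single shared pool).
#' @param n_ctrl Control genes drawn per signature gene; capped at bin size.
#' @param seed RNG seed for the control draw.
#' @return Named numeric vector of per-cell scores. Attribute
#'   `genes_used` records the signature genes found in the matrix.
#' @export
score_signature <- function(expr, sig, n_bins = 25, n_ctrl = 50, seed = 1L) {
  if (is.character(sig)) sig <- gene_signature("signature", sig)
  expr <- as_dense(expr)
  present <- sig$genes %in% rownames(expr)
  if (!any(present)) {
    stop("no signature genes present in matrix; missing: ",
         paste(sig$genes, collapse = ", "), call. = FALSE)
  }
  genes <- sig$genes[present]
  dirs <- sig$direction[present]
  avg <- rowMeans(expr)
  n_bins_eff <- max(1L, min(n_bins, nrow(expr)))
  bin <- ceiling(rank(avg, ties.method = "first") / (nrow(expr) / n_bins_eff))
  all_genes <- rownames(expr)
  scores <- numeric(ncol(expr))
  with_seed(seed, {
    for (i in seq_along(genes)) {
      g <- genes[i]
      cand <- all_genes[bin == bin[match(g, all_genes)]]
      cand <- setdiff(cand, sig$genes)
      if (!length(cand)) cand <- setdiff(all_genes, sig$genes)
      if (!length(cand)) {
        stop("no control genes available outside the signature", call. = FALSE)
      }
      ctrl <- if (length(cand) <= n_ctrl) cand else sample(cand, n_ctrl)
      ctrl_mean <- if (length(ctrl) == 1L) expr[ctrl, ] else colMeans(expr[ctrl, , drop = FALSE])
      scores <- scores + dirs[i] * (expr[g, ] - ctrl_mean)
    }
  })
  scores <- scores / length(genes)
  names(scores) <- colnames(expr)
  attr(scores, "genes_used") <- genes
  scores
}

#' Library-size log-normalize a count matrix
#'
#' Counts per cell are scaled to `scale` (default 1e4) and log1p-transformed
#' — the normalization all signature scores are computed on.
#'
#' @param counts Raw counts, genes x cells.
#' @param scale Target library size.
#' @return Dense normalized matrix.
#' @export
lognorm <- function(counts, scale = 1e4) lognorm_counts(counts, scale)

#' Stem-to-exhausted transition score
#'
#' The raw statistic is `exhausted - stem` per cell; the transition score is
#' its mid-rank empirical-CDF position among the scored cells, `(r - 0.5)/n`
#' with mid-ranks for ties, so the scored population is uniform on \[0, 1\]
#' by construction and the score is monotone in the raw statistic.
#'
#' @param stem_scores,exh_scores Aligned per-cell score vectors (length >= 2).
#' @return Numeric vector of transition scores in (0, 1).
#' @export
transition_score <- function(stem_scores, exh_scores) {
  if (length(stem_scores) != length(exh_scores)) {
    stop("stem and exhausted score vectors must be aligned", call. = FALSE)
  }
  n <- length(stem_scores)
  if (n < 2) stop("need at least 2 cells for a transition score", call. = FALSE)
  raw <- exh_scores - stem_scores
  out <- (rank(raw, ties.method = "average") - 0.5) / n
  names(out) <- names(stem_scores)
  out
}

#' Assign discrete states by margin-argmax over signature scores
#'
#' The label is the top-scoring signature provided it beats the runner-up by
#' at least `margin` (and strictly, so exact ties give `"other"`).
#'
#' @param scores Cells x signatures numeric matrix (colnames = signature
#'   names).
#' @param margin Required winning margin; default 0 ("other" only on ties).
#' @param label_map Optional named vector mapping signature names to state
#'   labels (e.g. `c(stem = "stem-like", cytotoxic = "effector")`).
#' @return Character vector of state labels, one per row.
#' @export
assign_states <- function(scores, margin = 0, label_map = NULL) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) stop("scores need signature colnames", call. = FALSE)
  lab <- apply(scores, 1, function(s) {
    o <- order(s, decreasing = TRUE)
    gap <- s[o[1]] - if (length(s) > 1) s[o[2]] else -Inf
    if (gap > 0 && gap >= margin) colnames(scores)[o[1]] else "other"
  })
  if (!is.null(label_map)) {
    mapped <- label_map[lab]
    lab <- ifelse(is.na(mapped), lab, mapped)
  }
  unname(lab)
}

#' Score a full CD8 state table
#'
#' Convenience wrapper: log-normalizes counts, scores each signature,
#' derives the transition score from the `stem` and `exhausted` signatures
#' and assigns discrete labels.
#'
#' @param counts Raw counts, genes x cells.
#' @param signatures Named list of gene vectors (needs `stem` and
#'   `exhausted`); default [cd8_signatures()].
#' @param margin,label_map Passed to [assign_states()].
#' @param n_bins,n_ctrl,seed Passed to [score_signature()].
#' @return StateScores data.frame: `cell_id`, one score column per
#'   signature, `transition`, `state_label`.
#' @export
score_state_table <- function(counts, signatures = cd8_signatures(),
                              margin = 0, label_map = NULL,
                              n_bins = 25, n_ctrl = 50, seed = 1L) {
  stopifnot(all(c("stem", "exhausted") %in% names(signatures)))
  expr <- lognorm(counts)
  sc <- vapply(names(signatures), function(nm) {
    as.numeric(score_signature(expr, gene_signature(nm, signatures[[nm]]),
                               n_bins = n_bins, n_ctrl = n_ctrl, seed = seed))
  }, numeric(ncol(expr)))
  rownames(sc) <- colnames(expr)
  out <- data.frame(cell_id = colnames(expr), sc, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$transition <- as.numeric(transition_score(sc[, "stem"], sc[, "exhausted"]))
  out$state_label <- assign_states(sc, margin = margin, label_map = label_map)
  rownames(out) <- NULL
  out
}
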