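## Clonotype construction from paired-chain TCR strings and clone-level
## expansion / stem-content statistics.

#' Build a clonotype table from paired-chain TCR assignments
#'
#' Clone identity is exact string match of the paired-chain key. Cells
#' without a TCR string are excluded and counted. Clones of size >= 3 are
#' flagged expanding.
#'
#' @param assignments data.frame with `cell_id` and `clonotype_id` (AIRR-
#'   flavored `junction_aa` pair strings are fine; any non-empty string
#'   works).
#' @param states Optional StateScores data.frame (`cell_id`,
#'   `state_label`) or named character vector of labels; joins per-state
#'   counts onto clones.
#' @return data.frame: `clonotype_id`, `size`, `expanding`,
#'   `stem_multiplicity`, plus one `n_<state>` column per observed state.
#'   Attribute `n_without_tcr` counts excluded cells.
#' @export
build_clonotypes <- function(assignments, states = NULL) {
  stopifnot(all(c("cell_id", "clonotype_id") %in% names(assignments)))
  if (anyDuplicated(assignments$cell_id)) {
    stop("duplicate cell_id in clonotype assignments", call. = FALSE)
  }
  has_tcr <- !is.na(assignments$clonotype_id) &
    nzchar(assignments$clonotype_id)
  n_excl <- sum(!has_tcr)
  asg <- assignments[has_tcr, , drop = FALSE]
  lab <- NULL
  if (!is.null(states)) {
    if (is.data.frame(states)) {
      lab <- stats::setNames(states$state_label, states$cell_id)
    } else {
      lab <- states
    }
  }
  ids <- sort(unique(asg$clonotype_id))
  split_cells <- split(asg$cell_id, asg$clonotype_id)[ids]
  sizes <- lengths(split_cells)
  out <- data.frame(clonotype_id = ids, size = as.integer(sizes),
                    expanding = sizes >= 3L, stringsAsFactors = FALSE)
  if (!is.null(lab)) {
    state_levels <- sort(unique(stats::na.omit(lab)))
    counts <- t(vapply(split_cells, function(cells) {
      vapply(state_levels, function(s) sum(lab[cells] == s, na.rm = TRUE),
             numeric(1))
    }, numeric(length(state_levels))))
    if (length(state_levels) == 1L) counts <- matrix(counts, ncol = 1L)
    colnames(counts) <- paste0("n_", gsub("[^A-Za-z0-9]", "_", state_levels))
    out <- cbind(out, as.data.frame(counts))
    out$stem_multiplicity <- if ("n_stem_like" %in% colnames(out)) {
      out$n_stem_like
    } else {
      rep(0L, nrow(out))
    }
  } else {
    out$stem_multiplicity <- NA_integer_
  }
  rownames(out) <- NULL
  attr(out, "n_without_tcr") <- n_excl
  attr(out, "members") <- split_cells
  out
}

#' Fraction of expanding clones containing multiple stem-like cells
#'
#' Numerator: expanding clones (size >= 3) with at least `min_stem`
#' stem-like members; denominator: all expanding clones. Also summarizes
#' the largest stem-like multiplicity seen in any clone. With zero
#' expanding clones the fraction is not computable and is returned as such
#' with a reason.
#'
#' @param clonotypes Result of [build_clonotypes()] (needs
#'   `stem_multiplicity`).
#' @param min_stem "Multiple" threshold, default 2.
#' @return List: `computable`, `fraction`, `n_expanding`,
#'   `n_multi_stem`, `max_stem_multiplicity`, `reason` (when not
#'   computable).
#' @export
stem_content_statistic <- function(clonotypes, min_stem = 2L) {
  if (!nrow(clonotypes)) stop("empty clonotype table", call. = FALSE)
  if (all(is.na(clonotypes$stem_multiplicity))) {
    stop("clonotype table has no state information", call. = FALSE)
  }
  exp_cl <- clonotypes[clonotypes$expanding, , drop = FALSE]
  if (!nrow(exp_cl)) {
    return(list(computable = FALSE, fraction = NA_real_, n_expanding = 0L,
                n_multi_stem = 0L,
                max_stem_multiplicity = max(clonotypes$stem_multiplicity),
                reason = "no expanding clones (size >= 3)"))
  }
  hit <- exp_cl$stem_multiplicity >= min_stem
  list(computable = TRUE, fraction = mean(hit), n_expanding = nrow(exp_cl),
       n_multi_stem = sum(hit),
       max_stem_multiplicity = max(clonotypes$stem_multiplicity))
}

#' Association between clone-level gene expression and stem content
#'
#' Kendall rank correlation between per-clone mean expression of a gene
#' (default CXCL13) and the clone's stem-like fraction. On exhaustion-
#' skewed repertoires the expected association is negative.
#'
#' @param clonotypes Result of [build_clonotypes()] (carries member lists).
#' @param expr Expression matrix, genes x cells, colnames = cell ids.
#' @param gene Gene symbol (default `"CXCL13"`).
#' @param min_clones Minimum clones required (default 5).
#' @return List: `computable`, `tau`, `p_value`, `per_clone` data.frame
#'   (clonotype_id, mean_expr, stem_fraction), `reason` when degenerate.
#' @export
clone_program_association <- function(clonotypes, expr, gene = "CXCL13",
                                      min_clones = 5L) {
  members <- attr(clonotypes, "members")
  if (is.null(members)) stop("clonotype table lacks member lists", call. = FALSE)
  if (!gene %in% rownames(expr)) {
    stop(sprintf("gene '%s' absent from expression matrix", gene), call. = FALSE)
  }
  expr <- as_dense(expr)
  keep <- vapply(members, function(cells) all(cells %in% colnames(expr)),
                 logical(1))
  tab <- clonotypes[keep, , drop = FALSE]
  members <- members[keep]
  if (nrow(tab) < min_clones) {
    stop(sprintf("need >= %d clones with expression", min_clones), call. = FALSE)
  }
  per_clone <- data.frame(
    clonotype_id = tab$clonotype_id,
    mean_expr = vapply(members, function(cells) mean(expr[gene, cells]),
                       numeric(1)),
    stem_fraction = tab$stem_multiplicity / tab$size,
    stringsAsFactors = FALSE
  )
  kt <- kendall_tau(per_clone$mean_expr, per_clone$stem_fraction)
  if (!kt$computable) {
    return(list(computable = FALSE, tau = NA_real_, p_value = NA_real_,
                per_clone = per_clone, reason = kt$reason))
  }
  list(computable = TRUE, tau = kt$tau, p_value = kt$p_value,
       per_clone = per_clone)
}
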