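## Consensus NMF of expression programs, anchor-gene cosine-similarity
## rankings, the weighted running-sum enrichment statistic, and
## over-representation analysis.

# Single NMF fit, X ~ W H with W (n x k), H (k x m), by HALS coordinate
# descent on the Frobenius objective. Deterministic under `seed`.
nmf_fit <- function(x, k, seed = 1L, maxit = 500L, tol = 1e-9) {
  x <- as_dense(x)
  if (any(x < 0)) stop("NMF requires a nonnegative matrix", call. = FALSE)
  n <- nrow(x); m <- ncol(x)
  normx <- sqrt(sum(x^2))
  with_seed(seed, {
    sc <- sqrt(mean(x) / k)
    w <- matrix(stats::runif(n * k, 0, 2 * sc), n, k)
    h <- matrix(stats::runif(k * m, 0, 2 * sc), k, m)
    err_prev <- Inf
    err <- NA_real_
    for (it in seq_len(maxit)) {
      # update W
      a <- x %*% t(h); b <- h %*% t(h)
      for (j in seq_len(k)) {
        denom <- b[j, j]
        if (denom < 1e-12) {
          w[, j] <- abs(stats::rnorm(n, 0, sc))
          next
        }
        w[, j] <- pmax(0, w[, j] + (a[, j] - w %*% b[, j]) / denom)
      }
      # update H
      cc <- t(w) %*% x; d <- t(w) %*% w
      for (j in seq_len(k)) {
        denom <- d[j, j]
        if (denom < 1e-12) {
          h[j, ] <- abs(stats::rnorm(m, 0, sc))
          next
        }
        h[j, ] <- pmax(0, h[j, ] + (cc[j, ] - d[j, ] %*% h) / denom)
      }
      err <- sqrt(sum((x - w %*% h)^2)) / max(normx, 1e-12)
      if (is.finite(err_prev) && abs(err_prev - err) < tol) break
      err_prev <- err
    }
    list(w = w, h = h, error = err, iterations = it,
         converged = is.finite(err))
  })
}

# Lawson-Hanson style active-set NNLS: min ||A x - b||, x >= 0.
nnls_solve <- function(a, b, tol = 1e-10) {
  k <- ncol(a)
  passive <- logical(k)
  x <- numeric(k)
  resid <- b
  ata <- crossprod(a)
  atb <- crossprod(a, b)
  for (outer in seq_len(10L * k + 10L)) {
    wgrad <- atb - ata %*% x
    cand <- which(!passive & wgrad > tol)
    if (!length(cand)) break
    passive[cand[which.max(wgrad[cand])]] <- TRUE
    repeat {
      p <- which(passive)
      z <- numeric(k)
      z[p] <- tryCatch(
        solve(ata[p, p, drop = FALSE], atb[p, , drop = FALSE]),
        error = function(e) rep(0, length(p))
      )
      if (all(z[p] > tol)) { x <- z; break }
      neg <- p[z[p] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg] + 1e-300))
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
  }
  pmax(x, 0)
}

cosine_dist_matrix <- function(rows) {
  norms <- sqrt(rowSums(rows^2))
  norms[norms == 0] <- 1
  sim <- tcrossprod(rows / norms)
  d <- 1 - sim
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# Mean silhouette width for labelled points given a distance matrix.
mean_silhouette <- function(d, labels) {
  n <- length(labels)
  if (length(unique(labels)) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Consensus non-negative matrix factorization
#'
#' Factorizes a nonnegative expression matrix (genes x cells) into cell
#' usages and gene program loadings. For each candidate `k`, `n_restarts`
#' seeded NMF runs are fit; their L2-normalized loading rows are pooled,
#' outlier factors (nearest-neighbor cosine distance above
#' `outlier_thresh`) dropped, the remainder clustered into `k` groups by
#' average-linkage on cosine distance, and the consensus loadings taken as
#' the component-wise median of each cluster (re-normalized). Usages are
#' refit by nonnegative least squares. Per-k stability is the mean
#' silhouette of the consensus clustering; `select_k()` picks `k` unless
#' the caller fixes it.
#'
#' @param x Nonnegative matrix, genes as rows and cells as columns.
#' @param k_grid Candidate factor counts (each in `[2, min(dim(x)) - 1]`,
#'   `1` allowed for the degenerate rank-1 case).
#' @param n_restarts Restarts per k (default 30).
#' @param seed Seed; each restart derives its own seed deterministically.
#' @param k Fix the selected k instead of data-driven selection.
#' @param selection `"stability"` (default) or `"elbow"`.
#' @param outlier_thresh Cosine-distance threshold for dropping outlier
#'   restart factors before consensus clustering.
#' @param maxit,tol HALS iteration controls.
#' @return A `cnmf_fit` list: `models` (one entry per k with `usages`
#'   cells x k, `loadings` k x genes with unit-L2 rows, `error`,
#'   `stability`, `restart_errors`, `n_factors_pooled`), `k_grid`,
#'   `selected_k`, `selection`.
#' @export
fit_cnmf <- function(x, k_grid = 2:8, n_restarts = 30L, seed = 1L,
                     k = NULL, selection = c("stability", "elbow"),
                     outlier_thresh = 0.3, maxit = 500L, tol = 1e-9) {
  selection <- match.arg(selection)
  x <- as_dense(x)
  if (any(x < 0)) stop("matrix must be nonnegative", call. = FALSE)
  if (!is.null(k)) k_grid <- union(k_grid, k)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1) || any(k_grid > min(dim(x)) - 1L)) {
    stop("k_grid must lie in [1, min(dim) - 1]", call. = FALSE)
  }
  xt <- t(x) # cells x genes; usages are rows
  models <- list()
  for (kk in k_grid) {
    fits <- lapply(seq_len(n_restarts), function(r) {
      nmf_fit(xt, kk, seed = stage_seed(seed, sprintf("nmf_k%d_r%d", kk, r)),
              maxit = maxit, tol = tol)
    })
    ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$error),
                 logical(1))
    if (!any(ok)) stop(sprintf("all restarts failed for k = %d", kk), call. = FALSE)
    fits <- fits[ok]
    pooled <- do.call(rbind, lapply(fits, function(f) {
      h <- f$h
      nrm <- sqrt(rowSums(h^2)); nrm[nrm == 0] <- 1
      h / nrm
    }))
    restart_errors <- vapply(fits, `[[`, numeric(1), "error")
    d <- cosine_dist_matrix(pooled)
    if (nrow(pooled) > kk) {
      nnd <- apply(d + diag(Inf, nrow(d)), 1, min)
      keep <- nnd <= outlier_thresh
      if (sum(keep) >= kk) {
        pooled <- pooled[keep, , drop = FALSE]
        d <- d[keep, keep, drop = FALSE]
      }
    }
    if (kk == 1L || nrow(pooled) <= kk) {
      labels <- if (kk == 1L) rep(1L, nrow(pooled)) else seq_len(nrow(pooled))
    } else {
      hc <- stats::hclust(stats::as.dist(d), method = "average")
      labels <- stats::cutree(hc, k = kk)
    }
    cons <- t(vapply(seq_len(max(labels)), function(l) {
      memb <- pooled[labels == l, , drop = FALSE]
      v <- apply(memb, 2, stats::median)
      nv <- sqrt(sum(v^2))
      if (nv == 0) v else v / nv
    }, numeric(ncol(pooled))))
    usages <- t(apply(xt, 1, function(row) nnls_solve(t(cons), row)))
    if (max(labels) == 1L) usages <- matrix(usages, ncol = 1L)
    err <- sqrt(sum((xt - usages %*% cons)^2)) / max(sqrt(sum(xt^2)), 1e-12)
    stab <- if (kk == 1L) NA_real_ else mean_silhouette(d, labels)
    colnames(cons) <- rownames(x)
    models[[as.character(kk)]] <- list(
      k = kk, usages = usages, loadings = cons, error = err,
      stability = stab, restart_errors = restart_errors,
      n_factors_pooled = nrow(pooled)
    )
  }
  selected <- if (!is.null(k)) as.integer(k) else select_k(models, selection)
  structure(list(models = models, k_grid = k_grid, selected_k = selected,
                 selection = if (is.null(k)) selection else "fixed",
                 seed = seed, n_restarts = n_restarts),
            class = "cnmf_fit")
}

#' Select the number of factors from a consensus-NMF sweep
#'
#' `"stability"` picks the smallest k that is both stable (consensus
#' silhouette at least `stab_threshold`) and achieves near-minimal
#' reconstruction error among the stable candidates (within `err_tol`
#' relative). Below the true factor count restarts agree on merged
#' programs (stable but poorly reconstructing); above it they disagree on
#' how to split (unstable) or split without improving the fit — so the
#' rule lands on the planted k. If no k reaches the stability threshold
#' the k with maximal silhouette is returned. `"elbow"` picks the knee of
#' the reconstruction-error curve (maximum second difference).
#'
#' @param models The `models` element of a [fit_cnmf()] result (or the
#'   `cnmf_fit` itself).
#' @param method Selection rule.
#' @param stab_threshold Silhouette cutoff for the stability rule.
#' @param err_tol Relative slack over the minimal stable-k error.
#' @return Selected integer k.
#' @export
select_k <- function(models, method = c("stability", "elbow"),
                     stab_threshold = 0.98, err_tol = 0.05) {
  method <- match.arg(method)
  if (inherits(models, "cnmf_fit")) models <- models$models
  ks <- as.integer(names(models))
  if (length(ks) == 1) return(ks)
  if (method == "stability") {
    stab <- vapply(models, `[[`, numeric(1), "stability")
    stab <- ifelse(is.na(stab), -Inf, stab)
    err <- vapply(models, `[[`, numeric(1), "error")
    ok <- stab >= stab_threshold
    if (any(ok)) {
      best <- min(err[ok])
      return(min(ks[ok & err <= best * (1 + err_tol)]))
    }
    return(ks[which.max(stab)])
  }
  err <- vapply(models, `[[`, numeric(1), "error")
  if (length(ks) < 3) return(ks[which.min(err)])
  curv <- diff(err, differences = 2) # indexed at interior ks
  ks[which.max(curv) + 1L]
}

#' The published analysis preset for consensus NMF
#'
#' Pins k = 13 factors with 30 restarts and the default outlier threshold —
#' the configuration used to derive the CXCL13/CXCR5 program rankings.
#' @return Named list of `fit_cnmf()` arguments.
#' @export
cnmf_paper_preset <- function() {
  list(k = 13L, n_restarts = 30L, outlier_thresh = 0.3)
}

#' Rank genes by loading-profile cosine similarity to an anchor gene
#'
#' Each gene's column of the consensus loadings (its contribution profile
#' across programs) is compared with the anchor gene's column by cosine
#' similarity; genes are ranked in decreasing similarity with lexicographic
#' tie-breaking, so rankings are deterministic.
#'
#' @param model A `cnmf_fit` (its selected-k model is used) or a k x genes
#'   loadings matrix with gene colnames.
#' @param anchor Anchor gene symbol (e.g. `"CXCL13"` or `"CXCR5"`).
#' @return data.frame `gene`, `similarity`, `rank` (1 = most similar), with
#'   attribute `anchor`.
#' @export
anchor_similarity <- function(model, anchor) {
  loadings <- if (inherits(model, "cnmf_fit")) {
    model$models[[as.character(model$selected_k)]]$loadings
  } else {
    model
  }
  if (is.null(colnames(loadings))) stop("loadings need gene colnames", call. = FALSE)
  if (!anchor %in% colnames(loadings)) {
    stop(sprintf("anchor gene '%s' absent from loadings", anchor), call. = FALSE)
  }
  a <- loadings[, anchor]
  na <- sqrt(sum(a^2))
  if (na == 0) stop("anchor gene has an all-zero loading profile", call. = FALSE)
  norms <- sqrt(colSums(loadings^2))
  sim <- as.numeric(crossprod(loadings, a)) / (norms * na)
  sim[norms == 0] <- 0
  sim[colnames(loadings) == anchor] <- 1
  ord <- order(-sim, colnames(loadings))
  out <- data.frame(gene = colnames(loadings)[ord], similarity = sim[ord],
                    rank = seq_along(sim), stringsAsFactors = FALSE)
  attr(out, "anchor") <- anchor
  out
}

# Signed maximum of the weighted KS running sum, computed from hit
# positions only. pos: sorted hit indices in 1..n; w: their weights.
es_from_positions <- function(pos, w, n) {
  m <- length(pos)
  if (m == 0) stop("empty overlap with the ranking", call. = FALSE)
  if (n == m) return(list(es = 0, peak = n)) # degenerate: no misses to step down
  sumw <- sum(w)
  if (sumw == 0) w <- rep(1, m); sumw <- max(sum(w), 1e-300)
  cw <- cumsum(w) / sumw
  miss_step <- 1 / (n - m)
  after <- cw - (pos - seq_len(m)) * miss_step            # just after each hit
  before <- c(0, cw[-m]) - (pos - seq_len(m)) * miss_step # just before each hit
  hi <- max(after); lo <- min(c(before, 0))
  if (hi >= -lo) {
    list(es = hi, peak = pos[which.max(after)])
  } else {
    list(es = lo, peak = pos[which.min(before)])
  }
}

#' Running-sum enrichment of a gene set in an anchor ranking
#'
#' Weighted Kolmogorov-Smirnov statistic: walking down the ranked list, the
#' running sum rises by `|similarity|^p / sum(|similarity|^p over hits)` at
#' each gene-set member and falls by `1/(N - m)` otherwise; ES is the
#' signed maximum deviation. The null distribution comes from `n_perm`
#' gene-label permutations; NES divides ES by the mean |null ES| of the
#' same sign and p is the same-sign permutation tail (with the +1
#' correction). A set covering the entire ranking is degenerate and returns
#' ES = 0.
#'
#' @param ranking An [anchor_similarity()] data.frame (`gene`,
#'   `similarity` in ranked order).
#' @param gene_set Character vector of gene symbols (or a
#'   [gene_signature()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @param p Weighting exponent (default 1).
#' @return List: `es`, `nes`, `p_value`, `leading_edge`, `n_hits`,
#'   `null_es`.
#' @export
ranked_enrichment <- function(ranking, gene_set, n_perm = 1000L, seed = 1L,
                              p = 1) {
  if (inherits(gene_set, "gene_signature")) gene_set <- gene_set$genes
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  genes <- ranking$gene
  s <- abs(ranking$similarity)^p
  n <- length(genes)
  pos <- which(genes %in% gene_set)
  if (!length(pos)) stop("gene set has empty overlap with the ranking", call. = FALSE)
  obs <- es_from_positions(pos, s[pos], n)
  m <- length(pos)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rp <- sort(sample.int(n, m))
      es_from_positions(rp, s[rp], n)$es
    }, numeric(1))
  })
  same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  p_value <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  nes <- if (length(same) && mean(abs(same)) > 0) obs$es / mean(abs(same)) else NA_real_
  leading <- if (obs$es >= 0) {
    genes[pos[pos <= obs$peak]]
  } else {
    genes[pos[pos >= obs$peak]]
  }
  list(es = obs$es, nes = nes, p_value = p_value, leading_edge = leading,
       n_hits = m, null_es = null_es)
}

#' Enrichment of a family of gene sets with BH correction
#'
#' Runs [ranked_enrichment()] for every set and applies Benjamini-Hochberg
#' across the family.
#'
#' @param ranking An [anchor_similarity()] result.
#' @param gene_sets Named list of gene vectors (e.g. from [read_gmt()]).
#' @param ... Passed to [ranked_enrichment()].
#' @return data.frame: `set`, `n_hits`, `es`, `nes`, `p`, `fdr`,
#'   `leading_edge` (comma-separated).
#' @export
ranked_enrichment_family <- function(ranking, gene_sets, ...) {
  res <- lapply(gene_sets, function(gs) ranked_enrichment(ranking, gs, ...))
  out <- data.frame(
    set = names(gene_sets),
    n_hits = vapply(res, `[[`, numeric(1), "n_hits"),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = vapply(res, `[[`, numeric(1), "nes"),
    p = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$leading_edge <- vapply(res, function(r) paste(r$leading_edge, collapse = ","),
                             character(1))
  rownames(out) <- NULL
  out
}

#' Over-representation analysis by the hypergeometric tail
#'
#' One-sided Fisher/hypergeometric test of each gene set against a module
#' gene list within a stated universe, with Benjamini-Hochberg correction
#' across sets. Reports overlap size and the fraction of module genes
#' covered by each set.
#'
#' @param module_genes Character vector (must lie within `universe`).
#' @param gene_sets Named list of gene vectors; each is intersected with
#'   the universe.
#' @param universe Character vector of all assayed genes.
#' @return data.frame: `set`, `overlap`, `set_size`, `module_size`,
#'   `prop_module`, `p`, `fdr`.
#' @export
overrepresentation <- function(module_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe)) {
    stop("module_genes must be a subset of the universe", call. = FALSE)
  }
  n_univ <- length(universe)
  n_mod <- length(module_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(set, module_genes))
    p <- stats::phyper(k - 1, length(set), n_univ - length(set), n_mod,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               module_size = n_mod, prop_module = k / max(n_mod, 1L),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
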