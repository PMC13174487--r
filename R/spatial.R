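## Spatial immune-niche analysis: density-based aggregate detection,
## composition/chemokine classification (Quiescent / Stimulated / Lymphoid),
## stromal densities, Moran's I, ECDF comparisons and size contrasts.

T_CELL_TYPES <- c("CD8 T", "CD4 T")
IMMUNE_TYPES <- c("B", "CD8 T", "CD4 T", "myeloid")

# eps-neighborhood lists via grid binning; O(n * local density).
eps_neighbors <- function(x, y, eps) {
  n <- length(x)
  bx <- floor(x / eps); by <- floor(y / eps)
  key <- paste(bx, by, sep = ",")
  bins <- split(seq_len(n), key)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- unlist(bins[paste(rep(bx[i] + (-1:1), each = 3),
                              rep(by[i] + (-1:1), 3), sep = ",")],
                   use.names = FALSE)
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    out[[i]] <- sort(cand[d2 <= eps^2 & cand != i])
  }
  out
}

#' Detect immune aggregates by density-based spatial clustering
#'
#' DBSCAN-style clustering of immune cells: a core cell has at least
#' `min_samples` neighbors (excluding itself) within `eps_um`; clusters are
#' connected components of core cells, plus border cells (non-core within
#' `eps_um` of a core) assigned to the lowest-id reachable core cluster.
#' Cluster ids are numbered by the lowest row index of their first core
#' cell, so the partition is deterministic given input order. Noise is
#' discarded, as are clusters smaller than `min_size`.
#'
#' @param map CellMap data.frame (see [read_cell_map()]).
#' @param eps_um Neighborhood radius in micrometers.
#' @param min_samples Core-point neighbor threshold (>= 2).
#' @param min_size Minimum cells per reported aggregate.
#' @param immune_types Cell types eligible for clustering.
#' @return List: `aggregates` data.frame (aggregate_id, size, centroid_x/y,
#'   hull_area_um2, T_fraction, plus one `frac_<type>` column per immune
#'   type) and `membership` (cell_id, aggregate_id). Empty immune subset
#'   gives empty tables.
#' @export
detect_aggregates <- function(map, eps_um = 50, min_samples = 10L,
                              min_size = 20L, immune_types = IMMUNE_TYPES) {
  stopifnot(eps_um > 0, min_samples >= 2)
  validate_cell_map(map)
  imm <- map[map$cell_type %in% immune_types, , drop = FALSE]
  if (!nrow(imm)) {
    message("no cells of the requested immune types; empty aggregate set")
    return(empty_aggregate_set(immune_types))
  }
  nb <- eps_neighbors(imm$x_um, imm$y_um, eps_um)
  core <- lengths(nb) >= min_samples
  lab <- integer(nrow(imm)) # 0 = noise
  nextid <- 0L
  for (i in seq_len(nrow(imm))) {
    if (!core[i] || lab[i] != 0L) next
    nextid <- nextid + 1L
    queue <- i; lab[i] <- nextid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (j in nb[[cur]]) {
        if (core[j] && lab[j] == 0L) {
          lab[j] <- nextid
          queue <- c(queue, j)
        }
      }
    }
  }
  # border points: lowest-id cluster among reachable cores
  for (i in which(!core)) {
    cl <- lab[nb[[i]][core[nb[[i]]]]]
    if (length(cl)) lab[i] <- min(cl)
  }
  keep <- which(tabulate(lab) >= min_size)
  lab[!(lab %in% keep)] <- 0L
  lab <- match(lab, c(0L, keep)) - 1L # renumber, preserving id order
  build_aggregate_set(imm, lab, immune_types)
}

empty_aggregate_set <- function(immune_types) {
  comp_cols <- stats::setNames(
    rep(list(numeric(0)), length(immune_types)),
    paste0("frac_", gsub(" ", "_", immune_types))
  )
  list(aggregates = do.call(data.frame, c(list(
         aggregate_id = integer(0), size = integer(0),
         centroid_x = numeric(0), centroid_y = numeric(0),
         hull_area_um2 = numeric(0), T_fraction = numeric(0)),
         comp_cols, stringsAsFactors = FALSE)),
       membership = data.frame(cell_id = character(0),
                               aggregate_id = integer(0),
                               stringsAsFactors = FALSE))
}

hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

build_aggregate_set <- function(imm, lab, immune_types) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(empty_aggregate_set(immune_types))
  rows <- lapply(ids, function(id) {
    m <- imm[lab == id, , drop = FALSE]
    comp <- vapply(immune_types, function(tp) mean(m$cell_type == tp),
                   numeric(1))
    out <- data.frame(aggregate_id = id, size = nrow(m),
                      centroid_x = mean(m$x_um), centroid_y = mean(m$y_um),
                      hull_area_um2 = hull_area(m$x_um, m$y_um),
                      T_fraction = mean(m$cell_type %in% T_CELL_TYPES),
                      stringsAsFactors = FALSE)
    out[paste0("frac_", gsub(" ", "_", immune_types))] <- as.list(comp)
    out
  })
  list(aggregates = do.call(rbind, rows),
       membership = data.frame(cell_id = imm$cell_id[lab > 0],
                               aggregate_id = lab[lab > 0],
                               stringsAsFactors = FALSE))
}

#' Classify detected aggregates into Quiescent / Stimulated / Lymphoid
#'
#' Decision list: (1) aggregates with T-cell fraction below `t_fraction_min`
#' are Unclassified; (2) aggregates whose mean CXCL13 AND mean CXCR5 both
#' reach the `coexpr_quantile` quantile of aggregate-level means across the
#' cohort are co-expressing and called Lymphoid; (3) remaining aggregates
#' with exhausted-CD8 fraction >= `exhausted_cut` are Stimulated;
#' (4) the rest are Quiescent. With fewer than two aggregates the quantile
#' thresholds are meaningless and fixed expression cutoffs are used instead
#' (logged).
#'
#' @param aggs Result of [detect_aggregates()].
#' @param map CellMap with a `state_label` column for CD8 T cells.
#' @param expr Expression matrix (genes x cells) containing CXCL13 and
#'   CXCR5; colnames must cover the member cells.
#' @param coexpr_quantile Cohort quantile defining chemokine co-expression
#'   (default 0.75).
#' @param exhausted_cut Exhausted-CD8 fraction separating Stimulated from
#'   Quiescent (default 0.4).
#' @param t_fraction_min Minimum T-cell fraction for classification
#'   (default 0.20).
#' @param fixed_cutoffs Named fallback expression cutoffs
#'   (`c(CXCL13 = , CXCR5 = )`) used when the cohort has < 2 aggregates.
#' @return `aggs` with added columns `mean_CXCL13`, `mean_CXCR5`,
#'   `exhausted_CD8_fraction`, `coexpression_flag`, `class_label`.
#' @export
classify_aggregates <- function(aggs, map, expr, coexpr_quantile = 0.75,
                                exhausted_cut = 0.4, t_fraction_min = 0.20,
                                fixed_cutoffs = c(CXCL13 = 1, CXCR5 = 1)) {
  agg <- aggs$aggregates
  if (!nrow(agg)) {
    agg$mean_CXCL13 <- agg$mean_CXCR5 <- agg$exhausted_CD8_fraction <- numeric(0)
    agg$coexpression_flag <- logical(0); agg$class_label <- character(0)
    return(c(aggs[setdiff(names(aggs), "aggregates")], list(aggregates = agg)))
  }
  if (!all(c("CXCL13", "CXCR5") %in% rownames(expr))) {
    stop("expr must contain CXCL13 and CXCR5", call. = FALSE)
  }
  expr <- as_dense(expr)
  mem <- split(aggs$membership$cell_id, aggs$membership$aggregate_id)
  state <- stats::setNames(map$state_label, map$cell_id)
  type <- stats::setNames(map$cell_type, map$cell_id)
  agg$mean_CXCL13 <- vapply(as.character(agg$aggregate_id), function(id) {
    mean(expr["CXCL13", mem[[id]]])
  }, numeric(1))
  agg$mean_CXCR5 <- vapply(as.character(agg$aggregate_id), function(id) {
    mean(expr["CXCR5", mem[[id]]])
  }, numeric(1))
  agg$exhausted_CD8_fraction <- vapply(as.character(agg$aggregate_id), function(id) {
    cd8 <- mem[[id]][type[mem[[id]]] == "CD8 T"]
    if (!length(cd8)) return(0)
    mean(state[cd8] == "exhausted", na.rm = TRUE)
  }, numeric(1))
  if (nrow(agg) >= 2) {
    cut13 <- stats::quantile(agg$mean_CXCL13, coexpr_quantile, names = FALSE)
    cut5 <- stats::quantile(agg$mean_CXCR5, coexpr_quantile, names = FALSE)
  } else {
    message("fewer than 2 aggregates: using fixed chemokine cutoffs")
    cut13 <- fixed_cutoffs[["CXCL13"]]; cut5 <- fixed_cutoffs[["CXCR5"]]
  }
  agg$coexpression_flag <- agg$mean_CXCL13 >= cut13 & agg$mean_CXCR5 >= cut5
  agg$class_label <- ifelse(
    agg$T_fraction < t_fraction_min, "Unclassified",
    ifelse(agg$coexpression_flag, "Lymphoid",
           ifelse(agg$exhausted_CD8_fraction >= exhausted_cut,
                  "Stimulated", "Quiescent")))
  list(aggregates = agg, membership = aggs$membership)
}

#' Stromal-area-normalized cell density
#'
#' Stromal area is estimated by an occupancy grid: the number of
#' `tile_um`-sized tiles containing at least one stromal-compartment cell,
#' times the tile area. Density is the count of `cell_type` cells in the
#' stroma divided by that area in mm^2.
#'
#' @param map CellMap data.frame.
#' @param cell_type Cell type to count.
#' @param tile_um Tile side length in micrometers (default 50).
#' @return Density per mm^2, with attributes `n_cells`, `area_mm2`,
#'   `n_tiles`.
#' @export
stromal_density <- function(map, cell_type, tile_um = 50) {
  stopifnot(tile_um > 0)
  validate_cell_map(map)
  stroma <- map[map$compartment == "stroma", , drop = FALSE]
  tiles <- unique(paste(floor(stroma$x_um / tile_um),
                        floor(stroma$y_um / tile_um)))
  area_mm2 <- length(tiles) * (tile_um / 1000)^2
  if (area_mm2 == 0) stop("zero stromal area", call. = FALSE)
  n <- sum(stroma$cell_type == cell_type)
  structure(n / area_mm2, n_cells = n, area_mm2 = area_mm2,
            n_tiles = length(tiles))
}

#' Spatial neighborhood weights
#'
#' k-nearest-neighbor (default, distance ties broken by cell index) or
#' fixed-radius weights over planar coordinates, optionally row-
#' standardized, with no self-weights.
#'
#' @param x,y Coordinates in micrometers.
#' @param scheme `"knn"` or `"radius"`.
#' @param k Neighbors per cell for knn (default 6).
#' @param radius_um Radius for the radius scheme.
#' @param row_standardize Scale each cell's weights to sum to 1.
#' @return A `spatial_weights` list: integer vectors `i`, `j`, numeric `w`,
#'   and `n`.
#' @export
spatial_weights <- function(x, y, scheme = c("knn", "radius"), k = 6L,
                            radius_um = 50, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  ii <- jj <- integer(0)
  if (scheme == "knn") {
    k <- min(k, n - 1L)
    for (i in seq_len(n)) {
      d2 <- (x - x[i])^2 + (y - y[i])^2
      d2[i] <- Inf
      nb <- order(d2, seq_len(n))[seq_len(k)]
      ii <- c(ii, rep(i, k)); jj <- c(jj, nb)
    }
  } else {
    nb <- eps_neighbors(x, y, radius_um)
    ii <- rep(seq_len(n), lengths(nb)); jj <- unlist(nb, use.names = FALSE)
  }
  w <- rep(1, length(ii))
  if (row_standardize && length(ii)) {
    rs <- tapply(w, ii, sum)
    w <- w / as.numeric(rs[as.character(ii)])
  }
  structure(list(i = ii, j = jj, w = w, n = n, scheme = scheme,
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' `I = (n/W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' values and `W` the total weight; the null expectation is `-1/(n-1)` and
#' the p-value comes from permuting values over locations.
#'
#' @param values Per-cell numeric vector (not all equal, length >= 3).
#' @param weights A [spatial_weights()] object for the same cells.
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed RNG seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List: `I`, `expected`, `p_value`, `permutations`.
#' @export
morans_i <- function(values, weights, n_perm = 999L, seed = 1L,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(weights, "spatial_weights"))
  n <- weights$n
  if (length(values) != n) stop("values and weights disagree on n", call. = FALSE)
  if (n < 3) stop("need at least 3 cells", call. = FALSE)
  if (stats::var(values) == 0) stop("values are constant (zero variance)", call. = FALSE)
  wsum <- sum(weights$w)
  stat <- function(v) {
    z <- v - mean(v)
    (n / wsum) * sum(weights$w * z[weights$i] * z[weights$j]) / sum(z^2)
  }
  obs <- stat(values)
  e_i <- -1 / (n - 1)
  perms <- numeric(0); p_value <- NA_real_
  if (n_perm > 0) {
    perms <- with_seed(seed, {
      vapply(seq_len(n_perm), function(q) stat(sample(values)), numeric(1))
    })
    p_value <- switch(alternative,
      greater = (1 + sum(perms >= obs)) / (n_perm + 1),
      less = (1 + sum(perms <= obs)) / (n_perm + 1),
      two.sided = (1 + sum(abs(perms - e_i) >= abs(obs - e_i))) / (n_perm + 1)
    )
  }
  list(I = obs, expected = e_i, p_value = p_value, permutations = perms)
}

ecdf_on_grid <- function(v, grid) {
  vapply(grid, function(g) mean(v <= g), numeric(1))
}

#' Compare transition-score ECDFs across aggregate classes
#'
#' Per class: the empirical CDF on `grid` plus pointwise 5th/95th
#' percentile bands from `n_boot` within-class bootstrap resamples of
#' cells, and the pairwise Kolmogorov-Smirnov distance. Classes with fewer
#' than `n_min` cells are excluded (logged). Bands are display aids only;
#' KS statistics are computed from the raw scores.
#'
#' @param scores_by_class Named list of numeric score vectors.
#' @param grid Evaluation grid (default 101 points on \[0, 1\]).
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed RNG seed.
#' @param n_min Minimum class size (default 10).
#' @param band Pointwise band coverage quantiles (default `c(0.05, 0.95)`).
#' @return List: `grid`, `curves` (class x grid), `lower`, `upper`
#'   (same shape), `ks` data.frame (class_a, class_b, ks).
#' @export
compare_transition_ecdf <- function(scores_by_class,
                                    grid = seq(0, 1, length.out = 101),
                                    n_boot = 200L, seed = 1L, n_min = 10L,
                                    band = c(0.05, 0.95)) {
  sizes <- lengths(scores_by_class)
  drop <- names(scores_by_class)[sizes < n_min]
  if (length(drop)) {
    message("excluding classes below n_min: ", paste(drop, collapse = ", "))
    scores_by_class <- scores_by_class[sizes >= n_min]
  }
  if (length(scores_by_class) < 2) {
    stop("need at least 2 classes with >= n_min cells", call. = FALSE)
  }
  cls <- names(scores_by_class)
  curves <- t(vapply(scores_by_class, ecdf_on_grid, numeric(length(grid)),
                     grid = grid))
  lower <- upper <- curves
  with_seed(seed, {
    for (ci in seq_along(cls)) {
      v <- scores_by_class[[ci]]
      boots <- vapply(seq_len(n_boot), function(b) {
        ecdf_on_grid(sample(v, length(v), replace = TRUE), grid)
      }, numeric(length(grid)))
      boots <- matrix(boots, nrow = length(grid))
      lower[ci, ] <- apply(boots, 1, stats::quantile, probs = band[1])
      upper[ci, ] <- apply(boots, 1, stats::quantile, probs = band[2])
    }
  })
  pairs <- utils::combn(cls, 2)
  ks <- data.frame(
    class_a = pairs[1, ], class_b = pairs[2, ],
    ks = apply(pairs, 2, function(pr) {
      pts <- sort(unique(c(scores_by_class[[pr[1]]], scores_by_class[[pr[2]]])))
      max(abs(ecdf_on_grid(scores_by_class[[pr[1]]], pts) -
              ecdf_on_grid(scores_by_class[[pr[2]]], pts)))
    }),
    stringsAsFactors = FALSE
  )
  list(grid = grid, curves = curves, lower = lower, upper = upper, ks = ks)
}

#' Compare aggregate sizes between two groups
#'
#' Reports `median(A) - median(B)` with a two-sided rank-based p-value:
#' the exact Wilcoxon rank-sum distribution when both groups are small and
#' tie-free, otherwise a permutation test of the rank-sum statistic.
#'
#' @param sizes_a,sizes_b Numeric size vectors (non-empty).
#' @param n_perm Permutations for the large-sample/tied case.
#' @param seed RNG seed.
#' @return List: `median_difference`, `p_value`, `method`.
#' @export
compare_aggregate_sizes <- function(sizes_a, sizes_b, n_perm = 10000L,
                                    seed = 1L) {
  if (!length(sizes_a) || !length(sizes_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  md <- stats::median(sizes_a) - stats::median(sizes_b)
  no_ties <- !any(duplicated(c(sizes_a, sizes_b)))
  if (no_ties && length(sizes_a) <= 50 && length(sizes_b) <= 50) {
    p <- stats::wilcox.test(sizes_a, sizes_b, exact = TRUE)$p.value
    method <- "exact rank-sum"
  } else {
    pooled <- c(sizes_a, sizes_b)
    r <- rank(pooled)
    na <- length(sizes_a)
    obs <- sum(r[seq_len(na)])
    center <- na * (length(pooled) + 1) / 2
    perms <- with_seed(seed, {
      vapply(seq_len(n_perm), function(q) {
        sum(r[sample.int(length(pooled), na)])
      }, numeric(1))
    })
    p <- (1 + sum(abs(perms - center) >= abs(obs - center))) / (n_perm + 1)
    method <- "permutation rank-sum"
  }
  list(median_difference = md, p_value = min(p, 1), method = method)
}

#' Stromal-versus-tumor localization of aggregates
#'
#' Per aggregate, the fraction of member cells lying in the stromal
#' compartment and a two-sided binomial test against the slide-wide
#' stromal fraction of immune cells.
#'
#' @param map CellMap data.frame.
#' @param aggs Result of [detect_aggregates()] / [classify_aggregates()].
#' @param immune_types Types defining the background immune population.
#' @return data.frame: aggregate_id, size, stromal_fraction,
#'   background_fraction, p_value. Empty aggregate set gives empty report.
#' @export
tumor_vs_stroma_localization <- function(map, aggs,
                                         immune_types = IMMUNE_TYPES) {
  if (!nrow(aggs$aggregates)) {
    return(data.frame(aggregate_id = integer(0), size = integer(0),
                      stromal_fraction = numeric(0),
                      background_fraction = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  comp <- stats::setNames(map$compartment, map$cell_id)
  imm <- map$cell_type %in% immune_types
  bg <- mean(comp[map$cell_id[imm]] == "stroma")
  mem <- split(aggs$membership$cell_id, aggs$membership$aggregate_id)
  rows <- lapply(names(mem), function(id) {
    k <- sum(comp[mem[[id]]] == "stroma")
    n <- length(mem[[id]])
    p <- if (bg <= 0 || bg >= 1) {
      if ((bg == 1 && k == n) || (bg == 0 && k == 0)) 1 else 0
    } else {
      stats::binom.test(k, n, bg)$p.value
    }
    data.frame(aggregate_id = as.integer(id), size = n,
               stromal_fraction = k / n, background_fraction = bg,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells;
#' used to measure recovery of planted aggregate memberships.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in \[-1, 1\] (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
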