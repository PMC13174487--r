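# Independent reference implementations used as oracles. Each is written
# the slow, obvious way (full pairwise distances, full running sums,
# explicit double loops) so it shares no code path with the package.

# Brute-force density clustering: full distance matrix, core points by
# row sums, BFS over the core graph, border points to the lowest-id
# reachable core cluster. Returns per-cell labels (0 = noise), clusters
# numbered by their first core point.
brute_dbscan <- function(x, y, eps, min_samples) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nbr <- d <= eps
  diag(nbr) <- FALSE
  core <- rowSums(nbr) >= min_samples
  lab <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != 0L) next
    cid <- cid + 1L
    stack <- i
    lab[i] <- cid
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      nxt <- which(nbr[cur, ] & core & lab == 0L)
      lab[nxt] <- cid
      stack <- c(stack, nxt)
    }
  }
  for (i in which(!core)) {
    cl <- lab[which(nbr[i, ] & core)]
    cl <- cl[cl > 0]
    if (length(cl)) lab[i] <- min(cl)
  }
  lab
}

# Brute-force weighted KS enrichment score: evaluate the full running sum
# at every position and take the signed maximum deviation.
brute_es <- function(similarity, is_hit, p = 1) {
  w <- abs(similarity)^p
  n <- length(similarity)
  m <- sum(is_hit)
  stopifnot(m > 0, m < n)
  sumw <- sum(w[is_hit])
  step <- ifelse(is_hit, if (sumw > 0) w / sumw else 1 / m, -1 / (n - m))
  if (sumw == 0) step[is_hit] <- 1 / m
  run <- cumsum(step)
  hi <- max(run); lo <- min(run)
  if (hi >= -lo) hi else lo
}

# Brute-force Kendall tau-b via explicit pair enumeration.
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) { tie_x <- tie_x + 1; tie_y <- tie_y + 1 }
      else if (dx == 0) tie_x <- tie_x + 1
      else if (dy == 0) tie_y <- tie_y + 1
      else if (sign(dx) == sign(dy)) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# Brute-force Moran's I by the explicit double sum.
brute_moran <- function(values, w_mat) {
  n <- length(values)
  z <- values - mean(values)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- s + w_mat[i, j] * z[i] * z[j]
    }
  }
  (n / sum(w_mat)) * s / sum(z^2)
}

# Dense weight matrix from a spatial_weights object.
weights_as_matrix <- function(w) {
  m <- matrix(0, w$n, w$n)
  m[cbind(w$i, w$j)] <- w$w
  m
}

# Planted nonnegative factor model: k blocks of genes, one dominant factor
# per cell, small uniform background, tiny half-normal noise.
planted_nmf <- function(k, n = 150, g = 60, seed = 1, noise = 0.05) {
  set.seed(seed)
  h <- matrix(0.05 * runif(k * g), k, g)
  per <- split(seq_len(g), rep(seq_len(k), length.out = g))
  for (j in seq_len(k)) h[j, per[[j]]] <- 1 + runif(length(per[[j]]))
  w <- matrix(0.05 * runif(n * k), n, k)
  fac <- sample(seq_len(k), n, replace = TRUE)
  w[cbind(seq_len(n), fac)] <- 1 + runif(n)
  x <- w %*% h + matrix(abs(rnorm(n * g, 0, noise)), n, g)
  x_t <- t(x)
  rownames(x_t) <- sprintf("G%03d", seq_len(g))
  colnames(x_t) <- sprintf("C%03d", seq_len(n))
  list(x = x_t, h = h, w = w)
}

# Best-match cosine between planted loading rows and recovered loadings.
match_cosines <- function(h_true, h_fit) {
  hn <- h_true / sqrt(rowSums(h_true^2))
  fn <- h_fit / sqrt(rowSums(h_fit^2))
  apply(hn %*% t(fn), 1, max)
}

# Map detected aggregate ids to planted ids by majority membership and
# return the per-aggregate class recovery accuracy.
class_recovery <- function(aggs, tissue) {
  truth_cell <- stats::setNames(tissue$truth$cell$aggregate_id,
                                tissue$truth$cell$cell_id)
  mem <- split(aggs$membership$cell_id, aggs$membership$aggregate_id)
  det <- aggs$aggregates
  hits <- vapply(seq_len(nrow(det)), function(r) {
    planted <- truth_cell[mem[[as.character(det$aggregate_id[r])]]]
    planted <- planted[!is.na(planted)]
    if (!length(planted)) return(NA_character_)
    maj <- as.integer(names(sort(table(planted), decreasing = TRUE))[1])
    tissue$truth$aggregates$class[tissue$truth$aggregates$aggregate_id == maj]
  }, character(1))
  mean(hits == det$class_label, na.rm = TRUE)
}
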