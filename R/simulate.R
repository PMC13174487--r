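## Synthetic data with recoverable ground truth: a CD8 differentiation
## continuum (stem-like -> effector -> exhausted) sampled as negative
## binomial counts with dropout, paired-chain clonotype structure with
## controlled stem content, and planar tissue maps with planted stromal
## immune aggregates of three composition classes.

REQUIRED_GENES <- c("CXCL13", "CXCR5", "TCF7", "IL7R", "CCR7", "TOX",
                    "HAVCR2", "PDCD1", "GZMB", "CD8A", "MS4A1")

CD8_STATES <- c("stem-like", "effector-memory", "effector", "exhausted")

#' Per-gene archetype table of the CD8 count generator
#'
#' Each panel gene has a baseline mean and a marker class; the class
#' determines how its mean scales along the latent differentiation
#' coordinate `u` in \[0, 1\] (see [archetype_multiplier()]). Marker-high
#' states sit at `marker_amp` times baseline (default 8x).
#'
#' @param gene_panel Character vector of gene symbols; defaults to
#'   [default_gene_panel()].
#' @return data.frame with columns `gene`, `baseline`, `class`.
#' @export
cd8_archetypes <- function(gene_panel = default_gene_panel()) {
  cls <- list(
    stem          = c("TCF7", "IL7R", "CCR7", "CXCR5", "SELL", "LEF1", "BACH2"),
    exhausted     = c("TOX", "HAVCR2", "PDCD1", "CXCL13", "LAG3", "TIGIT", "ENTPD1"),
    cytotoxic     = c("GZMB", "GZMA", "PRF1", "NKG7", "IFNG", "KLRG1"),
    proliferation = c("MKI67", "TOP2A", "PCNA", "STMN1", "MCM2", "CDK1",
                      "TYMS", "RRM2"),
    lineage       = c("CD8A", "CD3E"),
    offlineage    = c("MS4A1")
  )
  class_of <- rep("flat", length(gene_panel))
  for (nm in names(cls)) class_of[gene_panel %in% cls[[nm]]] <- nm
  baseline <- rep(NA_real_, length(gene_panel))
  baseline[class_of %in% c("stem", "exhausted", "cytotoxic", "proliferation")] <- 1
  baseline[class_of == "lineage"] <- 5
  baseline[class_of == "offlineage"] <- 0.05
  flat <- which(class_of == "flat")
  # fixed cycle of baselines so expression bins for control-gene matching
  # span low to high without any randomness
  baseline[flat] <- rep(c(0.2, 0.5, 1, 2, 5, 10), length.out = length(flat))
  data.frame(gene = gene_panel, baseline = baseline, class = class_of,
             stringsAsFactors = FALSE)
}

#' Mean multiplier along the differentiation coordinate
#'
#' Stem markers decay linearly from `amp` at u = 0 to 1 at u = 1; exhaustion
#' markers mirror them; cytotoxic markers form a Gaussian peak at u = 0.5
#' (width 0.12); proliferation
#' markers form a narrow Gaussian burst at u = 0.70, in the
#' effector-to-exhausted transition; all other classes are flat.
#'
#' @param class Marker class from [cd8_archetypes()].
#' @param u Latent coordinate(s) in \[0, 1\].
#' @param amp Marker amplitude (mean fold-change at the peak), default 8.
#' @return Numeric multiplier(s), same length as `u`.
#' @export
archetype_multiplier <- function(class, u, amp = 8) {
  a <- amp - 1
  switch(class,
    stem          = 1 + a * (1 - u),
    exhausted     = 1 + a * u,
    cytotoxic     = 1 + a * exp(-((u - 0.5) / 0.12)^2),
    proliferation = 1 + a * exp(-((u - 0.70) / 0.07)^2),
    rep(1, length(u))
  )
}

#' Default simulated gene panel
#'
#' The required markers, their class companions, and 30 flat "housekeeping"
#' genes spanning a range of baselines (needed for expression-bin-matched
#' control genes in signature scoring).
#' @return Character vector of gene symbols.
#' @export
default_gene_panel <- function() {
  c("TCF7", "IL7R", "CCR7", "CXCR5", "SELL", "LEF1", "BACH2",
    "TOX", "HAVCR2", "PDCD1", "CXCL13", "LAG3", "TIGIT", "ENTPD1",
    "GZMB", "GZMA", "PRF1", "NKG7", "IFNG", "KLRG1",
    "MKI67", "TOP2A", "PCNA", "STMN1", "MCM2", "CDK1", "TYMS", "RRM2",
    "CD8A", "CD3E", "MS4A1",
    sprintf("HK%02d", 1:30))
}

#' Default four-signature CD8 state gene sets
#'
#' Stem-like, cytotoxic, proliferating and exhausted marker sets matching
#' the generator's archetype classes.
#' @return Named list of character vectors (a GMT-shaped object).
#' @export
cd8_signatures <- function() {
  a <- cd8_archetypes()
  list(
    stem          = a$gene[a$class == "stem"],
    cytotoxic     = a$gene[a$class == "cytotoxic"],
    proliferating = a$gene[a$class == "proliferation"],
    exhausted     = a$gene[a$class == "exhausted"]
  )
}

#' Default planted aggregate specifications
#'
#' One aggregate per composition class. Lymphoid: B-cell rich with high
#' chemokine (CXCL13/CXCR5) means and stem-enriched CD8s; Stimulated: T-rich
#' with a high exhausted-CD8 fraction; Quiescent: T-rich, low exhaustion.
#' All have T-cell fraction >= 0.20.
#' @return List of aggregate spec lists.
#' @export
default_aggregate_specs <- function() {
  list(
    list(class = "Quiescent", n_cells = 150,
         composition = c("CD8 T" = 0.45, "CD4 T" = 0.25, "B" = 0.10, "myeloid" = 0.20),
         chemokine = 1, exhausted_frac = 0.10, stem_frac = 0.30),
    list(class = "Stimulated", n_cells = 150,
         composition = c("CD8 T" = 0.45, "CD4 T" = 0.25, "B" = 0.10, "myeloid" = 0.20),
         chemokine = 1, exhausted_frac = 0.60, stem_frac = 0.15),
    list(class = "Lymphoid", n_cells = 150,
         composition = c("CD8 T" = 0.30, "CD4 T" = 0.15, "B" = 0.35, "myeloid" = 0.20),
         chemokine = 8, exhausted_frac = 0.15, stem_frac = 0.60)
  )
}

#' Build and validate a simulation configuration
#'
#' All defaults define the package's "stated world"; `sim_preset()` provides
#' named variants. The seed fully determines every simulator output.
#'
#' @param seed Integer RNG seed.
#' @param n_cells Number of CD8 cells for the count simulator.
#' @param gene_panel Gene symbols (must include the canonical markers).
#' @param state_mixture Named per-state proportions summing to 1.
#' @param state_u Named list of `c(lo, hi)` latent-coordinate intervals per
#'   state; ordered so stem < effector < exhausted in expectation.
#' @param marker_amp Marker amplitude (peak mean fold-change over baseline).
#' @param nb_dispersion Negative binomial size parameter theta (variance
#'   mu + mu^2/theta); `Inf` gives the Poisson limit.
#' @param zero_inflation Dropout probability in \[0, 1\].
#' @param clone_size_law Geometric parameter p of the clone-size law,
#'   P(size = k) = p (1-p)^(k-1).
#' @param frac_expanding_with_stem Expected fraction of expanding clones
#'   (size >= 3) that contain >= 2 stem-like cells. Default 0.477.
#' @param tissue_width_um,tissue_height_um Tissue extent in micrometers.
#' @param aggregate_specs List of planted aggregate specs (see
#'   [default_aggregate_specs()]).
#' @param aggregate_sd_um Planted aggregate Gaussian spread.
#' @param min_center_sep_um Minimum pairwise distance between aggregate
#'   centers.
#' @param tumor_area_frac Fraction of tissue area covered by tumor blobs.
#' @param n_tumor_cells Tumor cells scattered in the tumor compartment.
#' @param background_immune_per_mm2 Homogeneous background immune density.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 2000L,
                       gene_panel = default_gene_panel(),
                       state_mixture = c("stem-like" = 0.25, "effector-memory" = 0.2,
                                         "effector" = 0.25, "exhausted" = 0.3),
                       state_u = list("stem-like" = c(0, 0.25),
                                      "effector-memory" = c(0.25, 0.5),
                                      "effector" = c(0.5, 0.75),
                                      "exhausted" = c(0.75, 1)),
                       marker_amp = 8,
                       nb_dispersion = 2,
                       zero_inflation = 0.2,
                       clone_size_law = 0.6,
                       frac_expanding_with_stem = 0.477,
                       tissue_width_um = 2000,
                       tissue_height_um = 2000,
                       aggregate_specs = default_aggregate_specs(),
                       aggregate_sd_um = 40,
                       min_center_sep_um = 400,
                       tumor_area_frac = 0.4,
                       n_tumor_cells = 600,
                       background_immune_per_mm2 = 40) {
  cfg <- list(seed = as.integer(seed), n_cells = as.integer(n_cells),
              gene_panel = gene_panel, state_mixture = state_mixture,
              state_u = state_u, marker_amp = marker_amp,
              nb_dispersion = nb_dispersion, zero_inflation = zero_inflation,
              clone_size_law = clone_size_law,
              frac_expanding_with_stem = frac_expanding_with_stem,
              tissue_width_um = tissue_width_um,
              tissue_height_um = tissue_height_um,
              aggregate_specs = aggregate_specs,
              aggregate_sd_um = aggregate_sd_um,
              min_center_sep_um = min_center_sep_um,
              tumor_area_frac = tumor_area_frac,
              n_tumor_cells = as.integer(n_tumor_cells),
              background_immune_per_mm2 = background_immune_per_mm2)
  missing <- setdiff(REQUIRED_GENES, cfg$gene_panel)
  if (length(missing)) {
    stop("gene_panel missing required genes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_proportions(cfg$state_mixture, "state_mixture")
  if (is.null(names(cfg$state_mixture)) ||
      !all(names(cfg$state_mixture) %in% names(cfg$state_u))) {
    stop("state_mixture names must be a subset of state_u names", call. = FALSE)
  }
  if (!is.finite(cfg$zero_inflation) || cfg$zero_inflation < 0 ||
      cfg$zero_inflation > 1) {
    stop("zero_inflation must be in [0, 1]", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive", call. = FALSE)
  if (cfg$clone_size_law <= 0 || cfg$clone_size_law > 1) {
    stop("clone_size_law must be a geometric parameter in (0, 1]", call. = FALSE)
  }
  if (cfg$frac_expanding_with_stem < 0 || cfg$frac_expanding_with_stem > 1) {
    stop("frac_expanding_with_stem must be in [0, 1]", call. = FALSE)
  }
  for (sp in cfg$aggregate_specs) {
    check_proportions(sp$composition,
                      sprintf("composition of aggregate '%s'", sp$class))
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Named simulation presets
#'
#' `"default"` is [sim_config()] as-is. `"well_separated"` narrows the
#' per-state latent intervals, removes dropout and tightens the NB noise so
#' planted states, niches and factors are recoverable by construction — the
#' regime used by the recovery tests.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("default", "well_separated"), ...) {
  name <- match.arg(name)
  if (name == "default") return(sim_config(...))
  sim_config(
    state_mixture = c("stem-like" = 1 / 3, "effector" = 1 / 3, "exhausted" = 1 / 3),
    state_u = list("stem-like" = c(0.02, 0.18),
                   "effector" = c(0.42, 0.58),
                   "exhausted" = c(0.82, 0.98)),
    nb_dispersion = 10,
    zero_inflation = 0,
    ...
  )
}

# NB sampler with Poisson limit at infinite dispersion and dropout.
rcounts <- function(n, mu, theta, zi) {
  y <- if (is.infinite(theta)) stats::rpois(n, mu) else {
    stats::rnbinom(n, size = theta, mu = mu)
  }
  if (zi > 0) y[stats::runif(n) < zi] <- 0L
  y
}

#' Simulate CD8 T cell counts along a stem-to-exhausted continuum
#'
#' Each cell draws a state from `state_mixture`, a latent coordinate `u`
#' uniform on that state's interval, per-gene means
#' `baseline * archetype_multiplier(class, u, marker_amp)`, and negative
#' binomial counts with dropout.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (genes x cells integer matrix), and `truth`
#'   data.frame (`cell_id`, `u`, `state`).
#' @export
simulate_cd8_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- cd8_archetypes(config$gene_panel)
  with_seed(stage_seed(config$seed, "cd8_counts"), {
    n <- config$n_cells
    states <- sample(names(config$state_mixture), n, replace = TRUE,
                     prob = config$state_mixture)
    u <- vapply(states, function(s) {
      iv <- config$state_u[[s]]
      stats::runif(1, iv[1], iv[2])
    }, numeric(1))
    mu <- matrix(0, nrow(arch), n)
    for (g in seq_len(nrow(arch))) {
      mu[g, ] <- arch$baseline[g] *
        archetype_multiplier(arch$class[g], u, config$marker_amp)
    }
    counts <- matrix(
      rcounts(length(mu), as.vector(mu), config$nb_dispersion,
              config$zero_inflation),
      nrow(arch), n,
      dimnames = list(arch$gene, sprintf("cell%05d", seq_len(n)))
    )
    list(counts = counts,
         truth = data.frame(cell_id = colnames(counts), u = unname(u),
                            state = states, stringsAsFactors = FALSE))
  })
}

#' Simulate paired-chain clonotype assignments with controlled stem content
#'
#' Clone sizes follow a geometric law. Each expanding clone (size >= 3) is
#' assigned a "stem-maintained" archetype with probability
#' `frac_expanding_with_stem` and is then filled with at least two stem-like
#' cells; "exhaustion-dominant" clones receive none (unless the non-stem
#' pool runs out, which is recorded). Smaller clones take the remaining
#' cells at random.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth data.frame from [simulate_cd8_counts()] (needs
#'   `cell_id` and `state`).
#' @return List with `assignments` (cell_id, clonotype_id) and `clones`
#'   (clonotype_id, size, expanding, archetype, n_stem_planted).
#' @export
simulate_clonotypes <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"),
            all(c("cell_id", "state") %in% names(truth)))
  with_seed(stage_seed(config$seed, "clonotypes"), {
    n <- nrow(truth)
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, stats::rgeom(max(16L, n %/% 4L), config$clone_size_law) + 1L)
    }
    keep <- which(cumsum(sizes) >= n)[1]
    sizes <- sizes[seq_len(keep)]
    sizes[keep] <- sizes[keep] - (sum(sizes) - n)
    if (sizes[keep] == 0L) sizes <- sizes[-keep]

    expanding <- sizes >= 3L
    archetype <- ifelse(expanding, "exhaustion-dominant", "small")
    if (any(expanding)) {
      coin <- stats::runif(sum(expanding)) < config$frac_expanding_with_stem
      archetype[expanding][coin] <- "stem-maintained"
    }

    is_stem <- truth$state == "stem-like"
    stem_pool <- sample(which(is_stem))
    other_pool <- sample(which(!is_stem))
    members <- vector("list", length(sizes))
    n_stem_planted <- integer(length(sizes))
    # fill expanding clones first so archetypes are honored while pools last
    for (ci in order(!expanding)) {
      s <- sizes[ci]
      take <- integer(0)
      if (archetype[ci] == "stem-maintained") {
        k <- min(2L, length(stem_pool), s)
        take <- stem_pool[seq_len(k)]
        stem_pool <- stem_pool[-seq_len(k)]
      }
      need <- s - length(take)
      if (need > 0) {
        if (archetype[ci] == "exhaustion-dominant") {
          k <- min(need, length(other_pool))
          take <- c(take, other_pool[seq_len(k)])
          if (k > 0) other_pool <- other_pool[-seq_len(k)]
          need <- need - k
        }
        if (need > 0) { # mixed leftover pool, shuffled across both states
          pool <- c(stem_pool, other_pool)
          pool <- pool[order(stats::runif(length(pool)))][seq_len(need)]
          stem_pool <- setdiff(stem_pool, pool)
          other_pool <- setdiff(other_pool, pool)
          take <- c(take, pool)
        }
      }
      members[[ci]] <- take
      n_stem_planted[ci] <- sum(is_stem[take])
    }
    clone_id <- sprintf("TRA:%04d|TRB:%04d", seq_along(sizes), seq_along(sizes))
    assignments <- data.frame(
      cell_id = truth$cell_id[unlist(members)],
      clonotype_id = rep(clone_id, lengths(members)),
      stringsAsFactors = FALSE
    )
    assignments <- assignments[order(match(assignments$cell_id, truth$cell_id)), ]
    rownames(assignments) <- NULL
    list(assignments = assignments,
         clones = data.frame(clonotype_id = clone_id, size = sizes,
                             expanding = expanding, archetype = archetype,
                             n_stem_planted = n_stem_planted,
                             stringsAsFactors = FALSE))
  })
}

# Separable Gaussian smoothing with reflected edges, used for tumor blobs.
smooth_field <- function(z, radius = 3) {
  kern <- stats::dnorm(seq(-radius, radius), sd = radius / 2)
  kern <- kern / sum(kern)
  conv1 <- function(x) {
    n <- length(x)
    pad <- c(x[radius:1], x, x[n:(n - radius + 1)])
    out <- stats::filter(pad, kern, sides = 2)
    as.numeric(out[(radius + 1):(radius + n)])
  }
  z <- apply(z, 2, conv1)
  t(apply(z, 1, conv1))
}

#' Simulate a tissue map with planted immune aggregates
#'
#' Tumor blobs are a thresholded Gaussian random field; stroma is the
#' remainder. Background immune cells follow a homogeneous Poisson process
#' over the stroma. Each planted aggregate is a 2-D Gaussian cluster centered
#' in the stroma (centers whose simulated footprint would overlap tumor
#' beyond 5% are re-sampled, up to 200 retries) with the spec's size,
#' composition, chemokine level and CD8 state mixture. Per-cell CXCL13 and
#' CXCR5 counts (plus CD8A/MS4A1) are emitted so aggregates can be
#' classified downstream.
#'
#' @param config A [sim_config()].
#' @return List with `map` (CellMap data.frame: cell_id, x_um, y_um,
#'   compartment, cell_type, state_label), `expr` (genes x cells counts for
#'   the tissue panel), and `truth` (`cell` data.frame with per-cell
#'   aggregate_id, `aggregates` data.frame with class, center, sd).
#' @export
simulate_tissue <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$aggregate_specs)) {
    stop("aggregate_specs must be non-empty", call. = FALSE)
  }
  W <- config$tissue_width_um; H <- config$tissue_height_um
  with_seed(stage_seed(config$seed, "tissue"), {
    step <- 25
    nx <- max(8L, ceiling(W / step)); ny <- max(8L, ceiling(H / step))
    field <- smooth_field(matrix(stats::rnorm(nx * ny), ny, nx), radius = 4)
    thr <- stats::quantile(field, 1 - config$tumor_area_frac)
    tumor_mask <- field > thr # ny x nx, row = y bin, col = x bin
    in_tumor <- function(x, y) {
      ix <- pmin(nx, pmax(1L, ceiling(x / step)))
      iy <- pmin(ny, pmax(1L, ceiling(y / step)))
      tumor_mask[cbind(iy, ix)]
    }

    # tumor cells: uniform over tumor grid cells
    tumor_cells <- which(tumor_mask, arr.ind = TRUE)
    pick <- tumor_cells[sample.int(nrow(tumor_cells), config$n_tumor_cells,
                                   replace = TRUE), , drop = FALSE]
    tx <- (pick[, 2] - stats::runif(config$n_tumor_cells)) * step
    ty <- (pick[, 1] - stats::runif(config$n_tumor_cells)) * step

    # background immune cells: homogeneous Poisson over stroma
    stroma_mm2 <- sum(!tumor_mask) * (step / 1000)^2
    n_bg <- stats::rpois(1, config$background_immune_per_mm2 * stroma_mm2)
    bx <- by <- numeric(0)
    while (length(bx) < n_bg) {
      cx <- stats::runif(n_bg, 0, W); cy <- stats::runif(n_bg, 0, H)
      ok <- !in_tumor(cx, cy)
      bx <- c(bx, cx[ok])[seq_len(min(n_bg, length(bx) + sum(ok)))]
      by <- c(by, cy[ok])[seq_len(length(bx))]
    }
    bg_types <- if (n_bg > 0) {
      sample(c("CD8 T", "CD4 T", "B", "myeloid"), length(bx), replace = TRUE,
             prob = c(0.4, 0.3, 0.1, 0.2))
    } else character(0)

    # planted aggregates
    sd_um <- config$aggregate_sd_um
    centers <- matrix(NA_real_, length(config$aggregate_specs), 2)
    agg_pts <- vector("list", length(config$aggregate_specs))
    for (ai in seq_along(config$aggregate_specs)) {
      sp <- config$aggregate_specs[[ai]]
      ok <- FALSE
      for (try in seq_len(200L)) {
        cx <- stats::runif(1, 3 * sd_um, W - 3 * sd_um)
        cy <- stats::runif(1, 3 * sd_um, H - 3 * sd_um)
        if (in_tumor(cx, cy)) next
        if (ai > 1) {
          d <- sqrt((centers[seq_len(ai - 1), 1] - cx)^2 +
                    (centers[seq_len(ai - 1), 2] - cy)^2)
          if (any(d < config$min_center_sep_um)) next
        }
        px <- stats::rnorm(sp$n_cells, cx, sd_um)
        py <- stats::rnorm(sp$n_cells, cy, sd_um)
        # clamp stray tails inside tissue bounds
        px <- pmin(pmax(px, 0), W); py <- pmin(pmax(py, 0), H)
        if (mean(in_tumor(px, py)) > 0.05) next
        centers[ai, ] <- c(cx, cy)
        agg_pts[[ai]] <- cbind(px, py)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf("could not place aggregate '%s' after 200 retries",
                     sp$class), call. = FALSE)
      }
    }

    # assemble cells
    type_list <- lapply(seq_along(config$aggregate_specs), function(ai) {
      sp <- config$aggregate_specs[[ai]]
      sample(names(sp$composition), sp$n_cells, replace = TRUE,
             prob = sp$composition)
    })
    x <- c(tx, bx, unlist(lapply(agg_pts, function(p) p[, 1])))
    y <- c(ty, by, unlist(lapply(agg_pts, function(p) p[, 2])))
    cell_type <- c(rep("tumor", length(tx)), bg_types, unlist(type_list))
    agg_id <- c(rep(NA_integer_, length(tx) + length(bx)),
                rep(seq_along(agg_pts),
                    vapply(agg_pts, nrow, integer(1))))
    n_all <- length(x)
    cell_id <- sprintf("tc%05d", seq_len(n_all))

    # CD8 state labels: background CD8s mostly non-exhausted; aggregate CD8s
    # follow the spec's exhausted/stem fractions
    state_label <- rep(NA_character_, n_all)
    is_cd8 <- cell_type == "CD8 T"
    draw_states <- function(k, exh, stem) {
      if (k == 0) return(character(0))
      sample(c("exhausted", "stem-like", "effector"), k, replace = TRUE,
             prob = c(exh, (1 - exh) * stem, (1 - exh) * (1 - stem)))
    }
    bg_cd8 <- which(is_cd8 & is.na(agg_id))
    state_label[bg_cd8] <- draw_states(length(bg_cd8), 0.2, 0.3)
    for (ai in seq_along(config$aggregate_specs)) {
      sp <- config$aggregate_specs[[ai]]
      idx <- which(is_cd8 & !is.na(agg_id) & agg_id == ai)
      state_label[idx] <- draw_states(length(idx), sp$exhausted_frac, sp$stem_frac)
    }
    # latent differentiation coordinate for CD8 cells, consistent with
    # their state labels (drives transition-score ECDF comparisons)
    u_lat <- rep(NA_real_, n_all)
    for (i in which(is_cd8)) {
      iv <- config$state_u[[state_label[i]]] %||%
        switch(state_label[i], "stem-like" = c(0, 0.25),
               "effector" = c(0.5, 0.75), "exhausted" = c(0.75, 1),
               c(0.25, 0.75))
      u_lat[i] <- stats::runif(1, iv[1], iv[2])
    }

    # tissue expression panel: chemokines driven by aggregate level,
    # lineage markers by cell type
    chem_level <- rep(1, n_all)
    for (ai in seq_along(config$aggregate_specs)) {
      chem_level[!is.na(agg_id) & agg_id == ai] <-
        config$aggregate_specs[[ai]]$chemokine
    }
    chem_level[cell_type == "tumor"] <- 0.2
    mu <- rbind(
      CXCL13 = 0.5 * chem_level,
      CXCR5  = 0.5 * chem_level,
      CD8A   = ifelse(is_cd8, 5, 0.05),
      MS4A1  = ifelse(cell_type == "B", 5, 0.05)
    )
    expr <- matrix(
      rcounts(length(mu), as.vector(mu), config$nb_dispersion,
              config$zero_inflation),
      nrow(mu), n_all, dimnames = list(rownames(mu), cell_id)
    )

    map <- data.frame(
      cell_id = cell_id, x_um = x, y_um = y,
      compartment = ifelse(in_tumor(x, y), "tumor", "stroma"),
      cell_type = cell_type, state_label = state_label, u = u_lat,
      stringsAsFactors = FALSE
    )
    truth_agg <- data.frame(
      aggregate_id = seq_along(config$aggregate_specs),
      class = vapply(config$aggregate_specs, `[[`, character(1), "class"),
      center_x = centers[, 1], center_y = centers[, 2],
      sd_um = sd_um,
      n_cells = vapply(config$aggregate_specs, `[[`, numeric(1), "n_cells"),
      stringsAsFactors = FALSE
    )
    list(map = validate_cell_map(map), expr = expr,
         truth = list(cell = data.frame(cell_id = cell_id, aggregate_id = agg_id,
                                        stringsAsFactors = FALSE),
                      aggregates = truth_agg))
  })
}
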