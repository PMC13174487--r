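## End-to-end pipeline driver: score -> cnmf -> niches -> clones -> assoc,
## with one global seed expanded deterministically into per-stage seeds and
## a content-hashed manifest of every output file.

#' Build and validate a pipeline configuration
#'
#' Either `simulate = TRUE` (the default; the well-separated synthetic
#' preset generates all inputs) or explicit input paths. Unknown parameter
#' keys are rejected so typos fail fast.
#'
#' @param out_dir Output directory.
#' @param seed Global seed; each stage derives its own with
#'   [stage_seed()]-style hashing.
#' @param simulate Generate inputs with the synthetic module.
#' @param paths List with `matrix_dir`, `cell_map`, `gmt`, `clonotypes`
#'   (required when `simulate = FALSE`; all must exist).
#' @param params Optional per-stage overrides: `simulate` (forwarded to
#'   [sim_config()]), `score` (`margin`, `n_bins`, `n_ctrl`), `cnmf`
#'   (`k_grid`, `n_restarts`, `k`), `niches` (`eps_um`, `min_samples`,
#'   `min_size`, `coexpr_quantile`, `exhausted_cut`), `enrich` (`n_perm`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            paths = list(), params = list()) {
  known_stages <- c("simulate", "score", "cnmf", "niches", "clones",
                    "assoc", "enrich")
  bad <- setdiff(names(params), known_stages)
  if (length(bad)) {
    stop("unknown parameter blocks: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!simulate) {
    need <- c("matrix_dir", "cell_map", "gmt", "clonotypes")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      stop("paths missing: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(absent)) {
      stop("input paths do not exist: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, paths = paths, params = params),
            class = "pipeline_config")
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes signature scoring, consensus NMF with anchor rankings and
#' enrichment, spatial niche detection/classification with statistics,
#' clonotype analysis and the association models, writing every result as
#' CSV/JSON under `out_dir` and returning a manifest with an MD5 hash per
#' file. A stage failure aborts with the failing stage named; files
#' already written are preserved.
#'
#' @param config A [pipeline_config()].
#' @return Manifest list (also written to `manifest.json`): `seed`,
#'   `stage_seeds`, `files` (name -> md5), `summary` of headline
#'   statistics.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pr <- config$params
  seeds <- vapply(c("simulate", "score", "cnmf", "niches", "clones", "assoc"),
                  function(s) stage_seed(config$seed, s), integer(1))
  files <- character(0)
  summary <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # ---- inputs ----------------------------------------------------------
  signatures <- NULL
  if (config$simulate) {
    stage("simulate", {
      sim_args <- c(list(seed = seeds[["simulate"]]), pr[["simulate"]] %||% list())
      scfg <- do.call(sim_preset,
                      c(list(name = "well_separated"), sim_args))
      sim <- simulate_cd8_counts(scfg)
      clo <- simulate_clonotypes(scfg, sim$truth)
      tis <- simulate_tissue(scfg)
      signatures <- cd8_signatures()
      dir.create(file.path(out, "inputs"), showWarnings = FALSE)
      write_expression(sim$counts, file.path(out, "inputs", "expression"))
      files <- c(files,
                 write_table(sim$truth, file.path(out, "inputs", "truth_cells.csv")),
                 write_table(clo$assignments, file.path(out, "inputs", "clonotypes.csv")),
                 write_table(tis$map, file.path(out, "inputs", "cell_map.csv")),
                 write_gmt(signatures, file.path(out, "inputs", "signatures.gmt")))
      files <- files
      counts <- sim$counts; truth <- sim$truth
      clon_assign <- clo$assignments
      tissue <- tis
    })
  } else {
    stage("inputs", {
      counts <- as_dense(read_expression(config$paths$matrix_dir))
      truth <- NULL
      signatures <- read_gmt(config$paths$gmt)
      clon_assign <- utils::read.csv(config$paths$clonotypes,
                                      stringsAsFactors = FALSE)
      map <- read_cell_map(config$paths$cell_map)
      tissue <- list(map = map, expr = counts, truth = NULL)
    })
  }

  # ---- score -----------------------------------------------------------
  scores <- stage("score", {
    sp <- pr[["score"]] %||% list()
    st <- score_state_table(
      counts, signatures,
      margin = sp[["margin"]] %||% 0,
      label_map = sp[["label_map"]] %||%
        c(stem = "stem-like", cytotoxic = "effector", exhausted = "exhausted"),
      n_bins = sp[["n_bins"]] %||% 25, n_ctrl = sp[["n_ctrl"]] %||% 50,
      seed = seeds[["score"]]
    )
    files <- c(files, write_table(st, file.path(out, "state_scores.csv")))
    files <- files
    st
  })

  # ---- cnmf ------------------------------------------------------------
  stage("cnmf", {
    cp <- pr[["cnmf"]] %||% list()
    fit <- fit_cnmf(lognorm(counts),
                    k_grid = cp[["k_grid"]] %||% 2:6,
                    n_restarts = cp[["n_restarts"]] %||% 10L,
                    seed = seeds[["cnmf"]], k = cp[["k"]])
    mod <- fit$models[[as.character(fit$selected_k)]]
    ep <- pr[["enrich"]] %||% list()
    enr <- list()
    for (anchor in c("CXCL13", "CXCR5")) {
      rk <- anchor_similarity(fit, anchor)
      files <- c(files, write_table(
        rk, file.path(out, sprintf("anchor_ranking_%s.csv", anchor))))
      enr[[anchor]] <- ranked_enrichment_family(
        rk, signatures, n_perm = ep[["n_perm"]] %||% 500L,
        seed = stage_seed(seeds[["cnmf"]], anchor))
      enr[[anchor]]$anchor <- anchor
    }
    enr <- do.call(rbind, enr)
    files <- c(files,
               write_table(as.data.frame(mod$loadings),
                           file.path(out, "cnmf_loadings.csv")),
               write_table(as.data.frame(mod$usages),
                           file.path(out, "cnmf_usages.csv")),
               write_table(enr, file.path(out, "enrichment.csv")))
    files <- files
    summary$cnmf <- list(selected_k = fit$selected_k,
                          error = mod$error, stability = mod$stability)
  })

  # ---- niches ----------------------------------------------------------
  stage("niches", {
    np <- pr[["niches"]] %||% list()
    aggs <- detect_aggregates(tissue$map,
                              eps_um = np[["eps_um"]] %||% 50,
                              min_samples = np[["min_samples"]] %||% 10L,
                              min_size = np[["min_size"]] %||% 20L)
    aggs <- classify_aggregates(aggs, tissue$map, tissue$expr,
                                coexpr_quantile = np[["coexpr_quantile"]] %||% 0.75,
                                exhausted_cut = np[["exhausted_cut"]] %||% 0.4)
    loc <- tumor_vs_stroma_localization(tissue$map, aggs)
    dens <- stromal_density(tissue$map, "CD8 T")
    cd8 <- tissue$map[tissue$map$cell_type == "CD8 T" &
                        !is.na(tissue$map$u), , drop = FALSE]
    stats_json <- list(
      n_aggregates = nrow(aggs$aggregates),
      classes = as.list(table(aggs$aggregates$class_label)),
      cd8_stromal_density_per_mm2 = as.numeric(dens),
      localization = loc
    )
    # transition ECDFs across classes on the latent-coordinate ranks
    cls_of <- stats::setNames(rep(NA_character_, nrow(tissue$map)),
                              tissue$map$cell_id)
    mem <- aggs$membership
    lab <- stats::setNames(
      aggs$aggregates$class_label[match(mem$aggregate_id,
                                        aggs$aggregates$aggregate_id)],
      mem$cell_id)
    cls_of[names(lab)] <- lab
    trans <- (rank(cd8$u) - 0.5) / nrow(cd8)
    by_class <- split(trans, cls_of[cd8$cell_id])
    if (length(by_class) >= 2 && sum(lengths(by_class) >= 10) >= 2) {
      ec <- compare_transition_ecdf(by_class, seed = seeds[["niches"]])
      stats_json$ecdf_ks <- ec$ks
    }
    files <- c(files,
               write_table(aggs$aggregates, file.path(out, "aggregates.csv")),
               write_table(aggs$membership,
                           file.path(out, "aggregate_membership.csv")))
    jsonlite::write_json(stats_json, file.path(out, "spatial_stats.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    files <- c(files, file.path(out, "spatial_stats.json"))
    files <- files
    summary$niches <- list(n_aggregates = nrow(aggs$aggregates),
                           classes = as.list(table(aggs$aggregates$class_label)))
  })

  # ---- clones ----------------------------------------------------------
  stage("clones", {
    ct <- build_clonotypes(clon_assign, scores)
    sc_stat <- stem_content_statistic(ct)
    assoc <- tryCatch(clone_program_association(ct, lognorm(counts)),
                      error = function(e) list(computable = FALSE,
                                               reason = conditionMessage(e)))
    files <- c(files, write_table(ct, file.path(out, "clonotypes_table.csv")))
    jsonlite::write_json(
      list(stem_content = sc_stat[c("computable", "fraction", "n_expanding",
                                    "n_multi_stem", "max_stem_multiplicity")],
           cxcl13_association = assoc[intersect(names(assoc),
                                                c("computable", "tau",
                                                  "p_value", "reason"))]),
      file.path(out, "clone_stats.json"), auto_unbox = TRUE, digits = 10,
      pretty = TRUE)
    files <- c(files, file.path(out, "clone_stats.json"))
    files <- files
    summary$clones <- list(fraction_multi_stem = sc_stat$fraction,
                            n_expanding = sc_stat$n_expanding)
  })

  # ---- assoc -----------------------------------------------------------
  stage("assoc", {
    expr <- lognorm(counts)
    tr <- scores$transition
    kt <- kendall_tau(expr["CXCL13", ], tr)
    qv <- quadratic_vs_linear(tr, expr["CXCL13", ])
    sub <- with_seed(seeds[["assoc"]], {
      sample.int(ncol(counts), min(800L, ncol(counts)))
    })
    zb <- zinb_lrt(round(counts["CXCL13", sub]), cbind(transition = tr[sub]))
    out_stats <- list(
      kendall_cxcl13_vs_transition = kt[c("tau", "p_value")],
      quadratic_vs_linear = qv[c("r2_linear", "r2_quadratic", "lrt", "p_value")],
      zinb_cxcl13 = list(pi = zb$fit_full$pi, theta = zb$fit_full$theta,
                         slope = unname(zb$fit_full$beta["transition"]),
                         lrt = zb$lrt, p_value = zb$p_value)
    )
    jsonlite::write_json(out_stats, file.path(out, "assoc_stats.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    files <- c(files, file.path(out, "assoc_stats.json"))
    files <- files
    summary$assoc <- out_stats
  })

  files <- unique(c(files,
                    file.path(out, "inputs", "expression",
                              c("matrix.mtx", "genes.tsv", "barcodes.tsv"))))
  files <- files[file.exists(files)]
  manifest <- list(
    seed = config$seed,
    stage_seeds = as.list(seeds),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    sub(paste0("^", out, "/?"), "", files))),
    summary = summary
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
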