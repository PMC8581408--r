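#' Pipeline configuration
#'
#' A single object wiring the whole analysis: either a synthetic-study
#' [sim_config()] or paths to a counts TSV and metadata TSV, an optional
#' GMT collection (a toy collection spiked with pool genes is generated
#' when absent), output directory, and the two significance thresholds.
#' One seed governs every stochastic stage.
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()] for a synthetic run, or `NULL` to read
#'   `counts_path`/`metadata_path`.
#' @param counts_path,metadata_path input TSVs (see [read_counts()],
#'   [read_metadata()]); required when `sim` is `NULL`.
#' @param gmt_path optional GMT file for enrichment.
#' @param model_alpha per-model significance threshold on adjusted p
#'   (default 0.05).
#' @param ora_alpha enrichment threshold on adjusted p (default 0.01).
#' @param min_mean minimum-mean count filter passed to [fit_model()].
#' @param n_top_genes top-variance genes for the PCA diagnostic.
#' @param timepoints timepoint levels to enumerate models over.
#' @param seed integer master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, counts_path = NULL,
                            metadata_path = NULL, gmt_path = NULL,
                            model_alpha = 0.05, ora_alpha = 0.01,
                            min_mean = 0, n_top_genes = 500L,
                            timepoints = c("6h", "24h"), seed = 1L) {
  check_number(model_alpha, "model_alpha", lower = 1e-12, upper = 1)
  check_number(ora_alpha, "ora_alpha", lower = 1e-12, upper = 1)
  seed <- check_count(seed, "seed")
  if (is.null(sim)) {
    if (is.null(counts_path) || is.null(metadata_path)) {
      stop_fustx("supply either 'sim' or both 'counts_path' and 'metadata_path'")
    }
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  structure(list(out_dir = out_dir, sim = sim, counts_path = counts_path,
                 metadata_path = metadata_path, gmt_path = gmt_path,
                 model_alpha = model_alpha, ora_alpha = ora_alpha,
                 min_mean = min_mean, n_top_genes = n_top_genes,
                 timepoints = timepoints, seed = seed),
            class = "pipeline_config")
}

write_tsv_stage <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config=%s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (synthetic simulation or TSV
#' reads), CE-MBA collinearity diagnostic, median-of-ratios normalization
#' with the PCA diagnostic, the eight per-gene NB regression models, signed
#' union pooling with exclusive-intersection accounting, and
#' over-representation analysis per pool and direction with redundancy
#' pruning and a gene-concept edge list. All tables are TSV with a
#' `# config=<hash>` provenance header; a JSON run manifest records the
#' configuration, seed, and per-stage row counts. Rerunning with an
#' identical configuration reproduces identical outputs. Any stage error
#' aborts with the stage name.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  # fingerprint the analysis parameters only: where outputs land must not
  # change what they contain
  hash <- fnv1a_hash(unclass(cfg)[setdiff(names(unclass(cfg)), "out_dir")])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = hash, seed = cfg$seed,
                   r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("fustx")),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop_fustx(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)))
    })
  }

  # -- inputs ----------------------------------------------------------
  inputs <- stage("inputs", {
    if (!is.null(cfg$sim)) {
      sim <- cfg$sim
      met <- simulate_metrics(sim)
      counts <- simulate_counts(met$truth, sim, met$samples)
      list(counts = counts, samples = met$samples, truth = met$truth)
    } else {
      for (p in c(cfg$counts_path, cfg$metadata_path)) {
        if (!file.exists(p)) stop_fustx("missing input file: ", p)
      }
      list(counts = read_counts(cfg$counts_path),
           samples = read_metadata(cfg$metadata_path), truth = NULL)
    }
  })
  counts <- drop_zero_genes(inputs$counts, quiet = TRUE)
  samples <- inputs$samples
  manifest$stages$inputs <- list(n_genes = nrow(counts),
                                 n_samples = nrow(samples),
                                 n_zero_genes_dropped =
                                   nrow(inputs$counts) - nrow(counts))

  # -- diagnostics -----------------------------------------------------
  col_rep <- stage("collinearity", collinearity(samples))
  jsonlite::write_json(unclass(col_rep),
                       file.path(cfg$out_dir, "collinearity.json"),
                       auto_unbox = TRUE, digits = NA)
  sf <- stage("normalization", size_factors(counts))
  write_tsv_stage(data.frame(sample_id = names(sf), size_factor = sf),
                  file.path(cfg$out_dir, "size_factors.tsv"), hash)
  pca <- stage("pca", vst_pca(counts, sf, n_top_genes = cfg$n_top_genes))
  write_tsv_stage(data.frame(sample_id = rownames(pca$x), pca$x),
                  file.path(cfg$out_dir, "pca.tsv"), hash)
  manifest$stages$diagnostics <- list(
    r_squared = col_rep$r_squared, vif = col_rep$vif,
    pc1_explained = pca$explained[1])

  # -- models ----------------------------------------------------------
  specs <- model_specs(timepoints = cfg$timepoints,
                       alpha_threshold = cfg$model_alpha)
  fits <- stage("models", run_models(counts, samples, specs,
                                     min_mean = cfg$min_mean))
  fit_dir <- file.path(cfg$out_dir, "fits")
  dir.create(fit_dir, showWarnings = FALSE)
  for (nm in names(fits)) {
    write_tsv_stage(as.data.frame(fits[[nm]]),
                    file.path(fit_dir, paste0(nm, ".tsv")), hash)
  }
  manifest$stages$models <- list(
    n_models = length(fits),
    n_significant = lapply(fits, function(f) length(significant_genes(f))))

  # -- pooling ---------------------------------------------------------
  pools <- stage("pooling", make_pools(fits, alpha = cfg$model_alpha))
  pool_df <- do.call(rbind, lapply(names(pools), function(k) {
    data.frame(pool = k, pools[[k]], stringsAsFactors = FALSE)
  })) %||% data.frame(pool = character(), gene = character(),
                      sign = character(), best_padj = numeric())
  write_tsv_stage(pool_df, file.path(cfg$out_dir, "pools.tsv"), hash)
  ups_pos <- upset_intersections(pools, "+")
  ups_neg <- upset_intersections(pools, "-")
  write_tsv_stage(ups_pos, file.path(cfg$out_dir, "intersections_pos.tsv"),
                  hash)
  write_tsv_stage(ups_neg, file.path(cfg$out_dir, "intersections_neg.tsv"),
                  hash)
  manifest$stages$pooling <- list(
    n_pools = length(pools),
    pool_sizes = lapply(pools, nrow),
    union_pos = sum(ups_pos$exclusive_count),
    union_neg = sum(ups_neg$exclusive_count))

  # -- enrichment ------------------------------------------------------
  collection <- stage("gene_sets", {
    if (!is.null(cfg$gmt_path)) {
      if (!file.exists(cfg$gmt_path)) {
        stop_fustx("missing input file: ", cfg$gmt_path)
      }
      read_gmt(cfg$gmt_path)
    } else {
      # toy collection drawn from the analysed gene universe so ORA has
      # sets to test on synthetic runs
      make_toy_gmt(50L, c(10L, 200L), universe = rownames(counts),
                   seed = cfg$seed + 2L)
    }
  })
  ora_dir <- file.path(cfg$out_dir, "ora")
  dir.create(ora_dir, showWarnings = FALSE)
  n_ora <- 0L
  net_all <- list()
  for (k in names(pools)) {
    universe <- attr(pools[[k]], "universe")
    for (d in c("pos", "neg")) {
      sgn <- if (d == "pos") "+" else "-"
      query <- pools[[k]]$gene[pools[[k]]$sign == sgn]
      tab <- stage(paste0("ora_", k, "_", d), {
        res <- suppressWarnings(ora(query, universe, collection,
                                    alpha = cfg$ora_alpha))
        prune_redundant(res, collection, universe = universe)
      })
      write_tsv_stage(as.data.frame(tab),
                      file.path(ora_dir, paste0(k, "_", d, ".tsv")), hash)
      n_ora <- n_ora + 1L
      if (nrow(tab)) {
        net <- concept_network(tab, pools, top_k = 5L)
        if (nrow(net)) {
          net_all[[paste(k, d)]] <- data.frame(pool = k, direction = sgn,
                                               net,
                                               stringsAsFactors = FALSE)
        }
      }
    }
  }
  net_df <- do.call(rbind, net_all) %||%
    data.frame(pool = character(), direction = character(),
               set = character(), gene = character(), pools = character(),
               n_pools = integer())
  rownames(net_df) <- NULL
  write_tsv_stage(net_df, file.path(cfg$out_dir, "concept_network.tsv"),
                  hash)
  manifest$stages$enrichment <- list(n_ora_tables = n_ora,
                                     n_network_edges = nrow(net_df))

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
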