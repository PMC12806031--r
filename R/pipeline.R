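#' Run the full glucose-flux analysis pipeline
#'
#' Orchestrates every stage end to end: differential expression -> gene
#' weights -> enzyme-activity proxy -> efficiency NNLS (+ EC-class
#' validation) -> ssGSEA capacity bounds -> per-sample flux QP -> lactate
#' fate partition -> proton ledger -> backdoor causal analysis -> signature
#' regressions -> polynomial glucose-import model. Stages whose inputs are
#' not provided (e.g. no Fenton gene set) are skipped; a stage failure marks
#' that stage failed and skips everything downstream of it.
#'
#' @param expression Gene-by-sample matrix (or data frame) of log2(TPM+1).
#' @param metadata Tibble with columns `sample_id`, `group`
#'   (`"tumor"`/`"normal"`) and optionally `stage`.
#' @param network A [glc_network].
#' @param priors Prior table (`reaction_id`, `eff0`, `source`) or TSV path.
#' @param gene_sets Named list of gene sets: one per sink pathway of the
#'   network, plus optionally `lactate_export`, `lactylation`,
#'   `fenton_reaction`, `migration`, `proliferation_signature`.
#' @param config A [flux_config()].
#' @param out_dir Optional output directory; when given, every table is
#'   written as TSV/JSON and the effective config as YAML, and the run
#'   report lists the file manifest.
#' @return A list of class `glc_run` with the per-stage results (`de`,
#'   `weights`, `activity`, `efficiencies`, `ec_test`, `scores`,
#'   `allocation`, `allocation_by_stage`, `lactate`, `proton`,
#'   `proton_by_stage`, `causal`, `signatures`, `import_model`) and a
#'   `report` tibble (stage, status, seconds).
#' @export
run_pipeline <- function(expression, metadata, network, priors, gene_sets,
                         config = flux_config(), out_dir = NULL) {
  expr <- as_expression_matrix(expression)
  metadata <- as_tibble(metadata)
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    abort("`metadata` needs columns sample_id and group.",
          class = "glucoflux_schema_error")
  }
  if (!"stage" %in% names(metadata)) metadata$stage <- NA_character_
  missing_sets <- setdiff(network$sink_pathways, names(gene_sets))
  if (length(missing_sets) > 0) {
    abort(paste("No gene set for sink pathway(s):",
                paste(missing_sets, collapse = ", ")),
          class = "glucoflux_schema_error")
  }
  expr <- expr[, metadata$sample_id, drop = FALSE]
  groups <- metadata$group
  tumor_ids <- metadata$sample_id[groups == "tumor"]
  expr_t <- expr[, tumor_ids, drop = FALSE]

  results <- list()
  report <- list()
  failed <- FALSE
  stage <- function(name, enabled, fun) {
    if (failed) {
      report[[length(report) + 1]] <<- tibble(stage = name,
                                              status = "skipped",
                                              seconds = NA_real_)
      return(invisible(NULL))
    }
    if (!enabled) {
      report[[length(report) + 1]] <<- tibble(stage = name,
                                              status = "not_requested",
                                              seconds = NA_real_)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failed <<- TRUE
      report[[length(report) + 1]] <<- tibble(stage = name,
                                              status = "failed",
                                              seconds = dt)
      warn(sprintf("Stage '%s' failed: %s", name, conditionMessage(res)))
      res <- NULL
    } else {
      report[[length(report) + 1]] <<- tibble(stage = name, status = "ok",
                                              seconds = dt)
    }
    res
  }

  de <- stage("differential_expression", TRUE, function() {
    differential_expression(expr, groups,
                            p_adj_threshold = config$p_adj_threshold)
  })
  weights <- stage("gene_weights", TRUE, function() {
    gene_weights(de, gamma = config$gamma, eta = config$eta)
  })
  E <- stage("activity_matrix", TRUE, function() {
    activity_matrix(expr_t, network, weights, scale = config$activity_scale)
  })
  eff <- stage("efficiency_nnls", TRUE, function() {
    pr <- assemble_priors(priors, network$reactions$id,
                          lambda = config$lambda_nnls)
    estimate_efficiencies(network, E, pr)
  })
  ec_test <- stage("ec_validation", TRUE, function() {
    tryCatch(ec_class_validation(eff, network),
             glucoflux_insufficient_groups = function(e) NULL)
  })
  scores <- stage("ssgsea_scores", TRUE, function() {
    ssgsea_matrix(expr_t, gene_sets[network$sink_pathways],
                  exponent = config$ssgsea_exponent)
  })
  allocation <- stage("flux_allocation", TRUE, function() {
    G <- pathway_activity_score(scores)
    drains <- sink_reactions(network)
    eff_sink <- setNames(eff$eff[match(drains, eff$reaction_id)],
                         names(drains))
    bounds <- compute_flux_bounds(G, eff_sink)
    influx <- glucose_influx(expr_t)
    allocate_fluxes(network, bounds, influx, lambda_qp = config$lambda_qp)
  })
  allocation_by_stage <- stage("allocation_table", TRUE, function() {
    allocation_fractions(allocation, metadata, by = "stage")
  })
  lactate <- stage(
    "lactate_partition",
    all(c("lactate_export", "lactylation") %in% names(gene_sets)) &&
      "lactate" %in% network$sink_pathways,
    function() {
      s <- ssgsea_matrix(expr_t,
                         gene_sets[c("lactate_export", "lactylation")],
                         exponent = config$ssgsea_exponent)
      s <- s - min(s) # shift nonnegative before log compression
      w <- lactate_fate_weights(s["lactate_export", ], s["lactylation", ],
                                tau = config$tau, alpha = config$alpha)
      v_lac <- allocation$flux[allocation$pathway == "lactate"]
      lam <- config$lambda_qp %||% (1 / (2 * mean(allocation$bound)))
      part <- partition_lactate(v_lac, w, lambda_qp = lam)
      dplyr::bind_cols(
        tibble(sample = allocation$sample[allocation$pathway == "lactate"]),
        part, w[, c("w_export", "w_lactylation")])
    })
  proton <- stage("proton_ledger", TRUE, function() {
    proton_ledger(allocation, network)
  })
  proton_by_stage <- stage("proton_table", TRUE, function() {
    df <- left_join(proton, metadata, by = c(sample = "sample_id"))
    df <- group_by(df, .data$stage, .data$pathway)
    out <- summarise(df,
                     mean_production_fraction = mean(.data$production_fraction),
                     .groups = "drop")
    out$mean_percent <- 100 * out$mean_production_fraction
    out
  })
  causal <- stage(
    "causal_inference",
    "proliferation_signature" %in% names(gene_sets) &&
      "nucleotide_synthesis" %in% names(gene_sets) &&
      "MKI67" %in% rownames(expr),
    function() {
      triple <- construct_causal_variables(
        expr_t, de,
        nucleotide_genes = gene_sets$nucleotide_synthesis,
        proliferation_genes = gene_sets$proliferation_signature,
        exponent = config$ssgsea_exponent)
      est <- estimate_ate(triple)
      est$permutation_p <- as.numeric(
        permutation_test(triple, n_perm = config$n_perm,
                         seed = config$seed))
      est$refutation_curve <- refute_with_latent_confounder(
        triple, seed = config$seed)
      list(triple = triple, estimate = est,
           partial = partial_regression(triple))
    })
  signatures <- stage(
    "signature_regressions",
    "MKI67" %in% rownames(expr) || "fenton_reaction" %in% names(gene_sets),
    function() {
      out <- list()
      if ("nucleotide_synthesis" %in% names(gene_sets) &&
          "MKI67" %in% rownames(expr)) {
        gs <- intersect(gene_sets$nucleotide_synthesis, rownames(expr_t))
        pls <- fit_pls(t(expr_t[gs, , drop = FALSE]), expr_t["MKI67", ],
                       k = config$pls_components)
        out$proliferation <- score_signature_regression(pls,
                                                        expr_t["MKI67", ])
      }
      if (all(c("migration", "sialic_acid") %in% names(gene_sets)) &&
          "sialic_acid" %in% network$sink_pathways) {
        gs <- intersect(gene_sets$sialic_acid, rownames(expr_t))
        mig <- migration_outcome(expr_t, gene_sets$migration)
        pls <- fit_pls(t(expr_t[gs, , drop = FALSE]), mig,
                       k = config$pls_components)
        out$migration <- score_signature_regression(pls, mig)
      }
      if ("fenton_reaction" %in% names(gene_sets)) {
        out$fenton <- fenton_neutralization_fit(
          expr_t, gene_sets$fenton_reaction,
          gene_sets[network$sink_pathways])
      }
      out
    })
  import_model <- stage("glucose_import_model", TRUE, function() {
    feats <- vapply(network$sink_pathways, function(p) {
      coexpression_hub_feature(expr_t, gene_sets[[p]],
                               r_threshold = config$r_threshold)$feature
    }, numeric(ncol(expr_t)))
    transporters <- intersect(
      c("SLC2A1", "SLC2A3", "SLC5A1", "SLC5A2", "SLC2A10"), rownames(expr_t))
    if (length(transporters) == 0) return(NULL)
    response <- colMeans(expr_t[transporters, , drop = FALSE])
    forward_polynomial_fit(feats, response, degree = config$poly_degree,
                           r2_stop = config$r2_stop,
                           max_features = config$max_features)
  })

  report <- bind_rows(report)
  run <- structure(list(
    de = de, weights = weights, activity = E, efficiencies = eff,
    ec_test = ec_test, scores = scores, allocation = allocation,
    allocation_by_stage = allocation_by_stage, lactate = lactate,
    proton = proton, proton_by_stage = proton_by_stage, causal = causal,
    signatures = signatures, import_model = import_model,
    config = config, report = report
  ), class = "glc_run")

  if (!is.null(out_dir)) {
    run$manifest <- write_run_outputs(run, out_dir)
  }
  run
}

#' @export
print.glc_run <- function(x, ...) {
  cat("<glc_run>\n")
  print(x$report)
  invisible(x)
}

# Write every tabular result of a run; returns the file manifest.
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_tsv <- function(obj, name) {
    if (is.null(obj)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    readr::write_tsv(as_tibble(obj), path)
    files <<- c(files, path)
  }
  put_tsv(run$de, "differential_expression.tsv")
  put_tsv(run$efficiencies, "efficiencies.tsv")
  put_tsv(run$allocation, "allocation.tsv")
  put_tsv(run$allocation_by_stage, "allocation_by_stage.tsv")
  put_tsv(run$lactate, "lactate_partition.tsv")
  put_tsv(run$proton, "proton_ledger.tsv")
  put_tsv(run$proton_by_stage, "proton_by_stage.tsv")
  if (!is.null(run$causal)) {
    est <- run$causal$estimate
    path <- file.path(out_dir, "causal.json")
    jsonlite::write_json(
      list(ate = est$ate, beta_w = est$beta_w, intercept = est$intercept,
           unadjusted = est$unadjusted, permutation_p = est$permutation_p,
           refutation_curve = est$refutation_curve),
      path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path)
    put_tsv(run$causal$partial, "partial_regression.tsv")
  }
  if (!is.null(run$signatures) && length(run$signatures) > 0) {
    path <- file.path(out_dir, "signatures.json")
    jsonlite::write_json(
      lapply(run$signatures, function(f) {
        list(r2 = f$r2, sigma = f$sigma,
             coefficients = as.list(coef(f$model)))
      }),
      path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path)
  }
  if (!is.null(run$import_model)) {
    put_tsv(tidy(run$import_model), "glucose_import_model.tsv")
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_flux_config(run$config, cfg_path)
  files <- c(files, cfg_path)
  rep_path <- file.path(out_dir, "run_report.tsv")
  readr::write_tsv(run$report, rep_path)
  files <- c(files, rep_path)
  files
}

#' Run the pipeline from input files
#'
#' Thin file-based wrapper around [run_pipeline()]: reads the expression
#' TSV (gene rows, sample columns), metadata TSV, network JSON, priors TSV
#' and one or more GMT gene-set files, then delegates.
#'
#' @param expression_file,metadata_file,network_file,priors_file Input
#'   paths.
#' @param gene_set_files Character vector of GMT paths (sets are merged).
#' @param config_file Optional YAML config path.
#' @param out_dir Output directory.
#' @return The `glc_run` object, invisibly.
#' @export
run_pipeline_files <- function(expression_file, metadata_file, network_file,
                               priors_file, gene_set_files,
                               config_file = NULL, out_dir = NULL) {
  for (f in c(expression_file, metadata_file, network_file, priors_file,
              gene_set_files, config_file)) {
    if (!is.null(f) && !file.exists(f)) {
      abort(sprintf("Input file not found: %s", f),
            class = "glucoflux_io_error")
    }
  }
  expr <- readr::read_tsv(expression_file, show_col_types = FALSE)
  metadata <- readr::read_tsv(metadata_file, show_col_types = FALSE)
  network <- read_network(network_file)
  gene_sets <- do.call(c, lapply(gene_set_files, read_gmt))
  config <- if (is.null(config_file)) flux_config() else {
    read_flux_config(config_file)
  }
  invisible(run_pipeline(expr, metadata, network, priors_file, gene_sets,
                         config, out_dir = out_dir))
}
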