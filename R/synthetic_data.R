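#' Simulation configuration for synthetic cohorts
#'
#' Bundles every tunable of the synthetic-data generator. Expression noise is
#' Gaussian on the log2 scale (i.e. log-normal TPM), matching the log2-TPM
#' working scale of the analysis. Sample-level latent effects (shared
#' metabolic activation, proliferation, nucleotide-synthesis activity,
#' lactate export/lactylation activity) are drawn per tumor sample and
#' empirically centered, so the zero-noise limit reproduces planted fold
#' changes exactly.
#'
#' @param n_tumor,n_normal Number of tumor / normal samples (each >= 2).
#' @param n_genes Total gene universe size; must cover the genes demanded by
#'   the network, the pathway marker sets and the phenotype gene sets.
#' @param noise_sd SD of iid Gaussian expression noise, log2 units (> 0).
#' @param activation_sd SD of the shared per-tumor-sample metabolic
#'   activation effect applied to all sink-pathway marker genes. This is what
#'   makes ssGSEA-derived capacity bounds co-vary across pathways within a
#'   sample, as overall metabolic activation does in tumors.
#' @param lfc_network Planted log2 fold change (tumor vs normal) of all
#'   network enzyme and transporter genes.
#' @param lfc_markers Planted log2 fold change of pathway marker genes.
#' @param planted_log2fc Optional named numeric vector of per-gene planted
#'   log2 fold changes for background genes; by default 10% of background
#'   genes receive fold changes of random sign and magnitude 0.5-2.
#' @param planted_fluxes,planted_efficiencies Optional named overrides of the
#'   network's planted sink fluxes / reaction efficiencies.
#' @param causal_beta,confounding_a,confounding_b Structural coefficients of
#'   the planted proliferation confounding model: the proliferation latent W
#'   drives the nucleotide latent (`confounding_a`) and the MKI67 outcome
#'   (`confounding_b`); `causal_beta` is the direct nucleotide -> MKI67
#'   effect, all on the latent scale.
#' @param markers_per_pathway Marker genes per sink-pathway gene set.
#' @param seed Master integer seed; all randomness derives from it.
#' @return A list of class `glc_sim_config`.
#' @export
sim_config <- function(n_tumor = 60, n_normal = 40, n_genes = 600,
                       noise_sd = 0.5, activation_sd = 0.5,
                       lfc_network = 1.0, lfc_markers = 0.8,
                       planted_log2fc = NULL,
                       planted_fluxes = NULL, planted_efficiencies = NULL,
                       causal_beta = 0.5, confounding_a = 0.8,
                       confounding_b = 0.6,
                       markers_per_pathway = 10, seed = 1) {
  cfg <- list(
    n_tumor = assert_count(n_tumor, "n_tumor", 2),
    n_normal = assert_count(n_normal, "n_normal", 2),
    n_genes = assert_count(n_genes, "n_genes", 1),
    noise_sd = assert_scalar(noise_sd, "noise_sd", 0, open_lower = TRUE),
    activation_sd = assert_scalar(activation_sd, "activation_sd", 0),
    lfc_network = assert_scalar(lfc_network, "lfc_network"),
    lfc_markers = assert_scalar(lfc_markers, "lfc_markers"),
    planted_log2fc = planted_log2fc,
    planted_fluxes = planted_fluxes,
    planted_efficiencies = planted_efficiencies,
    causal_beta = assert_scalar(causal_beta, "causal_beta"),
    confounding_a = assert_scalar(confounding_a, "confounding_a"),
    confounding_b = assert_scalar(confounding_b, "confounding_b"),
    markers_per_pathway = assert_count(markers_per_pathway,
                                       "markers_per_pathway", 3),
    seed = assert_count(seed, "seed", 0)
  )
  structure(cfg, class = "glc_sim_config")
}

canonical_sink_pathways <- function(n_sinks) {
  base <- c("nucleotide_synthesis", "lactate", "glycosylation",
            "sialic_acid", "lipid_synthesis", "serine_synthesis",
            "ganglioside_synthesis", "tca_cycle")
  if (n_sinks <= length(base)) {
    base[seq_len(n_sinks)]
  } else {
    c(base, paste0("sink_pathway_", seq(length(base) + 1, n_sinks)))
  }
}

# Default planted allocation fractions. For the canonical 8-sink network the
# ordering puts nucleotide synthesis first (the dominant sink in tumors);
# for other sizes a decreasing (n:1) profile is used.
default_fractions <- function(n_sinks) {
  if (n_sinks == 8) {
    f <- c(0.28, 0.18, 0.14, 0.11, 0.09, 0.08, 0.07, 0.05)
  } else {
    f <- seq(n_sinks, 1) / sum(seq_len(n_sinks))
  }
  f
}

#' Simulate a source-to-sink stoichiometric network with planted truth
#'
#' Generates an acyclic glucose-centric network: a single uptake reaction
#' (glucose transporters), a backbone chain of internal transit metabolites,
#' and one terminal drain per sink pathway attached to a backbone position.
#' A flux vector satisfying all mass-balance constraints is planted by
#' construction, together with per-reaction catalytic efficiencies. Sink
#' efficiencies are planted as flux / activity with a common activity scale,
#' so the allocation signal lives in the efficiencies exactly as the
#' downstream estimator assumes.
#'
#' @param n_internal_mets Number of internal transit metabolites (>= 1).
#' @param n_sinks Number of sink pathways (>= 2).
#' @param seed Integer seed; identical seeds give identical networks.
#' @param total_influx Planted glucose influx (arbitrary units).
#' @param fractions Optional planted sink allocation fractions (length
#'   `n_sinks`, summing to 1).
#' @return A list with elements `network` (a [glc_network]) and `truth`
#'   (planted `flux`, `eff`, `activity` per reaction, `fractions` per sink).
#'   The truth is also attached to the network as attribute `sim_truth`.
#' @export
simulate_network <- function(n_internal_mets = 10, n_sinks = 8, seed = 1,
                             total_influx = 100, fractions = NULL) {
  n_internal_mets <- assert_count(n_internal_mets, "n_internal_mets", 1)
  n_sinks <- assert_count(n_sinks, "n_sinks", 2)
  total_influx <- assert_scalar(total_influx, "total_influx", 0,
                                open_lower = TRUE)
  pathways <- canonical_sink_pathways(n_sinks)
  f <- fractions %||% default_fractions(n_sinks)
  if (length(f) != n_sinks || any(f < 0) || abs(sum(f) - 1) > 1e-8) {
    abort("`fractions` must be length n_sinks, nonnegative, summing to 1.",
          class = "glucoflux_invalid_config")
  }

  with_seed(child_seed(seed, 1), {
    k <- n_internal_mets
    mets <- tibble(
      id = c("glc", paste0("imet", seq_len(k))),
      name = c("imported glucose", paste0("transit metabolite ", seq_len(k))),
      role = c("source", rep("internal", k))
    )
    # sink attachment positions along the backbone; the last backbone node
    # always carries a sink so every chain edge conducts positive flux
    pos <- c(if (n_sinks > 1) sample.int(k, n_sinks - 1, replace = TRUE), k)

    v_sink <- f * total_influx
    uptake_capacity_factor <- 4 # transporter activity relative to influx
    sink_activity <- 2          # common sink-drain activity scale

    rxn_rows <- list()
    add_rxn <- function(id, stoich, pathway, genes, ec, hr, flux, activity) {
      rxn_rows[[length(rxn_rows) + 1]] <<- tibble(
        id = id, pathway = pathway, stoichiometry = list(stoich),
        ec = list(ec), genes = list(genes), proton_coefficient = hr,
        flux = flux, activity = activity)
    }
    transporters <- c("SLC2A1", "SLC2A3", "SLC5A1", "SLC5A2", "SLC2A10")
    add_rxn("r_uptake", c(glc = -1, imet1 = 1), "internal", transporters,
            "7.5.2.2", hr = 0, flux = total_influx,
            activity = uptake_capacity_factor * total_influx)
    if (k > 1) {
      for (j in seq_len(k - 1)) {
        st <- setNames(c(-1, 1), c(paste0("imet", j), paste0("imet", j + 1)))
        ng <- sample(1:3, 1)
        add_rxn(paste0("r_chain", j), st, "internal",
                paste0("GCH", j, letters[seq_len(ng)]),
                sprintf("%d.%d.1.%d", sample(1:6, 1), sample(1:9, 1), j),
                hr = sample(-1:2, 1),
                flux = sum(v_sink[pos > j]),
                activity = stats::rlnorm(1, log(2), 0.3))
      }
    }
    # planted proton coefficients: nucleotide synthesis nets 8 protons per
    # unit flux (purine synthesis), lactate 1, lipid synthesis consumes 1
    hr_sink <- setNames(sample(0:3, n_sinks, replace = TRUE), pathways)
    if ("nucleotide_synthesis" %in% pathways) hr_sink["nucleotide_synthesis"] <- 8
    if ("lactate" %in% pathways) hr_sink["lactate"] <- 1
    if ("lipid_synthesis" %in% pathways) hr_sink["lipid_synthesis"] <- -1
    for (s in seq_len(n_sinks)) {
      st <- setNames(-1, paste0("imet", pos[s]))
      ng <- sample(1:3, 1)
      add_rxn(paste0("r_sink_", pathways[s]), st, pathways[s],
              paste0("GSK", s, letters[seq_len(ng)]),
              sprintf("%d.%d.%d.%d", sample(1:6, 1), sample(1:9, 1),
                      sample(1:9, 1), s),
              hr = unname(hr_sink[s]),
              flux = v_sink[s], activity = sink_activity)
    }
    rxns <- bind_rows(rxn_rows)
    # efficiency = flux / activity, so flux = eff * activity holds exactly
    eff <- rxns$flux / rxns$activity

    if (!is.null(attr(f, "names"))) names(v_sink) <- names(f)
    network <- glc_network(mets,
                           rxns[, c("id", "pathway", "stoichiometry", "ec",
                                    "genes", "proton_coefficient")])
    truth <- structure(list(
      flux = tibble(reaction = rxns$id, pathway = rxns$pathway,
                    flux = rxns$flux),
      eff = tibble(reaction = rxns$id, eff = eff),
      activity = tibble(reaction = rxns$id, activity = rxns$activity),
      fractions = tibble(pathway = pathways, fraction = f),
      total_influx = total_influx,
      sink_positions = setNames(pos, pathways)
    ), class = "glc_sim_truth")
    attr(network, "sim_truth") <- truth
    list(network = network, truth = truth)
  })
}

#' Simulate a two-group expression cohort consistent with a planted network
#'
#' Generates log2(TPM + 1) expression for tumor and normal samples such that
#' every downstream stage can recover its planted parameters: network enzyme
#' genes carry expression proportional to planted flux / planted efficiency
#' (so catalytic efficiencies are identifiable), sink-pathway marker sets
#' share a per-sample metabolic activation effect (so ssGSEA-derived
#' capacity bounds co-vary within a sample), a proliferation/nucleotide
#' latent model with confounding drives the MKI67 outcome, and background
#' genes carry planted differential-expression fold changes.
#'
#' @param network A `glc_network` produced by [simulate_network()] (carrying
#'   its planted truth), or any network if `config` supplies
#'   `planted_fluxes` and `planted_efficiencies`.
#' @param config A [sim_config()].
#' @return A list with `expression` (gene-by-sample matrix of log2(TPM+1)),
#'   `metadata` (tibble: sample_id, group, stage), `gene_sets` (named list of
#'   gene-id vectors: one per sink pathway plus lactate_export, lactylation,
#'   fenton_reaction, migration, proliferation_signature), and `truth`
#'   (planted per-gene log2 fold changes, efficiencies, fluxes, fractions,
#'   and the latent causal coefficients).
#' @export
simulate_cohort <- function(network, config = sim_config()) {
  if (!inherits(config, "glc_sim_config")) {
    abort("`config` must be created with sim_config().",
          class = "glucoflux_invalid_config")
  }
  truth <- attr(network, "sim_truth")
  if (is.null(truth)) {
    abort("`network` carries no planted truth; use simulate_network().",
          class = "glucoflux_invalid_config")
  }
  act <- setNames(truth$activity$activity, truth$activity$reaction)
  flux <- setNames(truth$flux$flux, truth$flux$reaction)
  eff <- setNames(truth$eff$eff, truth$eff$reaction)
  if (!is.null(config$planted_fluxes)) flux[names(config$planted_fluxes)] <- config$planted_fluxes
  if (!is.null(config$planted_efficiencies)) eff[names(config$planted_efficiencies)] <- config$planted_efficiencies

  pathways <- network$sink_pathways
  rxns <- network$reactions
  n_t <- config$n_tumor
  n_n <- config$n_normal
  n <- n_t + n_n

  # ---- gene universe -------------------------------------------------------
  net_genes <- network_genes(network)
  markers <- lapply(pathways, function(p) {
    paste0("MK_", toupper(substr(p, 1, 4)), "_", seq_len(config$markers_per_pathway))
  })
  names(markers) <- pathways
  export_genes <- paste0("LEXP", 1:8)
  lactyl_genes <- paste0("LACT", 1:8)
  fenton_genes <- paste0("FENT", 1:10)
  migration_genes <- paste0("MIGR", 1:10)
  prolif_genes <- paste0("PROL", 1:30)
  special <- c(net_genes, unlist(markers), export_genes, lactyl_genes,
               fenton_genes, migration_genes, prolif_genes, "MKI67")
  if (anyDuplicated(special)) {
    abort("internal: duplicated gene ids in the synthetic universe.")
  }
  n_bg <- config$n_genes - length(special)
  if (n_bg < 0) {
    abort(sprintf("n_genes = %d is smaller than the %d genes demanded by the network and gene sets.",
                  config$n_genes, length(special)),
          class = "glucoflux_invalid_config")
  }
  bg_genes <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character(0)
  genes <- c(special, bg_genes)

  with_seed(child_seed(config$seed, 2), {
    # ---- per-gene tumor-mean baselines and planted fold changes -----------
    base <- setNames(numeric(length(genes)), genes)
    lfc <- setNames(numeric(length(genes)), genes)

    for (j in seq_len(nrow(rxns))) {
      gs <- rxns$genes[[j]]
      tpm_per_gene <- act[rxns$id[j]] / length(gs)
      base[gs] <- log2(tpm_per_gene + 1)
      lfc[gs] <- config$lfc_network
    }
    for (p in pathways) {
      base[markers[[p]]] <- rnorm(length(markers[[p]]), 7, 1)
      lfc[markers[[p]]] <- config$lfc_markers
    }
    for (gs in list(export_genes, lactyl_genes, fenton_genes,
                    migration_genes)) {
      base[gs] <- rnorm(length(gs), 6, 1)
      lfc[gs] <- 0.7
    }
    base[prolif_genes] <- rnorm(length(prolif_genes), 6, 1)
    lfc[prolif_genes] <- 0.6
    base["MKI67"] <- 6
    lfc["MKI67"] <- 0.5
    if (n_bg > 0) {
      base[bg_genes] <- rnorm(n_bg, 5, 1.5)
      n_de <- ceiling(0.1 * n_bg)
      de_idx <- sample(bg_genes, n_de)
      lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
        stats::runif(n_de, 0.5, 2)
    }
    if (!is.null(config$planted_log2fc)) {
      lfc[names(config$planted_log2fc)] <- config$planted_log2fc
    }

    # ---- per-tumor-sample latent effects (empirically centered) -----------
    centered <- function(x) x - mean(x)
    delta <- centered(rnorm(n_t, 0, config$activation_sd)) # shared activation
    idio <- lapply(pathways, function(p) centered(rnorm(n_t, 0, 1)))
    names(idio) <- pathways
    p_lat <- centered(rnorm(n_t))                      # proliferation W
    n_lat <- config$confounding_a * p_lat + centered(rnorm(n_t)) # nucleotide T
    e_lat <- centered(rnorm(n_t, 0, 0.7))              # lactate export
    l_lat <- centered(rnorm(n_t, 0, 0.7))              # lactylation

    # ---- assemble the matrix ----------------------------------------------
    expr <- matrix(rnorm(length(genes) * n, 0, config$noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes,
                                   c(sprintf("T%03d", seq_len(n_t)),
                                     sprintf("N%03d", seq_len(n_n)))))
    tum <- seq_len(n_t)
    nor <- n_t + seq_len(n_n)
    expr <- expr + base                       # tumor-mean baseline
    expr[, nor] <- expr[, nor] - lfc          # normals shifted down by lfc

    add_tumor_effect <- function(gs, effect) {
      expr[gs, tum] <<- expr[gs, tum] + rep(effect, each = length(gs))
    }
    for (p in pathways) {
      add_tumor_effect(markers[[p]], delta + 0.2 * idio[[p]])
    }
    # metabolic activation also drives glucose uptake, so the import
    # regression has a recoverable signal
    src_met <- network$metabolites$id[network$metabolites$role == "source"]
    uptake_genes <- rxns$genes[[which(map_lgl(rxns$stoichiometry,
                                              function(st) isTRUE(st[src_met] < 0)))]]
    add_tumor_effect(uptake_genes, 0.5 * delta)
    add_tumor_effect(markers[[pathways[1]]], 0.4 * n_lat) # nucleotide latent
    add_tumor_effect(prolif_genes, 0.8 * p_lat)
    add_tumor_effect(export_genes, e_lat)
    add_tumor_effect(lactyl_genes, l_lat)
    add_tumor_effect(fenton_genes, 0.8 * delta)
    sia <- if ("sialic_acid" %in% pathways) {
      delta + 0.2 * idio[["sialic_acid"]]
    } else {
      delta
    }
    add_tumor_effect(migration_genes, 0.6 * sia)
    expr["MKI67", tum] <- expr["MKI67", tum] +
      0.4 * (config$causal_beta * n_lat + config$confounding_b * p_lat)

    metadata <- tibble(
      sample_id = colnames(expr),
      group = c(rep("tumor", n_t), rep("normal", n_n)),
      stage = c(sample(c("I", "II", "III", "IV"), n_t, replace = TRUE),
                rep(NA_character_, n_n))
    )

    gene_sets <- c(markers,
                   list(lactate_export = export_genes,
                        lactylation = lactyl_genes,
                        fenton_reaction = fenton_genes,
                        migration = migration_genes,
                        proliferation_signature = prolif_genes))

    cohort_truth <- structure(list(
      true_log2fc = tibble(gene = genes, log2fc = unname(lfc)),
      true_eff = truth$eff,
      true_flux = truth$flux,
      true_fractions = truth$fractions,
      total_influx = truth$total_influx,
      causal = list(beta = config$causal_beta, a = config$confounding_a,
                    b = config$confounding_b,
                    nucleotide_latent = n_lat, proliferation_latent = p_lat),
      activation = delta
    ), class = "glc_sim_truth")

    list(expression = expr, metadata = metadata, gene_sets = gene_sets,
         truth = cohort_truth)
  })
}

#' Simulate a confounded treatment-outcome-confounder triple
#'
#' Draws from the linear structural causal model
#' \eqn{W \sim N(0,1)}, \eqn{T = aW + \epsilon_T},
#' \eqn{Y = \beta T + bW + \epsilon_Y} with standard normal noise. The
#' confounder W influences both treatment and outcome, so the unadjusted
#' regression of Y on T is biased by \eqn{ab\,\mathrm{Var}(W)/\mathrm{Var}(T)}
#' while adjustment for W recovers \eqn{\beta}.
#'
#' @param n Number of samples (>= 10).
#' @param beta True direct effect of T on Y.
#' @param a,b Confounding strengths W -> T and W -> Y.
#' @param seed Integer seed.
#' @return A tibble with columns `T`, `Y`, `W` and attribute `params`.
#' @export
simulate_causal_data <- function(n, beta, a, b, seed = 1) {
  n <- assert_count(n, "n", 10)
  with_seed(child_seed(seed, 3), {
    W <- rnorm(n)
    T_ <- a * W + rnorm(n)
    Y <- beta * T_ + b * W + rnorm(n)
    out <- tibble(T = T_, Y = Y, W = W)
    attr(out, "params") <- list(n = n, beta = beta, a = a, b = b, seed = seed)
    out
  })
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits `expression.tsv` (gene rows, sample columns), `metadata.tsv`,
#' `network.json`, `priors.tsv` (planted efficiencies as curated priors),
#' `gene_sets.gmt` (sink pathways) and `extra_sets.gmt` (lactate export,
#' lactylation, Fenton reaction, migration, proliferation signature), plus a
#' machine-readable `truth.json`.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param network The `glc_network` the cohort was generated from.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_inputs <- function(cohort, network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_df <- as_tibble(cohort$expression, rownames = "gene")
  readr::write_tsv(expr_df, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_network(network, file.path(dir, "network.json"))
  pr <- tibble(reaction_id = cohort$truth$true_eff$reaction,
               eff0 = cohort$truth$true_eff$eff,
               source = "curated")
  readr::write_tsv(pr, file.path(dir, "priors.tsv"))
  sink_sets <- cohort$gene_sets[network$sink_pathways]
  write_gmt(sink_sets, file.path(dir, "gene_sets.gmt"))
  write_gmt(cohort$gene_sets[setdiff(names(cohort$gene_sets),
                                     network$sink_pathways)],
            file.path(dir, "extra_sets.gmt"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(true_fractions = tr$true_fractions,
         true_eff = tr$true_eff,
         true_flux = tr$true_flux,
         total_influx = tr$total_influx,
         causal = tr$causal[c("beta", "a", "b")]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
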