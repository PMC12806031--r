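#' Construct a glucose-centric stoichiometric network
#'
#' A `glc_network` holds the metabolites and reactions of an acyclic
#' source-to-sink metabolic network: one source metabolite (imported
#' glucose), a set of internal transit metabolites, and one terminal drain
#' reaction per sink pathway. Each reaction carries its signed stoichiometry,
#' EC numbers, the gene set of its gene-protein-reaction (GPR) mapping, and a
#' net proton coefficient (protons produced per unit flux; negative means net
#' proton consumption).
#'
#' @param metabolites A data frame with columns `id`, `name`, `role`
#'   (one of `"source"`, `"internal"`, `"sink"`; sink metabolites are
#'   optional since sink pathways are modeled as terminal drains).
#' @param reactions A data frame with columns `id`, `pathway` (a sink
#'   pathway label or `"internal"`), `proton_coefficient`, and list-columns
#'   `stoichiometry` (named numeric, negative = consumed), `ec` (character)
#'   and `genes` (character).
#' @param validate If `TRUE` (default), [validate_network()] is run and any
#'   violation raises an error.
#'
#' @return An object of class `glc_network` with elements `metabolites`
#'   (tibble), `reactions` (tibble) and `sink_pathways` (character).
#' @seealso [read_network()], [stoich_matrix()], [validate_network()]
#' @export
glc_network <- function(metabolites, reactions, validate = TRUE) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  required_met <- c("id", "name", "role")
  required_rxn <- c("id", "pathway", "stoichiometry", "ec", "genes",
                    "proton_coefficient")
  if (!all(required_met %in% names(metabolites))) {
    abort("`metabolites` needs columns id, name, role.",
          class = "glucoflux_schema_error")
  }
  if (!all(required_rxn %in% names(reactions))) {
    abort("`reactions` needs columns id, pathway, stoichiometry, ec, genes, proton_coefficient.",
          class = "glucoflux_schema_error")
  }
  sinks <- unique(reactions$pathway[reactions$pathway != "internal"])
  net <- structure(
    list(metabolites = metabolites[, required_met],
         reactions = reactions[, required_rxn],
         sink_pathways = sinks),
    class = "glc_network"
  )
  if (validate) {
    report <- validate_network(net)
    if (nrow(report) > 0) {
      abort(paste0("Invalid network:\n",
                   paste(sprintf("- [%s] %s: %s", report$type, report$id,
                                 report$message), collapse = "\n")),
            class = "glucoflux_schema_error")
    }
  }
  net
}

#' @export
print.glc_network <- function(x, ...) {
  n_int <- sum(x$metabolites$role == "internal")
  cat(sprintf("<glc_network> %d metabolites (%d internal), %d reactions, %d sink pathways\n",
              nrow(x$metabolites), n_int, nrow(x$reactions),
              length(x$sink_pathways)))
  cat("sinks:", paste(x$sink_pathways, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a stoichiometric network
#'
#' Checks structural invariants: unique ids, exactly one source metabolite,
#' every stoichiometry referencing declared metabolites, non-empty
#' stoichiometries, every internal metabolite having at least one producer
#' and one consumer, all sinks reachable from the source, and acyclicity of
#' the metabolite-reaction graph.
#'
#' @param network A `glc_network` (constructed with `validate = FALSE` if it
#'   may be broken).
#' @return A tibble with columns `type`, `id`, `message`; zero rows means the
#'   network is valid.
#' @export
validate_network <- function(network) {
  mets <- network$metabolites
  rxns <- network$reactions
  bad <- list()
  note <- function(type, id, message) {
    bad[[length(bad) + 1]] <<- tibble(type = type, id = id, message = message)
  }

  if (anyDuplicated(mets$id)) {
    note("duplicate_metabolite", mets$id[duplicated(mets$id)][1],
         "metabolite id declared more than once")
  }
  if (anyDuplicated(rxns$id)) {
    note("duplicate_reaction", rxns$id[duplicated(rxns$id)][1],
         "reaction id declared more than once")
  }
  n_source <- sum(mets$role == "source")
  if (n_source != 1) {
    note("source_count", "<network>",
         sprintf("expected exactly 1 source metabolite, found %d", n_source))
  }
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[i]]
    if (length(st) == 0) {
      note("empty_stoichiometry", rxns$id[i], "reaction has no stoichiometry")
      next
    }
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown) > 0) {
      note("unknown_metabolite", rxns$id[i],
           paste("references undeclared metabolite(s):",
                 paste(unknown, collapse = ", ")))
    }
    if (!any(st < 0)) {
      note("no_substrate", rxns$id[i], "reaction consumes nothing")
    }
    if (!any(st > 0) && rxns$pathway[i] == "internal") {
      note("no_product", rxns$id[i],
           "internal reaction produces nothing (only sink drains may be pure consumers)")
    }
    if (!is.finite(rxns$proton_coefficient[i])) {
      note("proton_coefficient", rxns$id[i], "proton coefficient not finite")
    }
  }
  if (length(bad) > 0) {
    return(bind_rows(bad))
  }

  # producer/consumer ledger per internal metabolite
  internal <- mets$id[mets$role == "internal"]
  for (m in internal) {
    prod <- any(map_lgl(rxns$stoichiometry, function(st) isTRUE(st[m] > 0)))
    cons <- any(map_lgl(rxns$stoichiometry, function(st) isTRUE(st[m] < 0)))
    if (!prod) note("unproduced_internal", m, "internal metabolite is never produced")
    if (!cons) note("unconsumed_internal", m, "internal metabolite is never consumed")
  }

  # cycle / reachability checks on the bipartite metabolite->reaction graph
  edges <- character(0)
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[i]]
    rid <- paste0("rxn:", rxns$id[i])
    for (m in names(st)) {
      if (st[m] < 0) edges <- c(edges, paste0("met:", m), rid)
      if (st[m] > 0) edges <- c(edges, rid, paste0("met:", m))
    }
  }
  if (length(edges) > 0) {
    g <- igraph::make_graph(edges, directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::feedback_arc_set(g)
      members <- unique(sub("^rxn:", "", grep(
        "^rxn:", unlist(lapply(cyc, function(e) {
          igraph::ends(g, e)
        })), value = TRUE)))
      note("cycle", paste(members, collapse = ","),
           "network contains a directed cycle through the listed reaction(s)")
    } else if (n_source == 1) {
      src <- paste0("met:", mets$id[mets$role == "source"])
      reach <- igraph::subcomponent(g, src, mode = "out")$name
      sink_rxns <- rxns$id[rxns$pathway != "internal"]
      for (sid in sink_rxns) {
        if (!(paste0("rxn:", sid) %in% reach)) {
          note("unreachable_sink", sid,
               "sink drain not reachable from the source metabolite")
        }
      }
    }
  }
  if (length(bad) == 0) {
    tibble(type = character(), id = character(), message = character())
  } else {
    bind_rows(bad)
  }
}

#' Build the stoichiometric matrix S
#'
#' Rows are ordered by the network's metabolite list, columns by its reaction
#' list; entry \eqn{S_{mj}} is the signed coefficient of metabolite m in
#' reaction j (negative = consumed). Mass balance at pseudo-steady state
#' requires \eqn{S v = 0} on the internal rows.
#'
#' @param network A `glc_network`.
#' @return A dense numeric matrix with metabolite rownames and reaction
#'   colnames (0 columns if the network has no reactions).
#' @export
stoich_matrix <- function(network) {
  mets <- network$metabolites$id
  rxns <- network$reactions
  S <- matrix(0, nrow = length(mets), ncol = nrow(rxns),
              dimnames = list(mets, rxns$id))
  for (j in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[j]]
    S[names(st), j] <- unname(st)
  }
  S
}

# Rows of S for internal metabolites only (the mass-balanced nodes).
internal_stoich_matrix <- function(network) {
  S <- stoich_matrix(network)
  S[network$metabolites$id[network$metabolites$role == "internal"], ,
    drop = FALSE]
}

#' Read / write a network JSON file
#'
#' The JSON dialect is
#' `{"metabolites":[{id,name,role}...],`
#' `"reactions":[{id, stoichiometry:{met:coeff}, ec:[], genes:[],`
#' `proton_coefficient, pathway}...]}`.
#' `read_network(write_network(net, path))` is the identity.
#'
#' @param path File path.
#' @return `read_network()` returns a validated `glc_network`;
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Network file not found: %s", path),
          class = "glucoflux_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  mets <- as_tibble(raw$metabolites)
  rx <- raw$reactions
  reactions <- tibble(
    id = as.character(rx$id),
    pathway = as.character(rx$pathway),
    stoichiometry = lapply(seq_along(rx$id), function(i) {
      st <- rx$stoichiometry[i, , drop = TRUE]
      st <- unlist(st)
      st[!is.na(st)]
    }),
    ec = lapply(rx$ec, as.character),
    genes = lapply(rx$genes, as.character),
    proton_coefficient = as.numeric(rx$proton_coefficient)
  )
  glc_network(mets, reactions)
}

#' @param network A `glc_network`.
#' @rdname read_network
#' @export
write_network <- function(network, path) {
  rxns <- network$reactions
  out <- list(
    metabolites = network$metabolites,
    reactions = lapply(seq_len(nrow(rxns)), function(i) {
      list(id = rxns$id[i],
           stoichiometry = as.list(rxns$stoichiometry[[i]]),
           ec = rxns$ec[[i]],
           genes = rxns$genes[[i]],
           proton_coefficient = rxns$proton_coefficient[i],
           pathway = rxns$pathway[i])
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# All genes referenced by the network's GPR mappings.
network_genes <- function(network) {
  unique(unlist(network$reactions$genes))
}

# Map sink pathway label -> drain reaction id.
sink_reactions <- function(network) {
  rxns <- network$reactions
  setNames(rxns$id[rxns$pathway != "internal"],
           rxns$pathway[rxns$pathway != "internal"])
}
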