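# Self-contained synthetic inputs: a clustered multi-relational knowledge
# graph, SMILES-like strings with cluster-specific character profiles, and
# DDI labels with a plantable signal. Every artifact is reproducible from
# (config, seed) and round-trips through the package readers.

SMILES_ALPHABET <- c("C", "N", "O", "S", "c", "n", "1", "2", "3",
                     "[", "]", "=", "#", "(", ")")

#' Synthetic-dataset configuration
#'
#' The defaults emulate the profile of a dense clinical knowledge graph:
#' a few hundred drugs embedded among twice as many non-drug entities, 72%
#' of drugs carrying a structure record, and a DDI subgraph dense enough to
#' learn from. Drugs belong to latent clusters that drive both their graph
#' wiring (they attach mostly to their cluster's hub entities, when the
#' label signal has a topological component) and their SMILES character
#' profiles, so pairs sharing sampled neighbors and/or similar structural
#' vectors can be made more likely to interact.
#'
#' @param n_drugs number of drug entities.
#' @param n_other_entities number of non-drug entities.
#' @param n_relations number of relation types.
#' @param mean_degree target mean degree over all nodes.
#' @param smiles_fraction fraction of drugs with a SMILES record.
#' @param positive_rate fraction of all unordered drug pairs labelled
#'   interacting.
#' @param signal_mode what makes pairs interact: `"topology"` (shared one-hop
#'   neighbors), `"structure"` (structural-cluster co-membership), `"both"`,
#'   or `"none"` (labels independent of the data; null model).
#' @param signal_strength mixing weight in \[0, 1\]: 0 = uniform labels,
#'   1 = positives drawn only from high-affinity pairs.
#' @param n_clusters number of latent drug clusters.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_drugs = 200L, n_other_entities = 400L,
                              n_relations = 6L, mean_degree = 8L,
                              smiles_fraction = 0.72, positive_rate = 0.08,
                              signal_mode = c("both", "topology",
                                              "structure", "none"),
                              signal_strength = 1.0, n_clusters = 10L,
                              seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs),
              n_other_entities = as.integer(n_other_entities),
              n_relations = as.integer(n_relations),
              mean_degree = as.integer(mean_degree),
              smiles_fraction = smiles_fraction,
              positive_rate = positive_rate,
              signal_mode = match.arg(signal_mode),
              signal_strength = signal_strength,
              n_clusters = as.integer(n_clusters),
              seed = as.integer(seed))
  stopifnot(cfg$n_drugs >= 2, cfg$n_other_entities >= 1, cfg$n_relations >= 1,
            cfg$mean_degree >= 1,
            cfg$smiles_fraction >= 0, cfg$smiles_fraction <= 1,
            cfg$positive_rate > 0, cfg$positive_rate < 1,
            cfg$signal_strength >= 0, cfg$signal_strength <= 1,
            cfg$n_clusters >= 1)
  class(cfg) <- "sim_config"
  cfg
}

sim_drug_ids <- function(config) sprintf("DB%05d", seq_len(config$n_drugs))
sim_entity_ids <- function(config) sprintf("ENT%04d", seq_len(config$n_other_entities))

# latent cluster of each drug; shared by the KG wiring and the SMILES
# profiles so the two signal channels agree
latent_clusters <- function(config) {
  with_seed(derive_seed(config$seed, 11),
            sample.int(config$n_clusters, config$n_drugs, replace = TRUE))
}

#' Simulate a multi-relational knowledge graph
#'
#' Each drug receives `mean_degree` edges to entities; when the label signal
#' has a topological component (`signal_mode` topology/both) most of them
#' (7 of 8 at the default degree) go to the drug's cluster hub entities so
#' same-cluster drugs share neighbors, otherwise targets are uniform. Remaining edge budget
#' (`mean_degree * n_nodes / 2` total) is spent on random entity-entity
#' edges. Relations are uniform; duplicates and self-loops are avoided by
#' construction of the id spaces.
#'
#' @param config a `sim_config`.
#' @return list of class `synthetic_kg`: `triples` (data.frame head,
#'   relation, tail) and `latent` (cluster assignment, hub sets).
#' @export
simulate_kg <- function(config) {
  drugs <- sim_drug_ids(config)
  ents <- sim_entity_ids(config)
  rels <- sprintf("rel_%d", seq_len(config$n_relations))
  K <- config$n_clusters
  cl <- latent_clusters(config)
  clustered <- config$signal_mode %in% c("topology", "both")

  n_nodes <- config$n_drugs + config$n_other_entities
  L_total <- round(config$mean_degree * n_nodes / 2)
  deg_drug <- config$mean_degree
  if (config$n_drugs * deg_drug > 2L * L_total) {
    stop_smilegnn("mean_degree %d infeasible for %d drugs among %d nodes",
                  deg_drug, config$n_drugs, n_nodes)
  }

  with_seed(derive_seed(config$seed, 22), {
    # cluster hub pools: ~40% of each cluster's entity share
    ent_cl <- rep_len(seq_len(K), config$n_other_entities)
    hubs <- lapply(seq_len(K), function(k) {
      pool <- which(ent_cl == k)
      pool[seq_len(max(1L, round(0.4 * length(pool))))]
    })
    n_hub <- if (clustered) min(deg_drug, max(1L, ceiling(0.875 * deg_drug))) else 0L
    h <- character(0); t <- character(0)
    for (i in seq_len(config$n_drugs)) {
      pool <- hubs[[cl[i]]]
      tgt_hub <- if (n_hub > 0) {
        pool[sample.int(length(pool), min(n_hub, length(pool)),
                        replace = n_hub > length(pool))]
      } else integer(0)
      tgt_rand <- sample.int(config$n_other_entities, deg_drug - length(tgt_hub))
      tgt <- unique(c(tgt_hub, tgt_rand))
      h <- c(h, rep(drugs[i], length(tgt)))
      t <- c(t, ents[tgt])
    }
    L_ee <- max(0L, L_total - length(h))
    if (L_ee > 0 && config$n_other_entities >= 2) {
      a <- sample.int(config$n_other_entities, L_ee, replace = TRUE)
      b <- sample.int(config$n_other_entities, L_ee, replace = TRUE)
      ok <- a != b
      h <- c(h, ents[a[ok]]); t <- c(t, ents[b[ok]])
    }
    r <- rels[sample.int(config$n_relations, length(h), replace = TRUE)]
    triples <- data.frame(head = h, relation = r, tail = t,
                          stringsAsFactors = FALSE)
    triples <- triples[!duplicated(pair_key(triples$head, triples$tail)), ]
    structure(list(triples = triples,
                   latent = list(drug_cluster = cl, entity_cluster = ent_cl,
                                 hubs = hubs, drugs = drugs, entities = ents)),
              class = "synthetic_kg")
  })
}

#' Simulate SMILES-like structure records
#'
#' A `smiles_fraction` subset of drugs receives a random string over a
#' SMILES-like alphabet (lengths 30-150, always within the 250-character
#' featurisation limit). Each latent cluster has its own character-frequency
#' profile (a Dirichlet draw), so count vectors of same-cluster drugs are
#' more similar than between clusters. No chemical validity is implied.
#'
#' @param config a `sim_config`.
#' @return data.frame `drug_id`, `smiles` for the covered drugs.
#' @export
simulate_smiles <- function(config) {
  drugs <- sim_drug_ids(config)
  cl <- latent_clusters(config)
  n_with <- round(config$smiles_fraction * config$n_drugs)
  with_seed(derive_seed(config$seed, 33), {
    profiles <- lapply(seq_len(config$n_clusters), function(k) {
      w <- stats::rgamma(length(SMILES_ALPHABET), shape = 0.5)
      w / sum(w)
    })
    who <- sort(sample.int(config$n_drugs, n_with))
    smiles <- vapply(who, function(i) {
      len <- sample(30:150, 1)
      paste(sample(SMILES_ALPHABET, len, replace = TRUE,
                   prob = profiles[[cl[i]]]), collapse = "")
    }, character(1))
    data.frame(drug_id = drugs[who], smiles = smiles,
               stringsAsFactors = FALSE)
  })
}

#' Plant drug-drug interaction labels
#'
#' Assigns each unordered drug pair an affinity in \[0, 1\]: the topology
#' channel grades by the number of shared one-hop graph neighbors
#' (`min(1, shared / 3)`, so a single coincidental shared neighbor carries
#' only a third of the weight of a systematically shared neighborhood); the
#' structure channel is structural-cluster co-membership; `signal_mode`
#' selects one channel, their maximum (`"both"`) or neither. Positives are
#' then `positive_rate` of all pairs, sampled without replacement with
#' probability proportional to `(1 - signal_strength) + signal_strength *
#' affinity`; at strength 1 only pairs with nonzero affinity can interact, at
#' strength 0 (or mode `"none"`) labels are independent of the data.
#'
#' @param kg a `synthetic_kg` from [simulate_kg()].
#' @param smiles SMILES table from [simulate_smiles()] (recorded in the
#'   ground truth; the structure channel uses cluster co-membership).
#' @param config a `sim_config`.
#' @return list with `positives` (a `pair_dataset`, all label 1) and `truth`
#'   (per-pair mechanism record plus the latent clusters).
#' @export
plant_ddi_labels <- function(kg, smiles, config) {
  stopifnot(inherits(kg, "synthetic_kg"))
  drugs <- kg$latent$drugs
  n <- length(drugs)
  idx <- index_graph(kg$triples, drug_ids = drugs)
  # drug x entity incidence -> pairwise shared one-hop neighbor counts
  M <- matrix(0L, n, length(idx$entities))
  di <- kg_entity_id(idx, drugs)
  for (i in seq_len(n)) M[i, idx$adj[[di[i]]]$nbr] <- 1L
  shared <- tcrossprod(M)

  pr <- t(utils::combn(n, 2))
  topo_aff <- pmin(1, shared[pr] / 3)
  cl <- kg$latent$drug_cluster
  struct_aff <- cl[pr[, 1]] == cl[pr[, 2]]
  aff <- switch(config$signal_mode,
                topology = topo_aff,
                structure = as.numeric(struct_aff),
                both = pmax(topo_aff, struct_aff),
                none = rep(0, nrow(pr)))
  s <- if (config$signal_mode == "none") 0 else config$signal_strength
  w <- (1 - s) + s * as.numeric(aff)
  n_pos <- round(config$positive_rate * nrow(pr))
  if (sum(w > 0) < n_pos) {
    stop_smilegnn("positive_rate %.3f unachievable: %d pairs requested but only %d have nonzero weight",
                  config$positive_rate, n_pos, sum(w > 0))
  }
  pos_idx <- with_seed(derive_seed(config$seed, 44),
                       sample.int(nrow(pr), n_pos, prob = w))
  positives <- pair_dataset(drugs[pr[pos_idx, 1]], drugs[pr[pos_idx, 2]],
                            rep(1L, n_pos))
  truth <- list(
    signal_mode = config$signal_mode,
    signal_strength = config$signal_strength,
    drug_cluster = stats::setNames(cl, drugs),
    has_smiles = stats::setNames(drugs %in% smiles$drug_id, drugs),
    positives = data.frame(
      drug1 = drugs[pr[pos_idx, 1]], drug2 = drugs[pr[pos_idx, 2]],
      shared_neighbors = shared[pr][pos_idx],
      topology_affinity = topo_aff[pos_idx] > 0,
      structure_affinity = struct_aff[pos_idx],
      stringsAsFactors = FALSE))
  list(positives = positives, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_kg()], [simulate_smiles()] and [plant_ddi_labels()], adds
#' uniformly sampled negatives at `neg_ratio` per positive, and (optionally)
#' writes `triples.tsv`, `smiles.tsv`, `pairs.tsv` and `truth.json` to a
#' directory.
#'
#' @param config a `sim_config`.
#' @param dir optional output directory.
#' @param neg_ratio negatives per positive (default 1).
#' @return list with `kg` (indexed `knowledge_graph`), `triples`, `smiles`,
#'   `pairs` (a `pair_dataset` with labels 0/1), `truth`, `config`.
#' @export
simulate_dataset <- function(config, dir = NULL, neg_ratio = 1) {
  skg <- simulate_kg(config)
  smiles <- simulate_smiles(config)
  lab <- plant_ddi_labels(skg, smiles, config)
  pairs <- sample_negatives(lab$positives, ratio = neg_ratio,
                            rng_seed = derive_seed(config$seed, 55),
                            drugs = skg$latent$drugs)
  kg <- index_graph(skg$triples, drug_ids = skg$latent$drugs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_triples(skg$triples, file.path(dir, "triples.tsv"))
    utils::write.table(smiles, file.path(dir, "smiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_pairs(pairs, file.path(dir, "pairs.tsv"))
    jsonlite::write_json(lab$truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  list(kg = kg, triples = skg$triples, smiles = smiles, pairs = pairs,
       truth = lab$truth, config = config, latent = skg$latent)
}
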