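# Two-hop neighborhood-sampling graph neural encoder.
#
# Per drug pair (u, v): each drug's receptive field (fixed-width sampled
# neighborhoods, depth n_hops) is aggregated layer by layer. Neighbor
# relevance is the softmax, over each sampled neighborhood, of the inner
# product between the PARTNER drug's entity embedding (the query) and the
# relation embedding on each sampled edge — so the topological embedding of a
# drug is conditioned on the pair being scored. Inner layers use a rectifier,
# the final layer tanh. Aggregators: sum (self + neighborhood), concat
# (self || neighborhood), neigh (neighborhood only).

#' Initialise encoder + fusion parameters
#'
#' Entity and relation embeddings are drawn uniformly from \[-0.05, 0.05\];
#' projection matrices use Glorot (fan-averaged) uniform initialisation so the
#' topological path neither explodes nor vanishes relative to the structural
#' one. All draws derive from the configuration seed. A reserved null-relation
#' row (index `n_relations + 1`) carries the self-padding edges of isolated
#' entities.
#'
#' @param n_entities,n_relations graph sizes.
#' @param config a [train_config()] (fields `embed_dim`, `d_struct`, `n_hops`,
#'   `sample_size`, `aggregator_type`, `fusion_method`, `seed` are used).
#' @return list of class `gnn_params` with entity/relation embedding matrices,
#'   per-layer aggregation weights, fusion weights and the configuration.
#' @export
init_gnn_params <- function(n_entities, n_relations, config) {
  d <- config$embed_dim; ds <- config$d_struct; H <- config$n_hops
  if (config$fusion_method == "sum" && ds != d) {
    stop_smilegnn("sum fusion requires d_struct = embed_dim (%d vs %d)", ds, d)
  }
  agg_in_dim <- if (config$aggregator_type == "concat") 2L * d else d
  fuse_in_dim <- if (config$fusion_method == "concat") d + ds else d
  with_seed(derive_seed(config$seed, 101), {
    u <- function(n, m) matrix(stats::runif(n * m, -0.05, 0.05), n, m)
    glorot <- function(n, m) {
      lim <- sqrt(6 / (n + m))
      matrix(stats::runif(n * m, -lim, lim), n, m)
    }
    p <- list(
      E = u(n_entities, d),
      R = u(n_relations + 1L, d),
      W = lapply(seq_len(H), function(i) glorot(agg_in_dim, d)),
      b = lapply(seq_len(H), function(i) numeric(d)),
      Wf = glorot(fuse_in_dim, d),
      bf = numeric(d),
      config = config
    )
    class(p) <- "gnn_params"
    p
  })
}

# --- receptive-field sampling ------------------------------------------------

NULL_RELATION <- function(kg) length(kg$relations) + 1L

# Fixed-width neighbor sample for one entity at one hop. Deterministic given
# (rng_seed, entity, hop). Degree 0 pads with the entity itself under the
# reserved null relation; degree < sample_size keeps every neighbor once and
# fills the remaining slots with replacement; degree >= sample_size samples
# without replacement.
sample_entity_neighbors <- function(kg, entity, sample_size, hop, rng_seed) {
  a <- kg$adj[[entity]]
  deg <- length(a$nbr)
  if (deg == 0L) {
    return(list(nbr = rep(entity, sample_size),
                rel = rep(NULL_RELATION(kg), sample_size)))
  }
  idx <- with_seed(derive_seed(rng_seed, entity, hop), {
    if (deg >= sample_size) {
      sample.int(deg, sample_size)
    } else {
      c(seq_len(deg), sample.int(deg, sample_size - deg, replace = TRUE))
    }
  })
  list(nbr = a$nbr[idx], rel = a$rel[idx])
}

#' Sample the receptive field of one entity
#'
#' Hop 0 is the seed entity itself; hop `h` holds `sample_size^h` sampled
#' neighbor entity ids with their relation ids, fixed-width regardless of
#' degree (low-degree entities are sampled with replacement, isolated ones
#' self-padded with a null relation). Deterministic given `rng_seed`.
#'
#' @param kg a `knowledge_graph`.
#' @param seed_entity entity name or integer id.
#' @param n_hops receptive-field depth (default 2).
#' @param sample_size neighbors drawn per entity per hop (default 8).
#' @param rng_seed integer master seed.
#' @return list with `entities` and `relations`, each a list indexed by hop
#'   `0..n_hops` (`relations[[1]]` is NA for the seed layer).
#' @export
sample_receptive_field <- function(kg, seed_entity, n_hops = 2L,
                                   sample_size = 8L, rng_seed = 1L) {
  if (is.character(seed_entity)) seed_entity <- kg_entity_id(kg, seed_entity)
  if (seed_entity < 1 || seed_entity > length(kg$entities)) {
    stop_smilegnn("entity id %s not in graph", format(seed_entity))
  }
  ents <- list(as.integer(seed_entity))
  rels <- list(NA_integer_)
  for (h in seq_len(n_hops)) {
    parent <- ents[[h]]
    sampled <- lapply(parent, sample_entity_neighbors, kg = kg,
                      sample_size = sample_size, hop = h, rng_seed = rng_seed)
    ents[[h + 1L]] <- unlist(lapply(sampled, `[[`, "nbr"), use.names = FALSE)
    rels[[h + 1L]] <- unlist(lapply(sampled, `[[`, "rel"), use.names = FALSE)
  }
  names(ents) <- names(rels) <- paste0("hop", 0:n_hops)
  list(entities = ents, relations = rels)
}

# Precompute one fixed-width neighbor sample per (entity, hop) for the whole
# graph; fields for any seed entity are then index lookups. Matrices are
# n_entities x sample_size.
build_receptive_fields <- function(kg, n_hops, sample_size, rng_seed) {
  n <- length(kg$entities)
  hops <- lapply(seq_len(n_hops), function(h) {
    nbr <- matrix(0L, n, sample_size)
    rel <- matrix(0L, n, sample_size)
    for (e in seq_len(n)) {
      s <- sample_entity_neighbors(kg, e, sample_size, h, rng_seed)
      nbr[e, ] <- s$nbr
      rel[e, ] <- s$rel
    }
    list(nbr = nbr, rel = rel)
  })
  structure(list(hops = hops, n_hops = n_hops, sample_size = sample_size,
                 rng_seed = rng_seed), class = "receptive_fields")
}

# Flat per-depth id vectors for a batch of seed entities, block-major: the
# entry for (pair b, position j at depth h) sits at (b-1)*s^h + j.
field_tensors <- function(fields, uid) {
  s <- fields$sample_size
  ids <- list(as.integer(uid))
  rels <- list(NULL)
  for (h in seq_len(fields$n_hops)) {
    parent <- ids[[h]]
    ids[[h + 1L]] <- as.vector(t(fields$hops[[h]]$nbr[parent, , drop = FALSE]))
    rels[[h + 1L]] <- as.vector(t(fields$hops[[h]]$rel[parent, , drop = FALSE]))
  }
  list(ids = ids, rels = rels)
}

# --- exported layer primitives ----------------------------------------------

#' Attention weights over a sampled neighborhood
#'
#' Relevance of each sampled edge is the inner product between the query
#' drug's embedding and the edge's relation embedding, normalised by softmax
#' over the neighborhood, so the weights sum to 1.
#'
#' @param query_vec numeric query vector (the partner drug's embedding).
#' @param relation_ids integer relation ids of the sampled edges.
#' @param params a `gnn_params` object (its `R` matrix is used).
#' @return numeric weights, one per sampled edge, summing to 1.
#' @export
relation_attention <- function(query_vec, relation_ids, params) {
  scores <- as.vector(params$R[relation_ids, , drop = FALSE] %*% query_vec)
  softmax_blocks(scores, length(scores))
}

#' Apply one aggregation layer
#'
#' Combines each entity's own vector with its attention-weighted neighborhood
#' summary and projects through a learned layer: `sum` uses
#' `act(W (self + nbr) + b)`, `concat` uses `act(W [self || nbr] + b)` and
#' `neigh` ignores the self term, `act(W nbr + b)`.
#'
#' @param self_vecs matrix (n x d) of entity vectors.
#' @param neighbor_summary matrix (n x d) of attention-weighted neighbor means.
#' @param W,b layer weights: W is (d x d), or (2d x d) for `concat`.
#' @param aggregator one of `"sum"`, `"concat"`, `"neigh"`.
#' @param activation `"relu"` (inner hops), `"tanh"` (final hop) or `"linear"`.
#' @return updated matrix (n x d).
#' @export
aggregate_layer <- function(self_vecs, neighbor_summary, W, b,
                            aggregator = c("sum", "concat", "neigh"),
                            activation = c("relu", "tanh", "linear")) {
  aggregator <- match.arg(aggregator)
  activation <- match.arg(activation)
  z <- aggregate_input(self_vecs, neighbor_summary, aggregator) %*% W
  z <- sweep(z, 2, b, `+`)
  switch(activation, relu = relu(z), tanh = tanh(z), linear = z)
}

aggregate_input <- function(self_vecs, neighbor_summary, aggregator) {
  switch(aggregator,
         sum = self_vecs + neighbor_summary,
         concat = cbind(self_vecs, neighbor_summary),
         neigh = neighbor_summary,
         stop_smilegnn("unknown aggregator '%s'", aggregator))
}

# gradient of aggregate_input wrt (self, neighbor_summary)
aggregate_input_backward <- function(dIn, d, aggregator) {
  switch(aggregator,
         sum = list(self = dIn, nbr = dIn),
         concat = list(self = dIn[, seq_len(d), drop = FALSE],
                       nbr = dIn[, d + seq_len(d), drop = FALSE]),
         neigh = list(self = NULL, nbr = dIn))
}

# --- batched forward / backward ---------------------------------------------

# Forward pass for one side of a batch of pairs: seeds `uid`, attention
# queries are the raw entity embeddings of the partner drugs `qid`.
# Returns the final (B x d) topological embeddings, plus caches for backward.
gnn_side_forward <- function(params, fields, uid, qid, keep_cache = FALSE) {
  cfg <- params$config
  H <- cfg$n_hops; s <- fields$sample_size; d <- cfg$embed_dim
  B <- length(uid)
  ft <- field_tensors(fields, uid)
  q <- params$E[qid, , drop = FALSE]

  # raw embeddings per depth + attention weights per depth
  V <- vector("list", H + 1L)
  alpha <- vector("list", H + 1L) # alpha[[h+1]] aligns with depth h entries
  for (h in 0:H) {
    V[[h + 1L]] <- params$E[ft$ids[[h + 1L]], , drop = FALSE]
    if (h > 0) {
      Rh <- params$R[ft$rels[[h + 1L]], , drop = FALSE]
      qrep <- q[rep(seq_len(B), each = s^h), , drop = FALSE]
      alpha[[h + 1L]] <- softmax_blocks(rowSums(Rh * qrep), s)
    }
  }

  Vs <- if (keep_cache) list(V) else NULL # iteration snapshots
  ins <- if (keep_cache) vector("list", H) else NULL
  Zs <- if (keep_cache) vector("list", H) else NULL
  for (i in seq_len(H)) {
    newV <- vector("list", H - i + 1L)
    if (keep_cache) { ins[[i]] <- vector("list", H - i + 1L)
                      Zs[[i]] <- vector("list", H - i + 1L) }
    for (h in 0:(H - i)) {
      m <- sum_blocks(V[[h + 2L]] * alpha[[h + 2L]], s)
      inp <- aggregate_input(V[[h + 1L]], m, cfg$aggregator_type)
      z <- sweep(inp %*% params$W[[i]], 2, params$b[[i]], `+`)
      newV[[h + 1L]] <- if (i < H) relu(z) else tanh(z)
      if (keep_cache) { ins[[i]][[h + 1L]] <- inp; Zs[[i]][[h + 1L]] <- z }
    }
    V[seq_len(H - i + 1L)] <- newV
    if (keep_cache) Vs[[i + 1L]] <- V[seq_len(H - i + 1L)]
  }
  out <- V[[1L]]
  if (!keep_cache) return(list(topo = out))
  list(topo = out, Vs = Vs, ins = ins, Zs = Zs, alpha = alpha, ft = ft,
       uid = uid, qid = qid, q = q, B = B)
}

# Backward through one side. `dT` is the gradient wrt the side's topological
# output. Accumulates into the gradient environment `g` (dense dE, dR, dW, db).
gnn_side_backward <- function(params, fields, cache, dT, g) {
  cfg <- params$config
  H <- cfg$n_hops; s <- fields$sample_size; d <- cfg$embed_dim
  B <- cache$B
  agg <- cfg$aggregator_type

  dV <- vector("list", H + 1L) # grads wrt V_{i-1} snapshots, by depth
  dV[[1L]] <- dT
  dalpha <- vector("list", H + 1L)
  for (h in seq_len(H)) dalpha[[h + 1L]] <- numeric(B * s^h)

  for (i in H:1) {
    Vprev <- cache$Vs[[i]]
    dVnew <- vector("list", H - i + 2L)
    for (h in 0:(H - i)) {
      if (is.null(dV[[h + 1L]])) next # e.g. neigh: self path carries nothing
      z <- cache$Zs[[i]][[h + 1L]]
      dZ <- if (i < H) dV[[h + 1L]] * (z > 0) else dV[[h + 1L]] * (1 - tanh(z)^2)
      g$dW[[i]] <- g$dW[[i]] + crossprod(cache$ins[[i]][[h + 1L]], dZ)
      g$db[[i]] <- g$db[[i]] + colSums(dZ)
      dIn <- dZ %*% t(params$W[[i]])
      parts <- aggregate_input_backward(dIn, d, agg)
      # self path
      if (!is.null(parts$self)) {
        dVnew[[h + 1L]] <- (dVnew[[h + 1L]] %||% 0) + parts$self
      }
      # neighborhood path: m = sum_blocks(child * alpha)
      a <- cache$alpha[[h + 2L]]
      child <- Vprev[[h + 2L]]
      dMrep <- parts$nbr[rep(seq_len(nrow(parts$nbr)), each = s), , drop = FALSE]
      dVnew[[h + 2L]] <- (dVnew[[h + 2L]] %||% 0) + dMrep * a
      dalpha[[h + 2L]] <- dalpha[[h + 2L]] + rowSums(child * dMrep)
    }
    dV <- dVnew
  }

  # dV now holds gradients wrt the raw embedding lookups per depth
  for (h in 0:H) {
    if (is.null(dV[[h + 1L]]) || is.matrix(dV[[h + 1L]]) == FALSE) next
    scatter_add(g, "dE", cache$ft$ids[[h + 1L]], dV[[h + 1L]])
  }

  # attention backward: alpha = softmax(scores) per block; scores = <R, q>
  dq <- matrix(0, B, d)
  for (h in seq_len(H)) {
    a <- cache$alpha[[h + 1L]]
    da <- dalpha[[h + 1L]]
    inner <- sum_blocks(matrix(a * da, ncol = 1L), s) # per-block sum
    dsc <- a * (da - rep(inner, each = s))
    Rh <- params$R[cache$ft$rels[[h + 1L]], , drop = FALSE]
    qrep <- cache$q[rep(seq_len(B), each = s^h), , drop = FALSE]
    scatter_add(g, "dR", cache$ft$rels[[h + 1L]], dsc * qrep)
    dq <- dq + sum_blocks(dsc * Rh, s^h)
  }
  scatter_add(g, "dE", cache$qid, dq)
  invisible(NULL)
}

# dense scatter-add of gradient rows into g[[name]]
scatter_add <- function(g, name, ids, rows) {
  rs <- rowsum(rows, ids, reorder = FALSE)
  tgt <- as.integer(rownames(rs))
  g[[name]][tgt, ] <- g[[name]][tgt, , drop = FALSE] + rs
  invisible(NULL)
}

#' Pair-conditioned topological embeddings for one drug pair
#'
#' Runs the two-hop encoder for both drugs of a pair; each drug's receptive
#' field is aggregated with relation attention queried by the partner drug's
#' entity embedding.
#'
#' @param kg a `knowledge_graph`.
#' @param drug_pair length-2 vector of drug entity names (or integer ids).
#' @param params a `gnn_params` object.
#' @param rng_seed seed for the receptive-field sampling (default: the
#'   configuration seed).
#' @param fields optional precomputed `receptive_fields` to reuse.
#' @return list with `drug1` and `drug2`, each a topological embedding vector
#'   of length `embed_dim` with entries in (-1, 1).
#' @export
encode_topology <- function(kg, drug_pair, params, rng_seed = NULL,
                            fields = NULL) {
  cfg <- params$config
  ids <- if (is.character(drug_pair)) kg_entity_id(kg, drug_pair) else as.integer(drug_pair)
  stopifnot(length(ids) == 2L)
  if (is.null(fields)) {
    fields <- build_receptive_fields(kg, cfg$n_hops, cfg$sample_size,
                                     rng_seed %||% cfg$seed)
  }
  f1 <- gnn_side_forward(params, fields, ids[1L], ids[2L])
  f2 <- gnn_side_forward(params, fields, ids[2L], ids[1L])
  list(drug1 = as.vector(f1$topo), drug2 = as.vector(f2$topo))
}

# --- full pair model (GNN + fusion + sigmoid dot score) ----------------------

fuse_forward <- function(params, topo, Bmat_rows) {
  method <- params$config$fusion_method
  inp <- if (method == "concat") cbind(topo, Bmat_rows) else topo + Bmat_rows
  G <- sweep(inp %*% params$Wf, 2, params$bf, `+`)
  list(f = tanh(G), inp = inp)
}

# Score a batch of pairs; optionally keep everything needed for backward.
model_forward <- function(params, fields, Bmat, i1, i2, keep_cache = FALSE) {
  s1 <- gnn_side_forward(params, fields, i1, i2, keep_cache)
  s2 <- gnn_side_forward(params, fields, i2, i1, keep_cache)
  fu1 <- fuse_forward(params, s1$topo, Bmat[i1, , drop = FALSE])
  fu2 <- fuse_forward(params, s2$topo, Bmat[i2, , drop = FALSE])
  logit <- rowSums(fu1$f * fu2$f)
  out <- list(score = sigmoid(logit))
  if (keep_cache) out <- c(out, list(s1 = s1, s2 = s2, fu1 = fu1, fu2 = fu2))
  out
}

# Gradients of the mean BCE loss for one batch. Returns a gradient list with
# the same shapes as the parameters.
model_backward <- function(params, fields, fwd, y) {
  cfg <- params$config
  d <- cfg$embed_dim
  B <- length(y)
  g <- new.env(parent = emptyenv())
  g$dE <- matrix(0, nrow(params$E), d)
  g$dR <- matrix(0, nrow(params$R), d)
  g$dW <- lapply(params$W, function(w) matrix(0, nrow(w), ncol(w)))
  g$db <- lapply(params$b, function(b) numeric(length(b)))
  g$dWf <- matrix(0, nrow(params$Wf), ncol(params$Wf))
  g$dbf <- numeric(length(params$bf))

  dlogit <- (fwd$score - y) / B
  for (side in 1:2) {
    fu <- if (side == 1) fwd$fu1 else fwd$fu2
    other <- if (side == 1) fwd$fu2$f else fwd$fu1$f
    sc <- if (side == 1) fwd$s1 else fwd$s2
    dF <- dlogit * other
    dG <- dF * (1 - fu$f^2)
    g$dWf <- g$dWf + crossprod(fu$inp, dG)
    g$dbf <- g$dbf + colSums(dG)
    dInp <- dG %*% t(params$Wf)
    dT <- if (cfg$fusion_method == "concat") dInp[, seq_len(d), drop = FALSE] else dInp
    gnn_side_backward(params, fields, sc, dT, g)
  }
  list(E = g$dE, R = g$dR, W = g$dW, b = g$db, Wf = g$dWf, bf = g$dbf)
}
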