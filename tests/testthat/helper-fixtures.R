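# Shared fixtures, built in code.

# path graph DB1 - n2 - n3 - ... - n6 - DB7 with alternating relations
path_triples <- function() {
  ents <- c("DB00001", "n2", "n3", "n4", "n5", "n6", "DB00007")
  data.frame(head = ents[1:6],
             relation = rep(c("r1", "r2"), 3),
             tail = ents[2:7],
             stringsAsFactors = FALSE)
}

path_kg <- function() index_graph(path_triples(), drug_prefix = "DB")

# small planted-signal dataset for smoke tests
small_sim <- function(seed = 3, ...) {
  simulate_dataset(simulation_config(n_drugs = 40, n_other_entities = 80,
                                     n_clusters = 4, seed = seed, ...))
}

# training configuration used for desk-scale experiments
desk_config <- function(seed, ...) {
  args <- list(batch_size = 512, learning_rate = 2e-2, weight_decay = 0.3,
               embed_dim = 32, d_struct = 16, sample_size = 4, epochs = 12,
               aggregator_type = "concat", fusion_method = "concat",
               seed = seed)
  do.call(train_config, utils::modifyList(args, list(...)))
}

struct_for <- function(sim, d_struct = 16) {
  structural_features(sim$smiles, drug_ids = sim$latent$drugs,
                      d_struct = d_struct, seed = 1)
}

# independent scalar-loop oracle for the fusion layers
fusion_oracle <- function(A, B, W, b, method) {
  n <- nrow(A); d <- ncol(W)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    x <- if (method == "sum") A[i, ] + B[i, ] else c(A[i, ], B[i, ])
    for (j in seq_len(d)) {
      acc <- b[j]
      for (k in seq_along(x)) acc <- acc + x[k] * W[k, j]
      out[i, j] <- tanh(acc)
    }
  }
  out
}

# brute-force concordance AUC (ties count half)
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Hand-unrolled two-layer oracle for a graph whose degrees are all <= 2,
# evaluated with sample_size = 2 so the sampled neighborhoods are exhaustive
# (degree-1 entities contribute their single neighbor twice). Independent of
# the package's batched tensor path.
unrolled_oracle <- function(kg, E, R, W1, b1, W2, b2, agg, u, qvec) {
  s <- 2L
  nb <- function(e) {
    a <- kg$adj[[e]]
    idx <- if (length(a$nbr) >= s) seq_len(s) else rep(seq_along(a$nbr), length.out = s)
    list(ent = a$nbr[idx], rel = a$rel[idx])
  }
  att <- function(rels) {
    sc <- vapply(rels, function(r) {
      acc <- 0
      for (k in seq_along(qvec)) acc <- acc + R[r, k] * qvec[k]
      acc
    }, numeric(1))
    e <- exp(sc - max(sc))
    e / sum(e)
  }
  comb <- function(self, nbrsum) {
    switch(agg, sum = self + nbrsum, concat = c(self, nbrsum), neigh = nbrsum)
  }
  lin <- function(x, W, b) {
    out <- numeric(length(b))
    for (j in seq_along(b)) {
      acc <- b[j]
      for (k in seq_along(x)) acc <- acc + x[k] * W[k, j]
      out[j] <- acc
    }
    out
  }
  h1 <- nb(u)
  a1 <- att(h1$rel)
  # iteration 1, depth 1
  v1 <- lapply(seq_len(s), function(j) {
    h2 <- nb(h1$ent[j])
    a2 <- att(h2$rel)
    m <- a2[1] * E[h2$ent[1], ] + a2[2] * E[h2$ent[2], ]
    pmax(lin(comb(E[h1$ent[j], ], m), W1, b1), 0)
  })
  # iteration 1, depth 0
  m0 <- a1[1] * E[h1$ent[1], ] + a1[2] * E[h1$ent[2], ]
  v0 <- pmax(lin(comb(E[u, ], m0), W1, b1), 0)
  # iteration 2, depth 0
  m0p <- a1[1] * v1[[1]] + a1[2] * v1[[2]]
  tanh(lin(comb(v0, m0p), W2, b2))
}

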