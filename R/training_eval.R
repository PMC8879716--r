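#' Training configuration
#'
#' Defaults follow the denser-graph preset (batch 1024, learning rate 1e-2,
#' embedding dimension 64); `kegg.yaml` and `pdd.yaml` under
#' `inst/configs/` ship both published presets. `use_structure = FALSE`
#' trains the topology-only ablation (the structural matrix is zeroed).
#'
#' @param batch_size pairs per gradient step.
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled L2 penalty applied at each step; discourages
#'   per-pair memorisation through the free entity embeddings.
#' @param embed_dim topological embedding dimension (d_topo).
#' @param d_struct structural feature dimension after PCA.
#' @param aggregator_type neighborhood aggregator: `"sum"`, `"concat"`, `"neigh"`.
#' @param fusion_method feature fusion: `"sum"` or `"concat"`.
#' @param n_hops receptive-field depth.
#' @param sample_size neighbors sampled per entity per hop.
#' @param epochs training epochs.
#' @param n_folds cross-validation folds.
#' @param use_structure include structural features (FALSE = topology-only).
#' @param resample_fields redraw the sampled receptive fields each epoch (a
#'   fresh deterministic sample per epoch, as in stochastic neighborhood
#'   sampling); prediction always uses the epoch-1 fields.
#' @param seed master seed for initialisation, sampling and shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 1024L, learning_rate = 1e-2,
                         weight_decay = 1e-3,
                         embed_dim = 64L, d_struct = 64L,
                         aggregator_type = c("concat", "sum", "neigh"),
                         fusion_method = c("concat", "sum"),
                         n_hops = 2L, sample_size = 8L, epochs = 20L,
                         n_folds = 5L, use_structure = TRUE,
                         resample_fields = TRUE, seed = 1L) {
  cfg <- list(batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              weight_decay = weight_decay,
              embed_dim = as.integer(embed_dim),
              d_struct = as.integer(d_struct),
              aggregator_type = match.arg(aggregator_type),
              fusion_method = match.arg(fusion_method),
              n_hops = as.integer(n_hops),
              sample_size = as.integer(sample_size),
              epochs = as.integer(epochs),
              n_folds = as.integer(n_folds),
              use_structure = isTRUE(use_structure),
              resample_fields = isTRUE(resample_fields),
              seed = as.integer(seed))
  stopifnot(cfg$batch_size > 0, cfg$learning_rate > 0, cfg$weight_decay >= 0,
            cfg$embed_dim > 0,
            cfg$d_struct > 0, cfg$n_hops >= 1, cfg$sample_size >= 1,
            cfg$epochs > 0, cfg$n_folds >= 2)
  class(cfg) <- "train_config"
  cfg
}

#' Read a training configuration from YAML
#' @param path YAML file whose keys match [train_config()] arguments.
#' @param ... overrides.
#' @return a `train_config`.
#' @export
read_train_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  do.call(train_config, utils::modifyList(y, list(...)))
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  keys <- c("E", "R", "W", "b", "Wf", "bf")
  list(m = lapply(params[keys], zero_like),
       v = lapply(params[keys], zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, gr, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, gr, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * gr
    v <- beta2 * v + (1 - beta2) * gr^2
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  for (k in c("E", "R", "W", "b", "Wf", "bf")) {
    o <- upd(params[[k]], grads[[k]], state$m[[k]], state$v[[k]])
    params[[k]] <- o$p; state$m[[k]] <- o$m; state$v[[k]] <- o$v
  }
  list(params = params, state = state)
}

# --- negative sampling --------------------------------------------------

#' Sample negative drug pairs
#'
#' Draws uniformly random unordered drug pairs over the dataset's drug index
#' set, disjoint from the positive pairs and from each other, labelled 0.
#'
#' @param positives a `pair_dataset` of positive pairs (label 1).
#' @param ratio negatives per positive (default 1).
#' @param rng_seed integer seed.
#' @param drugs optional drug universe (default: drugs occurring in
#'   `positives`).
#' @return a `pair_dataset` combining the positives and sampled negatives.
#' @export
sample_negatives <- function(positives, ratio = 1, rng_seed = 1L,
                             drugs = NULL) {
  drugs <- drugs %||% attr(positives, "drugs") %||%
    sort(unique(c(positives$drug1, positives$drug2)))
  n <- length(drugs)
  n_pos <- nrow(positives)
  n_neg <- round(ratio * n_pos)
  n_all <- n * (n - 1) / 2
  pos_key <- pair_key(positives$drug1, positives$drug2)
  avail <- n_all - length(unique(pos_key))
  if (avail == 0L) stop_smilegnn("no non-positive pairs left to sample")
  if (n_neg > avail) {
    warning(sprintf("requested %d negatives but only %d non-positive pairs exist; returning all of them",
                    n_neg, avail), call. = FALSE)
    n_neg <- avail
  }
  neg1 <- character(0); neg2 <- character(0)
  with_seed(derive_seed(rng_seed, 271), {
    got <- character(0)
    while (length(got) < n_neg) {
      k <- min(max(2L * (n_neg - length(got)), 64L), 1e6)
      i <- sample.int(n, k, replace = TRUE)
      j <- sample.int(n, k, replace = TRUE)
      ok <- i != j
      a <- drugs[pmin(i[ok], j[ok])]; b <- drugs[pmax(i[ok], j[ok])]
      key <- pair_key(a, b)
      new <- !(key %in% pos_key) & !(key %in% got) & !duplicated(key)
      got <- c(got, key[new])
      neg1 <- c(neg1, a[new]); neg2 <- c(neg2, b[new])
    }
  })
  pair_dataset(c(positives$drug1, neg1[seq_len(n_neg)]),
               c(positives$drug2, neg2[seq_len(n_neg)]),
               c(positives$label, rep(0L, n_neg)))
}

# --- training ----------------------------------------------------------

align_struct_matrix <- function(struct, kg, config) {
  ds <- config$d_struct
  Bmat <- matrix(0, length(kg$entities), ds)
  if (!is.null(struct) && config$use_structure) {
    if (ncol(struct$features) != ds) {
      stop_smilegnn("structural features have %d dims but config$d_struct = %d",
                    ncol(struct$features), ds)
    }
    hit <- match(struct$drug_ids, kg$entities)
    ok <- !is.na(hit)
    feats <- struct$features[ok, , drop = FALSE]
    # per-column standardisation keeps PCA scores on the embedding scale
    sds <- apply(feats[!struct$missing_mask[ok], , drop = FALSE], 2, stats::sd)
    sds[!is.finite(sds) | sds == 0] <- 1
    Bmat[hit[ok], ] <- sweep(feats, 2, sds, `/`)
  }
  Bmat
}

#' Train the DDI model
#'
#' Mini-batch Adam on the mean binary cross-entropy of pair scores. All
#' randomness (initialisation, receptive-field sampling, epoch shuffling)
#' derives from `config$seed`, so training is fully reproducible. When
#' `val_pairs` is given, the parameters with the best validation AUC are
#' kept.
#'
#' @param kg a `knowledge_graph`.
#' @param struct a `structural_features` object, or NULL for topology-only.
#' @param dataset a `pair_dataset` of labelled training pairs.
#' @param config a `train_config`.
#' @param val_pairs optional `pair_dataset` scored each epoch for
#'   checkpointing.
#' @param verbose print per-epoch loss.
#' @return object of class `smilegnn_model` with fitted parameters, the
#'   receptive fields, the aligned structural matrix and the loss history.
#' @export
train <- function(kg, struct, dataset, config, val_pairs = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(kg, "knowledge_graph"), nrow(dataset) > 0)
  i1 <- kg_entity_id(kg, dataset$drug1)
  i2 <- kg_entity_id(kg, dataset$drug2)
  y <- dataset$label
  Bmat <- align_struct_matrix(struct, kg, config)
  fields <- build_receptive_fields(kg, config$n_hops, config$sample_size,
                                   derive_seed(config$seed, 7))
  params <- init_gnn_params(length(kg$entities), length(kg$relations), config)
  state <- adam_init(params)

  vi1 <- vi2 <- vy <- NULL
  if (!is.null(val_pairs)) {
    vi1 <- kg_entity_id(kg, val_pairs$drug1)
    vi2 <- kg_entity_id(kg, val_pairs$drug2)
    vy <- val_pairs$label
  }
  best_auc <- -Inf; best_params <- NULL
  n <- length(y)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_auc = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ep_fields <- if (config$resample_fields && epoch > 1L) {
      build_receptive_fields(kg, config$n_hops, config$sample_size,
                             derive_seed(config$seed, 7, epoch))
    } else fields
    ord <- with_seed(derive_seed(config$seed, 1000 + epoch), sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      fwd <- model_forward(params, ep_fields, Bmat, i1[idx], i2[idx],
                           keep_cache = TRUE)
      ep_loss <- ep_loss + bce_loss(y[idx], fwd$score)
      grads <- model_backward(params, ep_fields, fwd, y[idx])
      o <- adam_step(params, grads, state, config$learning_rate,
                     weight_decay = config$weight_decay)
      params <- o$params; state <- o$state
    }
    if (!is.finite(ep_loss)) {
      stop_smilegnn("training diverged at epoch %d (non-finite loss)", epoch)
    }
    val_auc <- NA_real_
    if (!is.null(val_pairs)) {
      vs <- model_forward(params, fields, Bmat, vi1, vi2)$score
      val_auc <- auc_score(vy, vs)
      if (is.finite(val_auc) && val_auc > best_auc) {
        best_auc <- val_auc; best_params <- params
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / n,
                                         val_auc = val_auc))
    if (verbose) {
      message(sprintf("epoch %3d  mean loss %.4f%s", epoch, ep_loss / n,
                      if (is.na(val_auc)) "" else sprintf("  val AUC %.4f", val_auc)))
    }
  }
  if (!is.null(best_params)) params <- best_params
  structure(list(params = params, config = config, fields = fields,
                 Bmat = Bmat, entities = kg$entities,
                 drug_idx = kg$drug_idx, history = history),
            class = "smilegnn_model")
}

#' @export
print.smilegnn_model <- function(x, ...) {
  cat(sprintf(
    "<smilegnn_model> %d entities, d_topo = %d, aggregator = %s, fusion = %s\n",
    nrow(x$params$E), x$config$embed_dim, x$config$aggregator_type,
    x$config$fusion_method))
  cat(sprintf("  trained %d epochs, final mean loss %.4f\n",
              nrow(x$history), utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Score drug pairs with a trained model
#'
#' @param object a `smilegnn_model`.
#' @param pairs data.frame with columns `drug1`, `drug2`.
#' @param ... unused.
#' @return numeric vector of interaction scores in (0, 1).
#' @export
predict.smilegnn_model <- function(object, pairs, ...) {
  i1 <- match(pairs$drug1, object$entities)
  i2 <- match(pairs$drug2, object$entities)
  if (anyNA(i1) || anyNA(i2)) {
    bad <- unique(c(pairs$drug1[is.na(i1)], pairs$drug2[is.na(i2)]))
    stop_smilegnn("drugs absent from the model's graph: %s",
                  paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- numeric(nrow(pairs))
  bs <- 4096L
  for (start in seq(1L, nrow(pairs), by = bs)) {
    idx <- start:min(start + bs - 1L, nrow(pairs))
    out[idx] <- model_forward(object$params, object$fields, object$Bmat,
                              i1[idx], i2[idx])$score
  }
  out
}

# --- metrics ------------------------------------------------------------

#' Area under the ROC curve by the Mann-Whitney rank statistic
#'
#' Equals the probability that a uniformly chosen positive outscores a
#' uniformly chosen negative, ties counted half.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return AUC in \[0, 1\]; NA if only one class is present.
#' @export
auc_score <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at the 0.5 threshold
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores; predicted label is 1 iff score > 0.5.
#' @return list with `accuracy`, `auc`, `f1` (binary F1 of the positive
#'   class; 0 when precision + recall is 0).
#' @export
classification_metrics <- function(labels, scores) {
  pred <- as.integer(scores > 0.5)
  acc <- mean(pred == labels)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = acc, auc = auc_score(labels, scores), f1 = f1)
}

# stratified fold assignment: splits positives and negatives separately so the
# label ratio of every fold matches the dataset within one pair
stratified_folds <- function(labels, n_folds, rng_seed) {
  fold <- integer(length(labels))
  with_seed(derive_seed(rng_seed, 555), {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

#' Stratified cross-validated evaluation
#'
#' Splits the pairs into `config$n_folds` label-stratified folds; for each
#' fold trains on the rest (with 10% of the training fold held out as a
#' validation set for epoch checkpointing) and computes accuracy, AUC and F1
#' on the held-out fold. Folds whose held-out part contains a single class
#' are skipped with a warning.
#'
#' @param kg a `knowledge_graph`.
#' @param struct a `structural_features` or NULL.
#' @param dataset a `pair_dataset`.
#' @param config a `train_config`.
#' @param verbose print fold progress.
#' @return list of class `eval_metrics`: `per_fold` data.frame and `mean`
#'   (named vector accuracy/auc/f1).
#' @export
evaluate_cv <- function(kg, struct, dataset, config, verbose = FALSE) {
  if (config$n_folds > sum(dataset$label == 1)) {
    stop_smilegnn("more folds (%d) than positive pairs (%d)",
                  config$n_folds, sum(dataset$label == 1))
  }
  fold <- stratified_folds(dataset$label, config$n_folds, config$seed)
  rows <- list()
  for (k in seq_len(config$n_folds)) {
    test <- dataset[fold == k, , drop = FALSE]
    if (length(unique(test$label)) < 2) {
      warning(sprintf("fold %d has a single class; skipped", k))
      next
    }
    tr <- dataset[fold != k, , drop = FALSE]
    vfold <- stratified_folds(tr$label, 10L, derive_seed(config$seed, k))
    val <- tr[vfold == 1L, , drop = FALSE]
    tr <- tr[vfold != 1L, , drop = FALSE]
    cfg_k <- config
    cfg_k$seed <- derive_seed(config$seed, 40 + k)
    model <- train(kg, struct, tr, cfg_k, val_pairs = val)
    m <- classification_metrics(test$label, predict(model, test))
    if (verbose) {
      message(sprintf("fold %d: acc %.4f auc %.4f f1 %.4f",
                      k, m$accuracy, m$auc, m$f1))
    }
    rows[[length(rows) + 1L]] <- data.frame(fold = k, accuracy = m$accuracy,
                                            auc = m$auc, f1 = m$f1)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[, c("accuracy", "auc", "f1")])),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> %d folds: mean ACC %.4f, AUC %.4f, F1 %.4f\n",
              nrow(x$per_fold), x$mean["accuracy"], x$mean["auc"],
              x$mean["f1"]))
  invisible(x)
}

#' Rank novel candidate interactions
#'
#' Scores every candidate pair, removes pairs already recorded as positives
#' (in either order), keeps scores strictly above `threshold` and returns
#' them sorted from highest to lowest.
#'
#' @param model a trained `smilegnn_model`.
#' @param candidate_pairs data.frame with `drug1`, `drug2`.
#' @param known_positives data.frame of recorded interactions to eliminate.
#' @param threshold minimum score, exclusive (default 0.9).
#' @param top_k maximum rows returned (default all).
#' @return data.frame `drug1`, `drug2`, `score`, `predicted_label`, ordered
#'   by decreasing score; may be empty.
#' @export
rank_novel_pairs <- function(model, candidate_pairs, known_positives,
                             threshold = 0.9, top_k = Inf) {
  key <- pair_key(candidate_pairs$drug1, candidate_pairs$drug2)
  keep <- !duplicated(key)
  if (!is.null(known_positives) && nrow(known_positives) > 0) {
    keep <- keep & !(key %in% pair_key(known_positives$drug1,
                                       known_positives$drug2))
  }
  cand <- candidate_pairs[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(drug1 = character(0), drug2 = character(0),
                      score = numeric(0), predicted_label = integer(0)))
  }
  sc <- predict(model, cand)
  sel <- sc > threshold
  out <- data.frame(drug1 = cand$drug1[sel], drug2 = cand$drug2[sel],
                    score = sc[sel], stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  out$predicted_label <- as.integer(out$score > 0.5)
  rownames(out) <- NULL
  out
}

#' Grid search over training configurations
#'
#' Evaluates every configuration with [evaluate_cv()] and returns the one
#' with the highest mean AUC; ties are broken by higher mean F1, then by
#' smaller embedding dimension.
#'
#' @param config_grid list of `train_config` objects.
#' @param kg,struct,dataset as in [evaluate_cv()].
#' @param verbose print progress.
#' @return list with `best` (the winning config), `best_metrics`, and
#'   `results` (a data.frame of mean metrics per configuration).
#' @export
grid_search <- function(config_grid, kg, struct, dataset, verbose = FALSE) {
  stopifnot(length(config_grid) >= 1)
  res <- lapply(seq_along(config_grid), function(i) {
    m <- evaluate_cv(kg, struct, dataset, config_grid[[i]])
    if (verbose) message(sprintf("config %d: mean AUC %.4f", i, m$mean["auc"]))
    data.frame(config = i, accuracy = m$mean["accuracy"], auc = m$mean["auc"],
               f1 = m$mean["f1"],
               embed_dim = config_grid[[i]]$embed_dim)
  })
  results <- do.call(rbind, res)
  o <- order(-results$auc, -results$f1, results$embed_dim)
  best_i <- results$config[o[1]]
  list(best = config_grid[[best_i]], best_index = best_i,
       best_metrics = results[o[1], ], results = results)
}
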