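# Shared fixtures: corpora built in code, tiny network setups, and a
# finite-difference gradient oracle.

# the four annotated sample sentences (temporal, sentiment, ordered
# emotions) used for mapping-fidelity checks
table1_corpus <- function() {
  mt_corpus(
    id = c("t1", "t2", "t3", "t4"),
    text = c("I did have dreams, just like everyone",
             "Like cherry blossoms in the spring let us so pure fall and radiant",
             "Wherever I look... they have come for me and I must go",
             "And the way the current system is set up, it protects all cops"),
    temporal = c("past", "future", "future", "present"),
    sentiment = NULL,
    emotions = list(c("sorrow", "hopelessness"),
                    c("hopefulness", "happiness_peacefulness", "instructions"),
                    c("information"),
                    c("blame", "anger", "information")))
}

table1_sentiments <- c("negative", "positive", "neutral", "negative")

tiny_config <- function(arch, seed = 11L, dropout = 0) {
  mt_config(embedding_dim = 5L, encoder_units = 3L, attn_units = 4L,
            mlp_units = 3L, dropout_rate = dropout, architecture = arch,
            seed = seed)
}

# a minimal two-sentence batch with hand-chosen padding for network tests
tiny_setup <- function(arch, seed = 11L, truth_seed = 99L) {
  cfg <- tiny_config(arch, seed)
  desc <- assemble(cfg)
  vocab <- c("<pad>", "<oov>", paste0("w", 1:6))
  emb <- mtcascade:::vocab_embedding_matrix(
    random_embeddings(vocab, 5L, seed = 3L), vocab)
  idx <- rbind(c(3L, 4L, 5L, 1L), c(6L, 7L, 1L, 1L))
  mask <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 0))
  params <- mtcascade:::init_params(desc, 5L, 21L)
  truth <- mtcascade:::with_seed(truth_seed, {
    list(temporal = rbind(c(1, 0, 0), c(0, 1, 0)),
         sentiment = rbind(c(0, 0, 1), c(1, 0, 0)),
         emotion = matrix(rbinom(30, 1, 0.3), 2, 15))
  })
  if (desc$single) truth <- truth[desc$tasks]
  list(cfg = cfg, desc = desc, emb = emb, idx = idx, mask = mask,
       params = params, truth = truth)
}

setup_loss <- function(s, params, w = c(0.3, 0.3, 1)) {
  fwd <- mtcascade:::network_forward(params, s$desc, s$emb, s$idx, s$mask,
                                     train = FALSE)
  lb <- joint_loss(s$truth, fwd$probs, w)
  if (s$desc$single) lb$l1 + lb$l2 + lb$l3 else lb$total
}

modify_leaf <- function(params, path, f) {
  if (!length(path)) return(f(params))
  params[[path[1L]]] <- modify_leaf(params[[path[1L]]], path[-1L], f)
  params
}

leaf_paths <- function(p, pre = character(0)) {
  if (!is.list(p)) return(list(pre))
  out <- list()
  for (nm in names(p)) out <- c(out, leaf_paths(p[[nm]], c(pre, nm)))
  out
}

get_leaf <- function(p, path) {
  for (k in path) p <- p[[k]]
  p
}

# central finite difference of the setup loss w.r.t. one parameter entry
numeric_grad <- function(s, path, i, w = c(0.3, 0.3, 1), eps = 1e-5) {
  lp <- setup_loss(s, modify_leaf(s$params, path,
                                  function(m) { m[i] <- m[i] + eps; m }), w)
  lm <- setup_loss(s, modify_leaf(s$params, path,
                                  function(m) { m[i] <- m[i] - eps; m }), w)
  (lp - lm) / (2 * eps)
}

# a small corpus whose tokens identify the labels perfectly
separable_corpus <- function(n = 60L, seed = 5L) {
  synth_corpus(default_synth_spec(n = n, seed = seed, signal_strength = 1))
}

# quick-training configuration for functional tests
fast_config <- function(arch, epochs = 5L, seed = 2L) {
  mt_config(embedding_dim = 12L, encoder_units = 6L, mlp_units = 8L,
            epochs = epochs, architecture = arch, seed = seed)
}
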