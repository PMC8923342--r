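test_that("intermediate-representation widths follow the cascade algebra", {
  cfg <- function(a) mt_config(encoder_units = 256, mlp_units = 128,
                               architecture = a)
  expect_equal(unname(assemble(cfg("spanmlc"))$ir_widths),
               c(640L, 1280L, 1920L))
  expect_equal(unname(assemble(cfg("mtl2"))$ir_widths), c(640L, 643L, 643L))
  expect_equal(unname(assemble(cfg("mtl4"))$ir_widths), c(640L, 640L, 640L))
  expect_equal(unname(assemble(cfg("mtl3"))$ir_widths),
               c(640L, 1280L, 1920L))
  expect_error(mt_config(architecture = "transformer"))
})

test_that("parameter counts order the ablations as their topology implies", {
  pc <- function(a) param_count(assemble(mt_config(architecture = a)))
  # removing private attentions shrinks the model; removing the cascade
  # shrinks the heads
  expect_lt(pc("mtl3"), pc("mtl4"))
  expect_lt(pc("mtl4"), pc("spanmlc"))
  expect_lt(pc("mtl1"), pc("mtl3"))
  expect_lt(pc("single_temporal"), pc("mtl1"))
  # counting oracle: the dimensional formula equals the allocated sizes
  for (a in c("single_emotion", "mtl1", "mtl2", "mtl3", "mtl4", "spanmlc")) {
    desc <- assemble(tiny_config(a))
    params <- mtcascade:::init_params(desc, 5L, 1L)
    n_alloc <- sum(rapply(params, length, how = "unlist"))
    expect_identical(param_count(desc, 5L), as.integer(n_alloc), label = a)
  }
})

test_that("probability contracts hold for random parameters", {
  for (seed in c(1, 5, 9, 13, 17)) {
    for (arch in c("mtl2", "spanmlc", "mtl1")) {
      s <- tiny_setup(arch, seed = seed)
      s$params <- mtcascade:::init_params(s$desc, 5L, seed * 31L)
      fwd <- mtcascade:::network_forward(s$params, s$desc, s$emb, s$idx,
                                         s$mask, train = FALSE)
      expect_equal(unname(rowSums(fwd$probs$temporal)), c(1, 1),
                   tolerance = 1e-6)
      expect_equal(unname(rowSums(fwd$probs$sentiment)), c(1, 1),
                   tolerance = 1e-6)
      expect_true(all(fwd$probs$emotion >= 0 & fwd$probs$emotion <= 1))
      # attention rows are convex weights over unmasked tokens
      aw <- fwd$cache$satt$weights
      expect_equal(unname(rowSums(aw)), c(1, 1), tolerance = 1e-9)
      expect_true(all(aw >= 0))
    }
  }
})

test_that("emotion-loss gradients reach the first subnet only through the cascade", {
  l3_grads <- function(arch) {
    s <- tiny_setup(arch)
    fwd <- mtcascade:::network_forward(s$params, s$desc, s$emb, s$idx,
                                       s$mask, train = FALSE)
    mtcascade:::network_backward(s$params, s$desc, fwd, s$truth, c(0, 0, 1))
  }
  g_span <- l3_grads("spanmlc")
  g_mtl4 <- l3_grads("mtl4")
  g_mtl2 <- l3_grads("mtl2")
  norm <- function(g) sum(abs(unlist(g)))
  # cascaded: the chain rule carries the emotion loss into subnet 1's
  # private attention; uncascaded: that path does not exist
  expect_gt(norm(g_span$att_private$temporal), 1e-8)
  expect_identical(norm(g_mtl4$att_private$temporal), 0)
  expect_gt(norm(g_mtl2$att_private$temporal), 1e-8)
  # same contrast for the temporal head, reached via O_T in the output
  # cascade only
  expect_gt(norm(g_mtl2$head$temporal), 1e-8)
  expect_identical(norm(g_mtl4$head$temporal), 0)
})

test_that("the joint loss is the stated weighted sum and zero at certainty", {
  y <- list(temporal = rbind(c(1, 0, 0)), sentiment = rbind(c(0, 1, 0)),
            emotion = matrix(rep(c(1, 0, 0), 5), 1, 15))
  perfect <- joint_loss(y, y, c(0.3, 0.3, 1))
  expect_equal(perfect$l1, 0)
  expect_equal(perfect$l2, 0)
  expect_equal(perfect$l3, 0)
  expect_equal(perfect$total, 0)
  # unit per-task losses combine to p + q + r = 1.6
  p1 <- list(temporal = rbind(c(exp(-1), 1 - exp(-1), 0)),
             sentiment = rbind(c(1 - exp(-1), exp(-1), 0)),
             emotion = matrix(ifelse(y$emotion == 1, exp(-1), 1 - exp(-1)),
                              1, 15))
  lb <- joint_loss(y, p1, c(0.3, 0.3, 1))
  expect_equal(lb$l1, 1, tolerance = 1e-12)
  expect_equal(lb$l2, 1, tolerance = 1e-12)
  expect_equal(lb$l3, 1, tolerance = 1e-12)
  expect_equal(lb$total, 1.6, tolerance = 1e-12)
  # half-confidence temporal, other tasks perfect: 0.3 * ln 2
  ph <- list(temporal = rbind(c(0.5, 0.5, 0)), sentiment = y$sentiment,
             emotion = y$emotion)
  expect_equal(joint_loss(y, ph, c(0.3, 0.3, 1))$total, 0.3 * log(2),
               tolerance = 1e-12)
  # linear in each weight with per-task losses fixed
  for (w in list(c(1, 0, 0), c(0, 2, 0), c(0.5, 0.25, 4))) {
    lw <- joint_loss(y, p1, w)
    expect_equal(lw$total, sum(w * c(lw$l1, lw$l2, lw$l3)), tolerance = 1e-12)
  }
  expect_error(joint_loss(list(temporal = diag(3)),
                          list(temporal = rbind(c(1, 0, 0))), c(1, 1, 1)),
               "shape")
})

test_that("attention export aligns with the forward pass layer by layer", {
  corp <- separable_corpus(40)
  fit <- mtcascade(corp, fast_config("spanmlc", epochs = 1))
  toks <- corp$tokens[[1L]]
  ex <- export_attention(fit, toks)
  expect_named(ex, c("shared", "temporal", "sentiment", "emotion"))
  for (ly in names(ex)) {
    expect_length(ex[[ly]], length(toks))
    expect_equal(sum(ex[[ly]]), 1, tolerance = 1e-9)
  }
  # one-token sentence: every layer reports weight 1
  ex1 <- export_attention(fit, toks[1L])
  for (ly in names(ex1)) expect_equal(ex1[[ly]], 1)
  # internal consistency with attend() on the same encoder states
  vec <- mtcascade:::vectorize_tokens(list(toks), fit$vocab, length(toks))
  fwd <- mtcascade:::network_forward(fit$params, fit$desc, fit$emb,
                                     vec$idx, vec$mask, train = FALSE)
  direct <- attend(fwd$cache$enc$H, vec$mask, fit$params$att_private$temporal)
  expect_equal(ex$temporal, as.vector(direct$weights[1L, ]),
               tolerance = 1e-12)
  # architectures without private attention export the shared layer only
  fit3 <- mtcascade(corp, fast_config("mtl3", epochs = 1))
  expect_warning(ex3 <- export_attention(fit3, toks), "private")
  expect_named(ex3, "shared")
  # TSV export
  f <- tempfile(fileext = ".tsv")
  suppressWarnings(export_attention(fit, toks, file = f))
  tab <- read.delim(f)
  expect_identical(nrow(tab), 4L * length(toks))
})
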