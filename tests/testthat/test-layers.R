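test_that("attention handles single and symmetric inputs exactly", {
  p <- list(W = matrix(c(0.2, -0.1, 0.3, 0.4), 2, 2), b = c(0.1, -0.2),
            u = c(0.5, 0.7))
  s1 <- list(matrix(c(1, 0.5), 1, 2))
  r1 <- attend(s1, matrix(1, 1, 1), p)
  expect_equal(as.vector(r1$weights), 1)
  expect_equal(r1$context, s1[[1L]])
  # identical states at every position -> uniform weights
  st <- matrix(c(0.3, -0.4), 1, 2)
  r4 <- attend(rep(list(st), 4), matrix(1, 1, 4), p)
  expect_equal(as.vector(r4$weights), rep(0.25, 4))
  expect_equal(r4$context, st)
  expect_error(attend(s1, matrix(0, 1, 1), p), "masked")
})

test_that("attention matches a hand-computed softmax on a 2-position toy", {
  p <- list(W = matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2), b = c(0.05, -0.1),
            u = c(1, -0.5))
  h1 <- c(0.2, 0.7); h2 <- c(-0.3, 0.4)
  states <- list(matrix(h1, 1, 2), matrix(h2, 1, 2))
  e <- vapply(list(h1, h2), function(h)
    sum(tanh(as.vector(h %*% p$W) + p$b) * p$u), numeric(1))
  alpha <- exp(e) / sum(exp(e))
  r <- attend(states, matrix(1, 1, 2), p)
  expect_equal(as.vector(r$weights), alpha, tolerance = 1e-6)
  expect_equal(as.vector(r$context), alpha[1] * h1 + alpha[2] * h2,
               tolerance = 1e-6)
})

test_that("a gated recurrence step matches the hand-rolled formula", {
  # 1-dimensional input and state with hand-set gate parameters
  p <- list(Wx = matrix(c(0.5, -0.3, 0.8), 1, 3),   # z, r, candidate
            Uzr = matrix(c(0.2, -0.1), 1, 2),
            Uh = matrix(0.4, 1, 1),
            b = c(0.1, -0.2, 0.05))
  x1 <- 0.6; x2 <- -0.4
  sig <- function(v) 1 / (1 + exp(-v))
  step <- function(x, h) {
    z <- sig(x * 0.5 + h * 0.2 + 0.1)
    r <- sig(x * -0.3 + h * -0.1 - 0.2)
    cc <- tanh(x * 0.8 + (r * h) * 0.4 + 0.05)
    (1 - z) * h + z * cc
  }
  h1 <- step(x1, 0); h2 <- step(x2, h1)
  X <- list(matrix(x1, 1, 1), matrix(x2, 1, 1))
  out <- mtcascade:::gru_forward(X, matrix(1, 1, 2), p, 1L)
  expect_equal(as.vector(out$H[[1L]]), h1, tolerance = 1e-12)
  expect_equal(as.vector(out$H[[2L]]), h2, tolerance = 1e-12)
})

test_that("padding positions never influence unmasked encoder states", {
  s <- tiny_setup("spanmlc")
  out1 <- mtcascade:::network_forward(s$params, s$desc, s$emb, s$idx,
                                      s$mask, train = FALSE)
  # change token ids under the mask; outputs must be identical
  idx2 <- s$idx
  idx2[1L, 4L] <- 7L
  idx2[2L, 3:4] <- c(4L, 5L)
  out2 <- mtcascade:::network_forward(s$params, s$desc, s$emb, idx2,
                                      s$mask, train = FALSE)
  expect_equal(out1$probs, out2$probs, tolerance = 1e-12)
  # masked attention weights are exactly zero
  expect_equal(out1$cache$satt$weights[1L, 4L], 0)
  expect_equal(out1$cache$satt$weights[2L, 3:4], c(0, 0))
})

test_that("analytic gradients match finite differences in every architecture", {
  for (arch in c("single_temporal", "single_emotion", "mtl1", "mtl2",
                 "mtl3", "mtl4", "spanmlc")) {
    s <- tiny_setup(arch)
    w <- c(0.3, 0.3, 1)
    fwd <- mtcascade:::network_forward(s$params, s$desc, s$emb, s$idx,
                                       s$mask, train = FALSE)
    g <- mtcascade:::network_backward(s$params, s$desc, fwd, s$truth, w)
    set.seed(7)
    for (pth in leaf_paths(s$params)) {
      ga <- get_leaf(g, pth)
      val <- get_leaf(s$params, pth)
      for (i in sample(length(val), min(3L, length(val)))) {
        ng <- numeric_grad(s, pth, i, w)
        expect_lt(abs(ng - ga[i]), 1e-6 + 1e-3 * max(abs(ng), abs(ga[i])),
                  label = sprintf("%s %s[%d]", arch,
                                  paste(pth, collapse = "$"), i))
      }
    }
  }
})

test_that("dropout is active only in training mode", {
  s <- tiny_setup("spanmlc")
  s$desc$config$dropout_rate <- 0.5
  ev1 <- mtcascade:::network_forward(s$params, s$desc, s$emb, s$idx,
                                     s$mask, train = FALSE)
  ev2 <- mtcascade:::network_forward(s$params, s$desc, s$emb, s$idx,
                                     s$mask, train = FALSE)
  expect_identical(ev1$probs, ev2$probs)
  set.seed(1)
  tr1 <- mtcascade:::network_forward(s$params, s$desc, s$emb, s$idx,
                                     s$mask, train = TRUE)
  tr2 <- mtcascade:::network_forward(s$params, s$desc, s$emb, s$idx,
                                     s$mask, train = TRUE)
  expect_false(identical(tr1$probs, tr2$probs))
})
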