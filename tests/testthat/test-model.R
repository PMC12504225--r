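# Architecture contracts: embedding, positional encoding, masking, forward
# shapes, freezing, and analytic-vs-numerical gradients.

test_that("patch embedding is affine and produces the stated shapes", {
  m <- init_model(model_spec(), seed = 1)       # reference 64/18/24 config
  w <- matrix(rnorm(64 * 18), 64, 18)
  tok <- embed_patches(w, m)
  expect_equal(dim(tok), c(64, 24))

  m0 <- m
  m0$params[["embed.b"]][] <- 0
  expect_equal(embed_patches(matrix(0, 64, 18), m0), matrix(0, 64, 24))

  a <- matrix(rnorm(64 * 18), 64, 18)
  b <- matrix(rnorm(64 * 18), 64, 18)
  expect_equal(embed_patches(a + b, m),
               embed_patches(a, m) + embed_patches(b, m) -
                 embed_patches(matrix(0, 64, 18), m),
               tolerance = 1e-10)
  expect_error(embed_patches(matrix(0, 10, 18), m),
               class = "gaitssl_schema_error")
})

test_that("sinusoidal positional encoding matches its closed form", {
  pe <- positional_encoding(64, 24)
  expect_equal(pe[1, seq(1, 23, 2)], rep(0, 12))   # sin(0)
  expect_equal(pe[1, seq(2, 24, 2)], rep(1, 12))   # cos(0)
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_true(all(pe >= -1 & pe <= 1))
  for (pos in c(0, 7, 63)) for (i in 0:11) {
    ang <- pos / 10000^(2 * i / 24)
    expect_equal(pe[pos + 1, 2 * i + 1], sin(ang), tolerance = 1e-12)
    expect_equal(pe[pos + 1, 2 * i + 2], cos(ang), tolerance = 1e-12)
  }
  expect_error(positional_encoding(8, 7), class = "gaitssl_invalid_argument")
})

test_that("masking replaces the exact count of positions reproducibly", {
  m <- init_model(toy_model_spec(window = 64L), seed = 2)
  tok <- matrix(rnorm(64 * 8), 64, 8)
  res <- apply_mask(tok, mask_spec(0.10, seed = 3), m)
  expect_length(res$masked_idx, 6)                 # round(0.10 * 64)
  expect_equal(res$tokens[res$masked_idx[1], ], m$params[["mask_token"]])
  expect_equal(res$tokens[-res$masked_idx, ], tok[-res$masked_idx, ])

  res0 <- apply_mask(tok, mask_spec(0, seed = 3), m)
  expect_length(res0$masked_idx, 0)
  expect_identical(res0$tokens, tok)

  res2 <- apply_mask(tok, mask_spec(0.10, seed = 3), m)
  expect_identical(res$masked_idx, res2$masked_idx)
  expect_error(apply_mask(tok, mask_spec(0.999, seed = 1), m),
               class = "gaitssl_invalid_argument")
})

test_that("forward pass honours shape contracts across configurations", {
  cases <- list(c(64L, 18L, 18L), c(64L, 2L, 2L), c(32L, 6L, 1L),
                c(16L, 1L, 3L))
  for (cs in cases) {
    sp <- model_spec(window = cs[1], n_channels_in = cs[2],
                     n_channels_out = cs[3], d_model = 8L, n_blocks = 1L,
                     n_heads = 2L, ffn_dim = 8L)
    m <- init_model(sp, seed = 1)
    y <- model_forward(m, matrix(rnorm(cs[1] * cs[2]), cs[1], cs[2]))
    expect_equal(dim(y), c(cs[1], cs[3]))
  }
  sp <- toy_model_spec()
  m <- init_model(sp, seed = 4)
  x <- matrix(rnorm(16 * 4), 16, 4)
  expect_identical(model_forward(m, x), model_forward(m, x))
  expect_error(model_forward(m, matrix(0, 16, 5)),
               class = "gaitssl_schema_error")
})

test_that("freezing six of eight blocks covers ~75% of encoder parameters", {
  m <- init_model(model_spec(), seed = 1)        # 8 blocks, d 24, ffn 2048
  fr <- freeze_prefix(m, 6)
  expect_equal(attr(fr, "frozen_fraction"), 0.75, tolerance = 0.01)
  expect_true(all(grepl("^(embed|mask_token|block0[1-6])",
                        fr$frozen)))
  expect_false(any(grepl("^head", fr$frozen)))

  un <- freeze_prefix(m, 0)
  expect_length(un$frozen, 0)
  expect_error(freeze_prefix(m, 9), class = "gaitssl_invalid_argument")
})

test_that("analytic gradients match numerical differentiation", {
  sp <- model_spec(window = 8L, n_channels_in = 3L, n_channels_out = 2L,
                   d_model = 8L, n_blocks = 2L, n_heads = 2L,
                   ffn_dim = 12L, dropout = 0)
  m <- init_model(sp, seed = 2)
  set.seed(7)
  B <- 3L; W <- 8L
  X <- matrix(rnorm(B * W * 3), B * W, 3)
  Tm <- matrix(rnorm(B * W * 2), B * W, 2)
  lossfun <- function(params) {
    mm <- m; mm$params <- params
    fwd <- gaitssl:::model_forward_pass(mm, X, W, training = TRUE)
    mean((fwd$Y - Tm)^2)
  }
  fwd <- gaitssl:::model_forward_pass(m, X, W, training = TRUE)
  gr <- gaitssl:::model_backward_pass(m, fwd, 2 * (fwd$Y - Tm) / length(Tm))
  eps <- 1e-6
  for (nm in c("embed.W", "mask_token", "block01.Wq", "block01.ln1.g",
               "block02.W1", "block02.bo", "head.W")) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      pp <- m$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- lossfun(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- lossfun(pp)
      num <- (up - dn) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("parameter count is a pure function of the architecture", {
  sp <- model_spec()
  n1 <- count_params(sp)$total
  n2 <- count_params(init_model(sp, seed = 99))$total
  expect_identical(n1, n2)
  d <- 24; ffn <- 2048
  block <- 4 * (d * d + d) + 2 * 2 * d + d * ffn + ffn + ffn * d + d
  expect_equal(count_params(sp)$encoder,
               18 * d + d + d + 8 * block)
})
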