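# Temperature softmax, channel-wise distillation loss, cross-entropy, and
# the distillation training step.

test_that("temperature softmax matches closed forms and normalises", {
  expect_equal(channel_softmax(rep(2.5, 4), temperature = 7),
               rep(0.25, 4))
  expect_equal(channel_softmax(c(0, log(2)), 1), c(1 / 3, 2 / 3))
  # direct evaluation at T = 4
  y <- c(0, log(2))
  e <- exp(y / 4)
  expect_equal(channel_softmax(y, 4), e / sum(e), tolerance = 1e-12)
  expect_error(channel_softmax(c(0, 1), 0), "positive")
  expect_error(channel_softmax(c(0, 1), -2), "positive")
})

test_that("softmax outputs are strictly positive and sum to one", {
  set.seed(81)
  for (i in 1:25) {
    y <- rnorm(sample(2:50, 1), sd = sample(c(0.1, 1, 30), 1))
    th <- channel_softmax(y, sample(c(0.5, 1, 4, 16), 1))
    expect_equal(sum(th), 1, tolerance = 1e-9)
    expect_true(all(th > 0))
  }
  # extreme logits stay finite thanks to max-subtraction
  expect_equal(sum(channel_softmax(c(1e4, 0, -1e4), 1)), 1)
})

test_that("distillation loss vanishes iff distributions coincide", {
  set.seed(82)
  y <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  for (tt in c(1, 4, 16))
    expect_equal(kd_loss(y, y, tt), 0, tolerance = 1e-12)
  # per-channel logit shifts leave the channel distributions unchanged
  y2 <- y
  for (cc in 1:3) y2[, , cc] <- y2[, , cc] + cc * 3.7
  expect_equal(kd_loss(y, y2, 4), 0, tolerance = 1e-10)
  # any genuine difference is penalised
  y3 <- y; y3[1, 1, 1] <- y3[1, 1, 1] + 1
  expect_gt(kd_loss(y, y3, 4), 0)
  expect_error(kd_loss(y, array(0, c(4, 5, 2)), 4), "shapes")
})

test_that("two-point single-channel distillation equals the hand-computed KL", {
  teacher <- array(c(0, 0), c(1, 2, 1))
  student <- array(c(0, log(3)), c(1, 2, 1))
  # uniform teacher vs (1/4, 3/4) student at T = 1:
  # 0.5 log(0.5/0.25) + 0.5 log(0.5/0.75) = 0.5 log(4/3)
  expect_equal(kd_loss(teacher, student, 1), 0.5 * log(4 / 3),
               tolerance = 1e-9)
})

test_that("kd loss is nonnegative and its temperature-normalised value shrinks", {
  set.seed(83)
  teacher <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  student <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  temps <- c(1, 4, 16, 64)
  vals <- vapply(temps, function(tt)
    kd_loss(teacher, student, tt) * 4 / tt^2, numeric(1))
  expect_true(all(vals >= 0))
  # softened distributions approach uniform: KL decreases monotonically
  expect_true(all(diff(vals) < 0))
})

test_that("the T^2 factor keeps gradient magnitudes comparable across T", {
  set.seed(84)
  teacher <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  student <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  norms <- vapply(c(1, 2, 4, 8), function(tt)
    sqrt(sum(lodgeseg:::kd_loss_grad(teacher, student, tt)^2)),
    numeric(1))
  expect_lt(max(norms) / min(norms), 10)
})

test_that("kd gradient agrees with finite differences", {
  set.seed(85)
  teacher <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  student <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  g <- lodgeseg:::kd_loss_grad(teacher, student, 4)
  eps <- 1e-6
  for (idx in list(c(1, 1, 1), c(2, 3, 2), c(3, 4, 1))) {
    sp <- student; sp[idx[1], idx[2], idx[3]] <- sp[idx[1], idx[2], idx[3]] + eps
    sm <- student; sm[idx[1], idx[2], idx[3]] <- sm[idx[1], idx[2], idx[3]] - eps
    num <- (kd_loss(teacher, sp, 4) - kd_loss(teacher, sm, 4)) / (2 * eps)
    expect_equal(g[idx[1], idx[2], idx[3]], num, tolerance = 1e-6)
  }
})

test_that("cross-entropy matches closed forms and a hand-summed toy case", {
  # confident-correct logits drive the loss to zero
  lab <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  logits <- array(-50, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) logits[i, j, lab[i, j] + 1L] <- 50
  expect_lt(ce_loss(logits, lab), 1e-10)
  # uniform logits, K = 2: log(2) per pixel
  expect_equal(ce_loss(array(0, c(2, 2, 2)), lab), log(2))
  # 2x2 toy case, hand-summed
  lg <- array(0, c(2, 2, 2))
  lg[, , 1] <- matrix(c(1, 0, 2, -1), 2, 2)
  lg[, , 2] <- matrix(c(0, 1, -1, 3), 2, 2)
  labs <- matrix(c(0L, 1L, 1L, 1L), 2, 2)
  hand <- 0
  for (i in 1:2) for (j in 1:2) {
    p <- exp(lg[i, j, ]) / sum(exp(lg[i, j, ]))
    hand <- hand - log(p[labs[i, j] + 1L])
  }
  expect_equal(ce_loss(lg, labs), hand / 4, tolerance = 1e-12)
  expect_error(ce_loss(lg, matrix(5L, 2, 2)), "range")
  # ignored pixels are excluded from the mean
  labs2 <- labs; labs2[1, 1] <- 255L
  hand2 <- 0
  for (i in 1:2) for (j in 1:2) {
    if (labs2[i, j] == 255L) next
    p <- exp(lg[i, j, ]) / sum(exp(lg[i, j, ]))
    hand2 <- hand2 - log(p[labs2[i, j] + 1L])
  }
  expect_equal(ce_loss(lg, labs2), hand2 / 3, tolerance = 1e-12)
})

test_that("total loss combines linearly with the distillation weight", {
  expect_equal(total_loss(1.3, 0.7, distill_config(alpha = 0))$total, 1.3)
  expect_equal(total_loss(1, 0.5, distill_config(alpha = 3))$total, 2.5)
  lb <- total_loss(0.9, 0.2, distill_config(alpha = 2))
  lb2 <- total_loss(0.9, 0.2, distill_config(alpha = 4))
  expect_equal(lb2$total - lb$total, 2 * 0.2)
  expect_equal(lb$total, lb$ce + lb$alpha * lb$kd)
})

test_that("distillation steps never touch the teacher and reduce to plain training", {
  ts <- toy_tileset()
  tiles <- ts$tiles[1:4]
  teacher <- build_segmodel(tiny_spec(stages = c(1L, 1L), base_width = 8L),
                            seed = 5)
  student0 <- build_segmodel(tiny_spec(), seed = 6)
  teacher_before <- serialize(teacher$params, NULL)

  # alpha = 0 distillation step equals the supervised step
  s1 <- distill_step(teacher, student0, tiles,
                     distill_config(alpha = 0), lr = 1e-3)
  s2 <- distill_step(NULL, student0, tiles, distill_config(alpha = 0),
                     lr = 1e-3)
  expect_equal(s1$student$params, s2$student$params, tolerance = 1e-14)
  expect_equal(s1$loss$kd, 0)

  # ten distillation steps leave the teacher bitwise unchanged
  st <- student0; os <- NULL
  for (i in 1:10) {
    r <- distill_step(teacher, st, tiles, distill_config(4, 3),
                      lr = 1e-3, opt_state = os)
    st <- r$student; os <- r$opt_state
  }
  expect_identical(serialize(teacher$params, NULL), teacher_before)

  # reported breakdown matches independent loss recomputation
  r1 <- distill_step(teacher, student0, tiles, distill_config(4, 3),
                     lr = 1e-3)
  ce <- mean(vapply(tiles, function(t)
    ce_loss(forward_segment(student0, t$image), t$mask), numeric(1)))
  kd <- mean(vapply(tiles, function(t)
    kd_loss(forward_segment(teacher, t$image),
            forward_segment(student0, t$image), 4), numeric(1)))
  expect_equal(r1$loss$ce, ce, tolerance = 1e-10)
  expect_equal(r1$loss$kd, kd, tolerance = 1e-10)
  expect_equal(r1$loss$total, ce + 3 * kd, tolerance = 1e-10)

  # class-count mismatches are rejected
  teacher2 <- build_segmodel(
    segmodel_spec(backbone_spec("resnet", stages = c(1L, 1L),
                                base_width = 4L),
                  aspp_rates = c(1L, 2L, 3L), num_classes = 4L,
                  decoder_channels = 8L), seed = 1)
  expect_error(distill_step(teacher2, student0, tiles,
                            distill_config(4, 3)), "class counts")
})
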