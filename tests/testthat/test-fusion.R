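# The worked 3-box cluster used in several tests: confidences 0.9/0.6/0.5,
# all NG, weighted corner mean [10.1, 10.1, 20.1, 20.1].
worked_cluster <- function() {
  list(members = detections(1, c(10, 12, 8), c(10, 12, 8),
                            c(20, 22, 18), c(20, 22, 18),
                            c(0.9, 0.6, 0.5), rep("NG", 3),
                            c("m1", "m2", "m3")))
}

test_that("fuse_cluster reproduces the hand-computed weighted average", {
  cl <- worked_cluster()
  f <- fuse_cluster(cl, n_models = 6, fusion_config(divisor = "models"))
  expect_equal(unlist(f[c("x1", "y1", "x2", "y2")], use.names = FALSE),
               c(10.1, 10.1, 20.1, 20.1), tolerance = 1e-12)
  expect_equal(f$confidence, 2.0 / 6, tolerance = 1e-12)
  f2 <- fuse_cluster(cl, n_models = 6, fusion_config(divisor = "majority"))
  expect_equal(f2$confidence, 2.0 / 3, tolerance = 1e-12)
  expect_identical(f$label, "NG")
})

test_that("identical members fuse to themselves; equal weights cancel", {
  cl <- list(members = detections(1, rep(10, 3), rep(10, 3), rep(20, 3),
                                  rep(20, 3), rep(1, 3), rep("NG", 3),
                                  c("m1", "m2", "m3")))
  f <- fuse_cluster(cl, 3, fusion_config(divisor = "models"))
  expect_equal(unlist(f[c("x1", "y1", "x2", "y2")], use.names = FALSE),
               c(10, 10, 20, 20))
  expect_equal(f$confidence, 1)
  f2 <- fuse_cluster(cl, 3, fusion_config(divisor = "majority"))
  expect_equal(f2$confidence, 1)
  # two members with equal confidence -> unweighted mean, any c > 0
  for (c0 in c(0.2, 0.7)) {
    cl2 <- list(members = detections(1, c(0, 10), c(0, 10), c(10, 20),
                                     c(10, 20), rep(c0, 2), rep("L", 2),
                                     c("m1", "m2")))
    f3 <- fuse_cluster(cl2, 2)
    expect_equal(unlist(f3[c("x1", "y1", "x2", "y2")], use.names = FALSE),
                 c(5, 5, 15, 15))
  }
})

test_that("majority vote counts labels and resolves ties by summed confidence", {
  mk <- function(labels, confs) {
    n <- length(labels)
    list(members = detections(1, seq_len(n), seq_len(n), seq_len(n) + 10,
                              seq_len(n) + 10, confs, labels,
                              paste0("m", seq_len(n))))
  }
  v <- vote_type(mk(c("NG", "NG", "NG", "M"), rep(0.8, 4)))
  expect_identical(v$label, "NG"); expect_identical(v$majority, 3L)
  expect_false(v$tie_broken)
  v2 <- vote_type(mk("NG", 0.9))
  expect_identical(v2$label, "NG"); expect_identical(v2$majority, 1L)
  expect_false(v2$tie_broken)
  # 2 NG (0.9 + 0.8 = 1.7) vs 2 L (0.6 + 0.5 = 1.1)
  v3 <- vote_type(mk(c("NG", "NG", "L", "L"), c(0.9, 0.8, 0.6, 0.5)))
  expect_identical(v3$label, "NG"); expect_identical(v3$majority, 2L)
  expect_true(v3$tie_broken)
  # residual tie (equal sums) falls back to canonical class index: NG before L
  v4 <- vote_type(mk(c("L", "L", "NG", "NG"), c(0.5, 0.5, 0.5, 0.5)))
  expect_identical(v4$label, "NG"); expect_true(v4$tie_broken)
  v5 <- vote_type(mk(c("L", "L", "NG", "NG"), c(0.9, 0.8, 0.1, 0.1)),
                  fusion_config(tie_break = "class_index"))
  expect_identical(v5$label, "NG")
})

test_that("support filter keeps clusters at the N >= M/2 boundary", {
  mk_cluster <- function(n) {
    list(members = detections(1, rep(10, n), rep(10, n), rep(20, n),
                              rep(20, n), rep(0.8, n), rep("NG", n),
                              paste0("m", seq_len(n))),
         fused_box = c(10, 10, 20, 20))
  }
  flt <- filter_clusters(list(mk_cluster(4), mk_cluster(1)), n_models = 6)
  expect_length(flt$kept, 1)
  expect_identical(nrow(flt$kept[[1]]$members), 4L)
  expect_identical(nrow(flt$discarded), 1L)
  # exactly M/2 is kept (rule discards strictly below)
  expect_length(filter_clusters(list(mk_cluster(3)), 6)$kept, 1)
  expect_length(filter_clusters(list(mk_cluster(2)), 6)$kept, 0)
  # single-model degenerate case: singleton survives
  expect_length(filter_clusters(list(mk_cluster(1)), 1)$kept, 1)
})

test_that("clustering separates well-separated groups like the overlap-graph oracle", {
  set.seed(21)
  for (rep in 1:10) {
    # two groups far apart; members jitter tightly around each anchor
    mk_group <- function(cx, cy, n, models) {
      do.call(rbind, lapply(seq_len(n), function(i) {
        j <- rnorm(4, 0, 0.3)
        data.frame(image_id = 1L, x1 = cx + j[1], y1 = cy + j[2],
                   x2 = cx + 30 + j[3], y2 = cy + 30 + j[4],
                   confidence = runif(1, 0.3, 1),
                   label = sample(lk_classes(), 1),
                   model_id = models[i], stringsAsFactors = FALSE)
      }))
    }
    d <- rbind(mk_group(0, 0, 5, paste0("m", 1:5)),
               mk_group(200, 200, 5, paste0("m", 1:5)))
    cl <- cluster_detections(d, fusion_config())
    expect_length(cl, ref_components(d))
  }
})

test_that("a model contributes at most one member per cluster", {
  # same model emits two near-identical boxes: they must not share a cluster
  d <- detections(1, c(10, 10.5, 10.2), c(10, 10.5, 10.2),
                  c(40, 40.5, 40.2), c(40, 40.5, 40.2),
                  c(0.9, 0.8, 0.7), rep("NG", 3), c("m1", "m1", "m2"))
  cl <- cluster_detections(d)
  expect_length(cl, 2)
  for (c0 in cl) {
    expect_false(anyDuplicated(c0$members$model_id) > 0)
  }
})

test_that("empty input yields an empty cluster list and empty fusion output", {
  d <- detections(integer(0), numeric(0), numeric(0), numeric(0), numeric(0),
                  numeric(0), character(0), character(0))
  expect_length(cluster_detections(d), 0)
  r <- ensemble_fuse(d, 6)
  expect_identical(nrow(r$fused), 0L)
  expect_identical(nrow(r$discarded), 0L)
})

test_that("the illustrative one-cluster scenario fuses to a single NG detection", {
  # M = 6; four overlapping boxes (3 NG + 1 M) plus one isolated singleton
  d <- rbind(
    detections(1, c(10, 11, 9, 10.5), c(10, 11, 9, 10.5),
               c(50, 51, 49, 50.5), c(50, 51, 49, 50.5),
               c(0.9, 0.8, 0.7, 0.6), c("NG", "NG", "NG", "M"),
               c("m1", "m2", "m3", "m4")),
    detections(1, 200, 200, 240, 240, 0.5, "L", "m5"))
  r <- ensemble_fuse(d, n_models = 6)
  expect_identical(nrow(r$fused), 1L)
  expect_identical(r$fused$label, "NG")
  expect_identical(r$fused$support, 4L)
  expect_identical(r$fused$majority, 3L)
  expect_identical(nrow(r$discarded), 1L)
  expect_identical(r$discarded$model_id, "m5")
})

test_that("fusing M identical single-model outputs is idempotent in models mode", {
  set.seed(22)
  base <- random_detections(4, n_models = 1, n_anchors = 4)
  base$model_id <- "m1"
  copies <- do.call(rbind, lapply(1:6, function(i) {
    b <- base; b$model_id <- paste0("m", i); b
  }))
  r <- ensemble_fuse(copies, n_models = 6)
  got <- r$fused[order(r$fused$x1), ]
  want <- base[order(base$x1), ]
  expect_equal(got$x1, want$x1); expect_equal(got$y1, want$y1)
  expect_equal(got$x2, want$x2); expect_equal(got$y2, want$y2)
  expect_equal(got$confidence, want$confidence)
  expect_identical(got$label, want$label)
})

test_that("fused coordinates stay inside the members' envelope (hull containment)", {
  set.seed(23)
  for (rep in 1:30) {
    d <- random_detections(sample(2:10, 1))
    r <- ensemble_fuse(d, n_models = 6, fusion_config(min_support = 1e-6))
    cl <- cluster_detections(d, fusion_config())
    eps <- 1e-9  # weighted means can drift past the envelope by float error only
    for (i in seq_len(nrow(r$fused))) {
      expect_true(r$fused$x1[i] >= min(d$x1) - eps && r$fused$x1[i] <= max(d$x1) + eps)
      expect_true(r$fused$y1[i] >= min(d$y1) - eps && r$fused$y1[i] <= max(d$y1) + eps)
      expect_true(r$fused$x2[i] >= min(d$x2) - eps && r$fused$x2[i] <= max(d$x2) + eps)
      expect_true(r$fused$y2[i] >= min(d$y2) - eps && r$fused$y2[i] <= max(d$y2) + eps)
    }
    # per-cluster hull containment, checked directly on each cluster
    for (c0 in cl) {
      f <- fuse_cluster(c0, 6)
      m <- c0$members
      expect_true(f$x1 >= min(m$x1) - eps && f$x1 <= max(m$x1) + eps)
      expect_true(f$y2 >= min(m$y2) - eps && f$y2 <= max(m$y2) + eps)
    }
  }
})

test_that("fusion is equivariant under translation and uniform scaling", {
  set.seed(24)
  d <- random_detections(8)
  r0 <- ensemble_fuse(d, 6)
  dt <- d; dt[c("x1", "x2")] <- dt[c("x1", "x2")] + 37
  dt[c("y1", "y2")] <- dt[c("y1", "y2")] - 12
  rt <- ensemble_fuse(dt, 6)
  expect_equal(rt$fused$x1, r0$fused$x1 + 37, tolerance = 1e-9)
  expect_equal(rt$fused$y2, r0$fused$y2 - 12, tolerance = 1e-9)
  expect_equal(rt$fused$confidence, r0$fused$confidence)
  ds <- d; ds[c("x1", "y1", "x2", "y2")] <- ds[c("x1", "y1", "x2", "y2")] * 2.5
  rs <- ensemble_fuse(ds, 6)
  expect_equal(rs$fused$x2, r0$fused$x2 * 2.5, tolerance = 1e-9)
  expect_equal(rs$fused$confidence, r0$fused$confidence)
})

test_that("fusion output is invariant to input row permutation", {
  set.seed(25)
  for (rep in 1:10) {
    d <- random_detections(10)
    r0 <- ensemble_fuse(d, 6)
    dp <- d[sample.int(nrow(d)), ]
    rownames(dp) <- NULL
    rp <- ensemble_fuse(dp, 6)
    key <- function(f) f[order(f$x1, f$y1, f$confidence), , drop = FALSE]
    a <- key(r0$fused); b <- key(rp$fused)
    expect_equal(a$x1, b$x1); expect_equal(a$confidence, b$confidence)
    expect_identical(a$label, b$label)
  }
})

test_that("optimized pipeline matches the straight-line reference on random instances", {
  set.seed(26)
  for (rep in 1:60) {
    d <- random_detections(sample(1:12, 1))
    for (div in c("models", "majority")) {
      got <- ensemble_fuse(d, 6, fusion_config(divisor = div))$fused
      want <- ref_fuse(d, 6, divisor = div)
      expect_identical(nrow(got), nrow(want))
      if (nrow(got)) {
        expect_equal(got$x1, want$x1, tolerance = 1e-9)
        expect_equal(got$y1, want$y1, tolerance = 1e-9)
        expect_equal(got$x2, want$x2, tolerance = 1e-9)
        expect_equal(got$y2, want$y2, tolerance = 1e-9)
        expect_equal(got$confidence, want$confidence, tolerance = 1e-9)
        expect_identical(got$label, want$label)
      }
    }
  }
})

test_that("confidence bounds: <= 1 in models mode, can exceed 1 in majority mode", {
  set.seed(27)
  for (rep in 1:20) {
    d <- random_detections(sample(2:12, 1))
    r <- ensemble_fuse(d, 6)
    if (nrow(r$fused)) expect_true(all(r$fused$confidence <= 1 + 1e-12))
  }
  # majority mode: minority confidences inflate C' above 1, reported unclipped
  cl <- list(members = detections(1, c(10, 10.2, 9.8), c(10, 10.2, 9.8),
                                  c(40, 40.2, 39.8), c(40, 40.2, 39.8),
                                  c(0.95, 0.9, 0.9), c("NG", "NG", "M"),
                                  c("m1", "m2", "m3")))
  f <- fuse_cluster(cl, 3, fusion_config(divisor = "majority"))
  expect_equal(f$confidence, 2.75 / 2)
  expect_gt(f$confidence, 1)
})

test_that("all-zero confidences raise an undefined-weights error", {
  cl <- list(members = detections(1, c(1, 2), c(1, 2), c(11, 12), c(11, 12),
                                  c(0, 0), c("NG", "NG"), c("m1", "m2")))
  expect_error(fuse_cluster(cl, 2), "zero")
})

test_that("majority_only scope averages only majority-label boxes", {
  cl <- list(members = detections(1, c(10, 10, 50), c(10, 10, 50),
                                  c(20, 20, 60), c(20, 20, 60),
                                  c(0.5, 0.5, 0.5), c("NG", "NG", "M"),
                                  c("m1", "m2", "m3")))
  f_all <- fuse_cluster(cl, 3, fusion_config(scope = "all_members"))
  f_maj <- fuse_cluster(cl, 3, fusion_config(scope = "majority_only"))
  expect_equal(unlist(f_maj[c("x1", "y1", "x2", "y2")], use.names = FALSE),
               c(10, 10, 20, 20))
  expect_gt(f_all$x1, f_maj$x1)
  # the confidence sum is over all members in either scope
  expect_equal(f_all$confidence, f_maj$confidence)
})
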