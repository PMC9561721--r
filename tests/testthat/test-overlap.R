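test_that("top_lists truncates, never pads, and respects portrait order", {
  s <- make_signed(sprintf("g%03d", 1:900),
                   c(seq(600, 1), -seq(1, 300)))
  tl <- top_lists(s, 1000)
  expect_length(tl$up, 600)
  expect_length(tl$down, 300)
  expect_length(intersect(tl$up, tl$down), 0)
  t1 <- top_lists(s, 1)
  expect_equal(t1$up, "G001")
  expect_equal(t1$down, "G900")
})

test_that("hypergeom_overlap matches the spec's enumerated examples", {
  # 2-vs-2 over 4, overlap 2: exactly one of the C(4,2)=6 draws has both
  r <- hypergeom_overlap(c("a", "b"), c("a", "b"), c("a", "b", "c", "d"))
  expect_equal(r$p, 1 / 6, tolerance = 1e-12)
  # 3-vs-4 over 10 with k = 3: p = 1/30
  u <- paste0("g", 1:10)
  r2 <- hypergeom_overlap(u[1:3], u[c(1:3, 10)], u)
  expect_equal(r2$p, 1 / 30, tolerance = 1e-12)
  expect_equal(r2$nlp, -log10(1 / 30), tolerance = 1e-12)
  # zero overlap: P(X >= 0) = 1
  r3 <- hypergeom_overlap(u[1:2], u[5:6], u)
  expect_equal(r3$p, 1)
  expect_equal(r3$nlp, 0)
  expect_error(hypergeom_overlap("a", "b", character(0)), "universe")
  expect_warning(hypergeom_overlap(c("a", "zz"), "a", c("a", "b")),
                 "outside the universe")
})

test_that("hypergeom_overlap is symmetric and monotone in k", {
  u <- paste0("g", 1:40)
  a <- u[1:12]; b <- u[5:20]
  expect_equal(hypergeom_overlap(a, b, u)$p, hypergeom_overlap(b, a, u)$p)
  nlp <- vapply(0:8, function(k) {
    l2 <- c(u[seq_len(k)], u[29 + seq_len(8 - k)])  # size 8, overlap k
    hypergeom_overlap(u[1:8], l2, u)$nlp
  }, numeric(1))
  expect_true(all(diff(nlp) >= 0))
})

test_that("quadrant_analysis: self, sign-flip, and the 8-gene example", {
  s <- ladder_signature(2400)
  q_self <- quadrant_analysis(s, s, n = 1000, compat_threshold = 0)
  expect_equal(c(q_self$A, q_self$B, q_self$C, q_self$D),
               c(1000, 0, 0, 1000))
  q_flip <- quadrant_analysis(s, sign_flip(s), n = 1000,
                              compat_threshold = 0)
  expect_equal(c(q_flip$A, q_flip$B, q_flip$C, q_flip$D),
               c(0, 1000, 1000, 0))

  # 8-gene worked example: pB = pC = 13/28
  sig1 <- make_signed(paste0("g", 1:8), c(3, 2, -3, -2, 0.5, -0.5, 0.1, -0.1))
  sig2 <- make_signed(paste0("g", c(3, 5, 1, 6, 2, 4, 7, 8)),
                      c(3, 2, -3, -2, 0.5, -0.5, 0.1, -0.1))
  q <- quadrant_analysis(sig1, sig2, n = 2, compat_threshold = 0)
  expect_equal(c(q$A, q$B, q$C, q$D), c(0, 1, 1, 0))
  expect_equal(q$pB, 13 / 28, tolerance = 1e-12)
  expect_equal(q$pC, 13 / 28, tolerance = 1e-12)
  expect_equal(congruence_score(q), 2 * log10(13 / 28), tolerance = 1e-12)
  expect_equal(treatment_score(q), -2 * log10(13 / 28), tolerance = 1e-12)
  # compatibility flag set for small shared universes, computation proceeds
  expect_false(quadrant_analysis(sig1, sig2, n = 2)$compatible)
})

test_that("score algebra: treatment_score is minus congruence_score", {
  q0 <- list(nlpA = 0, nlpB = 0, nlpC = 0, nlpD = 0)
  expect_equal(congruence_score(q0), 0)
  set.seed(5)
  for (i in 1:50) {
    q <- list(nlpA = rexp(1), nlpB = rexp(1), nlpC = rexp(1), nlpD = rexp(1))
    expect_equal(treatment_score(q), -congruence_score(q))
  }
})

test_that("reversed_genes returns the disjoint B/C/same-direction sets", {
  pair <- make_reversal_pair(B = 30, C = 40, n = 100, n_universe = 400)
  rv <- reversed_genes(pair$disease, pair$treatment, n = 100,
                       compat_threshold = 0)
  expect_length(rv$up_reversed, 30)
  expect_length(rv$down_reversed, 40)
  expect_equal(rv$quadrants$B, 30)
  expect_equal(rv$quadrants$C, 40)
  expect_length(intersect(rv$up_reversed, rv$down_reversed), 0)
  # a sign-flip treatment leaves nothing in the same direction
  s <- ladder_signature(300)
  rv2 <- reversed_genes(s, sign_flip(s), n = 50, compat_threshold = 0)
  expect_length(rv2$same_direction, 0)
  expect_length(rv2$up_reversed, 50)
})

test_that("combine_treatments takes the union with visible intersections", {
  mk <- function(up, dn) list(up_reversed = up, down_reversed = dn)
  r <- combine_treatments(list(x = mk(c("a", "b"), "c"),
                               y = mk("d", c("c", "e"))))
  expect_equal(r$n_combined, 5)
  expect_equal(r$pairwise_intersections["x", "y"], 1)
  # disjoint sets add; identical sets collapse
  r2 <- combine_treatments(list(mk(c("a", "b"), character(0)),
                                mk(c("c"), "d")))
  expect_equal(r2$n_combined, 4)
  r3 <- combine_treatments(list(mk("a", "b"), mk("a", "b")))
  expect_equal(r3$n_combined, 2)
})

test_that("rank_treatments forces sign-flip first, identical last", {
  s <- ladder_signature(2400, "disease")
  set.seed(8)
  shuffled <- make_signed(s$gene, sample(s$sign1), "shuffled")
  rk <- rank_treatments(s, list(flip = sign_flip(s, "flip"),
                                same = make_signed(s$gene, s$sign1, "same"),
                                shuffled = shuffled),
                        n = 400, compat_threshold = 0)
  expect_equal(rk$dataset_id, c("flip", "shuffled", "same"))
  expect_equal(rk$reversal_total[1], 800)
  expect_true(all(diff(rk$score) <= 0))
  # empty treatment set gives an empty ranking
  expect_equal(nrow(rank_treatments(s, list())), 0L)
})

test_that("gene_list_overlap handles identical and disjoint lists", {
  u <- paste0("g", 1:50)
  r <- gene_list_overlap(u[1:10], u[1:10], u)
  expect_equal(r$k, 10)
  expect_lt(r$p, 1e-9)
  r2 <- gene_list_overlap(u[1:10], u[11:20], u)
  expect_equal(r2$k, 0)
  expect_equal(r2$p, 1)
  expect_setequal(gene_list_overlap(u[1:5], u[3:8], u)$common, u[3:5])
})
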