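test_that("rank_directional splits and orders by sign1 with alpha ties", {
  s <- make_signed(c("A", "B", "C"), c(3, -2, 1))
  expect_equal(rank_directional(s), list(up = c("A", "C"), down = "B"))
  expect_equal(rank_directional(make_signed(c("A", "B"), c(0, 0))),
               list(up = character(0), down = character(0)))
  expect_equal(rank_directional(make_signed(c("B", "A"), c(3, 3)))$up,
               c("A", "B"))
})

test_that("stratum_weight is the default 8..1 staircase, 0 past 8000", {
  sc <- weight_scheme()
  expect_equal(stratum_weight(1, sc), 8)
  expect_equal(stratum_weight(1500, sc), 7)
  expect_equal(stratum_weight(9000, sc), 0)
  expect_equal(stratum_weight(c(1000, 1001, 8000, 8001), sc), c(8, 7, 1, 0))
  expect_error(stratum_weight(0, sc), "rank")
  # non-increasing everywhere
  expect_true(all(diff(stratum_weight(1:9001, sc)) <= 0))
  expect_error(weight_scheme(bounds = c(1000, 2000, 3000),
                             weights = c(8, 8, 7)), "decreasing")
  expect_error(weight_scheme(bounds = c(2000, 1000), weights = c(2, 1)),
               "increasing")
})

test_that("build_portrait sums signed stratum weights across studies", {
  g <- sprintf("g%02d", 1:30)
  set.seed(9)
  t1 <- make_signed(g, c(10, rnorm(29)), "d1")   # gene 1 strongest up
  t2 <- make_signed(g, c(11, rnorm(29)), "d2")
  p <- build_portrait(list(d1 = t1, d2 = t2))
  expect_equal(p$aggregate_score[p$gene == "G01"], 16)  # 8 + 8, top rank
  expect_equal(p$gene[1], "G01")
  expect_true(all(abs(p$aggregate_score) <= 8 * 2))     # bound
  # opposite top ranks cancel to zero and sort last
  t3 <- make_signed(c("Z", g), c(20, c(10, rnorm(29))), "d3")
  t4 <- make_signed(c("Z", g), c(-20, c(11, rnorm(29))), "d4")
  p2 <- build_portrait(list(d3 = t3, d4 = t4))
  expect_equal(p2$aggregate_score[p2$gene == "Z"], 0)
  expect_equal(p2$gene[nrow(p2)], "Z")
})

test_that("presence filter is strictly greater than the fraction", {
  g <- sprintf("g%02d", 1:12)
  tabs <- list(
    a = make_signed(g, rep(1, 12), "a"),
    b = make_signed(g, rep(1, 12), "b"),
    c = make_signed(g[1:6], rep(1, 6), "c"))
  p <- build_portrait(tabs)  # 2/3 of 3 = 2; need > 2, i.e. all 3
  expect_setequal(p$gene, toupper(g[1:6]))
  expect_equal(attr(p, "n_filtered"), 6L)
  # conservation: kept + filtered = distinct symbols
  expect_equal(nrow(p) + attr(p, "n_filtered"), 12L)
})

test_that("per-study dataset cap is enforced via the manifest", {
  g <- sprintf("g%02d", 1:10)
  tabs <- lapply(1:3, function(i) make_signed(g, rnorm(10), paste0("d", i)))
  names(tabs) <- paste0("d", 1:3)
  man <- data.frame(dataset_id = paste0("d", 1:3),
                    study_id = c("s1", "s1", "s1"))
  expect_error(build_portrait(tabs, manifest = man), "more than 2")
  man$study_id <- c("s1", "s1", "s2")
  expect_s3_class(build_portrait(tabs, manifest = man), "portrait")
  expect_error(
    build_portrait(tabs, manifest = man[1:2, ]), "does not cover")
})

test_that("portrait is invariant to table order and to monotone p transforms", {
  set.seed(11)
  g <- sprintf("g%03d", 1:200)
  mk <- function(id) {
    deg_table(g, runif(200), rnorm(200), study_id = id)
  }
  degs <- list(a = mk("a"), b = mk("b"), c = mk("c"))
  tabs <- lapply(degs, to_signed_scores)
  p1 <- build_portrait(tabs)
  p2 <- build_portrait(rev(tabs))
  expect_equal(p1$gene, p2$gene)
  expect_equal(p1$aggregate_score, p2$aggregate_score)
  # ranks are sufficient: squeezing one study's p-values monotonically
  # leaves the aggregate scores unchanged (mean_sign1 may differ)
  degs$b$p_value <- degs$b$p_value^3  # strictly monotone on [0,1]
  tabs2 <- lapply(degs, to_signed_scores)
  p3 <- build_portrait(tabs2)
  expect_equal(p1$aggregate_score[match(p3$gene, p1$gene)],
               p3$aggregate_score)
})

test_that("composite degenerate cases: single table and exact sign-flip", {
  s <- ladder_signature(60, "one")
  p <- build_composite(list(one = s), min_presence_fraction = 0)
  dl <- rank_directional(s)
  expect_equal(p$gene[p$aggregate_score > 0], dl$up)
  expect_equal(p$gene[p$aggregate_score < 0], dl$down)
  p2 <- build_composite(list(a = s, b = sign_flip(s)))
  expect_true(all(p2$aggregate_score == 0))
})

test_that("composite recovers planted genes at the top", {
  cfg <- sim_config(n_genes = 3000, n_studies = 11, n_planted_up = 50,
                    n_planted_down = 50, seed = 14)
  sim <- generate_study_collection(cfg)
  tabs <- lapply(sim$tables, to_signed_scores)
  p <- build_composite(tabs)
  planted <- c(sim$truth$planted_up, sim$truth$planted_down)
  expect_true(all(match(planted, p$gene) <= 150))
})

test_that("reverse_portrait negates scores, keeps order, is an involution", {
  set.seed(3)
  tabs <- lapply(1:2, function(i)
    make_signed(sprintf("g%02d", 1:40), rnorm(40), paste0("d", i)))
  names(tabs) <- c("d1", "d2")
  p <- build_portrait(tabs)
  r <- reverse_portrait(p)
  expect_equal(r$aggregate_score, -p$aggregate_score)
  expect_equal(r$mean_sign1, -p$mean_sign1)
  expect_equal(r$gene, p$gene)
  expect_equal(reverse_portrait(r), p)
  e <- p[0, ]
  expect_equal(nrow(reverse_portrait(e)), 0L)
})

test_that("portrait TSV round-trips", {
  set.seed(4)
  tabs <- list(a = make_signed(sprintf("g%02d", 1:25), rnorm(25), "a"),
               b = make_signed(sprintf("g%02d", 1:25), rnorm(25), "b"))
  p <- build_portrait(tabs)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_portrait(p, tf)
  r <- read_portrait(tf)
  expect_equal(r$gene, p$gene)
  expect_equal(r$aggregate_score, p$aggregate_score)
  expect_error(read_portrait(write_de_tsv(withr::local_tempfile(),
                                          "A", 0.1, 1)), "portrait")
})
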