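test_that("the exact filter keeps the maximal set under dominance", {
  pts <- tibble::tibble(a = c(2, 0, 1, 0.5), b = c(0, 2, 1, 0.5))
  goals <- goal_spec(c("a", "b"))
  nd <- nondominated_filter(pts, goals)
  expect_equal(nd, c(TRUE, TRUE, TRUE, FALSE)) # (0.5,0.5) dominated by (1,1)
  # single point is its own frontier
  expect_true(nondominated_filter(pts[1, ], goals))
  # sense matters: minimizing both flips the frontier
  nd_min <- nondominated_filter(pts, goal_spec(c("a", "b"), "minimize"))
  expect_equal(nd_min, c(TRUE, TRUE, FALSE, TRUE))
  # NaN goals are excluded with a warning
  pts$a[2] <- NA
  expect_warning(nd2 <- nondominated_filter(pts, goals), "excluded")
  expect_false(nd2[2])
})

test_that("the filter agrees with the pairwise dominance oracle", {
  set.seed(31)
  for (trial in 1:5) {
    pts <- tibble::as_tibble(matrix(runif(200 * 3), ncol = 3,
                                    dimnames = list(NULL, c("x", "y", "z"))))
    senses <- sample(c("maximize", "minimize"), 3, replace = TRUE)
    goals <- goal_spec(c("x", "y", "z"), senses)
    nd <- nondominated_filter(pts, goals)
    g <- as.matrix(pts)
    g[, senses == "minimize"] <- -g[, senses == "minimize"]
    expect_equal(nd, dominance_oracle(g))
  }
})

test_that("dominance filtering is idempotent and stable to dominated points", {
  set.seed(17)
  pts <- tibble::as_tibble(matrix(runif(100 * 2), ncol = 2,
                                  dimnames = list(NULL, c("x", "y"))))
  goals <- goal_spec(c("x", "y"))
  nd <- nondominated_filter(pts, goals)
  frontier <- pts[nd, ]
  expect_true(all(nondominated_filter(frontier, goals)))
  # appending a dominated point leaves the frontier unchanged
  dominated <- tibble::tibble(x = min(pts$x) / 2, y = min(pts$y) / 2)
  nd2 <- nondominated_filter(dplyr::bind_rows(pts, dominated), goals)
  expect_equal(nd2[seq_len(nrow(pts))], nd)
  expect_false(nd2[nrow(pts) + 1])
  # appending a non-dominating nondominated point grows the frontier by one
  spike <- tibble::tibble(x = max(pts$x) + 1, y = min(pts$y) / 2)
  nd3 <- nondominated_filter(dplyr::bind_rows(pts, spike), goals)
  expect_true(nd3[nrow(pts) + 1])
  expect_equal(sum(nd3), sum(nd) + 1)
})

test_that("NSGA-II output is always a subset of the exact frontier", {
  set.seed(23)
  pts <- tibble::as_tibble(matrix(runif(400 * 2), ncol = 2,
                                  dimnames = list(NULL, c("x", "y"))))
  goals <- goal_spec(c("x", "y"))
  exact <- nondominated_filter(pts, goals)
  approx <- nsga2_select(pts, goals, generations = 60, pop_size = 40,
                         seed = 0.6)
  expect_true(any(approx))
  expect_true(all(which(approx) %in% which(exact)))
  # one-goal degenerate case returns the single argmax design
  one <- nsga2_select(pts, goal_spec("x", weight = 1), generations = 40,
                      pop_size = 30, seed = 0.6)
  expect_equal(which(one), which.max(pts$x))
})

test_that("NSGA-II defaults follow the published parameterization", {
  fo <- formals(nsga2_select)
  expect_equal(fo$generations, 500)
  expect_equal(fo$pop_size, 100)
  expect_equal(fo$p_crossover, 0.85)
  expect_equal(fo$p_mutation, 0.05)
  expect_equal(fo$eta_crossover, 10)
  expect_equal(fo$eta_mutation, 20)
  expect_equal(fo$seed, 0.6)
})

test_that("tradeoff slopes recover linear frontiers exactly", {
  f <- tibble::tibble(purity = c(0, 1), rate = c(100, 0))
  seg <- tradeoff_slopes(f, x = "purity", y = "rate",
                         breakpoints = numeric(0))
  expect_equal(seg$slope, -100)
  expect_equal(seg$n_designs, 2L)
  # collinear frontier: zero residual, exact slope
  f2 <- tibble::tibble(purity = seq(0, 1, by = 0.1),
                       rate = 50 - 30 * seq(0, 1, by = 0.1))
  seg2 <- tradeoff_slopes(f2, "purity", "rate", breakpoints = numeric(0))
  expect_equal(seg2$slope, -30, tolerance = 1e-10)
  expect_lt(seg2$rss, 1e-18)
  # an automatic breakpoint splits a two-regime frontier near the kink
  steep <- tibble::tibble(purity = seq(0, 0.5, by = 0.1),
                          rate = 100 - 180 * seq(0, 0.5, by = 0.1))
  flat <- tibble::tibble(purity = seq(0.6, 1, by = 0.1),
                         rate = 10 - 8 * (seq(0.6, 1, by = 0.1) - 0.6))
  seg3 <- tradeoff_slopes(dplyr::bind_rows(steep, flat), "purity", "rate")
  expect_equal(nrow(seg3), 2)
  expect_lt(seg3$slope[1], -100)
  expect_gt(seg3$slope[2], -20)
  # too few points per segment reports an empty segment
  seg4 <- tradeoff_slopes(f[1, ], "purity", "rate", breakpoints = numeric(0))
  expect_true(is.na(seg4$slope))
})

test_that("weighted selection matches an exhaustive scalarized scan", {
  set.seed(41)
  pts <- tibble::as_tibble(matrix(runif(50 * 2), ncol = 2,
                                  dimnames = list(NULL, c("rate", "cost"))))
  goals <- goal_spec(c("rate", "cost"), weight = c(0.5, -0.5))
  expect_equal(goals$sense, c("maximize", "minimize"))
  best <- weighted_goal_select(pts, goals)
  # oracle: full scan over min-max normalized, sense-signed scores
  nr <- (pts$rate - min(pts$rate)) / diff(range(pts$rate))
  nc <- (pts$cost - min(pts$cost)) / diff(range(pts$cost))
  oracle <- which.max(0.5 * nr - 0.5 * nc)
  expect_equal(as.integer(best), oracle)
  # degenerate weights reduce to a single-goal argmax
  b1 <- weighted_goal_select(pts, goal_spec(c("rate", "cost"),
                                            weight = c(1, 0)))
  expect_equal(as.integer(b1), which.max(pts$rate))
  # the scalarized winner lies on the exact Pareto frontier
  nd <- nondominated_filter(pts, goals)
  expect_true(nd[as.integer(best)])
  pts$rate <- NA_real_
  expect_error(weighted_goal_select(pts, goals), "all NA")
})

test_that("pareto_front wraps the filter with tidy accessors", {
  ph <- toy_screen()
  eco <- ph[ph$economics_available, ]
  goals <- goal_spec(c("succinate_production_rate", "succinate_purity"))
  front <- pareto_front(eco, goals)
  expect_s3_class(front, "fs_pareto_front")
  expect_equal(nrow(front$frontier), sum(front$points$nondominated))
  expect_true(all(c("n_points", "n_nondominated") %in% names(glance(front))))
  expect_s3_class(autoplot(front), "ggplot")
})
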