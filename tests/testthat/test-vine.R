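test_that("pair-copula count identity holds across dimensions", {
  expect_equal(count_pair_copulas(2), 1)
  expect_equal(count_pair_copulas(102), 5151)
  expect_equal(count_pair_copulas(81), 3240)
  d <- 2:200
  expect_equal(count_pair_copulas(d), d * (d - 1) / 2)
  expect_error(count_pair_copulas(1), "d must be")
  # structure enumeration agrees with the identity, trees have d - t edges
  for (d in c(2, 5, 102)) {
    edges <- copulamodules:::cvine_edges(d)
    expect_length(edges, d * (d - 1) / 2)
    tr <- vapply(edges, `[[`, 1L, "tree")
    expect_equal(as.vector(table(tr)), (d - 1):1)
    csz <- vapply(edges, function(e) length(e$conditioning), 1L)
    expect_equal(csz, tr - 1L)
  }
})

test_that("tau-sum ordering puts the hub first and breaks ties by index", {
  # two near-independent variables plus a hub coupled to both
  spec <- synthetic_population_spec(3, 3000, edges = list(
    list(3, 1, parametric_copula("clayton", 5)),
    list(3, 2, parametric_copula("clayton", 5))))
  x <- generate_population(spec, seed = 51)
  u <- pseudo_obs(x, seed = 52)
  expect_equal(order_variables(u)[1], 3)
  # d = 2 and identical columns: ordering by original index
  expect_equal(order_variables(cbind(runif(100), runif(100)))[1] %in% 1:2, TRUE)
  z <- runif(200)
  expect_equal(order_variables(cbind(z, z, z)), 1:3)
})

test_that("independence test calibrates under the null and rejects Clayton", {
  set.seed(53)
  # type-I error across seeded repetitions at alpha = 0.05
  reps <- 200
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    u <- matrix(runif(2 * 2000), ncol = 2)
    rej[r] <- !independence_test(u, seed = 1000 + r)$is_independent
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
  # power: Clayton theta = 5 is always rejected at n = 5000
  for (r in 1:20) {
    ucl <- rcopula(parametric_copula("clayton", 5), 5000, seed = 2000 + r)
    expect_false(independence_test(ucl, seed = 3000 + r)$is_independent)
  }
  # a sample against itself: zero statistic, p = 1
  u <- matrix(runif(400), ncol = 2)
  self <- independence_test(u, reference = u)
  expect_lt(self$statistic, 1e-10)
  expect_equal(self$p_value, 1)
})

test_that("fit_cvine prunes independence and passes conditionals through", {
  set.seed(54)
  x <- matrix(rpois(3 * 1200, 2), ncol = 3)
  u <- pseudo_obs(x, seed = 55)
  fit <- fit_cvine(u, seed = 56)
  expect_s3_class(fit, "cvine")
  expect_length(fit$edges, 3)
  # all-independent data: every edge independent (within type-I error over
  # 3 tests; allow at most one false rejection)
  indep <- vapply(fit$edges, `[[`, TRUE, "independent")
  expect_gte(sum(indep), 2)
  expect_output(print(fit), "C-vine on 3 variables")
})

test_that("fit_cvine recovers a known 3-variable structure", {
  # hub 1 coupled to 2 and 3 by Clayton; 2 and 3 conditionally independent
  spec <- synthetic_population_spec(3, 2000, edges = list(
    list(1, 2, parametric_copula("clayton", 5)),
    list(1, 3, parametric_copula("clayton", 5))))
  surface_hits <- 0
  deep_indep <- 0
  for (r in 1:10) {
    x <- generate_population(spec, seed = 500 + r)
    u <- pseudo_obs(x, seed = 600 + r)
    fit <- fit_cvine(u, seed = 700 + r)
    expect_equal(fit$order[1], 1)  # hub found
    ind <- vapply(fit$edges, `[[`, TRUE, "independent")
    tr <- vapply(fit$edges, `[[`, 1L, "tree")
    if (!any(ind[tr == 1])) surface_hits <- surface_hits + 1
    if (ind[tr == 2]) deep_indep <- deep_indep + 1
  }
  expect_gte(surface_hits, 9)   # surface dependence recovered
  expect_gte(deep_indep, 8)     # conditional independence kept
})

test_that("density_matrix stacks only non-independent edges", {
  spec <- synthetic_population_spec(3, 1500, edges = list(
    list(1, 2, parametric_copula("clayton", 5))))
  x <- generate_population(spec, seed = 57)
  fit <- fit_cvine(pseudo_obs(x, seed = 58), G = 50, seed = 59)
  dm <- density_matrix(fit)
  expect_equal(ncol(dm$X), 2500)
  expect_equal(nrow(dm$X), sum(!vapply(fit$edges, `[[`, TRUE, "independent")))
  expect_true(all(abs(rowMeans(dm$X) - 1) < 1e-6))
  expect_equal(nrow(dm$meta), nrow(dm$X))
})

test_that("vine serialization writes valid JSON with the edge schema", {
  spec <- synthetic_population_spec(3, 1000, edges = list(
    list(1, 2, parametric_copula("frank", 6))))
  x <- generate_population(spec, seed = 60)
  fit <- fit_cvine(pseudo_obs(x, seed = 61), G = 30, seed = 62)
  f <- tempfile(fileext = ".json")
  vine_to_json(fit, f)
  doc <- jsonlite::read_json(f)
  expect_equal(doc$d, 3)
  expect_length(doc$edges, 3)
  expect_setequal(names(doc$edges[[1]]),
                  c("index", "tree", "root", "partner", "conditioning",
                    "p_value", "independent", "label"))
})

test_that("column permutation changes labels but not detected dependence", {
  spec <- synthetic_population_spec(4, 2000, edges = list(
    list(2, 1, parametric_copula("clayton", 5)),
    list(2, 4, parametric_copula("frank", 6))))
  x <- generate_population(spec, seed = 63)
  u <- pseudo_obs(x, seed = 64)
  fit1 <- fit_cvine(u, seed = 65)
  perm <- c(3, 1, 4, 2)
  fit2 <- fit_cvine(u[, perm], seed = 65)
  dep_pairs <- function(fit, names_map) {
    ind <- vapply(fit$edges, `[[`, TRUE, "independent")
    keep <- which(!ind & vapply(fit$edges, `[[`, 1L, "tree") == 1)
    sort(vapply(keep, function(e) {
      ed <- fit$edges[[e]]
      paste(sort(names_map[fit$order[c(ed$root, ed$partner)]]), collapse = "-")
    }, ""))
  }
  expect_equal(dep_pairs(fit1, paste0("n", 1:4)),
               dep_pairs(fit2, paste0("n", 1:4)[perm]))
})
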