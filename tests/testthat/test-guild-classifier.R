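# helper: a score vector by named items, zero elsewhere
sv <- function(...) {
  v <- stats::setNames(numeric(9L), diet_items())
  args <- list(...)
  v[names(args)] <- unlist(args)
  v
}

test_that("the dominant-item rule and both omnivore cases classify correctly", {
  expect_equal(classify_species(sv(seeds = 10)), "granivore")
  expect_equal(classify_species(sv(fruits = 5, invertebrates = 5)),
               "omnivore") # two equally consumed items
  expect_equal(classify_species(sv(invertebrates = 4, fruits = 3, seeds = 3)),
               "omnivore") # no item above the threshold
  expect_equal(classify_species(sv(invertebrates = 6, fruits = 4)),
               "insectivore")
  # a dominant miscellaneous score defines no specialist guild
  expect_equal(classify_species(sv(misc = 7, seeds = 3)), "omnivore")
})

test_that("invalid score vectors are rejected", {
  expect_error(classify_species(sv(seeds = 9)), "sum to 10")
  expect_error(classify_species(sv(seeds = 11, fruits = -1)), "negative")
  expect_error(classify_species(rep(1, 8)), "9 items")
})

test_that("classify_table counts the toy fixture and rejects bad tables", {
  toy <- data.frame(species = c("s1", "s2", "s3", "s4"),
                    rbind(sv(seeds = 10),
                          sv(fruits = 5, invertebrates = 5),
                          sv(invertebrates = 4, fruits = 3, seeds = 3),
                          sv(invertebrates = 6, fruits = 4)),
                    check.names = FALSE)
  ga <- classify_table(toy)
  got <- stats::setNames(ga$counts, ga$guilds)
  expect_equal(got[["granivore"]], 1L)
  expect_equal(got[["omnivore"]], 2L)
  expect_equal(got[["insectivore"]], 1L)
  expect_equal(sum(ga$counts), 4L)
  expect_equal(sum(ga$proportions), 1)

  expect_error(classify_table(toy[0, ]), "empty")
  expect_error(classify_table(rbind(toy, toy[1, ])), "duplicate")
})

test_that("classification is a pure function: species order never matters", {
  set.seed(21)
  m <- t(vapply(1:50, function(i) {
    v <- as.numeric(stats::rmultinom(1L, 10L, stats::runif(9L)))
    v
  }, numeric(9L)))
  colnames(m) <- diet_items()
  rownames(m) <- paste0("sp", 1:50)
  ga1 <- classify_table(m)
  perm <- sample(1:50)
  ga2 <- classify_table(m[perm, ])
  expect_equal(ga2$assignment[rownames(m)], ga1$assignment[rownames(m)])
})

test_that("omnivore count is monotonically non-decreasing in the threshold", {
  set.seed(33)
  for (rep in 1:20) {
    m <- t(vapply(1:40, function(i)
      as.numeric(stats::rmultinom(1L, 10L, stats::runif(9L))), numeric(9L)))
    colnames(m) <- diet_items()
    rownames(m) <- paste0("sp", 1:40)
    omn <- vapply(c(3, 5, 7, 9), function(t) {
      ga <- classify_table(m, classifier_config(t))
      sum(ga$assignment == "omnivore")
    }, numeric(1L))
    expect_true(all(diff(omn) >= 0))
  }
})

test_that("boundary properties: max <= t is omnivore, unique 10 is specialist", {
  set.seed(5)
  cfg <- classifier_config(5)
  for (i in 1:50) {
    v <- as.numeric(stats::rmultinom(1L, 10L, stats::runif(9L)))
    names(v) <- diet_items()
    g <- classify_species(v, cfg)
    if (max(v) <= 5) expect_equal(g, "omnivore")
  }
  for (it in diet_items()) {
    v <- stats::setNames(numeric(9L), diet_items())
    v[it] <- 10
    expected <- item_guilds()[[it]]
    expect_equal(classify_species(v, cfg),
                 if (is.na(expected)) "omnivore" else expected)
  }
})

test_that("diet CSV round trip and assignment export work", {
  toy <- data.frame(species = c("a", "b"),
                    rbind(sv(seeds = 10), sv(fish = 8, fruits = 2)),
                    check.names = FALSE)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(toy, f, row.names = FALSE)
  back <- read_diet_csv(f)
  ga <- classify_table(back)
  expect_equal(unname(ga$assignment), c("granivore", "piscivore"))
  out_csv <- tempfile(fileext = ".csv")
  out_json <- tempfile(fileext = ".json")
  write_guild_assignment(ga, out_csv, out_json)
  expect_equal(nrow(utils::read.csv(out_csv)), 2L)
  js <- jsonlite::read_json(out_json)
  expect_equal(js$n_species, 2L)
  expect_equal(js$counts$granivore, 1L)
})
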