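test_that("F2 projection matches hand-computed fixtures", {
  # four singleton clutches, one female: F2 = 1 x (20 - sqrt(1)) = 19
  tab <- host_rows("f1", "demo", clutch_sizes = c(1, 1, 1, 1),
                   n_females = c(1, 0, 0, 0))
  pr <- project_f2(tab)
  expect_identical(pr$f1_fertility, 4L)
  expect_identical(pr$f1_females, 1L)
  expect_equal(pr$f2_fertility, 19)
  expect_equal(pr$mean_offspring_fertility, 19)

  # no parasitized hosts at all
  empty <- data.frame(founder_id = "f2", group = "demo",
                      substrate = "usual_plant", host_species = "native",
                      parasitized = FALSE, clutch_size = NA_integer_,
                      n_females = NA_integer_, emerged = FALSE)
  pr0 <- project_f2(empty)
  expect_identical(pr0$f1_fertility, 0L)
  expect_equal(pr0$f2_fertility, 0)
  expect_true(is.na(pr0$mean_offspring_fertility))

  # one native (4,1) and one fictitious (3,1) clutch: the fictitious eggs
  # count against the egg expenditure but yield nothing
  mix <- rbind(
    host_rows("f3", "demo", 4, 1),
    host_rows("f3", "demo", 3, 1, host_species = "fictitious",
              substrate = "fictitious_plant"))
  prm <- project_f2(mix)
  expect_identical(prm$f1_eggs_laid, 7L)
  expect_identical(prm$f1_fertility, 4L)
  expect_equal(prm$f2_fertility, 18)  # 1 female x (20 - sqrt(4))
})

test_that("F2 projection equals a brute-force per-female sum on random tables", {
  set.seed(101)
  m <- fertility_model()
  for (rep in 1:50) {
    k <- sample(1:8, 1)
    sizes <- sample(1:7, k, replace = TRUE)
    fem <- vapply(sizes, function(s) sample(0:s, 1), integer(1))
    tab <- host_rows("f", "g", sizes, fem)
    pr <- project_f2(tab, m)
    # oracle: iterate over individual females
    brute <- 0
    for (i in seq_len(k)) for (j in seq_len(fem[i]))
      brute <- brute + (20 - sqrt(sizes[i])) |> round()
    expect_equal(pr$f2_fertility, brute)
  }
})

test_that("splitting clutches over more hosts never decreases F2 fertility", {
  # dominance: with total offspring and total females fixed, splitting any
  # clutch onto an empty host weakly shrinks every female's natal clutch,
  # so the monotone fertility mapping cannot lower projected F2 fertility
  set.seed(202)
  m <- fertility_model()
  f2_of <- function(sizes, fem) sum(fem * fertility_of_clutch(sizes, m))
  checked <- 0
  while (checked < 1000) {
    k <- sample(1:6, 1)
    sizes <- sample(1:7, k, replace = TRUE)
    fem <- vapply(sizes, function(s) sample(0:s, 1), integer(1))
    cand <- which(sizes >= 2)
    if (length(cand) == 0) next
    i <- cand[sample.int(length(cand), 1)]
    move <- sample.int(sizes[i] - 1L, 1)
    keep <- sizes[i] - move
    f_lo <- max(0L, fem[i] - keep)
    f_hi <- min(fem[i], move)
    f_move <- if (f_lo == f_hi) f_lo else sample(f_lo:f_hi, 1)
    new_sizes <- c(sizes, move)
    new_sizes[i] <- keep
    new_fem <- c(fem, f_move)
    new_fem[i] <- fem[i] - f_move
    expect_identical(sum(new_sizes), sum(sizes))
    expect_identical(sum(new_fem), sum(fem))
    expect_gte(f2_of(new_sizes, new_fem), f2_of(sizes, fem))
    checked <- checked + 1
  }
})

test_that("equal F1 fertility with different clutch profiles yields different F2", {
  # scenario logic: two founders each lay 8 offspring with 2 females;
  # spread over 8 singleton clutches vs packed into two clutches of 4
  spread <- host_rows("a", "ga", rep(1, 8), c(1, 1, rep(0, 6)))
  packed <- host_rows("b", "gb", c(4, 4), c(1, 1))
  pa <- project_f2(spread); pb <- project_f2(packed)
  expect_identical(pa$f1_fertility, pb$f1_fertility)
  expect_identical(pa$f1_females, pb$f1_females)
  expect_gt(pa$f2_fertility, pb$f2_fertility)   # 38 vs 36
  expect_equal(pa$f2_fertility, 2 * 19)
  expect_equal(pb$f2_fertility, 2 * 18)
})

test_that("scenario comparison reports pooled means and both-direction percent differences", {
  # identical groups differ by 0%
  g1 <- host_rows("x1", "g1", c(2, 2), c(1, 1))
  g2 <- host_rows("x2", "g2", c(2, 2), c(1, 1))
  cmp <- compare_scenarios(rbind(g1, g2))
  expect_equal(cmp$percent_diff$percent_diff, c(0, 0))

  # all-singletons vs all-fours with equal female counts: 19 vs 18
  a <- host_rows("a", "A", rep(1, 4), rep(1, 4))
  b <- host_rows("b", "B", rep(4, 4), rep(1, 4))
  cmp2 <- compare_scenarios(rbind(a, b))
  ga <- cmp2$groups[cmp2$groups$group == "A", ]
  gb <- cmp2$groups[cmp2$groups$group == "B", ]
  expect_equal(ga$per_offspring_f2, 19)
  expect_equal(gb$per_offspring_f2, 18)
  ab <- cmp2$percent_diff
  expect_equal(ab$percent_diff[ab$group_a == "A"], (19 - 18) / 18 * 100)
  expect_equal(ab$percent_diff[ab$group_a == "B"], (18 - 19) / 19 * 100)

  # a group with zero emerged females is excluded with a warning
  c0 <- host_rows("c", "C", c(3, 3), c(0, 0))
  expect_warning(cmp3 <- compare_scenarios(rbind(a, b, c0)), "zero emerged")
  expect_false("C" %in% cmp3$percent_diff$group_a)
  expect_error(compare_scenarios(a), "two groups")
})

test_that("host-egg tables round-trip through CSV with schema validation", {
  tab <- rbind(host_rows("f1", "g", c(2, 3), c(1, 1), n_unparasitized = 1),
               host_rows("f2", "g", 4, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_host_table(tab, path)
  back <- read_host_table(path)
  expect_identical(back$clutch_size, tab$clutch_size)
  expect_identical(back$parasitized, tab$parasitized)
  expect_identical(back$emerged, tab$emerged)
  # schema violations are caught with named columns
  malformed <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", malformed)
  expect_error(read_host_table(malformed), "missing column")
  bad <- tab
  bad$clutch_size[1] <- NA
  expect_error(write_host_table(bad, withr::local_tempfile(fileext = ".csv")),
               "clutch_size")
})

test_that("founder profiles built from clutch frequencies feed the projection", {
  d_small <- clutch_dist(c(`1` = 6, `2` = 3))    # small-clutch strategy
  d_big <- clutch_dist(c(`4` = 1))               # packed strategy
  tab <- rbind(
    founder_from_profile("small", total_offspring = 12, n_hosts = 12,
                         dist = d_small),
    founder_from_profile("big", total_offspring = 12, n_hosts = 12,
                         dist = d_big))
  cmp <- compare_scenarios(tab)
  small <- cmp$groups[cmp$groups$group == "small", ]
  big <- cmp$groups[cmp$groups$group == "big", ]
  # smaller clutches buy higher per-offspring F2 fertility
  expect_gt(small$per_offspring_f2, big$per_offspring_f2)
})
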