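test_that("stratum assignment follows the documented class boundaries", {
  s <- make_sessions(
    6,
    # Sat 14:00, Tue 02:00, then boundary probes
    start_utc = as.POSIXct(c(
      "2022-06-18 14:00:00", "2022-06-14 02:00:00", "2022-06-14 13:00:00",
      "2022-06-14 12:59:59", "2022-06-14 23:59:00", "2022-06-14 00:00:00"
    ), tz = "UTC"),
    duration_min = c(20, 45, 30, 30.01, 30, 30),
    region = c("West", "Northeast", rep("Midwest", 4))
  )
  a <- assign_stratum(s)
  expect_equal(a$stratum[1], "West/short/weekend/peak")
  expect_equal(a$stratum[2], "Northeast/long/weekday/offpeak")
  # exactly 30 minutes is short; 30.01 is long
  expect_equal(as.character(a$duration_class[3:4]), c("short", "long"))
  # 13:00 and 23:59 are peak; 12:59 and 00:00 off-peak
  expect_equal(as.character(a$hour_class[3:6]),
               c("peak", "offpeak", "peak", "offpeak"))
})

test_that("the stratum space has exactly 40 keys and the census conserves", {
  expect_length(teleco2:::stratum_keys(), 40)
  expect_false(anyDuplicated(teleco2:::stratum_keys()) > 0)

  s <- assign_stratum(apply_filters(generate_sessions(
    generator_config(n_sessions = 3000, seed = 8)
  ))$sessions)
  cen <- stratum_census(s)
  expect_equal(nrow(cen), 40)
  expect_equal(sum(cen$n_pop), nrow(s))
})

test_that("largest-remainder allocation matches hand-computed cases", {
  census <- function(pop) tibble::tibble(stratum = letters[seq_along(pop)],
                                         n_pop = pop)
  # symmetric split
  expect_equal(allocate_proportional(census(c(50, 50)), 10)$n_sample, c(5L, 5L))
  # equal thirds of 10: floors are 3, one leftover goes to the first key
  expect_equal(allocate_proportional(census(c(10, 10, 10)), 10)$n_sample,
               c(4L, 3L, 3L))
  # single stratum
  expect_equal(allocate_proportional(census(7), 7)$n_sample, 7L)
  # remainder ordering: quotas 4.5, 2.7, 1.8 -> floors 4,2,1 and the two
  # leftovers go to the .8 then the .7 remainder
  expect_equal(allocate_proportional(census(c(50, 30, 20)), 9)$n_sample,
               c(4L, 3L, 2L))
  expect_error(allocate_proportional(census(c(5, 5)), 11), "exceeds")
})

test_that("allocation sums exactly and bounds share distortion by 1/n", {
  set.seed(40)
  for (rep in 1:20) {
    pop <- rpois(40, lambda = sample(c(5, 50, 500), 1)) + 1L
    n <- sample.int(sum(pop), 1)
    al <- allocate_proportional(
      tibble::tibble(stratum = sprintf("k%02d", 1:40), n_pop = pop), n
    )
    expect_equal(sum(al$n_sample), n)
    expect_true(all(al$n_sample <= al$n_pop))
    expect_true(all(abs(al$n_sample / n - al$n_pop / sum(pop)) < 1 / n))
  }
})

test_that("stratified draw is deterministic, duplicate-free and proportional", {
  s <- assign_stratum(apply_filters(generate_sessions(
    generator_config(n_sessions = 20000, seed = 14)
  ))$sessions)
  cen <- stratum_census(s)
  al <- allocate_proportional(cen, 5000)

  d1 <- draw_sample(s, al, seed = 99)
  d2 <- draw_sample(s, al, seed = 99)
  expect_identical(d1, d2)

  expect_equal(nrow(d1), 5000)
  expect_false(anyDuplicated(d1$session_id) > 0)
  expect_true(all(d1$session_id %in% s$session_id))

  # sampled stratum shares match population shares within 1/n plus rounding
  got <- table(factor(d1$stratum, levels = cen$stratum))
  expect_equal(as.integer(got), al$n_sample)
  expect_true(all(abs(as.integer(got) / 5000 - cen$n_pop / nrow(s)) < 1 / 5000))

  # census case: allocating the whole population returns every record
  full <- cen
  full$n_sample <- full$n_pop
  expect_equal(sort(draw_sample(s, full, seed = 1)$session_id),
               sort(s$session_id))

  # infeasible allocation names the stratum
  bad <- al
  bad$n_sample[1] <- cen$n_pop[1] + 1L
  expect_error(draw_sample(s, bad, seed = 1), "infeasible")
})

test_that("draw_sample is invariant to input row order", {
  s <- assign_stratum(apply_filters(generate_sessions(
    generator_config(n_sessions = 2000, seed = 4)
  ))$sessions)
  al <- allocate_proportional(stratum_census(s), 400)
  d1 <- draw_sample(s, al, seed = 7)
  shuffled <- s[sample.int(nrow(s)), ]
  d2 <- draw_sample(shuffled, al, seed = 7)
  expect_equal(d1$session_id, d2$session_id)
})
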