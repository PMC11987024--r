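toy_plate <- function(wells, roles, conditions, times = c(0, 1, 2)) {
  tht_plate(times, wells,
            data.frame(well = colnames(wells), role = roles,
                       condition = conditions))
}

test_that("blank subtraction removes the time-pointwise blank mean", {
  w <- cbind(s1 = c(5, 6, 7), b1 = c(1, 1, 1), b2 = c(3, 3, 3))
  pl <- toy_plate(w, c("sample", "blank", "blank"), c("A", "blank", "blank"))
  out <- blank_subtract(pl)
  expect_equal(unname(out$wells[, "s1"]), c(3, 4, 5))

  # blanks with different time courses: [1,2] and [3,4] -> mean [2,3]
  w2 <- cbind(s1 = c(10, 10), b1 = c(1, 2), b2 = c(3, 4))
  pl2 <- toy_plate(w2, c("sample", "blank", "blank"),
                   c("A", "blank", "blank"), times = c(0, 1))
  out2 <- blank_subtract(pl2)
  expect_equal(unname(out2$wells[, "s1"]), c(8, 7))

  # zero blanks leave traces unchanged
  w3 <- cbind(s1 = c(2, 4), b1 = c(0, 0))
  pl3 <- toy_plate(w3, c("sample", "blank"), c("A", "blank"), c(0, 1))
  expect_equal(blank_subtract(pl3)$wells[, "s1"], pl3$wells[, "s1"])
})

test_that("plates without blanks are rejected at construction", {
  expect_error(
    tht_plate(c(0, 1), cbind(s1 = c(0, 1)),
              data.frame(well = "s1", role = "sample", condition = "A")),
    "blank")
})

test_that("normalization divides replicates by the max of their mean trace", {
  # replicate means ramp to 8 and 12; mean trace ramps to 10
  w <- cbind(s1 = c(0, 4, 8), s2 = c(0, 6, 12), b1 = c(0, 0, 0))
  pl <- toy_plate(w, c("sample", "sample", "blank"), c("A", "A", "blank"))
  out <- normalize_plate(blank_subtract(pl))
  expect_equal(unname(out$wells[, "s1"]), c(0, 4, 8) / 10)
  expect_equal(unname(out$wells[, "s2"]), c(0, 6, 12) / 10)
  # the condition-mean trace plateaus at exactly 1
  expect_equal(max(rowMeans(out$wells[, c("s1", "s2")])), 1)

  # idempotent
  out2 <- normalize_plate(out)
  expect_equal(out2$wells, out$wells)

  # single well: plain division by its max
  w3 <- cbind(s1 = c(0, 100, 200), b1 = c(0, 0, 0))
  pl3 <- toy_plate(w3, c("sample", "blank"), c("A", "blank"))
  expect_equal(unname(normalize_plate(blank_subtract(pl3))$wells[, "s1"]),
               c(0, 0.5, 1))
})

test_that("pipeline output is invariant under a constant plate offset", {
  pl <- gen_tht_plate(seed = 5, conditions = list(
    A = list(rates = macro_rates(0.05, 2), n_replicates = 3)))
  pl_off <- pl
  pl_off$wells <- pl$wells + 1234
  a <- normalize_plate(blank_subtract(pl))
  b <- normalize_plate(blank_subtract(pl_off))
  keep <- a$layout$well[a$layout$role != "blank"]
  expect_equal(a$wells[, keep], b$wells[, keep], tolerance = 1e-12)
})

test_that("activity calls combine fold-change thresholds with the rank test", {
  mk <- function(t50s_a, t50s_b) {
    # synthesize wells whose half-times are exactly as requested
    times <- seq(0, 30, by = 0.05)
    mkw <- function(t50) pmin(pmax((times - t50) * 5 + 0.5, 0), 1)
    w <- cbind(sapply(t50s_a, mkw), sapply(t50s_b, mkw),
               blank = rep(0, length(times)))
    colnames(w) <- c(paste0("c", seq_along(t50s_a)),
                     paste0("k", seq_along(t50s_b)), "b1")
    pl <- toy_plate(w, c(rep("sample", length(t50s_a)),
                         rep("control_no_compound", length(t50s_b)), "blank"),
                    c(rep("cmp", length(t50s_a)),
                      rep("ctrl", length(t50s_b)), "blank"),
                    times = times)
    pl$blank_subtracted <- TRUE
    call_activity(normalize_plate(pl), "cmp", "ctrl")
  }
  # identical groups: fold-change 1, inactive
  same <- mk(c(10, 10, 10), c(10, 10, 10))
  expect_equal(same$fold_change, 1.0, tolerance = 1e-6)
  expect_false(same$active)
  expect_equal(same$direction, "none")
  # 1.5x slower: inhibitor direction (p at n=3 cannot reach 1e-4)
  inh <- mk(c(15, 15, 15), c(10, 10, 10))
  expect_equal(inh$fold_change, 1.5, tolerance = 1e-6)
  expect_equal(inh$direction, "inhibitor")
  # 0.7x faster: accelerator direction
  acc <- mk(c(7, 7, 7), c(10, 10, 10))
  expect_equal(acc$fold_change, 0.7, tolerance = 1e-6)
  expect_equal(acc$direction, "accelerator")
  # reciprocity of the fold-change
  expect_equal(inh$fold_change * mk(c(10, 10, 10), c(15, 15, 15))$fold_change,
               1, tolerance = 1e-9)
})

test_that("wells without a half-time are excluded; empty groups give no-call", {
  times <- seq(0, 20, by = 0.1)
  rise <- pmin(pmax(times - 5, 0) / 2, 1)
  dead <- rep(0, length(times))  # failed well: no signal, no plateau
  w <- cbind(c1 = rise, c2 = dead, k1 = rise, k2 = rise, b1 = dead)
  pl <- toy_plate(w, c("sample", "sample", "control_no_compound",
                       "control_no_compound", "blank"),
                  c("cmp", "cmp", "ctrl", "ctrl", "blank"), times)
  pl$blank_subtracted <- TRUE
  pl$normalized <- TRUE
  cl <- call_activity(pl, "cmp", "ctrl")
  expect_equal(cl$excluded, "c2")
  expect_equal(cl$status, "ok")
  expect_equal(cl$fold_change, 1, tolerance = 1e-9)

  # every compound well failed -> explicit no-call
  pl$wells[, "c1"] <- dead
  nc <- call_activity(pl, "cmp", "ctrl")
  expect_equal(nc$status, "no_call")
  expect_true(is.na(nc$active))
})

test_that("endpoint intensities report plateau mean, SEM and settledness", {
  times <- seq(0, 10, by = 0.1)
  plateau_trace <- function(end) pmin(times / 2, 1) * end
  w <- cbind(a1 = plateau_trace(0.8), a2 = plateau_trace(0.9),
             a3 = plateau_trace(1.0), r1 = times / 10, b1 = 0 * times)
  pl <- toy_plate(w, c(rep("sample", 4), "blank"),
                  c("A", "A", "A", "ramp", "blank"), times)
  pl$blank_subtracted <- TRUE; pl$normalized <- TRUE
  expect_warning(ep <- endpoint_intensity(pl), "ramp")
  a <- ep[ep$condition == "A", ]
  expect_equal(a$endpoint, 0.9, tolerance = 1e-9)
  expect_equal(a$endpoint_sem, 0.1 / sqrt(3), tolerance = 1e-9)
  expect_true(a$plateau)
  expect_false(ep$plateau[ep$condition == "ramp"])
})

test_that("generator-identical groups are called inactive almost always", {
  n_active <- 0
  for (s in 1:25) {
    pl <- gen_tht_plate(seed = 1000 + s, conditions = list(
      ctrl = list(rates = macro_rates(0.04, 2), n_replicates = 12,
                  role = "control_no_compound"),
      cmp = list(rates = macro_rates(0.04, 2), n_replicates = 12)))
    cl <- call_activity(normalize_plate(blank_subtract(pl)), "cmp", "ctrl")
    if (isTRUE(cl$active)) n_active <- n_active + 1
  }
  expect_lte(n_active, 1)  # >= 96% inactive
})
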