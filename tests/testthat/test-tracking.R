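# Assignment solver, gated matching, fate labels and remodeling summaries
# on directly constructed records (no imaging involved).

test_that("optimal assignment matches brute-force enumeration", {
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n, 0, 2), n, n)
    a <- spinemorph:::solve_assignment(cost)
    expect_true(all(sort(a) == 1:n))
    total <- sum(cost[cbind(1:n, a)])
    perms <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    best <- min(vapply(perms(1:n), function(p) sum(cost[cbind(1:n, p)]),
                       numeric(1)))
    expect_equal(total, best, tolerance = 1e-9)
  }
})

test_that("gated matching minimizes total cost including unmatched penalties", {
  set.seed(6)
  gate <- 1
  for (rep in 1:25) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    cost <- matrix(runif(n1 * n2, 0, 2), n1, n2)
    mt <- spinemorph:::gated_match(cost, gate)
    if (nrow(mt$pairs)) expect_true(all(cost[mt$pairs] <= gate))
    oracle <- oracle_gated_match(cost, gate)
    expect_equal(match_cost_total(mt, cost, gate), oracle$total,
                 tolerance = 1e-9)
  }
})

test_that("crossing spines resolve to the minimum-cost assignment", {
  # two spines 0.4 um apart whose jitter crosses their naive nearest match
  a <- data.frame(id = 1:2, arclength = c(5.0, 5.4), azimuth = c(0, 0),
                  length = 1, head_width = 0.5, neck_width = 0.2,
                  head_volume = 0.1, class = "mushroom",
                  attach_x = 0, attach_y = 0, attach_z = 0)
  b <- a
  b$arclength <- c(5.45, 5.05)   # closer to each other's origin
  cost <- abs(outer(a$arclength, b$arclength, "-"))
  mt <- spinemorph:::gated_match(cost, 1)
  oracle <- oracle_gated_match(cost, 1)
  expect_equal(match_cost_total(mt, cost, 1), oracle$total, tolerance = 1e-12)
})

test_that("fate labels follow presence at the series ends", {
  expect_identical(assign_fates(0, 12, 13), "stable")
  expect_identical(assign_fates(0, 5, 13), "pruned")
  expect_identical(assign_fates(3, 12, 13), "new")
  expect_identical(assign_fates(3, 8, 13), "transient")
})

# construct a tracked series from synthetic record tables
make_records <- function(arcs, classes) {
  data.frame(id = seq_along(arcs), arclength = arcs,
             azimuth = rep(0, length(arcs)),
             length = ifelse(classes == "stubby", 0.8,
                             ifelse(classes == "thin", 2.5, 1.5)),
             head_width = ifelse(classes == "mushroom", 0.6, 0.3),
             neck_width = ifelse(classes == "stubby", 0.28, 0.2),
             head_volume = 0.1, class = classes,
             attach_x = arcs, attach_y = 0, attach_z = 0)
}

test_that("transition fractions, incidence and accounting identities", {
  # 10 thin at t0: 4 morph to mushroom, 3 pruned, 3 stay thin
  arcs <- seq(2, 29, by = 3)
  t0 <- make_records(arcs, rep("thin", 10))
  t1 <- make_records(arcs[1:7], c(rep("mushroom", 4), rep("thin", 3)))
  tk <- track_spines(list(t0, t1), gate = 1)
  expect_equal(nrow(tk$tracks), 10)
  expect_equal(sum(tk$tracks$fate == "stable"), 7)
  expect_equal(sum(tk$tracks$fate == "pruned"), 3)

  tr <- transitions(tk)
  expect_equal(unname(tr$by_class["thin", ]), c(0, 0.4, 0.3, 0.3))
  expect_equal(sum(tr$by_class["thin", ]), 1, tolerance = 1e-9)
  expect_true(all(is.na(tr$by_class["mushroom", ])))   # undefined, not zero
  expect_true(all(is.na(tr$by_class["stubby", ])))
  expect_equal(sum(tr$incidence, na.rm = TRUE), 1, tolerance = 1e-9)

  # accounting identities
  n0 <- sum(tk$tracks$first_t == 0)
  nE <- sum(tk$tracks$last_t == 1)
  expect_equal(n0, sum(tk$tracks$fate %in% c("stable", "pruned")))
  expect_equal(nE, sum(tk$tracks$fate %in% c("stable", "new")))
})

test_that("all-stable constant-class series gives a diagonal summary", {
  arcs <- seq(2, 20, by = 3)
  cls <- rep(c("stubby", "mushroom", "thin"), length.out = length(arcs))
  recs <- replicate(4, make_records(arcs, cls), simplify = FALSE)
  tk <- track_spines(recs, gate = 1)
  expect_true(all(tk$tracks$fate == "stable"))
  tr <- transitions(tk)
  expect_equal(unname(tr$by_class["stubby", "to_stubby"]), 1)
  expect_equal(unname(tr$by_class["mushroom", "to_mushroom"]), 1)
  expect_equal(unname(tr$by_class["thin", "to_thin"]), 1)
  expect_true(all(tr$by_class[, "pruned"] == 0))
})

test_that("mid-series appearances close as transient and open as new", {
  arcs <- c(3, 7, 11)
  r_full <- make_records(arcs, rep("thin", 3))
  r_mid <- make_records(c(arcs, 15), rep("thin", 4))
  recs <- list(r_full, r_mid, r_mid, r_full, r_full)
  tk <- track_spines(recs, gate = 1)
  expect_equal(sum(tk$tracks$fate == "transient"), 1)
  expect_equal(sum(tk$tracks$fate == "stable"), 3)
})

test_that("fate-group geometry reports group means of initial geometry", {
  arcs <- seq(2, 17, by = 3)
  t0 <- make_records(arcs, rep("mushroom", 6))
  t0$neck_width <- c(0.35, 0.25, 0.35, 0.25, 0.35, 0.25)
  t1 <- make_records(arcs[c(1, 3, 5)], rep("mushroom", 3))
  tk <- track_spines(list(t0, t1), gate = 1)
  fg <- fate_group_geometry(tk, "mushroom")
  expect_setequal(fg$group, c("stable", "pruned"))
  expect_equal(fg$n[fg$group == "stable"], 3)
  expect_equal(fg$neck_width[fg$group == "stable"], 0.35)
  expect_equal(fg$neck_width[fg$group == "pruned"], 0.25)
  expect_equal(fg$head_neck_ratio[fg$group == "stable"], 0.6 / 0.35)

  # identical geometries -> identical group means
  t0b <- make_records(arcs, rep("thin", 6))
  tkb <- track_spines(list(t0b, t0b), gate = 1)
  fgb <- fate_group_geometry(tkb, "thin")
  expect_equal(nrow(fgb), 1)
  expect_equal(fgb$group, "stable")
  expect_equal(fgb$head_neck_ratio, 0.3 / 0.2)
})
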