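test_that("the location schedule uses left-open intervals", {
  pr <- protocol_preset("four_3min")
  expect_equal(location_at(0, pr), c(-7e-3, 7e-3, 10e-3))
  expect_equal(location_at(180, pr), c(-7e-3, 7e-3, 10e-3))   # t1 -> P1
  expect_equal(location_at(200, pr), c(7e-3, 7e-3, 10e-3))    # (t1,t2] -> P2
  expect_equal(location_at(540, pr), c(-7e-3, -7e-3, 10e-3))  # t3 -> P3
  expect_equal(location_at(720, pr), c(7e-3, -7e-3, 10e-3))
  expect_error(location_at(721, pr), "schedule")
})

test_that("protocols enforce spacing and contiguous intervals", {
  expect_error(ablation_protocol(rbind(c(0, 0, 0.01), c(5e-3, 0, 0.01)),
                                 c(60, 60)), "spacing")
  pr <- protocol_preset("three_5min")
  expect_equal(nrow(pr$positions), 3)
  expect_gte(min(stats::dist(pr$positions)), 14e-3 - 1e-9)
  expect_equal(pr$t_bounds, c(300, 600, 900))
  expect_error(ablation_protocol(matrix(c(0, 0, 0.01), 1), -5), "positive")
})

test_that("damage report arithmetic matches the percent-killed definition", {
  fake <- structure(list(
    protocol = list(label = "fake"),
    accounting = list(ablation_cm3 = 33.7, healthy_damage_cm3 = 1.8,
                      remaining_tumor_cm3 = 1.55, tumor_cm3 = 33.5,
                      pct_tumor_killed = 100 * (33.5 - 1.55) / 33.5)),
    class = "abl_run_result")
  rep_ <- damage_report(fake)
  expect_equal(rep_$pct_tumor_killed, 95.37, tolerance = 1e-3)  # prints 95.5
  expect_equal(nrow(damage_report(list())), 0)
})

# one tiny shared phantom for the protocol behaviour tests
coarse_run <- local({
  cache <- new.env()
  function(power, durations = c(30, 30), dt = 10) {
    key <- paste(power, paste(durations, collapse = "_"), dt)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pos <- rbind(c(-7e-3, 7e-3, 10e-3), c(7e-3, -7e-3, 10e-3))
    pos <- pos[seq_along(durations), , drop = FALSE]
    pr <- ablation_protocol(pos, durations, power = power,
                            min_spacing = 10e-3)
    res <- run_protocol(pr, spec = geometry_spec(scale = 5), dt = dt,
                        verbose = FALSE)
    cache[[key]] <- res
    res
  }
})

test_that("zero input power relaxes to the metabolic equilibrium", {
  res <- coarse_run(0, durations = c(600, 600), dt = 50)
  target <- 37 + 33800 / (1058 * 0.0036 * 3600)
  tis <- unique(as.vector(res$mesh$tets[res$mesh$region %in%
                                          c("liver", "tumor"), ]))
  expect_lt(max(abs(res$final_T[tis] - target)), 0.6)
  expect_equal(res$accounting$ablation_cm3, 0)
})

test_that("heating concentrates near the antenna slot and tip", {
  res <- coarse_run(50)
  imax <- which.max(res$final_T)
  p <- res$mesh$vertices[imax, ]
  pos2 <- res$protocol$positions[2, ]   # last heated position
  rxy <- sqrt(sum((p[1:2] - pos2[1:2])^2))
  expect_lt(rxy, 8e-3)                  # laterally close to the shaft
  expect_lt(p[3], pos2[3] + 8e-3)       # not beyond the tip
  expect_gt(p[3], pos2[3] - 15e-3)      # within the slot/tip band
})

test_that("probe temperatures zig-zag across position switches", {
  res <- coarse_run(50)
  # probe 1 belongs to position 1 (3 mm offset): it heats during interval 1
  # and cools once the antenna moves away
  i1 <- res$times <= 30; i2 <- res$times > 30
  T1 <- res$probe_T[, 1]
  expect_gt(T1[sum(i1)] , T1[1])                  # rising while heated
  expect_lt(T1[length(T1)], T1[sum(i1)])          # falling after the switch
  # and the far position probe does the opposite
  Tfar <- res$probe_T[, 3]
  expect_gt(Tfar[length(Tfar)], Tfar[sum(i1)])
})

test_that("ablated volume is non-decreasing over the protocol", {
  res <- coarse_run(50)
  expect_true(all(diff(res$interval_summaries$ablation_cm3) >= -1e-12))
})

test_that("run outputs are written as VTU, CSV and JSON", {
  res <- coarse_run(50)
  dir <- tempfile("ablrun")
  paths <- write_run_outputs(res, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["damage"]])
  expect_true(is.numeric(js$ablation_cm3) || is.numeric(js$ablation_cm3[[1]]))
  pt <- utils::read.csv(paths[["probes"]])
  expect_equal(nrow(pt), length(res$times))
  vt <- readLines(paths[["vtu"]], n = 3)
  expect_match(vt[2], "UnstructuredGrid")
  unlink(dir, recursive = TRUE)
})
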