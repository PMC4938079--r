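## small hand-built measurement set with distinct heart rates
toy_set <- function(hr = c(60, 62, 64)) {
  mk <- function(hr, quantity, lvl) {
    Tp <- 60 / hr
    t <- Tp * (0:31) / 32
    waveform(t, lvl * (1 + 0.3 * sin(2 * pi * t / Tp)), quantity,
             period = Tp)
  }
  measurement_set(
    flows = list(`Asc Ao` = mk(hr[1], "flow", 9e-5),
                 `Desc Ao 1` = mk(hr[2], "flow", 6e-5)),
    areas = list(`Asc Ao` = mk(hr[3], "area", 5e-4)),
    pressures = list(Carotid = mk(hr[1], "pressure", 1e4))
  )
}

test_that("heart-rate harmonization averages, rescales and is idempotent", {
  ms <- toy_set()
  h <- harmonize_heart_rate(ms)
  expect_equal(h$heart_rate, mean(c(60, 62, 64, 60)))
  hrs <- vapply(c(h$set$flows, h$set$areas, h$set$pressures),
                waveform_heart_rate, numeric(1))
  expect_equal(unname(hrs), rep(h$heart_rate, 4), tolerance = 1e-12)
  ## cycle means survive the affine retiming exactly
  expect_equal(waveform_mean(h$set$flows[[1]]),
               waveform_mean(ms$flows[[1]]), tolerance = 1e-12)
  ## idempotent
  h2 <- harmonize_heart_rate(h$set)
  expect_equal(h2$heart_rate, h$heart_rate)
  expect_equal(h2$set$flows[[1]]$times, h$set$flows[[1]]$times,
               tolerance = 1e-12)
  ## already-harmonized input is untouched
  ms3 <- toy_set(hr = c(61, 61, 61))
  h3 <- harmonize_heart_rate(ms3)
  expect_equal(h3$set$flows[[1]]$times, ms3$flows[[1]]$times,
               tolerance = 1e-12)
})

test_that("the emulated session reproduces the per-modality heart rates", {
  hs <- heart_rate_summary(pw_session())
  expect_equal(hs$mean_bpm[hs$modality == "flow"], 61.5, tolerance = 1e-6)
  expect_equal(hs$sd_bpm[hs$modality == "flow"], 3.4, tolerance = 1e-6)
  expect_equal(hs$mean_bpm[hs$modality == "area"], 65.2, tolerance = 1e-6)
  expect_equal(hs$sd_bpm[hs$modality == "area"], 1.5, tolerance = 1e-6)
  expect_equal(hs$mean_bpm[hs$modality == "pressure"], 59.3,
               tolerance = 1e-6)
  expect_equal(hs$sd_bpm[hs$modality == "pressure"], 2.4,
               tolerance = 1e-6)
})

test_that("geometry rescaling matches measured areas and touches only radii", {
  net <- make_upper_aorta_network()
  ## identity when the measured areas equal the model areas
  sites <- c("Asc Ao", "Desc Ao 1", "Desc Ao 2", "Desc Ao 3", "Desc Ao 4")
  Ad_model <- vapply(sites, function(s) {
    loc <- plane_location(net, s)
    pulsewave:::segment_material_at(net, loc$segment, loc$frac)$Ad
  }, numeric(1))
  net_id <- rescale_geometry(net, Ad_model)
  expect_equal(net_id$segments$r_in, net$segments$r_in, tolerance = 1e-12)
  ## a single 1.21 area factor at one plane scales the local radius by 1.1
  Ad2 <- Ad_model
  Ad2[["Desc Ao 2"]] <- 1.21 * Ad_model[["Desc Ao 2"]]
  net2 <- rescale_geometry(net, Ad2)
  i12 <- match(12L, net2$segments$id)
  expect_rel_equal(net2$segments$r_out[i12],
                   1.1 * net$segments$r_out[i12], 1e-9)
  ## between plane factors 1.0 and 1.21 the interpolated factor is strictly
  ## intermediate (segment 10 ends between the two planes)
  i10 <- match(10L, net$segments$id)
  f10 <- (net2$segments$r_out[i10] / net$segments$r_out[i10])^2
  expect_gt(f10, 1); expect_lt(f10, 1.21)
  ## lengths and wave speeds are untouched
  expect_equal(net2$segments$length, net$segments$length)
  expect_equal(net2$segments$c_in, net$segments$c_in)
  expect_error(rescale_geometry(net, -Ad_model), "non-positive")
})

test_that("flow fractions follow the descending-mean rule and sum to one", {
  mk <- function(lvl) {
    t <- (0:31) / 32
    waveform(t, lvl * (1 + 0.5 * sin(2 * pi * t)), "flow", period = 1)
  }
  ms <- measurement_set(
    flows = list(`Asc Ao` = mk(100e-6), `Desc Ao 1` = mk(60e-6),
                 `Desc Ao 2` = mk(64e-6), `Desc Ao 3` = mk(63e-6),
                 `Desc Ao 4` = mk(62e-6)),
    priors = c(`22` = 1, `24` = 1, `26` = 1)
  )
  g <- compute_flow_fractions(ms)
  ## (60 + 64 + 63 + 62)/4 / 100 = 0.6225; equal branch split of the rest
  expect_equal(unname(g[["20"]]), 0.6225, tolerance = 1e-12)
  expect_equal(unname(g[["22"]]), (1 - 0.6225) / 3, tolerance = 1e-12)
  expect_equal(sum(g), 1, tolerance = 1e-12)
  ## identical descending means reduce to the single-plane ratio
  ms2 <- measurement_set(flows = list(`Asc Ao` = mk(100e-6),
                                      `Desc Ao 1` = mk(70e-6),
                                      `Desc Ao 2` = mk(70e-6)),
                         priors = c(`22` = 1, `24` = 1, `26` = 1))
  expect_equal(unname(compute_flow_fractions(ms2)[["20"]]), 0.7,
               tolerance = 1e-12)
  ## random admissible inputs always sum to 1
  set.seed(3)
  for (i in 1:20) {
    qasc <- stats::runif(1, 80, 120) * 1e-6
    qd <- stats::runif(4, 0.5, 0.95) * qasc
    msr <- measurement_set(
      flows = c(list(`Asc Ao` = mk(qasc)),
                stats::setNames(lapply(qd, mk),
                                paste("Desc Ao", 1:4))),
      priors = stats::setNames(stats::runif(3), c("22", "24", "26")))
    expect_equal(sum(compute_flow_fractions(msr)), 1, tolerance = 1e-12)
  }
  ## a descending mean far above the ascending mean is unphysical
  ms_bad <- measurement_set(flows = list(`Asc Ao` = mk(100e-6),
                                         `Desc Ao 1` = mk(120e-6)),
                            priors = c(`22` = 1, `24` = 1, `26` = 1))
  expect_error(compute_flow_fractions(ms_bad), "unphysical")
})
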